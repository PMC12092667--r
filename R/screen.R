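#' Gene phenotypes as median sgRNA log2 fold changes
#'
#' The gene phenotype is the median log2 fold change of the gene's
#' surviving sgRNAs (for an even count, the mean of the central pair).
#'
#' @param lfc numeric vector of sgRNA log2 fold changes.
#' @param gene gene label per sgRNA.
#' @return named numeric vector of per-gene medians.
#' @export
gene_phenotype <- function(lfc, gene) {
  stopifnot(length(lfc) == length(gene))
  vapply(split(lfc, gene), median, 0)
}

#' Fit the sorted-vs-bulk screen enrichment model
#'
#' The central fitting function of the package.  Starting from a raw
#' sgRNA count table it (1) median-normalizes samples, (2) computes
#' per-sgRNA log2 fold changes and two-sided negative-binomial p-values
#' for the treatment-vs-control contrast ([sgrna_stats()]), (3) summarises
#' genes by their median sgRNA LFC ([gene_phenotype()]), and (4) scores
#' genes by alpha-RRA with permutation p-values in both directions --
#' depletion and enrichment are separate one-sided analyses
#' ([alpha_rra()]).  The default contrast is the sorted
#' (reporter-positive) population against the day-13 dox-treated bulk;
#' set `ctrl_role = "day0"` for the day-0 comparison.
#'
#' @param counts raw count table (data.frame with `sgRNA`, `gene` and one
#'   column per sample) or a `sim_screen` object.
#' @param roles named character vector mapping sample to role; taken from
#'   the `sim_screen` object if omitted.
#' @param treat_role,ctrl_role contrast roles (defaults `sorted` vs
#'   `bulk_dox`).
#' @param alpha alpha-RRA screen fraction (default 0.25).
#' @param n_perm permutations for the RRA null (default 2000).
#' @param pseudocount LFC pseudocount (default 0.5).
#' @param seed permutation seed.
#' @return An object of class `rra_screen` with components `genes`
#'   (data.frame: `gene`, `phenotype`, `rho`, `p_depleted`, `p_enriched`,
#'   `fdr`, `n_sgRNAs`), `sgrnas` (per-sgRNA statistics), `size_factors`,
#'   `dispersion` and the call.  Methods: `print`, `summary`, `plot`,
#'   `coef` (gene phenotypes), `as.data.frame`.
#' @export
rra_screen <- function(counts, roles = NULL, treat_role = "sorted",
                       ctrl_role = "bulk_dox", alpha = 0.25,
                       n_perm = 2000L, pseudocount = 0.5, seed = 1L) {
  if (inherits(counts, "sim_screen")) {
    if (is.null(roles)) roles <- counts$roles
    counts <- counts$counts
  }
  if (is.null(roles)) stop("sample roles are required")
  norm <- median_normalize(counts)
  sg <- sgrna_stats(norm, roles, treat_role, ctrl_role, pseudocount)

  pheno <- gene_phenotype(sg$lfc, sg$gene)
  dep <- alpha_rra(sg$lfc, sg$gene, alpha = alpha, n_perm = n_perm,
                   seed = seed, direction = "depletion")
  enr <- alpha_rra(sg$lfc, sg$gene, alpha = alpha, n_perm = n_perm,
                   seed = seed + 1L, direction = "enrichment")

  g <- dep[, c("gene", "n_sgRNAs")]
  g$phenotype <- unname(pheno[g$gene])
  g$rho_depleted <- dep$rho
  g$p_depleted <- dep$p
  idx <- match(g$gene, enr$gene)
  g$rho_enriched <- enr$rho[idx]
  g$p_enriched <- enr$p[idx]
  ## one-sided tests in both directions: the reported rho follows the more
  ## significant direction, the FDR adjusts the doubled smaller p
  better_dep <- g$p_depleted <= g$p_enriched
  g$rho <- ifelse(better_dep, g$rho_depleted, g$rho_enriched)
  g$fdr <- p.adjust(pmin(1, 2 * pmin(g$p_depleted, g$p_enriched)), "BH")
  g <- g[order(pmin(g$p_depleted, g$p_enriched), g$rho),
         c("gene", "phenotype", "rho", "p_depleted", "p_enriched", "fdr",
           "n_sgRNAs", "rho_depleted", "rho_enriched")]
  rownames(g) <- NULL

  structure(list(genes = g, sgrnas = sg,
                 size_factors = attr(norm, "size_factors"),
                 dispersion = attr(sg, "dispersion"),
                 roles = roles, alpha = alpha, n_perm = n_perm,
                 treat_role = treat_role, ctrl_role = ctrl_role,
                 seed = seed, call = match.call()),
            class = "rra_screen")
}

#' @export
print.rra_screen <- function(x, n = 10, ...) {
  cat("alpha-RRA screen fit:", x$treat_role, "vs", x$ctrl_role,
      sprintf("(alpha = %g, %d permutations)\n", x$alpha, x$n_perm))
  cat(sprintf("  %d genes, %d sgRNAs tested; pooled NB dispersion %.4f\n",
              nrow(x$genes), nrow(x$sgrnas), x$dispersion))
  cat("  top genes:\n")
  print(head(x$genes[, 1:7], n), digits = 4)
  invisible(x)
}

#' @export
summary.rra_screen <- function(object, fdr_cutoff = 0.05, ...) {
  g <- object$genes
  hits_dep <- g$gene[g$fdr < fdr_cutoff & g$p_depleted <= g$p_enriched]
  hits_enr <- g$gene[g$fdr < fdr_cutoff & g$p_enriched < g$p_depleted]
  out <- list(n_genes = nrow(g), n_sgrnas = nrow(object$sgrnas),
              size_factors = object$size_factors,
              dispersion = object$dispersion, fdr_cutoff = fdr_cutoff,
              depleted_hits = hits_dep, enriched_hits = hits_enr,
              genes = g)
  class(out) <- "summary.rra_screen"
  out
}

#' @export
print.summary.rra_screen <- function(x, ...) {
  cat(sprintf("rra_screen: %d genes / %d sgRNAs\n", x$n_genes, x$n_sgrnas))
  cat("  size factors:", paste(sprintf("%s=%.3f", names(x$size_factors),
                                       x$size_factors), collapse = ", "), "\n")
  cat(sprintf("  %d depleted and %d enriched hits at FDR < %g\n",
              length(x$depleted_hits), length(x$enriched_hits),
              x$fdr_cutoff))
  if (length(x$depleted_hits))
    cat("  depleted:", paste(head(x$depleted_hits, 10), collapse = ", "), "\n")
  if (length(x$enriched_hits))
    cat("  enriched:", paste(head(x$enriched_hits, 10), collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.rra_screen <- function(object, ...) {
  setNames(object$genes$phenotype, object$genes$gene)
}

#' @export
as.data.frame.rra_screen <- function(x, ...) x$genes

#' Volcano plot of gene phenotypes
#'
#' Gene phenotype (median sgRNA LFC) against -log10 of the smaller
#' one-sided permutation p-value.
#'
#' @param x an `rra_screen` fit.
#' @param fdr_cutoff genes below this FDR are highlighted and labelled.
#' @param ... passed to [plot()].
#' @export
plot.rra_screen <- function(x, fdr_cutoff = 0.05, ...) {
  g <- x$genes
  pmin_ <- pmin(g$p_depleted, g$p_enriched)
  sig <- g$fdr < fdr_cutoff
  plot(g$phenotype, -log10(pmin_), pch = 16,
       col = ifelse(sig, "firebrick", "grey50"),
       xlab = expression(median ~ log[2] ~ "fold change (gene phenotype)"),
       ylab = expression(-log[10] ~ "permutation p"), ...)
  if (any(sig))
    text(g$phenotype[sig], -log10(pmin_)[sig], g$gene[sig],
         pos = 3, cex = 0.7)
  invisible(x)
}

#' Screen quality control
#'
#' Reports the median day-13-vs-day-0 log2 fold change of essential genes
#' against non-targeting controls (essential dropout indicates effective
#' knockdown) and the Pearson correlation between replicate sgRNA LFC
#' vectors, flagging correlations below the conventional 0.7 threshold.
#'
#' @param counts count table or `sim_screen` object.
#' @param essential character vector of essential gene names.
#' @param lfc_rep1,lfc_rep2 per-replicate sgRNA LFC vectors to correlate;
#'   if omitted they are computed from day-13 bulk vs day-0 per replicate.
#' @param roles sample roles (taken from a `sim_screen` if omitted).
#' @return list of class `screen_qc`: `essential_median_lfc`,
#'   `nontargeting_median_lfc`, `replicate_r`, `r_flag`.
#' @export
screen_qc <- function(counts, essential, lfc_rep1 = NULL, lfc_rep2 = NULL,
                      roles = NULL) {
  if (inherits(counts, "sim_screen")) {
    if (is.null(roles)) roles <- counts$roles
    counts <- counts$counts
  }
  norm <- median_normalize(counts)
  parts <- split_count_table(norm)
  d0 <- names(roles)[roles == "day0"]
  bk <- names(roles)[roles == "bulk_dox"]
  if (is.null(lfc_rep1) || is.null(lfc_rep2)) {
    if (length(d0) < 2 || length(bk) < 2)
      stop("need two replicates of day0 and bulk_dox (or explicit LFC vectors)")
    lfc_rep1 <- log2((parts$m[, bk[1]] + 0.5) / (parts$m[, d0[1]] + 0.5))
    lfc_rep2 <- log2((parts$m[, bk[2]] + 0.5) / (parts$m[, d0[2]] + 0.5))
  }
  lfc <- (lfc_rep1 + lfc_rep2) / 2
  ess <- parts$meta$gene %in% essential
  nt <- parts$meta$gene == "NONTARGETING"
  r <- cor(lfc_rep1, lfc_rep2)
  out <- list(essential_median_lfc = median(lfc[ess]),
              nontargeting_median_lfc = median(lfc[nt]),
              replicate_r = r, r_flag = r < 0.7)
  class(out) <- "screen_qc"
  out
}

#' @export
print.screen_qc <- function(x, ...) {
  cat("Screen QC\n")
  cat(sprintf("  essential median LFC (day13 vs day0): %.3f\n",
              x$essential_median_lfc))
  cat(sprintf("  non-targeting median LFC:             %.3f\n",
              x$nontargeting_median_lfc))
  cat(sprintf("  replicate Pearson r: %.3f%s\n", x$replicate_r,
              if (x$r_flag) "  [FLAG: r < 0.7]" else ""))
  invisible(x)
}
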