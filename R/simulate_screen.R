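#' Specify a CRISPRi screen library and gene-effect model
#'
#' Mirrors the composition of a focused CRISPRi library: `n_genes` genes at
#' `sgrnas_per_gene` sgRNAs each plus non-targeting controls (a typical
#' DNA-repair-focused library: 2015 genes x 5 sgRNAs + 2243 non-targeting
#' controls = 12,318 sgRNAs).  Each gene carries a multiplicative effect on the probability
#' that a cell converts the reporter and is sorted into the outcome-positive
#' population; 1.0 is the null, values below 1 deplete the gene's sgRNAs in
#' the sorted population, values above 1 enrich them.  The baseline sorted
#' fraction `pi0` defaults to 0.132, the observed GFP+ fraction of the
#' C-to-T screen.
#'
#' @param n_genes number of targeted genes (>= 2).
#' @param sgrnas_per_gene sgRNAs per gene (default 5).
#' @param n_nontargeting number of non-targeting control sgRNAs.
#' @param effect named numeric vector of per-gene multipliers on the
#'   reporter-conversion probability; genes not named get 1.0.
#' @param essential character vector of gene names depleted in the day-13
#'   bulk population.
#' @param essential_depletion bulk depletion factor applied to essential
#'   genes by day 13 (default 0.3).
#' @param pi0 baseline sorted (reporter-positive) fraction, in (0, 1).
#' @param skew_sd sdlog of the lognormal library-skew weights (0 = even
#'   library).
#' @return A list of class `library_spec`.
#' @export
library_spec <- function(n_genes, sgrnas_per_gene = 5L, n_nontargeting = 0L,
                         effect = NULL, essential = character(),
                         essential_depletion = 0.3, pi0 = 0.132,
                         skew_sd = 0.5) {
  n_genes <- as.integer(n_genes)
  if (n_genes < 2) stop("n_genes must be >= 2")
  stopifnot(sgrnas_per_gene >= 1, n_nontargeting >= 0,
            essential_depletion > 0, skew_sd >= 0)
  if (pi0 <= 0 || pi0 >= 1) stop("pi0 must be in (0, 1)")
  genes <- sprintf("gene%04d", seq_len(n_genes))
  eff <- setNames(rep(1, n_genes), genes)
  if (!is.null(effect)) {
    bad <- setdiff(names(effect), genes)
    if (length(bad)) stop("unknown gene(s) in effect: ",
                          paste(bad, collapse = ", "))
    if (any(effect < 0)) stop("effect multipliers must be >= 0")
    eff[names(effect)] <- effect
  }
  bad <- setdiff(essential, genes)
  if (length(bad)) stop("unknown essential gene(s): ",
                        paste(bad, collapse = ", "))
  structure(list(n_genes = n_genes,
                 sgrnas_per_gene = as.integer(sgrnas_per_gene),
                 n_nontargeting = as.integer(n_nontargeting),
                 genes = genes, effect = eff, essential = essential,
                 essential_depletion = essential_depletion,
                 pi0 = pi0, skew_sd = skew_sd),
            class = "library_spec")
}

total_sgrnas <- function(lib) {
  lib$n_genes * lib$sgrnas_per_gene + lib$n_nontargeting
}

#' Simulate sgRNA counts for a FACS-sorted CRISPRi screen
#'
#' Generates day-0, day-13 bulk (dox-treated, pre-sort) and sorted
#' (reporter-positive) count tables under a composition-reweighting model.
#' Each sgRNA s of gene g carries a lognormal library weight w_s and a
#' conversion probability pi_s = min(1, pi0 * effect\[g\]); non-targeting
#' controls have effect 1.  Bulk means are depth * w_s (essential genes
#' further multiplied by `essential_depletion`), sorted means are
#' proportional to w_s * pi_s renormalised to the same total depth, and
#' counts are negative-binomial with the configured dispersion (Poisson in
#' the dispersion-to-zero limit).  The truth table records each sgRNA's
#' expected sorted-vs-bulk log2 fold change log2(pi_s / pibar), with pibar
#' the library-weighted mean conversion probability.
#'
#' @param lib a [library_spec()].
#' @param cfg a [sim_config()]; `depth`, `dispersion` and `seed` are used.
#' @param n_replicates replicates per arm (default 2, as screened).
#' @return A list of class `sim_screen`: `counts` (data.frame with columns
#'   `sgRNA`, `gene`, then one integer column per sample), `roles` (named
#'   character vector mapping sample to role `day0`/`bulk_dox`/`sorted`)
#'   and `truth` (per-sgRNA weights, conversion probabilities and expected
#'   LFC).
#' @export
simulate_screen <- function(lib, cfg, n_replicates = 2L) {
  stopifnot(inherits(lib, "library_spec"), inherits(cfg, "sim_config"))
  if (cfg$depth <= 0) stop("sequencing depth must be positive")
  n_replicates <- as.integer(n_replicates)
  with_seed(cfg$seed, {
    gene <- c(rep(lib$genes, each = lib$sgrnas_per_gene),
              rep("NONTARGETING", lib$n_nontargeting))
    sg <- sprintf("sg%05d", seq_along(gene))
    n <- length(sg)

    w <- if (lib$skew_sd > 0) rlnorm(n, 0, lib$skew_sd) else rep(1, n)
    w <- w / mean(w)
    ess <- gene %in% lib$essential
    dfac <- ifelse(ess, lib$essential_depletion, 1)
    eff <- ifelse(gene == "NONTARGETING", 1, lib$effect[gene])
    pi_s <- pmin(1, lib$pi0 * eff)

    mu_day0 <- cfg$depth * w
    mu_bulk <- cfg$depth * w * dfac
    wb <- w * dfac
    mu_sort <- cfg$depth * n * (wb * pi_s) / sum(wb * pi_s)

    rcount <- function(mu) {
      if (cfg$dispersion < 1e-12) rpois(n, mu)
      else rnbinom(n, mu = mu, size = 1 / cfg$dispersion)
    }
    samples <- list()
    roles <- character()
    for (r in seq_len(n_replicates)) {
      samples[[paste0("day0_r", r)]] <- rcount(mu_day0)
      samples[[paste0("bulk_r", r)]] <- rcount(mu_bulk)
      samples[[paste0("sorted_r", r)]] <- rcount(mu_sort)
      roles[paste0("day0_r", r)] <- "day0"
      roles[paste0("bulk_r", r)] <- "bulk_dox"
      roles[paste0("sorted_r", r)] <- "sorted"
    }
    counts <- data.frame(sgRNA = sg, gene = gene, samples,
                         stringsAsFactors = FALSE, check.names = FALSE)
    pibar <- sum(wb * pi_s) / sum(wb)
    truth <- data.frame(sgRNA = sg, gene = gene, weight = w,
                        conversion_prob = pi_s,
                        expected_lfc = log2(pi_s / pibar),
                        essential = ess, stringsAsFactors = FALSE)
    structure(list(counts = counts, roles = roles, truth = truth, lib = lib),
              class = "sim_screen")
  })
}
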