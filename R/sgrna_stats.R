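#' Per-sgRNA log2 fold changes and negative-binomial tests
#'
#' For each sgRNA the log2 fold change between a treatment role (e.g. the
#' sorted, reporter-positive population) and a control role (the day-13
#' bulk) is computed on normalized counts with a pseudocount, averaged
#' over paired replicates.  Two-sided p-values come from a pooled
#' negative-binomial model: a single method-of-moments dispersion is
#' estimated from the non-targeting sgRNAs' within-condition replicate
#' variability (falling back to all sgRNAs when fewer than 10
#' non-targeting guides are present, with a warning), and the summed
#' treatment count is compared with the NB tail probabilities implied by
#' the summed control mean.  The two-sided p is the equal-distance
#' convention around the null mean, so a treatment identical to its
#' control gives p = 1 exactly.
#'
#' With `propagate_control_noise = TRUE` (the default) the null variance
#' additionally carries the sampling noise of the control mean itself,
#' which keeps null p-values approximately uniform when both arms are
#' random; with `FALSE` the test conditions on the control mean as known
#' (the textbook NB tail, whose dispersion-to-zero limit is the Poisson
#' tail).  This is a simplified pooled-dispersion test, not a fitted
#' mean-variance regression.
#'
#' @param norm normalized count table from [median_normalize()].
#' @param roles named character vector mapping sample column to role
#'   (`day0`, `bulk_dox`, `bulk_nodox`, `sorted`).
#' @param treat_role,ctrl_role roles to compare (default `sorted` vs
#'   `bulk_dox`).
#' @param pseudocount added to both sides of the LFC (default 0.5).
#' @param propagate_control_noise include control-mean sampling variance
#'   in the null (default TRUE).
#' @return data.frame: `sgRNA`, `gene`, `lfc`, `treat_mean`, `ctrl_mean`,
#'   `p`, `fdr` (Benjamini-Hochberg across sgRNAs); attribute
#'   `dispersion` carries the pooled estimate.  sgRNAs with a zero count
#'   in any compared sample are removed before testing (logged).
#' @export
sgrna_stats <- function(norm, roles, treat_role = "sorted",
                        ctrl_role = "bulk_dox", pseudocount = 0.5,
                        propagate_control_noise = TRUE) {
  stopifnot(pseudocount > 0)
  parts <- split_count_table(norm)
  tcols <- intersect(colnames(parts$m), names(roles)[roles == treat_role])
  ccols <- intersect(colnames(parts$m), names(roles)[roles == ctrl_role])
  if (!length(tcols) || !length(ccols))
    stop("roles must include at least one '", treat_role, "' and one '",
         ctrl_role, "' sample")
  if (length(tcols) != length(ccols))
    warning("unequal replicate numbers (", length(tcols), " vs ",
            length(ccols), "); proceeding with all samples")
  tm <- parts$m[, tcols, drop = FALSE]
  cm <- parts$m[, ccols, drop = FALSE]

  ## zero-count sgRNAs (zero in any compared sample) are removed
  keep <- rowSums(cbind(tm, cm) == 0) == 0
  if (any(!keep))
    bedit_log("sgrna_stats: removing ", sum(!keep),
              " sgRNA(s) with a zero count in a compared sample")
  tm <- tm[keep, , drop = FALSE]; cm <- cm[keep, , drop = FALSE]
  meta <- parts$meta[keep, , drop = FALSE]

  nrep <- min(ncol(tm), ncol(cm))
  lfc <- rowMeans(log2((tm[, seq_len(nrep), drop = FALSE] + pseudocount) /
                         (cm[, seq_len(nrep), drop = FALSE] + pseudocount)))

  disp <- pooled_dispersion(list(tm, cm), meta$gene)

  kt <- ncol(tm); kc <- ncol(cm)
  tsum <- round(rowSums(tm))
  cmu <- rowSums(cm) * kt / kc              # control mean on the treat scale
  size <- if (propagate_control_noise) {
    ## null variance of the treat sum given a noisy control mean:
    ## M*(1 + kt/kc) + phi*M^2*(1/kt + 1/kc), matched by an NB size
    1 / ((kt / kc) / cmu + disp * (1 / kt + 1 / kc))
  } else rep(kt / max(disp, 1e-10), length(cmu))

  ## equal-distance two-sided tail around the null mean
  d <- abs(tsum - cmu)
  plo <- pnbinom(floor(cmu - d), mu = cmu, size = size)
  pup <- pnbinom(ceiling(cmu + d) - 1, mu = cmu, size = size,
                 lower.tail = FALSE)
  p <- pmin(1, plo + pup)

  out <- data.frame(sgRNA = meta$sgRNA, gene = meta$gene, lfc = lfc,
                    treat_mean = rowMeans(tm), ctrl_mean = rowMeans(cm),
                    p = p, fdr = p.adjust(p, "BH"),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "dispersion") <- disp
  out
}

## method-of-moments NB dispersion, pooled over non-targeting sgRNAs'
## within-condition replicate variability; phi solves var = mu + phi*mu^2
pooled_dispersion <- function(mats, gene, min_nt = 10L) {
  if (is.matrix(mats)) mats <- list(mats)
  nt <- which(gene == "NONTARGETING")
  if (length(nt) < min_nt) {
    warning("fewer than ", min_nt, " non-targeting sgRNAs; ",
            "estimating dispersion from all sgRNAs")
    nt <- seq_len(nrow(mats[[1]]))
  }
  ## pooled ratio estimator: sum(v - mu) / sum(mu^2) over sgRNAs solves
  ## E[v] = mu + phi*mu^2 without the small-replicate bias a per-sgRNA
  ## median would carry
  num <- den <- 0
  for (m in mats) {
    if (ncol(m) < 2) next
    mu <- rowMeans(m[nt, , drop = FALSE])
    v <- apply(m[nt, , drop = FALSE], 1, var)
    ok <- mu > 0
    num <- num + sum(v[ok] - mu[ok])
    den <- den + sum(mu[ok]^2)
  }
  if (den == 0) return(0.1)
  max(num / den, 0)
}
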