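#' Z-score of an editing efficiency against non-targeting controls
#'
#' z = (x - mu) / sigma, where mu and sigma are the mean and standard
#' deviation of the negative-control (non-targeting sgRNA) efficiencies.
#' Samples with |z| > 3 are flagged as having a strong effect.  The SD
#' convention defaults to the sample SD (denominator n - 1); the
#' population SD is available via `sd_type = "population"` -- the printed
#' worked examples are insensitive to the choice at their precision.
#'
#' @param x observed efficiency (percent); may be a vector (one z per
#'   replicate).
#' @param nc_values negative-control efficiencies (>= 3 values).
#' @param sd_type `"sample"` (n - 1) or `"population"` (n).
#' @return numeric vector of class `zscore` with attributes `mu`,
#'   `sigma`, `strong` (|z| > 3) and `direction` (`up`/`down`).
#' @export
zscore <- function(x, nc_values, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  if (length(nc_values) < 3)
    stop("need >= 3 negative-control values")
  mu <- mean(nc_values)
  sigma <- sd(nc_values)
  if (sd_type == "population")
    sigma <- sigma * sqrt((length(nc_values) - 1) / length(nc_values))
  if (!is.finite(sigma) || sigma <= 0)
    stop("negative-control SD is zero; provide more varied NC replicates")
  z <- (x - mu) / sigma
  structure(z, mu = mu, sigma = sigma, strong = abs(z) > 3,
            direction = ifelse(z >= 0, "up", "down"), class = "zscore")
}

#' @export
print.zscore <- function(x, ...) {
  cat(sprintf("z-score(s) vs NC (mu = %.3f, sigma = %.3f):\n",
              attr(x, "mu"), attr(x, "sigma")))
  print(round(as.numeric(x), 3))
  if (any(attr(x, "strong")))
    cat("  strong effects (|z| > 3):", sum(attr(x, "strong")), "\n")
  invisible(x)
}

#' Adjusted z-score over replicates, with significance tier
#'
#' adjusted z-score = |mean(z)| - sigma(z) over the replicate z-scores: a
#' conservative effect measure that rewards consistent replicates.  It
#' never exceeds |mean(z)| and equals it only when replicates agree
#' exactly.  Tiers: `ns` below 1.5, `*` for 1.5-2, `**` for 2-3, `***`
#' above 3; exact boundaries go to the higher tier.
#'
#' @param zs numeric vector of replicate z-scores (>= 2).  With a single
#'   replicate the plain |z| is used, with a warning.
#' @param sd_type SD convention for sigma(z), as in [zscore()].
#' @return list of class `adjusted_zscore`: `adjusted`, `tier`, `mean_z`,
#'   `sd_z`, `direction`.
#' @export
adjusted_zscore <- function(zs, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  zs <- as.numeric(zs)
  if (length(zs) < 1) stop("no z-scores supplied")
  if (length(zs) == 1) {
    warning("single replicate: falling back to |z| as the adjusted score")
    adj <- abs(zs); sdz <- 0
  } else {
    sdz <- sd(zs)
    if (sd_type == "population")
      sdz <- sdz * sqrt((length(zs) - 1) / length(zs))
    adj <- abs(mean(zs)) - sdz
  }
  structure(list(adjusted = adj, tier = z_tier(adj), mean_z = mean(zs),
                 sd_z = sdz,
                 direction = if (mean(zs) >= 0) "up" else "down"),
            class = "adjusted_zscore")
}

z_tier <- function(adj) {
  if (adj >= 3) "***" else if (adj >= 2) "**" else if (adj >= 1.5) "*"
  else "ns"
}

#' @export
print.adjusted_zscore <- function(x, ...) {
  cat(sprintf("adjusted z = |mean z| - sd(z) = |%.3f| - %.3f = %.3f  [%s, %s]\n",
              x$mean_z, x$sd_z, x$adjusted, x$tier, x$direction))
  invisible(x)
}

#' Fold change between control and knockdown mean efficiencies
#'
#' The fold change is always reported as the ratio of the larger to the
#' smaller mean (so it is >= 1), rounded half-up to `decimals` places,
#' with the direction carried separately; the log2 fold change
#' log2(kd / nc) is reported unrounded.
#'
#' @param nc_mean mean efficiency of the negative controls (percent, > 0).
#' @param kd_mean mean efficiency under knockdown (percent, > 0).
#' @param decimals decimal places for the reported fold (default 1).
#' @return list of class `fold_change`: `fold`, `direction` (`up`/`down`),
#'   `lfc`, `nc_mean`, `kd_mean`.
#' @examples
#' fold_change(15.6, 7.5)$fold   # 2.1, direction "down"
#' @export
fold_change <- function(nc_mean, kd_mean, decimals = 1) {
  if (!is.finite(nc_mean) || !is.finite(kd_mean) ||
      nc_mean <= 0 || kd_mean <= 0)
    stop("nc_mean and kd_mean must be positive")
  structure(list(fold = round_half_up(max(nc_mean / kd_mean,
                                          kd_mean / nc_mean), decimals),
                 direction = if (kd_mean >= nc_mean) "up" else "down",
                 lfc = log2(kd_mean / nc_mean),
                 nc_mean = nc_mean, kd_mean = kd_mean),
            class = "fold_change")
}

#' @export
print.fold_change <- function(x, ...) {
  cat(sprintf("%.6g%% -> %.6g%%: %s-fold %s (LFC %.3f)\n", x$nc_mean,
              x$kd_mean, format(x$fold), x$direction, x$lfc))
  invisible(x)
}

#' Relative outcome fractions (percent of edited reads)
#'
#' Re-expresses outcome efficiencies as the percent of edited
#' (non-wild-type) reads in each category; the relative percentages sum
#' to 100 over the edited categories.  Accepts an `outcome_profile` (its
#' relative table is returned) or a named vector of edited-category
#' efficiencies/counts.
#'
#' @param x an `outcome_profile` from [aggregate_outcomes()], or a named
#'   numeric vector of edited-category values (WT entries are excluded).
#' @return data.frame `category`, `pct`, or `NULL` (with a warning) when
#'   there are no edited reads.
#' @export
relative_outcomes <- function(x) {
  if (inherits(x, "outcome_profile")) {
    if (is.null(x$relative)) warning("no edited reads; relative outcomes undefined")
    return(x$relative)
  }
  stopifnot(is.numeric(x), !is.null(names(x)))
  x <- x[names(x) != "WT"]
  if (!length(x) || sum(x) <= 0) {
    warning("no edited reads; relative outcomes undefined")
    return(NULL)
  }
  data.frame(category = names(x), pct = 100 * as.numeric(x) / sum(x),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Rescue fraction from knockdown, rescue and control efficiencies
#'
#' For each outcome category, the fraction of the knockdown effect that a
#' rescue (cDNA re-expression) construct reverses:
#' (rescue - kd) / (nc - kd).  1 means full rescue back to the negative
#' control, 0 means none; movement towards the control is positive
#' regardless of the direction of the knockdown effect.  Categories where
#' nc equals kd have no effect to rescue and return NA.
#'
#' @param kd,rescue,nc numeric vectors (per category) of efficiencies.
#' @return numeric vector of rescue fractions.
#' @export
rescue_delta <- function(kd, rescue, nc) {
  stopifnot(length(kd) == length(rescue), length(kd) == length(nc))
  den <- nc - kd
  out <- (rescue - kd) / den
  if (any(den == 0)) {
    warning("nc == kd for ", sum(den == 0),
            " categor(ies); rescue fraction undefined there")
    out[den == 0] <- NA_real_
  }
  out
}

#' Relative expression by the delta-delta-Ct method
#'
#' DeltaCt = Ct(target) - Ct(reference) per sample; DeltaDeltaCt =
#' DeltaCt(knockdown) - DeltaCt(control); relative expression =
#' 2^(-DeltaDeltaCt), so the control maps to 1 and one extra cycle of
#' difference halves the expression.  (Relative expression is necessarily
#' positive; the occasionally printed "-2^DDCt" form is a typesetting
#' artifact of the same method.)
#'
#' @param ct_target_kd,ct_ref_kd Ct of target and reference gene in the
#'   knockdown sample.
#' @param ct_target_nc,ct_ref_nc same in the control sample.
#' @return list of class `expression_result`: `delta_delta_ct`,
#'   `relative_expression`, and the per-sample DeltaCt values.
#' @export
delta_delta_ct <- function(ct_target_kd, ct_ref_kd, ct_target_nc,
                           ct_ref_nc) {
  cts <- c(ct_target_kd, ct_ref_kd, ct_target_nc, ct_ref_nc)
  if (!all(is.finite(cts))) stop("all Ct values must be finite")
  dct_kd <- ct_target_kd - ct_ref_kd
  dct_nc <- ct_target_nc - ct_ref_nc
  ddct <- dct_kd - dct_nc
  structure(list(delta_ct_kd = dct_kd, delta_ct_nc = dct_nc,
                 delta_delta_ct = ddct,
                 relative_expression = 2^(-ddct)),
            class = "expression_result")
}

#' @export
print.expression_result <- function(x, ...) {
  cat(sprintf("DeltaDeltaCt = %.3f; relative expression = %.3f of control\n",
              x$delta_delta_ct, x$relative_expression))
  invisible(x)
}
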