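#' Median-of-ratios normalization of an sgRNA count table
#'
#' Size factor per sample = median, over sgRNAs whose geometric mean
#' across samples is positive, of count / geometric mean; normalized
#' counts are raw counts divided by the sample's size factor.  This is the
#' median normalization applied to pooled-screen reads before testing.
#' Rows that are zero in every sample carry no information and are dropped
#' (the number removed is logged and attached).
#'
#' @param counts count table: data.frame with `sgRNA`, `gene` and one
#'   integer column per sample (as from [simulate_screen()] or
#'   [read_counts()]), or a bare numeric matrix.
#' @return The same shape with sample columns normalized; attributes
#'   `size_factors` (named numeric) and `n_dropped` (all-zero rows
#'   removed).
#' @export
median_normalize <- function(counts) {
  parts <- split_count_table(counts)
  m <- parts$m
  if (ncol(m) < 2) stop("need >= 2 samples to normalize")
  if (any(colSums(m) == 0)) stop("every sample needs >= 1 positive count")
  allzero <- rowSums(m) == 0
  if (any(allzero)) {
    bedit_log("median_normalize: dropping ", sum(allzero),
              " all-zero sgRNA row(s)")
    m <- m[!allzero, , drop = FALSE]
    parts$meta <- parts$meta[!allzero, , drop = FALSE]
  }
  logg <- rowMeans(log(m))          # -Inf for rows with any zero
  use <- is.finite(logg)
  if (!any(use)) stop("no sgRNA has positive counts in every sample")
  sf <- apply(m, 2, function(col) median((col / exp(logg))[use]))
  norm <- sweep(m, 2, sf, "/")
  out <- rebuild_count_table(parts$meta, norm)
  attr(out, "size_factors") <- sf
  attr(out, "n_dropped") <- sum(allzero)
  out
}

## split a count table into metadata (sgRNA/gene) and numeric matrix
split_count_table <- function(counts) {
  if (is.matrix(counts)) {
    meta <- data.frame(sgRNA = rownames(counts) %||%
                         sprintf("sg%05d", seq_len(nrow(counts))),
                       gene = NA_character_)
    return(list(meta = meta, m = counts))
  }
  stopifnot(is.data.frame(counts))
  idcols <- intersect(c("sgRNA", "gene"), names(counts))
  samp <- setdiff(names(counts), idcols)
  m <- as.matrix(counts[, samp, drop = FALSE])
  rownames(m) <- counts$sgRNA
  if (any(m < 0, na.rm = TRUE)) stop("counts must be >= 0")
  list(meta = counts[, idcols, drop = FALSE], m = m)
}

rebuild_count_table <- function(meta, m) {
  cbind(as.data.frame(meta, stringsAsFactors = FALSE),
        as.data.frame(m, check.names = FALSE), row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
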