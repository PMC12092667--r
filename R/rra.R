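#' Alpha robust rank aggregation (alpha-RRA) over sgRNA ranks
#'
#' Gene-level enrichment test in the modified robust-rank-aggregation
#' style used for pooled CRISPR screens.  sgRNAs are ranked by a score in
#' the chosen direction (ascending for depletion, descending for
#' enrichment) and converted to percentiles in (0, 1] with average ranks
#' for ties.  For a gene with k sgRNAs and sorted percentiles
#' r(1) <= ... <= r(k), only the k' sgRNAs with percentile <= alpha enter
#' the score (the alpha screen), and
#' rho = min over j = 1..k' of P(Beta(j, k - j + 1) <= r(j)),
#' the smallest order-statistic tail probability.  Genes with no sgRNA
#' passing the alpha screen get rho = 1.  Significance comes from a
#' gene-size-stratified permutation null (random reassignment of the
#' observed percentiles to gene-sized groups):
#' p = (1 + #\{permuted rho <= observed rho\}) / (1 + n_perm), followed by
#' Benjamini-Hochberg FDR across genes.
#'
#' @param score numeric sgRNA score (e.g. log2 fold change); smaller =
#'   more extreme for `direction = "depletion"`.
#' @param gene character vector of gene labels, same length as `score`;
#'   `"NONTARGETING"` sgRNAs shape the rank universe but are not tested.
#' @param alpha fraction of the rank universe admitted to the score
#'   (default 0.25).
#' @param n_perm number of permutations (>= 1000 recommended).
#' @param seed integer seed for the permutation RNG.
#' @param direction `"depletion"` (ascending score) or `"enrichment"`
#'   (descending).
#' @return data.frame: `gene`, `n_sgRNAs`, `rho`, `p`, `fdr`, ordered by
#'   `p` then `rho`.
#' @examples
#' ## a single-sgRNA gene at percentile r has rho = r (Beta(1, 1) uniform)
#' @export
alpha_rra <- function(score, gene, alpha = 0.25, n_perm = 2000L,
                      seed = 1L, direction = c("depletion", "enrichment")) {
  direction <- match.arg(direction)
  stopifnot(length(score) == length(gene), is.numeric(score))
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  n_perm <- as.integer(n_perm)
  if (n_perm < 1) stop("n_perm must be >= 1")

  n <- length(score)
  s <- if (direction == "depletion") score else -score
  pct <- rank(s, ties.method = "average") / n   # in (0, 1]

  targeted <- gene != "NONTARGETING" & !is.na(gene)
  groups <- split(pct[targeted], gene[targeted])
  ks <- lengths(groups)
  obs_rho <- vapply(groups, rra_rho, 0, alpha = alpha)

  if (all(obs_rho >= 1))
    warning("no gene has an sgRNA passing the alpha screen; all p = 1")

  ## stratified permutation null: for each gene size, n_perm random
  ## gene-sized draws (without replacement) from the observed percentiles;
  ## drawing from the sorted percentiles makes the null, and hence every
  ## p-value, invariant to the order sgRNA rows arrive in
  spct <- sort(pct)
  p <- setNames(numeric(length(groups)), names(groups))
  with_seed(seed, {
    for (k in sort(unique(ks))) {
      null_rho <- vapply(seq_len(n_perm), function(i)
        rra_rho(spct[sample.int(n, k)], alpha = alpha), 0)
      idx <- which(ks == k)
      cnt <- vapply(obs_rho[idx], function(r) sum(null_rho <= r), 0)
      p[idx] <- (1 + cnt) / (1 + n_perm)
    }
  })

  out <- data.frame(gene = names(groups), n_sgRNAs = as.vector(ks),
                    rho = as.vector(obs_rho), p = as.vector(p),
                    fdr = p.adjust(p, "BH"),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$p, out$rho, out$gene), , drop = FALSE]
}

## the rho score of one gene: smallest Beta order-statistic tail over the
## alpha-passing prefix of its sorted percentiles
rra_rho <- function(r, alpha) {
  r <- sort(r)
  k <- length(r)
  kp <- sum(r <= alpha)
  if (kp == 0) return(1)
  j <- seq_len(kp)
  min(pbeta(r[j], j, k - j + 1))
}
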