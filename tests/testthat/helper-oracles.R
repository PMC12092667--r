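# Independent oracles used across the suite.

# Brute-force global affine-gap alignment score (Gotoh).  A gap of length
# L costs |open| + L * |extend|, matching the package's convention.  The
# inner horizontal-gap recurrence is vectorised with the running-maximum
# trick; everything else is plain dynamic programming, independent of the
# package's alignment path.
oracle_align_score <- function(x, y, match = 2, mismatch = -3,
                               gap_open = 10, gap_extend = 1) {
  xs <- strsplit(x, "")[[1]]; ys <- strsplit(y, "")[[1]]
  n <- length(xs); m <- length(ys)
  NEG <- -1e9
  go <- gap_open; ge <- gap_extend
  jj <- seq_len(m)
  # rows indexed over x; columns 0..m stored at 1..(m+1)
  Vprev <- c(0, -(go + jj * ge))
  Ixprev <- rep(NEG, m + 1)
  for (i in seq_len(n)) {
    sub <- ifelse(xs[i] == ys, match, mismatch)
    M <- Vprev[jj] + sub                       # diagonal into column j
    Ix <- pmax(Vprev[jj + 1] - go - ge, Ixprev[jj + 1] - ge)
    A <- pmax(M, Ix)                           # V without horizontal gaps
    A0 <- -(go + i * ge)                       # boundary column 0
    # Iy[j] = max_{j' < j} (A[j'] - go - (j - j') * ge), A[0] = boundary
    run <- cummax(c(A0, A[-m]) + (0:(m - 1)) * ge)
    Iy <- run - go - jj * ge
    V <- pmax(A, Iy)
    Vprev <- c(A0, V)
    Ixprev <- c(NEG, Ix)
  }
  Vprev[m + 1]
}

# Exhaustive alpha-RRA permutation null: rho of every k-subset of the
# percentile universe (for tiny universes only).
oracle_rra_exact <- function(pct, k, alpha) {
  combs <- utils::combn(length(pct), k)
  apply(combs, 2, function(ix) beditscan:::rra_rho(pct[ix], alpha))
}

# binomial standard error of a proportion
binom_se <- function(p, n) sqrt(p * (1 - p) / n)
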