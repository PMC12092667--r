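test_that("identity and single-substitution alignments are exact", {
  site <- toy_site()
  len <- nchar(site$amplicon)
  a <- align_read(site$amplicon, site)
  expect_equal(a$score, 2 * len)
  expect_false(a$unalignable)
  expect_equal(nrow(a$deletions) + nrow(a$insertions), 0)

  p <- beditscan:::proto_to_ref(site, 10L)
  rd <- site$amplicon
  substr(rd, p, p) <- "T"
  a <- align_read(rd, site)
  expect_equal(a$score, 2 * (len - 1) - 3)
  expect_equal(which(a$calls != strsplit(site$amplicon, "")[[1]]), p)
})

test_that("a planted in-window deletion is recovered as one gap span", {
  site <- toy_site()
  w <- beditscan:::window_ref(site)
  s <- w[1] + 2L
  rd <- paste0(substr(site$amplicon, 1, s - 1),
               substr(site$amplicon, s + 3, nchar(site$amplicon)))
  a <- align_read(rd, site)
  expect_equal(a$score,
               oracle_align_score(rd, site$amplicon))  # DP oracle agrees
  expect_equal(nrow(a$deletions), 1)
  expect_equal(a$deletions$end - a$deletions$start + 1L, 3L)
  # ambiguity can slide the gap within equal-scoring context only
  expect_lte(abs(a$deletions$start - s), 3)
})

test_that("alignment scores match the brute-force affine-gap DP oracle", {
  site <- toy_site()
  amp <- site$amplicon
  set.seed(99)
  for (i in 1:40) {
    rd <- amp
    # plant 0-3 substitutions
    for (k in seq_len(sample(0:3, 1))) {
      p <- sample(nchar(rd), 1)
      substr(rd, p, p) <- sample(c("A", "C", "G", "T"), 1)
    }
    # plant an indel half the time
    if (runif(1) < 0.5) {
      L <- sample(1:6, 1); s <- sample(10:(nchar(rd) - 12), 1)
      rd <- if (runif(1) < 0.5)
        paste0(substr(rd, 1, s), substr(rd, s + L + 1, nchar(rd)))
      else paste0(substr(rd, 1, s),
                  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                        collapse = ""),
                  substr(rd, s + 1, nchar(rd)))
    }
    expect_equal(align_read(rd, site)$score, oracle_align_score(rd, amp),
                 info = paste("read", i))
  }
})

test_that("degenerate reads are rejected or flagged", {
  site <- toy_site()
  expect_error(align_read("", site), "empty")
  expect_error(align_read("ACGTACGT", site), "30 nt")
  junk <- strrep("A", nchar(site$amplicon))
  expect_true(align_read(junk, site)$unalignable)
  # N scores as a mismatch
  rd <- site$amplicon
  substr(rd, 50, 50) <- "N"
  expect_equal(align_read(rd, site)$score, 2 * (nchar(rd) - 1) - 3)
})

test_that("batch classification equals the per-read reference path", {
  site <- toy_site()
  spec <- outcome_spec(site, c("T10" = 0.2, "G16" = 0.1, "T10/T16" = 0.1,
                               indel = 0.1, WT = 0.5))
  sim <- simulate_reads(site, spec, sim_config(n_reads = 300,
                                               error_rate = 0.003, seed = 6))
  batch <- beditscan:::classify_reads_batch(sim$reads, site)
  for (i in seq_along(sim$reads)) {
    ref <- classify_read(align_read(sim$reads[i], site), site)
    expect_equal(batch$status[i], ref$status, info = paste("read", i))
    expect_equal(batch$category[i], ref$category, info = paste("read", i))
  }
})
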