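test_that("library arithmetic matches the screen design", {
  # 2015 genes x 5 sgRNAs + 2243 non-targeting controls = 12,318 sgRNAs
  lib <- library_spec(2015, 5, 2243, skew_sd = 0)
  expect_equal(beditscan:::total_sgrnas(lib), 12318L)
  scr <- simulate_screen(lib, sim_config(depth = 5, dispersion = 0,
                                         seed = 2), n_replicates = 1)
  expect_equal(nrow(scr$counts), 12318L)
  expect_equal(sum(scr$counts$gene == "NONTARGETING"), 2243L)
})

test_that("null model: sorted/bulk ratios are flat across sgRNAs", {
  lib <- library_spec(10, 5, 20, skew_sd = 0)
  scr <- simulate_screen(lib, sim_config(depth = 5000, dispersion = 1e-14,
                                         seed = 7), n_replicates = 1)
  r <- scr$counts$sorted_r1 / scr$counts$bulk_r1
  # all effects 1.0, no skew: ratios equal up to Poisson sampling
  expect_lt(sd(r) / mean(r), 0.05)
  expect_true(all(abs(scr$truth$expected_lfc) < 1e-12))
})

test_that("a depleted gene has negative expected sorted-vs-bulk LFC", {
  lib <- library_spec(20, 5, 40, effect = c(gene0003 = 0.25), pi0 = 0.132)
  scr <- simulate_screen(lib, sim_config(depth = 200, dispersion = 0.1,
                                         seed = 8))
  tr <- scr$truth
  expect_true(all(tr$expected_lfc[tr$gene == "gene0003"] < 0))
  expect_true(median(tr$expected_lfc[tr$gene == "NONTARGETING"]) > -0.1)
  # closed form: pi_s/pibar with all-null genes at pi0 approaches 0.25
  expect_equal(mean(2^tr$expected_lfc[tr$gene == "gene0003"]),
               0.25 / mean(2^tr$expected_lfc[tr$gene != "gene0003"]),
               tolerance = 0.05)
})

test_that("raising a gene effect strictly raises its expected sorted share", {
  shares <- vapply(c(0.5, 1, 2, 4), function(e) {
    lib <- library_spec(10, 5, 20, effect = c(gene0002 = e))
    scr <- simulate_screen(lib, sim_config(depth = 100, dispersion = 0.1,
                                           seed = 12))
    tr <- scr$truth
    g <- tr$gene == "gene0002"
    sum(tr$weight[g] * tr$conversion_prob[g]) /
      sum(tr$weight * tr$conversion_prob)
  }, 0)
  expect_true(all(diff(shares) > 0))
})

test_that("essential genes are depleted in the day-13 bulk", {
  lib <- library_spec(20, 5, 100, essential = c("gene0001", "gene0002"),
                      essential_depletion = 0.3)
  scr <- simulate_screen(lib, sim_config(depth = 300, dispersion = 0.05,
                                         seed = 9))
  qc <- screen_qc(scr, essential = c("gene0001", "gene0002"))
  expect_lt(qc$essential_median_lfc, qc$nontargeting_median_lfc)
  expect_lt(qc$essential_median_lfc, -1)  # factor 0.3 is ~ -1.7 in log2
})

test_that("screen simulation is reproducible and input-validated", {
  lib <- library_spec(5, 5, 10)
  cfg <- sim_config(depth = 50, dispersion = 0.2, seed = 33)
  expect_identical(simulate_screen(lib, cfg)$counts,
                   simulate_screen(lib, cfg)$counts)
  expect_error(library_spec(1, 5, 10), "n_genes")
  expect_error(sim_config(depth = -1, seed = 1))
})
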