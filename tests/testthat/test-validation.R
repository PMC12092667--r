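test_that("z-scores follow the definitional arithmetic", {
  nc <- c(10, 12, 14)
  expect_equal(as.numeric(zscore(12, nc)), 0)
  # x = mu + 3*sigma sits exactly on the strong-effect boundary
  x <- mean(nc) + 3 * sd(nc)
  z <- zscore(x, nc)
  expect_equal(as.numeric(z), 3)
  expect_false(attr(z, "strong"))      # strictly greater than 3 is strong
  expect_true(attr(zscore(x + 0.01, nc), "strong"))
  # a 3-NC x 3-replicate design, against hand arithmetic
  set.seed(19)
  ncs <- rnorm(9, 15, 1.2)
  x <- 18.4
  expect_equal(as.numeric(zscore(x, ncs)),
               (x - mean(ncs)) / sd(ncs))
  expect_equal(as.numeric(zscore(x, ncs, sd_type = "population")),
               (x - mean(ncs)) / (sd(ncs) * sqrt(8 / 9)))
})

test_that("z-scores are invariant to affine changes of scale", {
  set.seed(23)
  nc <- rnorm(9, 15, 2)
  x <- 19
  z0 <- as.numeric(zscore(x, nc))
  for (i in 1:10) {
    c1 <- rnorm(1); c2 <- abs(rnorm(1)) + 0.1
    expect_equal(as.numeric(zscore(x + c1, nc + c1)), z0)
    expect_equal(as.numeric(zscore(x * c2, nc * c2)), z0)
  }
  expect_error(zscore(5, c(10, 12)), ">= 3")
  expect_error(zscore(5, c(10, 10, 10)), "SD is zero")
})

test_that("adjusted z-scores and tiers follow the replicate convention", {
  a <- adjusted_zscore(c(2.5, 2.5))
  expect_equal(a$adjusted, 2.5)       # sd(z) = 0
  expect_equal(a$tier, "**")
  a <- adjusted_zscore(c(4, -4))      # cancellation: |mean| = 0
  expect_lt(a$adjusted, 0)
  expect_equal(a$tier, "ns")
  a <- adjusted_zscore(c(3.2, 4.0, 4.8))
  expect_equal(a$adjusted, 4.0 - sd(c(3.2, 4.0, 4.8)))
  expect_equal(a$adjusted, 3.2)
  expect_equal(a$tier, "***")
  expect_warning(a1 <- adjusted_zscore(-2.2), "single replicate")
  expect_equal(a1$adjusted, 2.2)
})

test_that("adjusted z never exceeds |mean z|, with equality iff exact agreement", {
  set.seed(29)
  for (i in 1:50) {
    zs <- rnorm(sample(2:5, 1), sample(-4:4, 1), runif(1, 0, 2))
    a <- adjusted_zscore(zs)
    expect_lte(a$adjusted, abs(mean(zs)))
    if (a$adjusted == abs(mean(zs))) expect_true(sd(zs) == 0)
  }
  expect_equal(adjusted_zscore(c(1.7, 1.7, 1.7))$adjusted, 1.7)
})

test_that("tier boundaries go to the higher tier", {
  expect_equal(beditscan:::z_tier(1.49), "ns")
  expect_equal(beditscan:::z_tier(1.5), "*")
  expect_equal(beditscan:::z_tier(1.99), "*")
  expect_equal(beditscan:::z_tier(2), "**")
  expect_equal(beditscan:::z_tier(3), "***")
  expect_equal(beditscan:::z_tier(10), "***")
})

test_that("fold changes reproduce the printed knockdown examples", {
  fc <- fold_change(15.6, 7.5)
  expect_equal(fc$fold, 2.1)
  expect_equal(fc$direction, "down")
  fc <- fold_change(17.3, 9.7)
  expect_equal(fc$fold, 1.8)
  expect_equal(fc$direction, "down")
  fc <- fold_change(10, 10)
  expect_equal(fc$fold, 1)
  expect_equal(fc$lfc, 0)
  expect_error(fold_change(0, 5), "positive")
})

test_that("fold change is symmetric in magnitude with flipped direction", {
  set.seed(37)
  for (i in 1:20) {
    a <- runif(1, 1, 50); b <- runif(1, 1, 50)
    f1 <- fold_change(a, b, decimals = 6)
    f2 <- fold_change(b, a, decimals = 6)
    expect_equal(f1$fold, f2$fold)
    expect_equal(f1$lfc, -f2$lfc)
    if (a != b) expect_false(f1$direction == f2$direction)
  }
})

test_that("relative outcomes renormalize over edited categories", {
  expect_equal(relative_outcomes(c(T10 = 30, G10 = 10, WT = 60))$pct,
               c(75, 25))
  one <- relative_outcomes(c(G10 = 7, WT = 93))
  expect_equal(one$pct, 100)
  expect_warning(out <- relative_outcomes(c(WT = 100)), "undefined")
  expect_null(out)
})

test_that("rescue fractions interpolate between knockdown and control", {
  expect_equal(rescue_delta(7.5, 15.6, 15.6), 1)
  expect_equal(rescue_delta(7.5, 7.5, 15.6), 0)
  expect_equal(rescue_delta(7.5, 11.55, 15.6), 0.5)
  # movement toward NC is positive also when knockdown increased the value
  expect_equal(rescue_delta(30, 25, 20), 0.5)
  expect_warning(r <- rescue_delta(c(5, 8), c(6, 9), c(10, 8)), "undefined")
  expect_true(is.na(r[2]))
})

test_that("delta-delta-Ct closed forms hold", {
  expect_equal(delta_delta_ct(20, 18, 20, 18)$relative_expression, 1)
  # one extra cycle of difference halves expression
  r <- delta_delta_ct(21, 18, 20, 18)
  expect_equal(r$delta_delta_ct, 1)
  expect_equal(r$relative_expression, 0.5)
  r <- delta_delta_ct(19, 18, 21, 18)
  expect_equal(r$delta_delta_ct, -2)
  expect_equal(r$relative_expression, 4)
  expect_error(delta_delta_ct(NA, 18, 20, 18), "finite")
})
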