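test_that("a single-sgRNA gene's rho is its percentile", {
  # Beta(1, 1) is uniform, so rho = r for k = 1
  for (r in c(0.01, 0.1, 0.2)) {
    expect_equal(beditscan:::rra_rho(r, alpha = 0.25), r)
  }
  # and above the alpha screen the gene scores 1
  expect_equal(beditscan:::rra_rho(0.6, alpha = 0.25), 1)
})

test_that("rho uses only the alpha-passing prefix of sorted percentiles", {
  r <- c(0.02, 0.10, 0.70)
  # k' = 2 of 3 pass alpha = 0.25
  expected <- min(pbeta(0.02, 1, 3), pbeta(0.10, 2, 2))
  expect_equal(beditscan:::rra_rho(r, 0.25), expected)
  # rho always lands in (0, 1]
  set.seed(41)
  for (i in 1:50) {
    rho <- beditscan:::rra_rho(runif(sample(1:6, 1)), alpha = 0.25)
    expect_gt(rho, 0); expect_lte(rho, 1)
  }
})

test_that("appending a worse-ranked sgRNA never decreases a Beta term", {
  # Beta(j, k - j + 1) at fixed j shrinks stochastically as k grows, so
  # every order-statistic tail probability can only increase
  set.seed(43)
  for (i in 1:30) {
    k <- sample(2:6, 1)
    r <- sort(runif(k))
    j <- seq_len(k)
    t_k <- pbeta(r, j, k - j + 1)
    t_k1 <- pbeta(r, j, (k + 1) - j + 1)   # after adding a worse sgRNA
    expect_true(all(t_k1 >= t_k - 1e-12))
  }
})

test_that("permutation p matches exhaustive enumeration on a 9-sgRNA universe", {
  score <- c(0.05, 0.10, 0.30, 0.40, 0.50, 0.60, 0.70, 0.80, 0.90)
  gene <- c("hit", "hit", "hit", paste0("n", 1:6))
  pct <- rank(score) / 9
  obs <- beditscan:::rra_rho(pct[1:3], alpha = 0.4)
  exact_null <- oracle_rra_exact(pct, 3, alpha = 0.4)
  q <- mean(exact_null <= obs)
  res <- alpha_rra(score, gene, alpha = 0.4, n_perm = 20000, seed = 77)
  p_hat <- res$p[res$gene == "hit"]
  expect_equal(res$rho[res$gene == "hit"], obs)
  # the sampled permutation p converges on the enumeration proportion
  expect_lt(abs(p_hat - q), 3 * binom_se(q, 20000) + 2 / 20001)
})

test_that("results are invariant to sgRNA row order", {
  scr <- toy_screen(effect = c(gene0004 = 0.3))
  fit1 <- rra_screen(scr, n_perm = 500, seed = 3)
  perm <- withr::with_seed(1, sample(nrow(scr$counts)))
  scr2 <- scr
  scr2$counts <- scr$counts[perm, ]
  fit2 <- rra_screen(scr2, n_perm = 500, seed = 3)
  expect_equal(fit1$genes, fit2$genes)
})

test_that("an alpha screen no gene passes yields p = 1 with a warning", {
  score <- 1:20
  gene <- rep(paste0("g", 1:4), each = 5)
  expect_warning(res <- alpha_rra(score, gene, alpha = 0.01, n_perm = 100,
                                  seed = 1), "alpha screen")
  expect_true(all(res$rho == 1))
  expect_true(all(res$p == 1))
})

test_that("the fitted screen object exposes the usual accessors", {
  scr <- toy_screen(effect = c(gene0002 = 0.25))
  fit <- rra_screen(scr, n_perm = 500, seed = 13)
  expect_s3_class(fit, "rra_screen")
  expect_named(coef(fit), fit$genes$gene)
  expect_equal(as.data.frame(fit), fit$genes)
  expect_output(print(fit), "alpha-RRA screen fit")
  s <- summary(fit)
  expect_output(print(s), "hits at FDR")
  # the spiked gene is the top depletion hit with a negative phenotype
  expect_equal(fit$genes$gene[1], "gene0002")
  expect_lt(fit$genes$phenotype[1], 0)
  # gene phenotype is the median of the gene's sgRNA LFCs
  sg <- fit$sgrnas
  expect_equal(unname(coef(fit)["gene0002"]),
               median(sg$lfc[sg$gene == "gene0002"]))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("gene phenotype is the median, robust to outliers", {
  expect_equal(unname(gene_phenotype(c(-2, -1, 0, 1, 2), rep("g", 5))["g"]), 0)
  expect_equal(unname(gene_phenotype(c(-3, -2, -1, 0, 4), rep("g", 5))["g"]), -1)
  set.seed(31)
  for (i in 1:20) {
    x <- rnorm(5)
    expect_equal(unname(gene_phenotype(x, rep("g", 5))["g"]),
                 sort(x)[3])  # sort-based oracle for odd n
  }
  # even count: mean of the central pair
  expect_equal(unname(gene_phenotype(c(1, 2, 3, 10), rep("g", 4))["g"]), 2.5)
})
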