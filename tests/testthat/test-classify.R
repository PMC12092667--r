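test_that("the outcome taxonomy is applied with indel precedence", {
  site <- toy_site()
  wt <- classify_read(align_read(site$amplicon, site), site)
  expect_equal(wt$category, "WT")
  expect_equal(wt$allele_key, "C@10|C@16")

  t10 <- classify_read(align_read(edited_read(site, "T10"), site), site)
  expect_equal(t10$category, "T10")
  expect_equal(t10$allele_key, "T@10|C@16")

  mixed <- classify_read(align_read(edited_read(site, "T10/G16"), site), site)
  expect_equal(mixed$category, "T10/G16")

  # an in-window deletion wins over substitutions
  rd <- edited_read(site, "T10")
  w <- beditscan:::window_ref(site)
  rd <- paste0(substr(rd, 1, w[2] - 3), substr(rd, w[2] + 1, nchar(rd)))
  indel <- classify_read(align_read(rd, site), site)
  expect_equal(indel$category, "indel")
})

test_that("non-target window substitutions flag other-edit", {
  site <- toy_site()
  w <- beditscan:::window_ref(site)
  tref <- beditscan:::proto_to_ref(site, site$target_c)
  pos <- setdiff(w[1]:w[2], tref)[1]
  rd <- site$amplicon
  old <- substr(rd, pos, pos)
  substr(rd, pos, pos) <- setdiff(c("A", "C", "G", "T"), old)[1]
  cl <- classify_read(align_read(rd, site), site)
  expect_equal(cl$status, "other-edit")
  # but a target edit takes precedence over the stray substitution
  rd2 <- rd
  p10 <- beditscan:::proto_to_ref(site, 10L)
  substr(rd2, p10, p10) <- "T"
  cl2 <- classify_read(align_read(rd2, site), site)
  expect_equal(cl2$status, "classified")
  expect_equal(cl2$category, "T10")
})

test_that("read accounting is conserved across statuses", {
  site <- toy_site()
  spec <- outcome_spec(site, c("T10" = 0.2, indel = 0.05, WT = 0.75))
  sim <- simulate_reads(site, spec, sim_config(n_reads = 3000,
                                               error_rate = 0.004, seed = 13))
  oc <- call_outcomes(sim, site)
  expect_equal(sum(oc$accounting), length(sim$reads))
  expect_equal(sum(oc$allele_table$n_reads),
               unname(oc$accounting["classified"]))
})

test_that("absolute and relative efficiencies follow the worked arithmetic", {
  site <- toy_site()
  # 1000 reads: 156 single C-to-T, 66 single C-to-G, 778 WT
  prof <- aggregate_outcomes(c("T10" = 156, "G10" = 66, WT = 778), site)
  expect_equal(prof$absolute$pct[prof$absolute$category == "T10"], 15.6)
  expect_equal(prof$absolute$pct[prof$absolute$category == "G10"], 6.6)
  expect_equal(sum(prof$absolute$pct), 100)
  expect_equal(prof$total_editing, 22.2)

  # relative efficiencies: 10 of 40 edited reads carry the C-to-G outcome
  prof2 <- aggregate_outcomes(c("T10" = 30, "G10" = 10, WT = 60), site)
  expect_equal(prof2$relative$pct[prof2$relative$category == "G10"], 25)
  expect_equal(sum(prof2$relative$pct), 100)

  # all-WT: no relative table, not zeros
  prof3 <- aggregate_outcomes(c(WT = 1000), site)
  expect_null(prof3$relative)
  expect_equal(prof3$total_editing, 0)
})

test_that("per-position marginals sum the joint categories", {
  site <- toy_site()
  prof <- aggregate_outcomes(c("T10" = 100, "T10/T16" = 50, "T10/G16" = 25,
                               "G10" = 25, WT = 800), site)
  m <- prof$marginals
  get <- function(b, p) m$pct[m$base == b & m$position == p]
  expect_equal(get("T", 10), (100 + 50 + 25) / 10)  # 17.5% of 1000
  expect_equal(get("T", 16), 50 / 10)
  expect_equal(get("G", 16), 25 / 10)
  expect_equal(get("G", 10), 25 / 10)
  expect_equal(get("A", 10), 0)
})

test_that("profiles are invariant to the strand the site is described on", {
  fwd <- toy_site()
  # same locus written on the opposite strand: reverse-complement the
  # amplicon; the protospacer footprint start flips accordingly
  rc <- beditscan:::revcomp(fwd$amplicon)
  rev <- target_site("toy_rc", rc,
                     nchar(rc) - fwd$protospacer_start - fwd$protospacer_len,
                     fwd$protospacer_len, "reverse", fwd$target_c)
  spec_f <- outcome_spec(fwd, c("T10" = 0.3, "G16" = 0.2, WT = 0.5))
  sim_f <- simulate_reads(fwd, spec_f, sim_config(n_reads = 800,
                                                  error_rate = 0, seed = 21))
  # present the same molecules to the reverse-strand description
  rc_reads <- beditscan:::revcomp(sim_f$reads)
  sim_rc <- sim_f; sim_rc$reads <- rc_reads
  prof_f <- call_outcomes(sim_f, fwd)$profile
  prof_r <- call_outcomes(sim_rc, rev)$profile
  expect_equal(prof_f$absolute, prof_r$absolute)
  expect_equal(prof_f$total_editing, prof_r$total_editing)
})

test_that("apparent conversion under pure sequencing error stays bounded", {
  site <- toy_site()
  e <- 0.004
  spec <- outcome_spec(site, c(WT = 1))
  sim <- simulate_reads(site, spec, sim_config(n_reads = 20000,
                                               error_rate = e, seed = 17))
  prof <- call_outcomes(sim, site)$profile
  # a target C misread as any specific base occurs at ~ e/3
  for (b in c("T", "G", "A")) for (p in site$target_c) {
    obs <- prof$marginals$pct[prof$marginals$base == b &
                                prof$marginals$position == p] / 100
    expect_lt(obs, e / 3 + 3 * binom_se(e / 3, 20000))
  }
})

test_that("empty input fails loudly", {
  site <- toy_site()
  tf <- tempfile(fileext = ".fastq")
  file.create(tf)
  expect_error(call_outcomes(tf, site), "empty")
})
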