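#' Read a FASTQ file
#'
#' Plain or gzip 4-line FASTQ (Phred+33).  Malformed records fail with the
#' offending line number.
#'
#' @param path FASTQ path; `.gz` is decompressed transparently.
#' @return data.frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ not found: ", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  on.exit(close(con))
  lines <- readLines(con)
  if (!length(lines)) stop("FASTQ is empty: ", path)
  if (length(lines) %% 4 != 0)
    stop("truncated FASTQ record near line ", length(lines), " of ", path)
  hdr <- lines[seq(1, length(lines), 4)]
  seqs <- lines[seq(2, length(lines), 4)]
  plus <- lines[seq(3, length(lines), 4)]
  qual <- lines[seq(4, length(lines), 4)]
  bad <- which(!startsWith(hdr, "@"))
  if (length(bad)) stop("FASTQ record header missing '@' at line ",
                        (bad[1] - 1) * 4 + 1)
  bad <- which(!startsWith(plus, "+"))
  if (length(bad)) stop("FASTQ separator missing '+' at line ",
                        (bad[1] - 1) * 4 + 3)
  bad <- which(nchar(seqs) != nchar(qual))
  if (length(bad)) stop("sequence/quality length mismatch at line ",
                        (bad[1] - 1) * 4 + 2)
  data.frame(id = sub("^@", "", sub("\\s.*", "", hdr)), seq = toupper(seqs),
             qual = qual, stringsAsFactors = FALSE)
}

## writer used by all tabular outputs: header comment with version and a
## digest of the effective configuration, then a TSV with header row
write_tsv_with_header <- function(df, path, config = NULL,
                                  sep = if (grepl("\\.csv$", path)) ","
                                        else "\t") {
  cfg_dig <- if (is.null(config)) "none" else
    substr(.string_md5(paste(deparse(config), collapse = "")), 1, 8)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# beditscan %s config=%s", .bedit_version(), cfg_dig),
             con)
  write.table(df, con, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

.string_md5 <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(x, tf)
  unname(tools::md5sum(tf))
}

#' Read and write sgRNA count tables
#'
#' Tab-separated with a header row (`sgRNA`, `gene`, one column per
#' sample) and optional leading `#` comment lines.  Reading validates
#' that counts are non-negative integers (naming the offending row) and
#' that sgRNA ids are unique.
#'
#' @param path file path.
#' @param counts count table data.frame (for writing).
#' @return `read_counts()` returns the count data.frame;
#'   `write_counts()` returns `path` invisibly.
#' @export
read_counts <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                   check.names = FALSE)
  if (!all(c("sgRNA", "gene") %in% names(df)))
    stop("count table must have 'sgRNA' and 'gene' columns")
  if (anyDuplicated(df$sgRNA))
    stop("duplicate sgRNA id: ", df$sgRNA[duplicated(df$sgRNA)][1])
  samp <- setdiff(names(df), c("sgRNA", "gene"))
  if (!length(samp)) stop("count table has no sample columns")
  for (s in samp) {
    v <- df[[s]]
    bad <- which(!is.finite(v) | v < 0 | v != round(v))
    if (length(bad))
      stop("non-integer or negative count in column '", s, "', row ",
           bad[1], " (sgRNA ", df$sgRNA[bad[1]], ")")
    df[[s]] <- as.integer(v)
  }
  df
}

#' @rdname read_counts
#' @export
write_counts <- function(counts, path) {
  if (inherits(counts, "sim_screen")) counts <- counts$counts
  write_tsv_with_header(counts, path)
  invisible(path)
}

#' Write gene-level screen results
#'
#' TSV with columns `gene`, `phenotype`, `rho`, `p_depleted`,
#' `p_enriched`, `fdr`, `n_sgRNAs`.
#'
#' @param fit an `rra_screen` fit (or its `genes` data.frame).
#' @param path output path.
#' @export
write_results <- function(fit, path) {
  g <- if (inherits(fit, "rra_screen")) fit$genes else fit
  write_tsv_with_header(
    g[, c("gene", "phenotype", "rho", "p_depleted", "p_enriched", "fdr",
          "n_sgRNAs")], path)
  invisible(path)
}

#' Pipeline configuration
#'
#' Flat key-value configuration for [run_pipeline()]; unknown keys are
#' rejected.  Defaults cover a desk-scale demonstration run.
#'
#' @param ... overrides of the defaults listed below.
#' @return list of class `run_config`.
#' @export
run_config <- function(...) {
  defaults <- list(
    seed = 1L, out_dir = "beditscan_run",
    n_reads = 20000L, error_rate = 0.001,
    n_genes = 60L, sgrnas_per_gene = 5L, n_nontargeting = 60L,
    depth = 200, dispersion = 0.1, n_replicates = 2L, pi0 = 0.132,
    alpha = 0.25, n_perm = 1000L, pseudocount = 0.5, decimals = 1L,
    spike_gene = "gene0001", spike_effect = 0.25)
  ov <- list(...)
  unknown <- setdiff(names(ov), names(defaults))
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, ov)
  structure(cfg, class = "run_config")
}

## parse "key = value" lines of a flat config file
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- grep("^\\s*(#|$)", readLines(path), invert = TRUE, value = TRUE)
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- which(lengths(kv) != 2)
  if (length(bad)) stop("malformed config line: ", lines[bad[1]])
  vals <- lapply(kv, function(x) {
    v <- type.convert(x[2], as.is = TRUE)
    if (is.character(v)) v else v
  })
  do.call(run_config, setNames(vals, vapply(kv, `[`, "", 1)))
}

#' Run the full simulate / call / screen / validate pipeline
#'
#' Demonstration driver tying the four stages together on synthetic data:
#' (1) simulate amplicon reads at NC-like outcome frequencies and call
#' their outcomes; (2) simulate a screen with one spiked depleted gene;
#' (3) run the alpha-RRA screen test; (4) compute validation statistics
#' (z-scores and fold change of the spiked knockdown profile against
#' simulated NC replicates).  All randomness derives from `config$seed`;
#' a manifest with versions, seeds and output digests is written, so two
#' runs with the same configuration are byte-identical.
#'
#' @param config a [run_config()] (or path to a flat key-value file).
#' @return Invisibly, the manifest list; artifacts land in
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config = run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- character()

  ## stage 1: amplicon simulation + outcome calling
  site <- default_sites()$reporter
  tc <- site$target_c[1]
  spec <- outcome_spec(site, setNames(
    c(0.156, 0.066, 1 - 0.156 - 0.066),
    c(paste0("T", tc), paste0("G", tc), "WT")))
  sim <- simulate_reads(site, spec,
                        sim_config(n_reads = config$n_reads,
                                   error_rate = config$error_rate,
                                   seed = config$seed))
  fq <- file.path(config$out_dir, "reads.fastq")
  write_fastq(sim, fq)
  oc <- call_outcomes(fq, site)
  write_tsv_with_header(oc$allele_table,
                        file.path(config$out_dir, "alleles.csv"))
  write_tsv_with_header(oc$profile$absolute,
                        file.path(config$out_dir, "profile.tsv"))
  stages <- c(stages, "simulate-reads", "call-outcomes")

  ## stage 2+3: screen simulation and enrichment test
  lib <- library_spec(config$n_genes, config$sgrnas_per_gene,
                      config$n_nontargeting,
                      effect = setNames(config$spike_effect,
                                        config$spike_gene),
                      pi0 = config$pi0)
  scr <- simulate_screen(lib, sim_config(depth = config$depth,
                                         dispersion = config$dispersion,
                                         seed = config$seed + 1L),
                         n_replicates = config$n_replicates)
  write_counts(scr, file.path(config$out_dir, "counts.tsv"))
  fit <- rra_screen(scr, alpha = config$alpha, n_perm = config$n_perm,
                    pseudocount = config$pseudocount,
                    seed = config$seed + 2L)
  write_results(fit, file.path(config$out_dir, "gene_results.tsv"))
  stages <- c(stages, "simulate-screen", "screen-test")

  ## stage 4: validation statistics on the called profile
  abs_tab <- oc$profile$absolute
  ct <- abs_tab$pct[abs_tab$category == paste0("T", tc)]
  nc_sim <- with_seed(config$seed + 3L, rnorm(9, mean = ct, sd = 0.05 * ct))
  z <- zscore(ct, nc_sim)
  fc <- fold_change(15.6, 7.5, decimals = config$decimals)
  val <- data.frame(stat = c("z_vs_simulated_nc", "fold_example"),
                    value = c(as.numeric(z)[1], fc$fold))
  write_tsv_with_header(val, file.path(config$out_dir, "validation.tsv"))
  stages <- c(stages, "validate")

  outs <- list.files(config$out_dir, full.names = TRUE)
  outs <- outs[!grepl("manifest\\.json$", outs)]
  manifest <- list(tool = "beditscan", version = .bedit_version(),
                   seed = config$seed, stages = stages,
                   config = unclass(config),
                   digests = as.list(tools::md5sum(sort(outs))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  bedit_log("run_pipeline: completed ", length(stages), " stages in ",
            config$out_dir)
  invisible(manifest)
}
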