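#' Specify an editing-outcome mixture for read simulation
#'
#' An outcome specification assigns a frequency to each editing outcome
#' category at a site.  Categories are named in the field's tract-plot
#' style: `"WT"` (unedited), `"indel"`, or a slash-separated list of
#' per-position conversions on the protospacer strand such as `"T10"`
#' (single C-to-T at protospacer position 10), `"G14"`, `"T10/T16"` (dual
#' C-to-T) or `"T10/G14"` (mixed).  Positions must be declared target Cs of
#' the site; target Cs not mentioned in a category remain unedited.
#'
#' @param site a [target_site()].
#' @param freqs named numeric vector of category frequencies; must include
#'   `"WT"` and sum to 1 (tolerance 1e-9).
#' @return An object of class `outcome_spec`.
#' @examples
#' site <- default_sites()$reporter
#' spec <- outcome_spec(site, c("T8" = 0.156, "G8" = 0.066, WT = 0.778))
#' @export
outcome_spec <- function(site, freqs) {
  stopifnot(inherits(site, "target_site"))
  if (is.null(names(freqs)) || any(!nzchar(names(freqs))))
    stop("freqs must be a named vector of category frequencies")
  if (anyDuplicated(names(freqs))) stop("duplicate category names")
  if (!"WT" %in% names(freqs)) stop("a WT category is required")
  if (any(freqs < 0) || abs(sum(freqs) - 1) > 1e-9)
    stop("frequencies must be non-negative and sum to 1")
  for (cat in setdiff(names(freqs), c("WT", "indel")))
    parse_category(cat, site)   # validates
  structure(list(site = site$site_id, freqs = freqs), class = "outcome_spec")
}

## parse "T10/G14" into data.frame(pos, base); validates against the site
parse_category <- function(cat, site) {
  toks <- strsplit(cat, "/", fixed = TRUE)[[1]]
  m <- regmatches(toks, regexec("^([ATG])([0-9]+)$", toks))
  if (any(lengths(m) != 3))
    stop("cannot parse outcome category '", cat,
         "' (expected e.g. 'T10' or 'T10/G14')")
  pos <- as.integer(vapply(m, `[`, "", 3))
  base <- vapply(m, `[`, "", 2)
  if (any(!pos %in% site$target_c))
    stop("category '", cat, "' uses non-target position(s) ",
         paste(setdiff(pos, site$target_c), collapse = ","))
  if (anyDuplicated(pos)) stop("category '", cat, "' repeats a position")
  data.frame(pos = pos, base = base)
}

## full amplicon sequence for one substitution category
category_sequence <- function(site, cat) {
  if (cat == "WT") return(site$amplicon)
  ed <- parse_category(cat, site)
  amp <- strsplit(site$amplicon, "")[[1]]
  ref <- proto_to_ref(site, ed$pos)
  amp[ref] <- if (site$strand == "forward") ed$base
              else unname(comp_base(ed$base))
  paste(amp, collapse = "")
}

#' Simulation configuration
#'
#' @param n_reads number of amplicon reads to simulate.
#' @param error_rate per-base substitution error probability (< 0.05).
#' @param depth sequencing depth per sgRNA for screen simulation (the
#'   screens were sequenced to at least 200x per sgRNA).
#' @param dispersion negative-binomial dispersion of the count model.
#' @param seed integer seed fixing every random draw.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_reads = 50000L, error_rate = 0.001, depth = 200,
                       dispersion = 0.1, seed = 1L) {
  stopifnot(n_reads > 0, depth > 0, dispersion >= 0)
  if (error_rate < 0 || error_rate >= 0.05)
    stop("error_rate must be in [0, 0.05)")
  structure(list(n_reads = as.integer(n_reads), error_rate = error_rate,
                 depth = depth, dispersion = dispersion,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate amplicon reads with known editing outcomes
#'
#' Draws a multinomial sample of outcome categories, applies each
#' category's substitutions at the target C positions (or an indel
#' overlapping the quantification window: deletions of 1-10 nt or
#' insertions of 1-3 nt), then applies uniform per-base substitution
#' errors.  Reads span the full amplicon; base qualities are constant Q30.
#'
#' @param site a [target_site()].
#' @param spec an [outcome_spec()].
#' @param cfg a [sim_config()]; `n_reads`, `error_rate` and `seed` are used.
#' @return A list of class `sim_reads` with elements `reads` (character
#'   vector), `ids`, `truth` (data.frame `read_id`, `category`), `site`,
#'   and `spec`.  Category counts are multinomial in `spec$freqs`.
#' @seealso [write_fastq()], [call_outcomes()]
#' @export
simulate_reads <- function(site, spec, cfg) {
  stopifnot(inherits(site, "target_site"), inherits(spec, "outcome_spec"),
            inherits(cfg, "sim_config"))
  if (spec$site != site$site_id)
    stop("outcome_spec was built for site '", spec$site, "'")
  cats <- names(spec$freqs)
  with_seed(cfg$seed, {
    draw <- sample(cats, cfg$n_reads, replace = TRUE, prob = spec$freqs)
    reads <- character(cfg$n_reads)
    for (cat in setdiff(cats, "indel")) {
      idx <- which(draw == cat)
      if (length(idx)) reads[idx] <- category_sequence(site, cat)
    }
    idx <- which(draw == "indel")
    if (length(idx)) reads[idx] <- vapply(idx, function(i)
      .plant_indel(site), "")
    if (cfg$error_rate > 0) reads <- .apply_errors(reads, cfg$error_rate)
    ids <- sprintf("read%06d", seq_len(cfg$n_reads))
    structure(list(reads = reads, ids = ids,
                   truth = data.frame(read_id = ids, category = draw,
                                      stringsAsFactors = FALSE),
                   site = site, spec = spec),
              class = "sim_reads")
  })
}

## one indel read: deletion of 1-10 nt or insertion of 1-3 nt placed so it
## overlaps the quantification window and stays inside the amplicon
.plant_indel <- function(site) {
  w <- window_ref(site)
  len <- nchar(site$amplicon)
  if (runif(1) < 0.5) {  # deletion
    L <- sample.int(10L, 1L)
    lo <- max(1L, w[1] - L + 1L); hi <- min(w[2], len - L + 1L)
    s <- sample(lo:hi, 1L)
    paste0(substr(site$amplicon, 1L, s - 1L),
           substr(site$amplicon, s + L, len))
  } else {               # insertion after position s, strictly in-window
    L <- sample.int(3L, 1L)
    s <- sample(w[1]:(w[2] - 1L), 1L)
    ins <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                 collapse = "")
    paste0(substr(site$amplicon, 1L, s), ins,
           substr(site$amplicon, s + 1L, len))
  }
}

## uniform substitution errors: each base flips to one of the other three
.apply_errors <- function(reads, rate) {
  n_err <- rbinom(length(reads), nchar(reads), rate)
  hit <- which(n_err > 0)
  for (i in hit) {
    pos <- sample.int(nchar(reads[i]), n_err[i])
    for (p in pos) {
      b <- substr(reads[i], p, p)
      substr(reads[i], p, p) <- sample(setdiff(c("A", "C", "G", "T"), b), 1L)
    }
  }
  reads
}

#' Write simulated reads as FASTQ
#'
#' Four-line FASTQ records (Phred+33) with constant Q30 qualities.
#'
#' @param x a `sim_reads` object from [simulate_reads()].
#' @param path output path; a `.gz` suffix gzip-compresses.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(x, path) {
  stopifnot(inherits(x, "sim_reads"))
  qual <- vapply(nchar(x$reads), function(n)
    paste(rep("?", n), collapse = ""), "")      # '?' is Phred+33 Q30
  lines <- as.vector(rbind(paste0("@", x$ids), x$reads, "+", qual))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
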