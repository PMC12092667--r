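#' Describe an amplicon target site for base-editing quantification
#'
#' A target site couples a reference amplicon with the geometry of the
#' protospacer the base editor is directed to: where the protospacer sits on
#' the amplicon, which strand it is on, which cytosines inside the editing
#' window are the targets, and where the Cas9 nickase cuts.  Protospacer
#' positions are 1-based and counted from the PAM-distal 5' end, so "C10"
#' is the tenth protospacer base; the PAM is 3' of the protospacer.
#'
#' @param site_id character scalar naming the site.
#' @param amplicon reference amplicon sequence (A/C/G/T, 100-400 nt).
#' @param protospacer_start 0-based offset of the protospacer footprint on
#'   the (forward) amplicon.
#' @param protospacer_len protospacer length in nt (20 or 21).
#' @param strand `"forward"` if the protospacer strand is the amplicon
#'   strand as given, `"reverse"` if it is the reverse complement.
#' @param target_c integer vector of 1-based protospacer positions carrying
#'   the target cytosines (e.g. `c(10, 16)`).
#' @param nick_offset 1-based protospacer position immediately 5' of the
#'   nick on the sgRNA-complementary strand; the default 17 places the nick
#'   3 bp 5' of the PAM, the canonical Cas9n HNH cut.
#' @param window_halfwidth half-width of the quantification window centred
#'   on the nick, in protospacer coordinates (default 10).
#' @return An object of class `target_site`.
#' @seealso [default_sites()], [call_outcomes()]
#' @export
target_site <- function(site_id, amplicon, protospacer_start, protospacer_len,
                        strand = c("forward", "reverse"), target_c,
                        nick_offset = 17L, window_halfwidth = 10L) {
  strand <- match.arg(strand)
  amplicon <- toupper(as.character(amplicon))
  if (!grepl("^[ACGT]+$", amplicon))
    stop("amplicon must contain only A/C/G/T")
  if (nchar(amplicon) < 100 || nchar(amplicon) > 400)
    stop("amplicon length must be in 100-400 nt, got ", nchar(amplicon))
  protospacer_len <- as.integer(protospacer_len)
  if (!protospacer_len %in% c(20L, 21L))
    stop("protospacer_len must be 20 or 21")
  protospacer_start <- as.integer(protospacer_start)
  if (protospacer_start < 0 ||
      protospacer_start + protospacer_len > nchar(amplicon))
    stop("protospacer does not fit inside the amplicon")
  target_c <- sort(unique(as.integer(target_c)))
  if (length(target_c) < 1 || any(target_c < 1 | target_c > protospacer_len))
    stop("target_c positions must lie in 1..protospacer_len")
  nick_offset <- as.integer(nick_offset)
  if (nick_offset < 1 || nick_offset > protospacer_len)
    stop("nick_offset must lie in 1..protospacer_len")
  window_halfwidth <- as.integer(window_halfwidth)
  if (window_halfwidth < 1) stop("window_halfwidth must be >= 1")

  site <- structure(
    list(site_id = as.character(site_id), amplicon = amplicon,
         protospacer_start = protospacer_start,
         protospacer_len = protospacer_len, strand = strand,
         target_c = target_c, nick_offset = nick_offset,
         window_halfwidth = window_halfwidth),
    class = "target_site")

  ## every declared target position must read C on the protospacer strand
  bad <- target_c[proto_base(site, target_c) != "C"]
  if (length(bad))
    stop("protospacer position(s) ", paste(bad, collapse = ", "),
         " do not carry a C on the protospacer strand")
  w <- window_ref(site)
  if (w[1] < 1 || w[2] > nchar(amplicon))
    stop("quantification window extends outside the amplicon")
  site
}

## map 1-based protospacer positions to 1-based amplicon positions
proto_to_ref <- function(site, pos) {
  if (site$strand == "forward") site$protospacer_start + pos
  else site$protospacer_start + site$protospacer_len - pos + 1L
}

## base at protospacer position(s), read on the protospacer strand
proto_base <- function(site, pos) {
  b <- substring(site$amplicon, proto_to_ref(site, pos), proto_to_ref(site, pos))
  if (site$strand == "reverse") b <- unname(comp_base(b))
  b
}

## quantification window as an amplicon [start, end] range (1-based),
## centred on the nick: protospacer positions nick_offset +/- halfwidth
window_ref <- function(site) {
  p <- c(site$nick_offset - site$window_halfwidth,
         site$nick_offset + site$window_halfwidth)
  sort(proto_to_ref(site, p))
}

#' @export
print.target_site <- function(x, ...) {
  cat("Target site:", x$site_id, "\n")
  cat("  amplicon:", nchar(x$amplicon), "nt; protospacer",
      x$protospacer_len, "nt at offset", x$protospacer_start,
      paste0("(", x$strand, " strand)"), "\n")
  cat("  target C positions:", paste0("C", x$target_c, collapse = ", "),
      "; nick after position", x$nick_offset, "\n")
  w <- window_ref(x)
  cat("  quantification window: amplicon", w[1], "-", w[2],
      paste0("(halfwidth ", x$window_halfwidth, ")"), "\n")
  invisible(x)
}

## deterministic synthetic amplicon: random non-C background within the
## window so that only the declared target positions carry a C there
.synth_amplicon <- function(seed, len, proto_start, proto_len, strand,
                            target_c, nick_offset = 17L, halfwidth = 10L) {
  with_seed(seed, {
    amp <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    ## window footprint in amplicon coordinates (strand-aware)
    site0 <- list(protospacer_start = proto_start, protospacer_len = proto_len,
                  strand = strand)
    p <- (nick_offset - halfwidth):(nick_offset + halfwidth)
    refw <- if (strand == "forward") proto_start + p
            else proto_start + proto_len - p + 1L
    refw <- refw[refw >= 1 & refw <= len]
    ## protospacer-strand C at a window position means amplicon C (forward)
    ## or amplicon G (reverse); scrub both, then plant the targets
    forbidden <- if (strand == "forward") "C" else "G"
    amp[refw][amp[refw] == forbidden] <-
      sample(setdiff(c("A", "C", "G", "T"), forbidden), sum(amp[refw] == forbidden),
             replace = TRUE)
    reft <- if (strand == "forward") proto_start + target_c
            else proto_start + proto_len - target_c + 1L
    amp[reft] <- if (strand == "forward") "C" else "G"
    paste(amp, collapse = "")
  })
}

#' Built-in synthetic target sites
#'
#' Returns three synthetic stand-in sites with the geometries used
#' throughout the package: a reporter-like site with a single target C in
#' the editing window (mimicking a codon-optimised fluorescent reporter
#' where only one target C is editable), a HEK3-like endogenous site with
#' target Cs at protospacer positions 10 and 16 (C16 one base pair from the
#' nick), and an RNF2-like site with target Cs at positions 10 and 14.
#' Sequences are deterministic synthetic constructs, not the real loci;
#' real amplicons can be supplied through [target_site()] or a site file.
#'
#' @return A named list of [target_site()] objects.
#' @examples
#' sites <- default_sites()
#' sites$hek3_like$target_c   # 10 16
#' @export
default_sites <- function() {
  list(
    reporter = target_site(
      "reporter", .synth_amplicon(101L, 220L, 90L, 21L, "forward", 8L),
      protospacer_start = 90, protospacer_len = 21, strand = "forward",
      target_c = 8),
    hek3_like = target_site(
      "hek3_like", .synth_amplicon(102L, 240L, 100L, 20L, "forward", c(10L, 16L)),
      protospacer_start = 100, protospacer_len = 20, strand = "forward",
      target_c = c(10, 16)),
    rnf2_like = target_site(
      "rnf2_like", .synth_amplicon(103L, 240L, 110L, 20L, "reverse", c(10L, 14L)),
      protospacer_start = 110, protospacer_len = 20, strand = "reverse",
      target_c = c(10, 14))
  )
}

#' Read and write site description files
#'
#' Site files are tab-separated with one site per row and columns
#' `site_id`, `amplicon`, `protospacer_start`, `protospacer_len`, `strand`,
#' `target_c_positions` (comma-separated), `nick_offset`,
#' `window_halfwidth`.  Reading validates every record through
#' [target_site()], so malformed rows fail with the offending field named.
#'
#' @param path file path.
#' @param sites named list of `target_site` objects (for writing).
#' @return `read_site_file()` returns a named list of `target_site`
#'   objects; `write_site_file()` returns `path` invisibly.
#' @export
read_site_file <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("site_id", "amplicon", "protospacer_start", "protospacer_len",
            "strand", "target_c_positions", "nick_offset", "window_halfwidth")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("site file missing column(s): ",
                         paste(miss, collapse = ", "))
  out <- lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    target_site(r$site_id, r$amplicon, r$protospacer_start,
                r$protospacer_len, r$strand,
                as.integer(strsplit(as.character(r$target_c_positions), ",")[[1]]),
                r$nick_offset, r$window_halfwidth)
  })
  names(out) <- df$site_id
  out
}

#' @rdname read_site_file
#' @export
write_site_file <- function(sites, path) {
  if (inherits(sites, "target_site")) sites <- list(sites)
  df <- do.call(rbind, lapply(sites, function(s) {
    data.frame(site_id = s$site_id, amplicon = s$amplicon,
               protospacer_start = s$protospacer_start,
               protospacer_len = s$protospacer_len, strand = s$strand,
               target_c_positions = paste(s$target_c, collapse = ","),
               nick_offset = s$nick_offset,
               window_halfwidth = s$window_halfwidth)
  }))
  write_tsv_with_header(df, path)
  invisible(path)
}
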