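## default scoring for read-vs-amplicon global alignment
default_scoring <- function() {
  list(match = 2, mismatch = -3, gap_open = -10, gap_extend = -1)
}

.subst_matrix <- function(scoring) {
  ## N is scored as a mismatch against everything, including N
  bases <- c("A", "C", "G", "T", "N")
  m <- matrix(scoring$mismatch, 5, 5, dimnames = list(bases, bases))
  diag(m)[1:4] <- scoring$match
  m
}

#' Globally align an amplicon read to its reference
#'
#' Needleman-Wunsch global alignment with affine gap penalties (defaults:
#' match +2, mismatch -3, gap open -10, gap extend -1; a gap of length L
#' costs 10 + L).  Returns an edit transcript in reference coordinates:
#' the base call at every reference position (`-` for deleted bases) plus
#' deletion and insertion spans.  Reads scoring below
#' `min_score_frac` times the perfect score (match x amplicon length) are
#' flagged unalignable.  Ambiguous bases (N) score as mismatches.
#'
#' @param read read sequence (>= 30 nt).
#' @param site a [target_site()].
#' @param scoring list with `match`, `mismatch`, `gap_open`, `gap_extend`.
#' @param min_score_frac unalignable threshold as a fraction of the
#'   perfect score (default 0.6).
#' @return A list of class `read_alignment`: `score`, `unalignable`,
#'   `calls` (character vector, one call per reference position),
#'   `deletions` (data.frame `start`, `end` in reference coordinates),
#'   `insertions` (data.frame `after`, `len`: bases inserted after the
#'   given reference position).
#' @export
align_read <- function(read, site, scoring = default_scoring(),
                       min_score_frac = 0.6) {
  stopifnot(inherits(site, "target_site"))
  read <- toupper(as.character(read))
  if (!nzchar(read)) stop("empty read")
  if (nchar(read) < 30) stop("read shorter than 30 nt")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(read), Biostrings::DNAString(site$amplicon),
    type = "global", substitutionMatrix = .subst_matrix(scoring),
    gapOpening = -scoring$gap_open, gapExtension = -scoring$gap_extend)
  .transcript(pa, 1L, site, scoring, min_score_frac)
}

## Biostrings charges gapOpening once per gap plus gapExtension per gap
## position (first position included), so a length-L gap costs
## |open| + L*|extend| -- the convention used throughout this package.

## build the transcript for read i of a (possibly vectorised) alignment;
## aligned pattern/subject strings may be passed precomputed for speed
.transcript <- function(pa, i, site, scoring, min_score_frac,
                        ap = NULL, as_ = NULL, sc = NULL) {
  ref_len <- nchar(site$amplicon)
  if (is.null(ap)) ap <- as.character(Biostrings::pattern(pa))[i]
  if (is.null(as_)) as_ <- as.character(Biostrings::subject(pa))[i]
  if (is.null(sc)) sc <- Biostrings::score(pa[i])
  aln_p <- strsplit(ap, "")[[1]]
  aln_s <- strsplit(as_, "")[[1]]
  calls <- character(ref_len)
  dels <- list(); inss <- list()
  ref <- 0L
  j <- 1L
  while (j <= length(aln_s)) {
    if (aln_s[j] == "-") {              # insertion relative to reference
      k <- j
      while (k < length(aln_s) && aln_s[k + 1L] == "-") k <- k + 1L
      inss[[length(inss) + 1L]] <- c(after = ref, len = k - j + 1L)
      j <- k + 1L
    } else {
      ref <- ref + 1L
      calls[ref] <- aln_p[j]
      j <- j + 1L
    }
  }
  ## deletion spans from runs of "-" in the reference-coordinate calls
  r <- rle(calls == "-")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  del <- data.frame(start = starts[r$values], end = ends[r$values])
  ins <- if (length(inss))
    data.frame(after = vapply(inss, `[[`, 0L, "after"),
               len = vapply(inss, `[[`, 0L, "len"))
  else data.frame(after = integer(), len = integer())
  structure(list(score = sc,
                 unalignable = sc < min_score_frac * scoring$match * ref_len,
                 calls = calls, deletions = del, insertions = ins),
            class = "read_alignment")
}

## Batch align-and-classify used by call_outcomes().  Reads equal in
## length to the amplicon with few mismatches are provably gapless under
## the default scoring (one insertion + one deletion cost at least
## 2*(|open| + |extend|) = 22, more than 4 mismatches' 4*(match -
## mismatch) = 20, so <= 4 mismatches guarantees the gapless alignment is
## optimal); those are classified by vectorised byte comparison.  The
## remainder goes through pairwiseAlignment and the per-read
## classify_read(), whose semantics this path reproduces exactly.
## Returns data.frame(status, category, allele_key).
classify_reads_batch <- function(reads, site, scoring = default_scoring(),
                                 min_score_frac = 0.6) {
  n <- length(reads)
  ref_len <- nchar(site$amplicon)
  status <- character(n); category <- rep(NA_character_, n)
  key <- rep(NA_character_, n)

  eq <- which(nchar(reads) == ref_len & !grepl("N", reads, fixed = TRUE))
  fast <- integer(0)
  if (length(eq)) {
    rawmat <- matrix(charToRaw(paste(reads[eq], collapse = "")),
                     nrow = ref_len)
    refraw <- charToRaw(site$amplicon)
    mm <- as.integer(colSums(rawmat != refraw))
    fast <- eq[mm <= 4L]
    if (length(fast)) {
      tpos <- site$target_c
      tref <- proto_to_ref(site, tpos)
      w <- window_ref(site)
      ## per-target-C calls on the protospacer strand
      calls <- vapply(tref, function(p) substring(reads[fast], p, p),
                      character(length(fast)))
      calls <- matrix(calls, nrow = length(fast))
      if (site$strand == "reverse")
        calls <- matrix(unname(comp_base(calls)), nrow = length(fast))
      ## joint category and allele key, vectorised over reads
      keyparts <- lapply(seq_along(tpos), function(j)
        paste0(calls[, j], "@", tpos[j]))
      key[fast] <- do.call(paste, c(keyparts, sep = "|"))
      catp <- lapply(seq_along(tpos), function(j)
        ifelse(calls[, j] != "C", paste0(calls[, j], tpos[j]), ""))
      cats <- do.call(paste, c(catp, sep = "/"))
      cats <- gsub("^/+|/+$", "", gsub("/{2,}", "/", cats))
      edited <- cats != ""
      ## substitutions inside the window at non-target positions
      wpos <- setdiff(w[1]:w[2], tref)
      sub_eq <- match(fast, eq)
      mm_nt <- colSums(rawmat[wpos, sub_eq, drop = FALSE] != refraw[wpos]) > 0
      status[fast] <- ifelse(edited | !mm_nt, "classified", "other-edit")
      category[fast] <- ifelse(edited, cats,
                               ifelse(mm_nt, NA_character_, "WT"))
    }
  }

  slow <- setdiff(seq_len(n), fast)
  if (length(slow)) {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(reads[slow]),
      Biostrings::DNAString(site$amplicon),
      type = "global", substitutionMatrix = .subst_matrix(scoring),
      gapOpening = -scoring$gap_open, gapExtension = -scoring$gap_extend)
    ## pattern()/subject() give the gapped alignment strings directly and
    ## are far cheaper than alignedPattern()/alignedSubject()
    aps <- as.character(Biostrings::pattern(pa))
    ass <- as.character(Biostrings::subject(pa))
    scs <- Biostrings::score(pa)
    for (k in seq_along(slow)) {
      aln <- .transcript(pa, k, site, scoring, min_score_frac,
                         ap = aps[k], as_ = ass[k], sc = scs[k])
      cl <- classify_read(aln, site)
      i <- slow[k]
      status[i] <- cl$status; category[i] <- cl$category
      key[i] <- cl$allele_key
    }
  }
  data.frame(status = status, category = category, allele_key = key,
             stringsAsFactors = FALSE)
}

## base call at reference position(s) of a read_alignment
aln_calls_at <- function(aln, pos) aln$calls[pos]
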