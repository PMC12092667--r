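#' Classify an aligned read into an editing-outcome category
#'
#' Applies the mutually exclusive outcome taxonomy used for tract plots.
#' Precedence: (1) any indel overlapping the quantification window makes
#' the read `indel`; (2) otherwise the base call at every target C, read on
#' the protospacer strand (reverse-complemented for reverse-strand sites),
#' defines the category -- `WT` if all targets still read C, else a joint
#' key such as `T10`, `T10/T16` or `T10/G14`; (3) reads whose only window
#' substitutions sit at non-target positions are flagged `other-edit` and
#' excluded from the joint taxonomy (they still count towards read totals).
#' Reads whose alignment does not cover the window (terminal gaps across
#' it) are `dropped`; unalignable reads are reported as `unalignable`.
#'
#' @param aln a `read_alignment` from [align_read()].
#' @param site the [target_site()] the read was aligned to.
#' @return A list: `status` in `classified` / `other-edit` / `dropped` /
#'   `unalignable`; `category` (taxonomy label or NA); `allele_key` like
#'   `"T@10|C@16"` giving the per-target-C calls.
#' @export
classify_read <- function(aln, site) {
  stopifnot(inherits(aln, "read_alignment"), inherits(site, "target_site"))
  if (aln$unalignable)
    return(list(status = "unalignable", category = NA_character_,
                allele_key = NA_character_))
  w <- window_ref(site)
  ref_len <- nchar(site$amplicon)
  del <- aln$deletions
  if (nrow(del)) {
    ## terminal gaps (read not covering the amplicon end) spanning the
    ## window mean the window was not sequenced: drop, don't call indel
    term <- (del$start == 1L) | (del$end == ref_len)
    if (any(term & del$start <= w[2] & del$end >= w[1]))
      return(list(status = "dropped", category = NA_character_,
                  allele_key = NA_character_))
    internal <- del[!term, , drop = FALSE]
    if (any(internal$start <= w[2] & internal$end >= w[1]))
      return(.classified("indel", NA_character_))
  }
  ins <- aln$insertions
  if (nrow(ins) && any(ins$after >= w[1] - 1L & ins$after <= w[2]))
    return(.classified("indel", NA_character_))

  tpos <- site$target_c
  tref <- proto_to_ref(site, tpos)
  calls <- aln_calls_at(aln, tref)
  if (site$strand == "reverse") calls <- unname(comp_base(calls))
  key <- paste0(calls, "@", tpos, collapse = "|")
  edited <- calls != "C"
  if (any(edited)) {
    cat <- paste0(calls[edited], tpos[edited], collapse = "/")
    return(.classified(cat, key))
  }
  ## all target Cs intact: any other substitution inside the window?
  wpos <- setdiff(w[1]:w[2], tref)
  wcalls <- aln_calls_at(aln, wpos)
  refb <- substring(site$amplicon, wpos, wpos)
  if (any(wcalls != refb))
    return(list(status = "other-edit", category = NA_character_,
                allele_key = key))
  .classified("WT", key)
}

.classified <- function(category, key) {
  list(status = "classified", category = category, allele_key = key)
}

#' Aggregate classified reads into an outcome profile
#'
#' Computes absolute efficiencies (percent of classified reads per
#' mutually exclusive category, summing to 100 with WT), relative
#' efficiencies (percent of edited, i.e. non-WT, reads per edited
#' category), total editing, and per-position C-to-T / C-to-G / C-to-A
#' marginals obtained by summing every joint category containing that
#' conversion.  With zero edited reads the relative table is absent
#' (`NULL`), not zero.
#'
#' @param categories character vector of taxonomy categories, one per
#'   classified read (as produced by [classify_read()]), or a named
#'   numeric vector of per-category read counts.
#' @param site the [target_site()] (for the marginal positions).
#' @param include_indel_in_edited should indel reads count towards the
#'   "edited" denominator of relative efficiencies? Default TRUE.
#' @return An object of class `outcome_profile`: data.frames `absolute`
#'   (category, n_reads, pct) and `relative` (category, pct or NULL),
#'   `marginals` (position, base, pct), scalar `total_editing`, and the
#'   read counts used.
#' @export
aggregate_outcomes <- function(categories, site,
                               include_indel_in_edited = TRUE) {
  stopifnot(inherits(site, "target_site"))
  counts <- if (is.numeric(categories)) {
    if (is.null(names(categories))) stop("counts must be named by category")
    categories
  } else table(categories)
  counts <- counts[counts > 0]
  total <- sum(counts)
  if (total < 1) stop("no classified reads to aggregate")
  cats <- names(counts)
  absolute <- data.frame(category = cats, n_reads = as.vector(counts),
                         pct = 100 * as.vector(counts) / total,
                         stringsAsFactors = FALSE)
  absolute <- absolute[order(-absolute$n_reads), ]
  rownames(absolute) <- NULL

  edited_cats <- setdiff(cats, "WT")
  if (!include_indel_in_edited) edited_cats <- setdiff(edited_cats, "indel")
  n_edited <- sum(counts[edited_cats])
  relative <- NULL
  if (n_edited > 0) {
    relative <- data.frame(category = edited_cats,
                           pct = 100 * as.vector(counts[edited_cats]) / n_edited,
                           stringsAsFactors = FALSE)
    relative <- relative[order(-relative$pct), ]
    rownames(relative) <- NULL
  }

  ## per-position conversion marginals over the joint taxonomy
  marg <- expand.grid(position = site$target_c, base = c("T", "G", "A"),
                      stringsAsFactors = FALSE)
  marg$pct <- vapply(seq_len(nrow(marg)), function(i) {
    tag <- paste0(marg$base[i], marg$position[i])
    hit <- vapply(cats, function(cc)
      cc != "WT" && cc != "indel" &&
        tag %in% strsplit(cc, "/", fixed = TRUE)[[1]], TRUE)
    100 * sum(counts[cats[hit]]) / total
  }, 0)

  structure(list(absolute = absolute, relative = relative, marginals = marg,
                 total_editing = 100 * sum(counts[setdiff(cats, "WT")]) / total,
                 n_classified = total, n_edited = n_edited,
                 include_indel_in_edited = include_indel_in_edited,
                 site_id = site$site_id),
            class = "outcome_profile")
}

#' @export
print.outcome_profile <- function(x, ...) {
  cat("Editing outcome profile for site", x$site_id, "\n")
  cat(sprintf("  %d classified reads; total editing %.2f%%\n",
              x$n_classified, x$total_editing))
  cat("  absolute efficiencies (% of classified reads):\n")
  print(head(transform(x$absolute, pct = round(pct, 2)), 10))
  if (!is.null(x$relative)) {
    cat("  relative efficiencies (% of edited reads):\n")
    print(transform(x$relative, pct = round(pct, 2)))
  } else cat("  no edited reads; relative efficiencies undefined\n")
  invisible(x)
}

#' Call editing outcomes from amplicon reads
#'
#' End-to-end allele-level quantification: align every read to the site's
#' amplicon ([align_read()] semantics), classify it ([classify_read()]),
#' and aggregate ([aggregate_outcomes()]).  The constrained equivalent of
#' an amplicon-editing quantifier run with a nick-centred window of
#' halfwidth 10.
#'
#' @param fastq path to a FASTQ file (plain or gzip), a data.frame from
#'   [read_fastq()], or a `sim_reads` object.
#' @param site a [target_site()].
#' @param scoring,min_score_frac alignment parameters, see [align_read()].
#' @param include_indel_in_edited see [aggregate_outcomes()].
#' @return A list of class `outcome_call`: `allele_table` (data.frame
#'   `allele_key`, `category`, `indel_flag`, `n_reads`, `pct_reads`),
#'   `profile` (an `outcome_profile`), and `accounting` (classified /
#'   other_edit / dropped / unalignable read tallies; these sum to the
#'   input read count).
#' @export
call_outcomes <- function(fastq, site, scoring = default_scoring(),
                          min_score_frac = 0.6,
                          include_indel_in_edited = TRUE) {
  stopifnot(inherits(site, "target_site"))
  reads <- if (inherits(fastq, "sim_reads")) fastq$reads
  else if (is.data.frame(fastq)) fastq$seq
  else read_fastq(fastq)$seq
  if (length(reads) == 0) stop("no reads: the FASTQ input is empty")

  cls <- classify_reads_batch(reads, site, scoring, min_score_frac)
  status <- cls$status
  category <- cls$category
  key <- cls$allele_key

  acct <- c(classified = sum(status == "classified"),
            other_edit = sum(status == "other-edit"),
            dropped = sum(status == "dropped"),
            unalignable = sum(status == "unalignable"))
  bedit_log("call_outcomes[", site$site_id, "]: ", length(reads),
            " reads; ", acct["classified"], " classified, ",
            acct["other_edit"], " other-edit, ", acct["dropped"],
            " dropped, ", acct["unalignable"], " unalignable")
  if (acct["classified"] == 0)
    stop("no reads classified; check the site description")

  ok <- status == "classified"
  akey <- ifelse(category == "indel", "indel", key)[ok]
  tab <- table(akey, category[ok])
  at <- data.frame(allele_key = rownames(tab)[row(tab)[tab > 0]],
                   category = colnames(tab)[col(tab)[tab > 0]],
                   n_reads = as.vector(tab[tab > 0]),
                   stringsAsFactors = FALSE)
  at$indel_flag <- at$category == "indel"
  at$pct_reads <- 100 * at$n_reads / sum(at$n_reads)
  at <- at[order(-at$n_reads),
           c("allele_key", "category", "indel_flag", "n_reads", "pct_reads")]
  rownames(at) <- NULL

  profile <- aggregate_outcomes(category[ok], site,
                                include_indel_in_edited = include_indel_in_edited)
  structure(list(allele_table = at, profile = profile, accounting = acct,
                 site_id = site$site_id),
            class = "outcome_call")
}

#' @export
print.outcome_call <- function(x, ...) {
  cat("Outcome call for site", x$site_id, "\n")
  cat("  reads:", paste(names(x$accounting), x$accounting, collapse = ", "),
      "\n")
  print(x$profile)
  invisible(x)
}
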