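#' Alignment scoring scheme
#'
#' Container for the nucleotide scoring scheme used by [local_align()] and
#' [search_genome()]. A gap of length g scores `gap_open + g * gap_extend`
#' (the opening penalty is charged once per gap, the extension penalty per
#' gapped base). Defaults match a stringent nucleotide-search scheme:
#' match +2, mismatch -3, gap open -5, gap extend -2.
#'
#' @param match,mismatch,gap_open,gap_extend integer scores; `mismatch`,
#'   `gap_open` and `gap_extend` must be negative
#' @return list of class `align_scoring`
#' @export
align_scoring <- function(match = 2, mismatch = -3, gap_open = -5,
                          gap_extend = -2) {
  stopifnot(match > 0, mismatch < 0, gap_open <= 0, gap_extend < 0)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend)),
            class = "align_scoring")
}

#' Best local alignment of a query against a reference
#'
#' Affine-gap Smith-Waterman considering both query orientations. Ties
#' between orientations are broken in favour of the forward strand; within
#' an orientation the earliest (lowest reference end coordinate) maximal
#' cell is reported. Intervals are 0-based half-open; minus-strand query
#' intervals are reported in original query coordinates.
#'
#' @param query,reference DNA strings (non-empty)
#' @param scoring an [align_scoring()] scheme
#' @param both_strands also consider the reverse complement of the query?
#' @return list of class `local_alignment` with elements `score`, `strand`
#'   (`"+"`/`"-"`), `query_start`, `query_end`, `ref_start`, `ref_end`,
#'   `matches`, `mismatches`, `gap_opens`, `gap_bases`, `align_length`
#'   (alignment columns) and `identity` (percent of columns that match).
#'   A query with no positive-scoring local alignment returns `score = 0`
#'   and `NA` intervals.
#' @export
local_align <- function(query, reference, scoring = align_scoring(),
                        both_strands = TRUE) {
  query <- check_dna_loose(query, "query")
  reference <- check_dna_loose(reference, "reference")
  fwd <- sw_align_cpp(query, reference, scoring$match, scoring$mismatch,
                      scoring$gap_open, scoring$gap_extend)
  best <- fwd; strand <- "+"
  if (both_strands) {
    rc <- dna_revcomp(query)
    rev <- sw_align_cpp(rc, reference, scoring$match, scoring$mismatch,
                        scoring$gap_open, scoring$gap_extend)
    if (rev$score > fwd$score) { best <- rev; strand <- "-" }
  }
  if (best$score <= 0) {
    return(structure(list(score = 0, strand = NA_character_,
                          query_start = NA_integer_, query_end = NA_integer_,
                          ref_start = NA_integer_, ref_end = NA_integer_,
                          matches = 0L, mismatches = 0L, gap_opens = 0L,
                          gap_bases = 0L, align_length = 0L,
                          identity = NA_real_),
                     class = "local_alignment"))
  }
  qs <- best$qstart; qe <- best$qend
  if (strand == "-") {
    L <- nchar(query)
    tmp <- qs; qs <- L - qe; qe <- L - tmp
  }
  structure(list(score = best$score, strand = strand,
                 query_start = qs, query_end = qe,
                 ref_start = best$rstart, ref_end = best$rend,
                 matches = best$matches, mismatches = best$mismatches,
                 gap_opens = best$gap_opens, gap_bases = best$gap_bases,
                 align_length = best$align_len,
                 identity = 100 * best$matches / best$align_len),
            class = "local_alignment")
}

# like check_dna but allows N (reads can contain Ns; N never matches)
check_dna_loose <- function(x, what) {
  if (length(x) != 1L || is.na(x) || !nzchar(x)) {
    stop(what, " must be a non-empty string")
  }
  x <- toupper(x)
  if (grepl("[^ACGTN]", x)) stop(what, " contains non-ACGTN characters")
  x
}

#' @export
print.local_alignment <- function(x, ...) {
  if (x$score == 0) { cat("local_alignment: no alignment\n"); return(invisible(x)) }
  cat(sprintf(
    "local_alignment: score %d, strand %s, query [%d,%d), ref [%d,%d), %.1f%% identity\n",
    x$score, x$strand, x$query_start, x$query_end, x$ref_start, x$ref_end,
    x$identity))
  invisible(x)
}

#' Trim 3' adapter read-through
#'
#' Removes the longest 3'-terminal read suffix that matches a prefix of the
#' adapter with at least `min_overlap` aligned bases and at most
#' `max_mismatch_rate` mismatches. An adapter fully contained near the 3'
#' end (followed by filler bases, as produced when the insert plus adapter
#' is shorter than the read) is also removed, together with everything
#' after it. Reads with no acceptable match are returned unchanged.
#'
#' @param read character vector of read sequences
#' @param adapter adapter sequence (non-empty)
#' @param min_overlap minimum aligned bases (default 8)
#' @param max_mismatch_rate maximum mismatch fraction (default 0.1)
#' @return character vector of trimmed reads
#' @export
trim_adapter <- function(read, adapter, min_overlap = 8,
                         max_mismatch_rate = 0.1) {
  adapter <- check_dna_loose(adapter, "adapter")
  trim_adapter_cpp(toupper(read), adapter, as.integer(min_overlap),
                   max_mismatch_rate)
}
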