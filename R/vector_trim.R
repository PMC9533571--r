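#' Construct a read-pair table
#'
#' Read pairs are carried as a plain data.frame with one row per pair and
#' library metadata columns. Read 1 is the genome-walking end of the
#' amplicon, read 2 the transgene (border) end.
#'
#' @param id character vector of pair identifiers
#' @param read1_seq,read2_seq DNA strings
#' @param line_id transgenic line identifier
#' @param border `"LB"` or `"RB"` -- which border library the pair came from
#' @param walking_primer_id walking-primer identifier (e.g. `"PST1"` or
#'   `"pooled"`)
#' @param library_id optional library identifier (defaults to
#'   `line_border_primer`)
#' @param read1_qual,read2_qual optional per-base quality strings
#' @return data.frame of read pairs
#' @export
make_read_pairs <- function(id, read1_seq, read2_seq, line_id = "line1",
                            border = "LB", walking_primer_id = "PST1",
                            library_id = NULL,
                            read1_qual = NA_character_,
                            read2_qual = NA_character_) {
  stopifnot(all(border %in% c("LB", "RB")))
  if (anyDuplicated(id)) stop("read pair ids must be unique")
  n <- length(id)
  rl <- function(x) rep_len(x, n)
  data.frame(
    id = as.character(id),
    read1_seq = toupper(rl(read1_seq)), read2_seq = toupper(rl(read2_seq)),
    read1_qual = rl(read1_qual), read2_qual = rl(read2_qual),
    line_id = rl(line_id), border = rl(border),
    walking_primer_id = rl(walking_primer_id),
    library_id = rl(library_id %||% paste(line_id, border,
                                          walking_primer_id, sep = "_")),
    stringsAsFactors = FALSE
  )
}

#' Read a paired FASTQ library
#'
#' Reads two FASTQ files (plain or gzipped) into a read-pair table. Read
#' names are truncated at the first whitespace and must agree between the
#' two files.
#'
#' @param r1,r2 FASTQ paths for read 1 and read 2
#' @inheritParams make_read_pairs
#' @return data.frame as from [make_read_pairs()]
#' @export
read_paired_fastq <- function(r1, r2, line_id = "line1", border = "LB",
                              walking_primer_id = "PST1", library_id = NULL) {
  s1 <- Biostrings::readDNAStringSet(r1, format = "fastq", with.qualities = TRUE)
  s2 <- Biostrings::readDNAStringSet(r2, format = "fastq", with.qualities = TRUE)
  n1 <- sub("\\s.*$", "", names(s1)); n2 <- sub("\\s.*$", "", names(s2))
  if (length(s1) != length(s2) || !identical(n1, n2)) {
    stop("read 1 and read 2 FASTQ files do not pair up")
  }
  q1 <- as.character(S4Vectors::mcols(s1)$qualities %||% NA_character_)
  q2 <- as.character(S4Vectors::mcols(s2)$qualities %||% NA_character_)
  make_read_pairs(n1, as.character(s1), as.character(s2), line_id = line_id,
                  border = border, walking_primer_id = walking_primer_id,
                  library_id = library_id,
                  read1_qual = q1, read2_qual = q2)
}

# Align one read sequence to the vector reference (one or more construct
# sequences) and measure its placement confidence: margin = best score
# minus the best alternative placement (the best of: any other construct,
# the opposite strand, and the same construct/strand with the best
# interval masked out). This is the mapping-quality analog used as the
# confidence filter.
align_to_vector_one <- function(seq, vectors, scoring, min_score = 0) {
  seq <- toupper(seq)
  rc <- dna_revcomp(seq)
  # cheap score-only scan of every construct and strand
  sc <- function(q, ref) sw_score_cpp(q, ref, scoring$match, scoring$mismatch,
                                      scoring$gap_open, scoring$gap_extend)
  scores <- vapply(names(vectors), function(v)
    c(`+` = sc(seq, vectors[[v]]), `-` = sc(rc, vectors[[v]])), numeric(2))
  top <- which(scores == max(scores), arr.ind = TRUE)[1, ] # prefer + on tie
  best_score <- max(scores)
  if (best_score <= 0 || best_score < min_score) {
    return(list(score = best_score, strand = NA_character_,
                ref_start = NA_real_, ref_end = NA_real_,
                query_start = NA_real_, query_end = NA_real_,
                identity = NA_real_, margin = 0, vector_id = NA_character_))
  }
  best_id <- names(vectors)[top[["col"]]]
  strand <- c("+", "-")[top[["row"]]]
  vec <- vectors[[best_id]]
  # full alignment with traceback only for the winner
  a <- sw_align_cpp(if (strand == "+") seq else rc, vec,
                    scoring$match, scoring$mismatch,
                    scoring$gap_open, scoring$gap_extend)
  qs <- a$qstart; qe <- a$qend
  if (strand == "-") {
    L <- nchar(seq); tmp <- qs; qs <- L - qe; qe <- L - tmp
  }
  alt <- max(scores[-(top[["row"]] + (top[["col"]] - 1L) * 2L)], 0)
  # same construct and strand with the best interval masked
  masked <- paste0(substr(vec, 1, a$rstart),
                   strrep("N", a$rend - a$rstart),
                   substr(vec, a$rend + 1, nchar(vec)))
  alt <- max(alt, sc(if (strand == "+") seq else rc, masked))
  list(score = a$score, strand = strand,
       ref_start = a$rstart, ref_end = a$rend,
       query_start = qs, query_end = qe,
       identity = 100 * a$matches / a$align_len,
       margin = a$score - alt, vector_id = best_id)
}

#' Classify read pairs by their vector alignment
#'
#' Aligns each read 2 (the transgene end) to the T-DNA vector with the
#' local aligner on both strands. A pair is retained only when read 2's
#' best alignment passes the confidence filter: `score >= min_score` and
#' best-minus-second-best `score margin >= min_margin` (the second-best
#' placement is the better of the opposite strand and the same strand with
#' the best interval masked). For retained pairs read 1 is aligned and
#' recorded whether or not it maps. Identical read sequences are aligned
#' once and the result reused.
#'
#' @param pairs read-pair table from [make_read_pairs()] /
#'   [read_paired_fastq()]
#' @param vector vector reference: a string, named character vector,
#'   `DNAStringSet` or FASTA path; multiple sequences (e.g. two construct
#'   T-DNAs) are each considered and the winning construct recorded
#' @param scoring an [align_scoring()] scheme
#' @param min_score minimum read-2 alignment score (default 40)
#' @param min_margin minimum best-minus-second-best margin (default 10)
#' @param min_read_len reads shorter than this are rejected with reason
#'   `"too_short"` (default 16)
#' @return list with `records` (one row per aligned read: `read_id`,
#'   `which_read`, `vstart`/`vend` 0-based half-open on the vector,
#'   `qstart`/`qend` on the read, `strand`, `score`, `margin`, `identity`,
#'   `accepted`) and `pairs` (the input with `accepted` and `reason`
#'   columns)
#' @export
classify_read_pairs <- function(pairs, vector, scoring = align_scoring(),
                                min_score = 40, min_margin = 10,
                                min_read_len = 16) {
  vecs <- as_vector_seqs(vector)
  n <- nrow(pairs)
  too_short <- nchar(pairs$read2_seq) < min_read_len |
    nchar(pairs$read1_seq) < min_read_len

  # align each distinct read sequence once; sequences below min_score get
  # the cheap score-only treatment
  align_unique <- function(seqs, floor = 0) {
    u <- unique(seqs)
    res <- lapply(u, align_to_vector_one, vectors = vecs, scoring = scoring,
                  min_score = floor)
    stat <- function(field, default) {
      vapply(res, function(a) a[[field]] %||% default,
             if (is.character(default)) character(1) else numeric(1))
    }
    tab <- data.frame(
      seq = u,
      score = stat("score", 0), margin = stat("margin", 0),
      vstart = stat("ref_start", NA_real_), vend = stat("ref_end", NA_real_),
      qstart = stat("query_start", NA_real_), qend = stat("query_end", NA_real_),
      strand = stat("strand", NA_character_),
      identity = stat("identity", NA_real_),
      vector_id = stat("vector_id", NA_character_),
      stringsAsFactors = FALSE
    )
    tab[match(seqs, tab$seq), , drop = FALSE]
  }

  eligible <- !too_short
  a2 <- align_unique(pairs$read2_seq[eligible], floor = min_score)
  ok2 <- a2$score >= min_score & a2$margin >= min_margin

  accepted <- logical(n); reason <- character(n)
  reason[too_short] <- "too_short"
  reason[eligible][!ok2] <- ifelse(a2$score[!ok2] < min_score,
                                   "no_vector_alignment",
                                   "ambiguous_placement")
  accepted[eligible][ok2] <- TRUE
  reason[accepted] <- "accepted"

  # read 1 of accepted pairs, recorded whether or not it maps
  a1 <- align_unique(pairs$read1_seq[accepted], floor = min_score)
  ok1 <- a1$score >= min_score & a1$margin >= min_margin

  rec_of <- function(ids, which_read, a, acc) {
    if (length(ids) == 0L) return(NULL)
    acc <- rep_len(acc, length(ids))
    data.frame(read_id = ids, which_read = which_read,
               vector_id = a$vector_id,
               vstart = a$vstart, vend = a$vend,
               qstart = a$qstart, qend = a$qend, strand = a$strand,
               score = a$score, margin = a$margin, identity = a$identity,
               accepted = acc, stringsAsFactors = FALSE)
  }
  keep2 <- accepted[eligible]
  records <- rbind(
    rec_of(pairs$id[eligible][keep2], 2L, a2[keep2, , drop = FALSE], TRUE),
    rec_of(pairs$id[accepted], 1L, a1, ok1)
  )
  if (is.null(records)) {
    records <- data.frame(read_id = character(), which_read = integer(),
                          vector_id = character(), vstart = numeric(),
                          vend = numeric(), qstart = numeric(),
                          qend = numeric(), strand = character(),
                          score = numeric(), margin = numeric(),
                          identity = numeric(), accepted = logical(),
                          stringsAsFactors = FALSE)
  }
  rownames(records) <- NULL
  pairs$accepted <- accepted
  pairs$reason <- reason
  list(records = records, pairs = pairs)
}

#' @rdname classify_read_pairs
#' @param pair a single-row read-pair table
#' @export
classify_read_pair <- function(pair, vector, scoring = align_scoring(),
                               min_score = 40, min_margin = 10,
                               min_read_len = 16) {
  stopifnot(nrow(pair) == 1L)
  classify_read_pairs(pair, vector, scoring, min_score, min_margin,
                      min_read_len)
}

as_vector_seqs <- function(vector) {
  if (is.character(vector) && length(vector) == 1L && file.exists(vector) &&
      !grepl("^[ACGTNacgtn]+$", vector)) {
    vector <- Biostrings::readDNAStringSet(vector)
  }
  if (is(vector, "XString")) vector <- as.character(vector)
  if (is(vector, "XStringSet")) {
    nm <- names(vector) %||% paste0("vector", seq_along(vector))
    vector <- stats::setNames(as.character(vector), sub("\\s.*$", "", nm))
  }
  if (is.null(names(vector))) {
    names(vector) <- paste0("vector", seq_along(vector))
  }
  toupper(vector)
}

#' Recover border-distal genomic fragments from classified read pairs
#'
#' For each vector-aligned read, the unaligned terminal segment on the
#' border-distal side -- the read end that, given the alignment's position
#' and strand on the vector, points away from the T-DNA border into the
#' plant genome -- is emitted as a candidate genomic fragment when it is at
#' least `min_len` bp. A read 1 with no acceptable vector alignment is
#' emitted whole (`whole_unmapped_mate`). The clip side is computed from
#' the alignment geometry rather than hard-coded per border, so vectors
#' recorded in either orientation behave correctly given their border
#' coordinates.
#'
#' @param classified output of [classify_read_pairs()]
#' @param vector the vector reference given to [classify_read_pairs()]
#'   (used for sequence lengths and default border coordinates)
#' @param min_len minimum fragment length in bp (default 20)
#' @param vector_borders named list: for each construct, a named numeric
#'   giving the 1-based coordinate of each border junction on that
#'   sequence; default `c(RB = 1, LB = <sequence length>)` per construct,
#'   i.e. vectors recorded in RB-to-LB orientation
#' @return data.frame of fragments: `fragment_id`, `sequence`, `read_id`,
#'   `which_read`, `clip_side` (`border_distal_5prime`,
#'   `border_distal_3prime` or `whole_unmapped_mate`), `construct` (which
#'   vector sequence the pair's read 2 matched) plus the library metadata
#'   columns
#' @export
extract_genomic_fragments <- function(classified, vector, min_len = 20,
                                      vector_borders = NULL) {
  vecs <- as_vector_seqs(vector)
  vector_borders <- vector_borders %||%
    lapply(vecs, function(v) c(RB = 1, LB = nchar(v)))
  pairs <- classified$pairs[classified$pairs$accepted, , drop = FALSE]
  if (nrow(pairs) == 0L) return(empty_fragments())
  records <- classified$records

  border_coord <- function(vector_id, border) {
    mapply(function(v, bb) {
      bc <- vector_borders[[v]]
      if (is.null(bc) || is.null(bc[[bb]])) {
        stop("no border coordinate for ", bb, " on ", v)
      }
      bc[[bb]]
    }, vector_id, border)
  }

  clip_of <- function(rec, seqs, b) {
    side <- border_distal_side(rec$vstart, rec$vend, rec$strand, b)
    frag <- ifelse(side == "3p",
                   substr(seqs, rec$qend + 1L, nchar(seqs)),
                   substr(seqs, 1L, rec$qstart))
    list(side = ifelse(side == "3p", "border_distal_3prime",
                       "border_distal_5prime"),
         frag = frag)
  }

  rec2 <- records[records$which_read == 2L, , drop = FALSE]
  rec2 <- rec2[match(pairs$id, rec2$read_id), , drop = FALSE]
  construct <- rec2$vector_id
  b2 <- unname(border_coord(rec2$vector_id, pairs$border))
  c2 <- clip_of(rec2, pairs$read2_seq, b2)

  rec1 <- records[records$which_read == 1L, , drop = FALSE]
  rec1 <- rec1[match(pairs$id, rec1$read_id), , drop = FALSE]
  r1_mapped <- !is.na(rec1$read_id) & rec1$accepted
  b1 <- b2
  if (any(r1_mapped)) {
    b1[r1_mapped] <- unname(unlist(border_coord(
      rec1$vector_id[r1_mapped], pairs$border[r1_mapped])))
  }
  c1 <- clip_of(rec1, pairs$read1_seq, b1)
  c1$side[!r1_mapped] <- "whole_unmapped_mate"
  c1$frag[!r1_mapped] <- pairs$read1_seq[!r1_mapped]

  res <- rbind(
    fragment_rows(pairs, 2L, c2$side, c2$frag, construct),
    fragment_rows(pairs, 1L, c1$side, c1$frag, construct)
  )
  res <- res[nchar(res$sequence) >= min_len, , drop = FALSE]
  # stable order: by pair, read 2 before read 1
  res <- res[order(match(res$read_id, pairs$id), -res$which_read), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

# Which read end points toward the border (and beyond it, into the genome)?
# The border lies at vector coordinate b (1-based). If the border is to the
# right of the aligned vector interval, a plus-strand alignment points at it
# with the read's 3' end, a minus-strand alignment with its 5' end; mirrored
# for a border on the left. Vectorized.
border_distal_side <- function(vstart, vend, strand, b) {
  dir_right <- (b - 0.5) >= (vstart + vend) / 2
  ifelse(strand == "+",
         ifelse(dir_right, "3p", "5p"),
         ifelse(dir_right, "5p", "3p"))
}

fragment_rows <- function(p, which_read, clip_side, sequence, construct) {
  data.frame(
    fragment_id = paste(p$id, paste0("r", which_read), clip_side, sep = "|"),
    sequence = sequence, read_id = p$id, which_read = which_read,
    clip_side = clip_side, line_id = p$line_id, border = p$border,
    walking_primer_id = p$walking_primer_id, library_id = p$library_id,
    construct = construct,
    stringsAsFactors = FALSE
  )
}

empty_fragments <- function() {
  data.frame(fragment_id = character(), sequence = character(),
             read_id = character(), which_read = integer(),
             clip_side = character(), line_id = character(),
             border = character(), walking_primer_id = character(),
             library_id = character(), construct = character(),
             stringsAsFactors = FALSE)
}

#' Remove duplicated fragment sequences
#'
#' Keeps exactly one representative (the first occurrence, preserving input
#' order) per distinct sequence string; provenance of the representative is
#' preserved. Fragments are compared in read orientation, without
#' re-orientation, matching a read-level unique filter.
#'
#' @param fragments fragment table from [extract_genomic_fragments()]
#' @return de-duplicated fragment table
#' @export
dedupe_fragments <- function(fragments) {
  fragments[!duplicated(fragments$sequence), , drop = FALSE]
}

#' Write genomic fragments as FASTA with provenance-encoding headers
#'
#' Headers have the form
#' `readid|r1|border|primer|clipside|line|library|construct`;
#' [read_fragments_fasta()] parses them back.
#' @param fragments fragment table
#' @param file output path
#' @export
write_fragments_fasta <- function(fragments, file) {
  x <- Biostrings::DNAStringSet(fragments$sequence)
  if (nrow(fragments) > 0L) {
    names(x) <- paste(fragments$read_id, paste0("r", fragments$which_read),
                      fragments$border, fragments$walking_primer_id,
                      fragments$clip_side, fragments$line_id,
                      fragments$library_id, fragments$construct, sep = "|")
  }
  Biostrings::writeXStringSet(x, file)
  invisible(file)
}

#' @rdname write_fragments_fasta
#' @export
read_fragments_fasta <- function(file) {
  x <- Biostrings::readDNAStringSet(file)
  parts <- strsplit(names(x), "|", fixed = TRUE)
  if (any(lengths(parts) != 8L)) {
    stop("fragment FASTA headers must have 8 |-separated fields")
  }
  m <- do.call(rbind, parts)
  data.frame(
    fragment_id = paste(m[, 1], m[, 2], m[, 5], sep = "|"),
    sequence = as.character(x),
    read_id = m[, 1], which_read = as.integer(sub("^r", "", m[, 2])),
    clip_side = m[, 5], line_id = m[, 6], border = m[, 3],
    walking_primer_id = m[, 4], library_id = m[, 7], construct = m[, 8],
    stringsAsFactors = FALSE
  )
}
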