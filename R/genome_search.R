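#' Build an exact-match seed index over a genome
#'
#' Indexes every `word_size`-mer of the forward strand of each genome
#' sequence for O(1) lookup. Words containing ambiguous bases are skipped;
#' both strands are handled at query time by also querying the reverse
#' complement of the fragment.
#'
#' @param genome a `DNAStringSet`, named character vector or FASTA path
#' @param word_size seed word length in bp (default 11, minimum 8)
#' @return object of class `seed_index`
#' @export
build_seed_index <- function(genome, word_size = 11) {
  if (word_size < 8) stop("word_size must be >= 8")
  genome <- as_genome(genome)
  if (sum(vapply(genome, function(s) {
        nchar(s) - lengths(regmatches(s, gregexpr("N", s)))
      }, numeric(1))) == 0) {
    stop("genome contains no non-N bases")
  }
  ptr <- seed_index_build_cpp(genome, as.integer(word_size))
  info <- seed_index_info_cpp(ptr)
  structure(list(ptr = ptr, word_size = as.integer(word_size),
                 chromosomes = info$chromosomes,
                 lengths = as.numeric(info$lengths),
                 total_length = sum(as.numeric(info$lengths)),
                 n_words = info$n_words,
                 genome = genome),
            class = "seed_index")
}

#' @export
print.seed_index <- function(x, ...) {
  cat(sprintf("seed_index: %d sequences, %.0f bp, word size %d, %.0f words\n",
              length(x$chromosomes), x$total_length, x$word_size, x$n_words))
  invisible(x)
}

#' Look up the genome positions of one word
#' @param index a `seed_index`
#' @param word DNA string of exactly the index's word size
#' @return data.frame with `chromosome` and 0-based `pos`
#' @export
seed_lookup <- function(index, word) {
  stopifnot(inherits(index, "seed_index"))
  word <- toupper(word)
  if (nchar(word) != index$word_size) {
    stop("word must have length ", index$word_size)
  }
  h <- seed_index_lookup_cpp(index$ptr, word)
  data.frame(chromosome = index$chromosomes[h$chrom], pos = h$pos,
             stringsAsFactors = FALSE)
}

#' Karlin-Altschul parameters for a match/mismatch scoring scheme
#'
#' Solves for the ungapped lambda of a uniform-composition nucleotide
#' scheme (the root of `sum p_i p_j exp(lambda * s_ij) = 1`) and computes
#' the relative entropy H. K is taken from published values for the
#' supported scheme (0.408 for match +2 / mismatch -3) or supplied by the
#' user for other schemes.
#'
#' @param match,mismatch match and mismatch scores
#' @param K Karlin-Altschul K; required for schemes without a bundled value
#' @return list with `lambda`, `K`, `H`, `match`, `mismatch`
#' @export
karlin_params <- function(match = 2, mismatch = -3, K = NULL) {
  stopifnot(match > 0, mismatch < 0)
  f <- function(l) 0.25 * exp(l * match) + 0.75 * exp(l * mismatch) - 1
  lambda <- uniroot(f, c(1e-8, 10), tol = 1e-12)$root
  qm <- 0.25 * exp(lambda * match)
  qx <- 0.75 * exp(lambda * mismatch)
  H <- lambda * (qm * match + qx * mismatch)
  if (is.null(K)) {
    if (match == 2 && mismatch == -3) {
      K <- 0.408
    } else {
      stop("no bundled K for scheme (", match, ", ", mismatch,
           "); supply K explicitly")
    }
  }
  list(lambda = lambda, K = K, H = H, match = match, mismatch = mismatch)
}

#' Expected number of chance alignments (e-value)
#'
#' Standard extreme-value statistic for an ungapped-calibrated nucleotide
#' search: `E = K * m' * n' * exp(-lambda * S)`, where `m'` and `n'` are the
#' effective query and database lengths after subtracting the expected
#' length `l = ln(K m n) / H` of a chance high-scoring pair from the query
#' and `n_seqs * l` from the database (each floored at 1). Set
#' `length_correct = FALSE` for the raw search-space product.
#'
#' @param score raw alignment score (not bits)
#' @param query_len,db_len query length and total database length in bp
#' @param karlin parameters from [karlin_params()]
#' @param n_seqs number of database sequences (for the length correction)
#' @param length_correct apply the edge-effect length correction?
#' @return numeric e-value
#' @export
evalue <- function(score, query_len, db_len, karlin = karlin_params(),
                   n_seqs = 1, length_correct = TRUE) {
  if (any(!is.finite(score)) || any(!is.finite(query_len)) ||
      any(!is.finite(db_len)) || any(query_len <= 0) || any(db_len <= 0)) {
    stop("score and lengths must be finite and lengths positive")
  }
  m <- query_len; n <- db_len
  if (length_correct) {
    l <- pmax(log(karlin$K * m * n) / karlin$H, 0)
    m <- pmax(m - l, 1)
    n <- pmax(n - n_seqs * l, 1)
  }
  karlin$K * m * n * exp(-karlin$lambda * score)
}

#' Bit score of a raw alignment score
#' @inheritParams evalue
#' @return numeric bit score `(lambda * S - ln K) / ln 2`
#' @export
bitscore <- function(score, karlin = karlin_params()) {
  (karlin$lambda * score - log(karlin$K)) / log(2)
}

#' Search genomic fragments against an indexed genome
#'
#' Seed-and-extend nucleotide search: exact word seeds are grouped by
#' diagonal, each seed cluster is extended by banded local alignment
#' within a window around the seeds, and alignments passing both the
#' identity floor and the e-value ceiling are reported. Multiple hits per
#' fragment are kept (no best-hit cap): in a polyploid, homeologous copies
#' of the true locus legitimately produce hit doublets or triplets that are
#' informative downstream. Results are sorted by fragment (input order)
#' and ascending e-value.
#'
#' @param fragments fragment table from [extract_genomic_fragments()] (or a
#'   named character vector of sequences)
#' @param index a [build_seed_index()] object
#' @param min_identity minimum percent identity (default 95)
#' @param max_evalue maximum e-value (default 1e-10)
#' @param scoring an [align_scoring()] scheme; its match/mismatch scores
#'   must correspond to `karlin`
#' @param karlin Karlin-Altschul parameters from [karlin_params()]
#' @param min_seeds two-hit seeding heuristic: a diagonal seed cluster is
#'   extended only when it contains at least this many exact word hits
#'   (default 2; set to 1 for exhaustive single-seed extension). Chance
#'   word collisions almost never recur on one diagonal, so this prunes
#'   the extension work without losing alignments that have two or more
#'   seed words -- any >=95%-identity match of practical length does
#' @return data.frame in 12-column tabular-hit layout -- `qseqid`, `sseqid`,
#'   `pident`, `length`, `mismatch`, `gapopen`, `qstart`, `qend`, `sstart`,
#'   `send`, `evalue`, `bitscore` -- plus `strand`, `score`, `qlen` and any
#'   provenance columns present in the input. Query coordinates are 1-based
#'   inclusive with `qstart < qend`; subject coordinates have
#'   `sstart > send` on the minus strand. Fragments shorter than the word
#'   size are skipped; their count is in `attr(, "skipped_short")`.
#' @export
search_genome <- function(fragments, index, min_identity = 95,
                          max_evalue = 1e-10, scoring = align_scoring(),
                          karlin = karlin_params(scoring$match,
                                                 scoring$mismatch),
                          min_seeds = 2) {
  stopifnot(inherits(index, "seed_index"))
  if (is.character(fragments)) {
    fragments <- data.frame(
      fragment_id = names(fragments) %||% paste0("frag", seq_along(fragments)),
      sequence = unname(fragments), stringsAsFactors = FALSE)
  }
  prov_cols <- setdiff(names(fragments), c("fragment_id", "sequence"))
  k <- index$word_size
  seqs <- toupper(fragments$sequence)
  short <- nchar(seqs) < k
  n_short <- sum(short)

  hit_list <- vector("list", nrow(fragments))
  for (i in which(!short)) {
    hit_list[[i]] <- search_one_fragment(
      seqs[i], index, scoring, karlin, min_identity, max_evalue,
      min_seeds = min_seeds)
  }
  nonempty <- !vapply(hit_list, is.null, logical(1))
  res <- do.call(rbind, hit_list[nonempty])
  if (is.null(res)) {
    res <- empty_hits()
  } else {
    idx <- rep(which(nonempty),
               vapply(hit_list[nonempty], nrow, integer(1)))
    res <- cbind(qseqid = fragments$fragment_id[idx], res,
                 qlen = nchar(seqs)[idx],
                 fragments[idx, prov_cols, drop = FALSE])
    res <- res[order(match(res$qseqid, fragments$fragment_id), res$evalue), ,
               drop = FALSE]
  }
  rownames(res) <- NULL
  attr(res, "skipped_short") <- n_short
  res
}

# seed, cluster by diagonal, extend, filter -- for a single fragment
search_one_fragment <- function(seq, index, scoring, karlin,
                                min_identity, max_evalue,
                                diag_tol = 15, pad = 25, min_seeds = 2) {
  qlen <- nchar(seq)
  out <- list()
  for (strand in c("+", "-")) {
    q <- if (strand == "+") seq else dna_revcomp(seq)
    h <- seed_index_hits_cpp(index$ptr, q)
    if (nrow(h) == 0L) next
    diag <- h$rpos - h$qpos
    ord <- order(h$chrom, diag, h$rpos)
    h <- h[ord, , drop = FALSE]; diag <- diag[ord]
    new_cluster <- c(TRUE, diff(h$chrom) != 0 | diff(diag) > diag_tol |
                       diff(h$rpos) > qlen + 2 * pad)
    cl <- cumsum(new_cluster)
    keep_cl <- which(tabulate(cl) >= min_seeds)
    for (g in split(seq_len(nrow(h)), cl)[as.character(keep_cl)]) {
      chrom_i <- h$chrom[g[1]]
      chrom_seq <- index$genome[[chrom_i]]
      clen <- nchar(chrom_seq)
      w0 <- max(min(h$rpos[g] - h$qpos[g]) - pad, 0)
      w1 <- min(max(h$rpos[g] - h$qpos[g]) + qlen + pad, clen)
      window <- substr(chrom_seq, w0 + 1, w1)
      a <- sw_align_cpp(q, window, scoring$match, scoring$mismatch,
                        scoring$gap_open, scoring$gap_extend)
      if (a$score <= 0) next
      gstart <- w0 + a$rstart   # 0-based genome interval [gstart, gend)
      gend <- w0 + a$rend
      pid <- 100 * a$matches / a$align_len
      ev <- evalue(a$score, qlen, index$total_length, karlin,
                   n_seqs = length(index$chromosomes))
      if (pid < min_identity || ev > max_evalue) next
      if (strand == "+") {
        qs <- a$qstart + 1L; qe <- a$qend
        ss <- gstart + 1L; se <- gend
      } else {
        qs <- qlen - a$qend + 1L; qe <- qlen - a$qstart
        ss <- gend; se <- gstart + 1L
      }
      out[[length(out) + 1L]] <- data.frame(
        sseqid = index$chromosomes[chrom_i], pident = pid,
        length = a$align_len, mismatch = a$mismatches,
        gapopen = a$gap_opens, qstart = qs, qend = qe,
        sstart = ss, send = se, evalue = ev,
        bitscore = bitscore(a$score, karlin),
        strand = strand, score = a$score,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) return(NULL)
  res <- do.call(rbind, out)
  # drop redundant overlapping placements (same chromosome & strand),
  # keeping the best-scoring one
  res <- res[order(-res$score), , drop = FALSE]
  keep <- rep(TRUE, nrow(res))
  lo <- pmin(res$sstart, res$send); hi <- pmax(res$sstart, res$send)
  for (i in seq_len(nrow(res))[-1]) {
    prev <- which(keep[seq_len(i - 1L)])
    overl <- res$sseqid[prev] == res$sseqid[i] &
      res$strand[prev] == res$strand[i] &
      lo[prev] <= hi[i] & hi[prev] >= lo[i]
    if (any(overl)) keep[i] <- FALSE
  }
  res[keep, , drop = FALSE]
}

empty_hits <- function() {
  data.frame(qseqid = character(), sseqid = character(), pident = numeric(),
             length = integer(), mismatch = integer(), gapopen = integer(),
             qstart = integer(), qend = integer(), sstart = integer(),
             send = integer(), evalue = numeric(), bitscore = numeric(),
             strand = character(), score = integer(), qlen = integer(),
             stringsAsFactors = FALSE)
}

#' Write / read hits in the 12-column tabular dialect
#'
#' Writes the standard tabular hit columns plus this package's `strand`,
#' `score`, `qlen` and provenance columns, with a comment header naming the
#' coordinate convention (1-based inclusive; `sstart > send` on the minus
#' strand). `read_hits_tsv()` also accepts plain 12-column files from an
#' external search, reconstructing `strand` from the subject coordinates
#' and provenance columns from `|`-separated query ids written by
#' [write_fragments_fasta()] when present.
#'
#' @param hits hits data.frame from [search_genome()]
#' @param file path
#' @return `read_hits_tsv()`: hits data.frame
#' @export
write_hits_tsv <- function(hits, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("# coordinates: 1-based inclusive; sstart > send on minus strand",
             con)
  suppressWarnings(write.table(hits, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(file)
}

#' @rdname write_hits_tsv
#' @export
read_hits_tsv <- function(file) {
  d <- read.table(file, sep = "\t", header = TRUE, comment.char = "#",
                  stringsAsFactors = FALSE)
  base12 <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
              "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  if (!all(base12 %in% names(d)) && ncol(d) >= 12 &&
      !any(base12 %in% names(d))) {
    names(d)[1:12] <- base12   # headerless external file read with header=TRUE
  }
  if (!all(base12 %in% names(d))) {
    stop("hits file lacks the 12 standard tabular columns")
  }
  if (is.null(d$strand)) d$strand <- ifelse(d$sstart <= d$send, "+", "-")
  if (is.null(d$qlen)) d$qlen <- pmax(d$qend, d$qstart)
  if (is.null(d$border) && any(grepl("|", d$qseqid, fixed = TRUE))) {
    parts <- strsplit(d$qseqid, "|", fixed = TRUE)
    full <- lengths(parts) == 8L
    get_part <- function(k) {
      vapply(seq_along(parts), function(i)
        if (full[i]) parts[[i]][k] else NA_character_, character(1))
    }
    d$read_id <- get_part(1)
    d$which_read <- as.integer(sub("^r", "", get_part(2)))
    d$border <- get_part(3)
    d$walking_primer_id <- get_part(4)
    d$clip_side <- get_part(5)
    d$line_id <- get_part(6)
    d$library_id <- get_part(7)
    d$construct <- get_part(8)
  }
  d
}
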