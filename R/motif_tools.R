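#' Scan a genome for a fixed DNA motif
#'
#' Finds every exact, case-insensitive occurrence of `motif` on the forward
#' strand of each genome sequence and summarises occurrence statistics used
#' to judge a palindromic hexamer as a genome-walking primer 3' anchor.
#' Overlapping occurrences are all reported; ambiguous bases (`N`) in the
#' genome never match.
#'
#' @param genome a `DNAStringSet`, named character vector, or FASTA path
#' @param motif DNA string of length >= 4 (ACGT only)
#' @return an object of class `motif_profile`: a list with elements
#'   `motif`, `positions` (per-chromosome integer vectors of 0-based start
#'   coordinates, strictly increasing), `count_per_chromosome`,
#'   `genome_count`, `mean_gap` (per chromosome; `NA` where fewer than two
#'   sites), `mean_gap_genome` (mean of successive-position differences
#'   pooled over chromosomes), `density_per_mb` and `density_cv`
#'   (coefficient of variation of per-chromosome density), and
#'   `chrom_lengths`.
#' @examples
#' scan_motif(c(c1 = "GTTAACGGGTTAAC"), "gttaac")
#' @export
scan_motif <- function(genome, motif) {
  motif <- check_dna(motif, "motif", min_len = 4L)
  genome <- as_genome(genome)
  positions <- lapply(genome, function(seq) {
    m <- Biostrings::matchPattern(motif, Biostrings::DNAString(seq),
                                  fixed = TRUE)
    as.integer(Biostrings::start(m)) - 1L
  })
  counts <- vapply(positions, length, integer(1))
  lens <- nchar(genome)
  gaps <- lapply(positions, function(p) if (length(p) >= 2L) diff(p) else integer(0))
  mean_gap <- vapply(gaps, function(g) if (length(g)) mean(g) else NA_real_,
                     numeric(1))
  all_gaps <- unlist(gaps, use.names = FALSE)
  density <- counts / (lens / 1e6)
  structure(list(
    motif = motif,
    positions = positions,
    count_per_chromosome = counts,
    genome_count = sum(counts),
    mean_gap = mean_gap,
    mean_gap_genome = if (length(all_gaps)) mean(all_gaps) else NA_real_,
    density_per_mb = density,
    density_cv = if (mean(density) > 0) sd(density) / mean(density) else NA_real_,
    chrom_lengths = lens
  ), class = "motif_profile")
}

#' @export
print.motif_profile <- function(x, ...) {
  cat("motif_profile:", x$motif,
      sprintf("(%d occurrences on %d sequences)\n",
              x$genome_count, length(x$positions)))
  cat("  density/Mb:",
      paste(sprintf("%s=%.2f", names(x$density_per_mb), x$density_per_mb),
            collapse = " "), "\n")
  if (!is.na(x$mean_gap_genome))
    cat(sprintf("  mean gap: %.1f bp; density CV: %.3f\n",
                x$mean_gap_genome, x$density_cv))
  invisible(x)
}

#' Is a DNA motif palindromic?
#'
#' A motif is palindromic when it equals its own reverse complement, so a
#' walking primer ending in it binds both strands at every occurrence.
#' @param motif DNA string
#' @return logical
#' @export
is_palindromic <- function(motif) {
  motif <- check_dna(motif, "motif")
  identical(motif, dna_revcomp(motif))
}

#' GC content of a motif, in percent
#' @param motif DNA string
#' @return numeric percentage in `[0, 100]`
#' @examples
#' motif_gc("CCATGG") # 66.67
#' motif_gc("GTTAAC") # 33.33
#' @export
motif_gc <- function(motif) {
  motif <- check_dna(motif, "motif")
  b <- strsplit(motif, "")[[1]]
  100 * mean(b %in% c("G", "C"))
}

#' Predict in-silico PCR amplicon counts between motif sites
#'
#' Counts, per chromosome, ordered site pairs (i < j) whose span -- distance
#' between the two motif starts plus the motif length, i.e. outer-edge to
#' outer-edge -- falls within `[min_len, max_len]`. Only palindromic motifs
#' are supported: a palindromic primer anchor binds both strands at every
#' occurrence, so every in-range pair is a potential amplicon.
#'
#' @param profile a `motif_profile` from [scan_motif()]
#' @param min_len,max_len amplicon size window in bp (defaults 30 and 2000)
#' @return list with `per_chromosome` (named integer vector) and `total`
#' @export
predict_amplicons <- function(profile, min_len = 30, max_len = 2000) {
  stopifnot(inherits(profile, "motif_profile"))
  if (!is_palindromic(profile$motif)) {
    stop("motif '", profile$motif, "' is not palindromic; strand-specific ",
         "amplicon handling is unsupported")
  }
  if (min_len > max_len) stop("min_len must be <= max_len")
  k <- nchar(profile$motif)
  per <- vapply(profile$positions, function(p) {
    n <- length(p)
    if (n < 2L) return(0L)
    # span(i, j) = p[j] - p[i] + k; count j with p[j] in
    # [p[i] + min_len - k, p[i] + max_len - k], j > i
    lo <- findInterval(p + min_len - k - 1L, p)       # last index < lower bound
    hi <- findInterval(p + max_len - k, p)            # last index <= upper bound
    sum(pmax(hi - pmax(lo, seq_len(n)), 0L))
  }, integer(1))
  list(per_chromosome = per, total = sum(per))
}

#' Rank candidate walking-primer motifs
#'
#' Ranks motif profiles for library design: motifs whose genome-wide density
#' lies inside a moderate-frequency band (relative to the median density of
#' the candidate set) are ranked above motifs outside it; within the band,
#' motifs with a lower coefficient of variation of per-chromosome density
#' (i.e. more uniform across chromosomes) rank higher; remaining ties break
#' lexicographically on the motif string. Motifs with zero occurrences are
#' flagged `unamplifiable` and rank last.
#'
#' @param profiles list of `motif_profile` objects over the same genome
#' @param target_band numeric length-2: multiplicative band around the
#'   median per-motif genome density (default `c(0.5, 1.5)`)
#' @return data.frame with columns `motif`, `genome_count`, `density_per_mb`,
#'   `density_cv`, `in_band`, `flag` (`ok`, `out_of_band` or
#'   `unamplifiable`) and `rank`, ordered by rank
#' @export
rank_motifs <- function(profiles, target_band = c(0.5, 1.5)) {
  stopifnot(is.list(profiles), length(profiles) >= 2L,
            all(vapply(profiles, inherits, logical(1), "motif_profile")))
  ref <- profiles[[1]]$chrom_lengths
  same <- vapply(profiles, function(p) {
    identical(names(p$chrom_lengths), names(ref)) &&
      identical(unname(p$chrom_lengths), unname(ref))
  }, logical(1))
  if (!all(same)) stop("profiles were computed over different genomes")

  total_mb <- sum(ref) / 1e6
  density <- vapply(profiles, function(p) p$genome_count / total_mb, numeric(1))
  counts <- vapply(profiles, function(p) p$genome_count, numeric(1))
  cvs <- vapply(profiles, function(p) p$density_cv %||% NA_real_, numeric(1))
  motifs <- vapply(profiles, function(p) p$motif, character(1))

  med <- median(density)
  in_band <- counts > 0 & density >= target_band[1] * med &
    density <= target_band[2] * med
  unamp <- counts == 0
  flag <- ifelse(unamp, "unamplifiable", ifelse(in_band, "ok", "out_of_band"))
  ord <- order(!in_band, unamp, ifelse(is.na(cvs), Inf, cvs), motifs)
  out <- data.frame(
    motif = motifs, genome_count = as.integer(counts),
    density_per_mb = density, density_cv = cvs,
    in_band = in_band, flag = flag,
    stringsAsFactors = FALSE
  )[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Write a per-chromosome motif report as TSV
#'
#' One row per motif and chromosome with occurrence count, density, mean
#' inter-site gap and the predicted number of in-range amplicons.
#'
#' @param profiles list of `motif_profile` objects (or a single one)
#' @param file output path
#' @param min_len,max_len amplicon window passed to [predict_amplicons()]
#' @return the report data.frame, invisibly
#' @export
write_motif_report <- function(profiles, file, min_len = 30, max_len = 2000) {
  if (inherits(profiles, "motif_profile")) profiles <- list(profiles)
  rows <- lapply(profiles, function(p) {
    amp <- if (is_palindromic(p$motif)) {
      predict_amplicons(p, min_len, max_len)$per_chromosome
    } else rep(NA_integer_, length(p$positions))
    data.frame(
      motif = p$motif,
      chromosome = names(p$count_per_chromosome),
      count = unname(p$count_per_chromosome),
      density_per_mb = unname(p$density_per_mb),
      mean_gap = unname(p$mean_gap),
      amplicons_in_range = unname(amp),
      stringsAsFactors = FALSE
    )
  })
  report <- do.call(rbind, rows)
  write.table(report, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(report)
}

#' Write motif positions as a BED file (0-based half-open)
#' @param profile a `motif_profile`
#' @param file output path
#' @return the exported `GRanges`, invisibly
#' @export
write_motif_bed <- function(profile, file) {
  stopifnot(inherits(profile, "motif_profile"))
  k <- nchar(profile$motif)
  gr <- GenomicRanges::GRanges(
    seqnames = rep(names(profile$positions),
                   lengths(profile$positions)),
    ranges = IRanges::IRanges(
      start = unlist(profile$positions, use.names = FALSE) + 1L, width = k),
    name = profile$motif
  )
  rtracklayer::export(gr, file, format = "BED")
  invisible(gr)
}
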