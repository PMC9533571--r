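#' Detect T-DNA insertion sites from read pairs (in-memory pipeline core)
#'
#' Runs the full detection chain: optional 3' adapter trimming, read-2
#' vector classification with the score-and-margin confidence filter,
#' border-distal genomic fragment extraction (soft clips and whole
#' unmapped mates), exact deduplication, seed-and-extend genome search
#' under the identity/e-value filters, hotspot clustering, hierarchical
#' flagging and ranking, homeolog grouping/resolution, orientation
#' inference and junction estimation. Entirely deterministic: a re-run on
#' identical inputs gives identical output.
#'
#' @param pairs read-pair table ([make_read_pairs()] /
#'   [read_paired_fastq()], possibly concatenated across libraries)
#' @param vector vector reference (one or more construct sequences)
#' @param genome reference genome
#' @param min_clip minimum genomic-fragment length in bp (default 20)
#' @param min_score,min_margin read-2 vector-alignment confidence filter
#' @param min_identity,max_evalue genome-search filters (defaults 95, 1e-10)
#' @param word_size seed word size (default 11)
#' @param cluster_gap hotspot chaining / border pairing radius (default
#'   1000 bp)
#' @param scoring an [align_scoring()] scheme
#' @param adapters optional named list/vector with `r1` and `r2` 3' adapter
#'   sequences to trim before alignment
#' @param other_lines list of hit tables or [cluster_hits()] outputs of
#'   other lines (for the cross-line uniqueness flag)
#' @param vector_borders per-construct border coordinates (see
#'   [extract_genomic_fragments()])
#' @param ... further arguments passed to [flag_and_rank()] and
#'   [annotate_sites()]
#' @return list with `sites`, `hits`, `fragments`, `hotspots`, `pairs`
#'   (with accept/reject reasons) and `metrics`
#' @export
detect_insertions <- function(pairs, vector, genome, min_clip = 20,
                              min_score = 40, min_margin = 10,
                              min_identity = 95, max_evalue = 1e-10,
                              word_size = 11, cluster_gap = 1000,
                              scoring = align_scoring(), adapters = NULL,
                              other_lines = list(), vector_borders = NULL,
                              ...) {
  metrics <- list(pairs_in = nrow(pairs))
  if (!is.null(adapters)) {
    pairs$read1_seq <- trim_adapter(pairs$read1_seq, adapters[["r1"]])
    pairs$read2_seq <- trim_adapter(pairs$read2_seq, adapters[["r2"]])
  }
  cls <- classify_read_pairs(pairs, vector, scoring, min_score, min_margin)
  metrics$pairs_accepted <- sum(cls$pairs$accepted)

  frags <- extract_genomic_fragments(cls, vector, min_clip, vector_borders)
  metrics$fragments <- nrow(frags)
  frags <- dedupe_fragments(frags)
  metrics$fragments_unique <- nrow(frags)

  index <- build_seed_index(genome, word_size)
  hits <- search_genome(frags, index, min_identity, max_evalue, scoring)
  metrics$fragments_skipped_short <- attr(hits, "skipped_short") %||% 0L
  metrics$hits <- nrow(hits)

  clustered <- cluster_hits(hits, cluster_gap)
  metrics$hotspots <- nrow(clustered$hotspots)

  dots <- list(...)
  fr_args <- dots[intersect(names(dots), c("strong_evalue", "strong_identity",
                                           "long_read_bp", "count_pooled"))]
  sites <- do.call(flag_and_rank,
                   c(list(clustered, other_lines = other_lines,
                          gap = cluster_gap), fr_args))
  an_args <- dots[intersect(names(dots), c("id_margin", "count_ratio",
                                           "quorum"))]
  if (nrow(sites) > 0L) sites <- do.call(annotate_sites, c(list(sites), an_args))
  metrics$candidates <- nrow(sites)

  list(sites = sites, hits = attr(sites, "hits") %||% clustered$hits,
       fragments = frags, hotspots = clustered$hotspots,
       pairs = cls$pairs, metrics = metrics)
}

#' Run insertion-site detection from files, writing all reports
#'
#' File-level wrapper around [detect_insertions()]. The configuration is a
#' list (or a YAML file) with a `paths` block -- `library_sheet` (TSV:
#' `library_id`, `fastq_r1`, `fastq_r2`, `line_id`, `border`,
#' `walking_primer_id`), `vector` and `genome` FASTA, `outdir` -- and an
#' optional `params` block overriding any [detect_insertions()] argument.
#' Writes `fragments.fa`, `hits.tsv`, `sites.tsv`, `sites.bed`,
#' `primer_windows.fa` and `metrics.json` into `outdir`. Empty input
#' produces empty reports, zero counts and a warning.
#'
#' @param config list or YAML path
#' @return the [detect_insertions()] result, invisibly
#' @export
run_detect <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  paths <- config$paths %||% config
  for (p in c("library_sheet", "vector", "genome")) {
    if (is.null(paths[[p]]) || !file.exists(paths[[p]])) {
      stop("config path '", p, "' missing or does not exist")
    }
  }
  outdir <- paths$outdir %||% "."
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  sheet <- read.table(paths$library_sheet, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
  pairs <- do.call(rbind, lapply(seq_len(nrow(sheet)), function(i) {
    read_paired_fastq(sheet$fastq_r1[i], sheet$fastq_r2[i],
                      line_id = sheet$line_id[i], border = sheet$border[i],
                      walking_primer_id = sheet$walking_primer_id[i],
                      library_id = sheet$library_id[i])
  }))
  if (is.null(pairs) || nrow(pairs) == 0L) {
    warning("no read pairs in input; writing empty reports")
    pairs <- make_read_pairs(character(), character(), character())[0, ]
  }

  args <- c(list(pairs = pairs, vector = paths$vector,
                 genome = paths$genome), config$params %||% list())
  res <- tryCatch(do.call(detect_insertions, args),
                  error = function(e) stop("detect stage failed: ",
                                           conditionMessage(e), call. = FALSE))

  write_fragments_fasta(res$fragments, file.path(outdir, "fragments.fa"))
  write_hits_tsv(res$hits, file.path(outdir, "hits.tsv"))
  write_sites_tsv(res$sites, file.path(outdir, "sites.tsv"))
  if (nrow(res$sites) > 0L) {
    write_sites_bed(res$sites, file.path(outdir, "sites.bed"))
    genome <- as_genome(paths$genome)
    wins <- do.call(rbind, lapply(seq_len(nrow(res$sites)), function(i) {
      w <- suppressWarnings(primer_windows(res$sites$junction[i],
                                           res$sites$chromosome[i], genome))
      if (nrow(w)) w$site_id <- res$sites$site_id[i]
      w
    }))
    if (!is.null(wins) && nrow(wins)) {
      x <- Biostrings::DNAStringSet(wins$sequence)
      names(x) <- sprintf("%s|%s|%s:%d-%d", wins$site_id, wins$side,
                          wins$chromosome, wins$start, wins$end)
      Biostrings::writeXStringSet(x, file.path(outdir, "primer_windows.fa"))
    }
  }
  jsonlite::write_json(res$metrics, file.path(outdir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}

#' Genotype a T2 population sheet and summarise segregation
#'
#' Delegates to [call_zygosity()] and [summarize_segregation()]; writes the
#' per-plant calls and per-locus summary when output paths are given.
#' Malformed rows are reported with their line numbers by
#' [read_zygosity_sheet()].
#'
#' @param sheet data.frame or TSV path with `plant_id`, `locus_id`,
#'   `pcrA`, `pcrB`
#' @param calls_out,summary_out optional output TSV paths
#' @param expected_ratio het:hmz:null ratio for the goodness-of-fit test
#' @return list with `calls` and `summary`
#' @export
run_zygosity <- function(sheet, calls_out = NULL, summary_out = NULL,
                         expected_ratio = c(2, 1, 1)) {
  if (is.character(sheet)) sheet <- read_zygosity_sheet(sheet)
  calls <- sheet
  calls$genotype <- call_zygosity(sheet$pcrA, sheet$pcrB)
  summary <- summarize_segregation(sheet, expected_ratio)
  if (!is.null(calls_out)) {
    write.table(calls, calls_out, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  if (!is.null(summary_out)) {
    write.table(summary, summary_out, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  list(calls = calls, summary = summary)
}
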