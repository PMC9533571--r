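# Shared fixture builders. Everything is generated in code under fixed
# seeds; no data files beyond the worked-example zygosity sheet.

# a small single-subgenome scenario with one planted insertion, suitable
# for exercising the trim -> search -> call chain quickly
tiny_scenario <- function(seed = 7, orientation = "RB-LB", position = 50000,
                          error_rate = 0, duplicate_rate = 0,
                          background_fraction = 0, depth = 10,
                          chromosome_length = 1e5) {
  cfg <- simulation_config(
    seed = seed, n_subgenomes = 1, chromosomes_per_subgenome = 1,
    chromosome_length = chromosome_length, homeolog_divergence = 0,
    amplicon_depth = depth, error_rate = error_rate,
    duplicate_rate = duplicate_rate,
    background_fraction = background_fraction)
  g <- make_polyploid_genome(cfg)
  constructs <- c(tdna1 = random_construct(1200, seed = seed + 1000))
  if (is.null(position)) {
    position <- sample_detectable_positions(g$genome, cfg, 1,
                                            seed = seed + 1)$position
  }
  specs <- data.frame(construct_id = "tdna1", chromosome = "chr1A",
                      position = position, orientation = orientation,
                      stringsAsFactors = FALSE)
  ins <- insert_constructs(g$genome, constructs, specs)
  lib <- suppressWarnings(simulate_library(ins$genome, ins$truth, cfg))
  list(cfg = cfg, genome = g$genome, constructs = constructs,
       ins = ins, lib = lib)
}

reads_to_pairs <- function(reads) {
  make_read_pairs(reads$id, reads$read1_seq, reads$read2_seq,
                  line_id = reads$line_id, border = reads$border,
                  walking_primer_id = reads$walking_primer_id,
                  library_id = reads$library_id)
}

# reference-coordinate junctions of a truth table (the truth records are in
# post-insertion coordinates; hits are on the pre-insertion reference)
ref_junctions <- function(truth) {
  shift <- stats::ave(truth$insert_length, truth$chromosome,
                      FUN = function(x) cumsum(c(0, utils::head(x, -1))))
  truth$position - shift
}

example_sheet_path <- function() {
  system.file("extdata", "t2_zygosity_example.tsv", package = "tdnawalk")
}

# brute-force local alignment oracle built on Biostrings' dynamic
# programming aligner (independent of the package's own kernel)
oracle_local_score <- function(query, ref, scoring = align_scoring()) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = scoring$match, mismatch = scoring$mismatch)
  s <- function(q) Biostrings::pairwiseAlignment(
    Biostrings::DNAString(q), Biostrings::DNAString(ref), type = "local",
    substitutionMatrix = mat, gapOpening = -scoring$gap_open,
    gapExtension = -scoring$gap_extend, scoreOnly = TRUE)
  max(s(query), s(dna_revcomp_test(query)), 0)
}

dna_revcomp_test <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

random_dna_test <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
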