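# geometry of the classify -> extract chain on hand-built read pairs

make_vector <- function(seed = 123, len = 800) {
  set.seed(seed)
  c(tdna = random_dna_test(len))
}

test_that("classify accepts junction pairs and rejects background and
           ambiguous reads", {
  vec <- make_vector()
  set.seed(4)
  flank <- random_dna_test(400)
  # read 2: 90 bp of vector ending at the LB border (vector end), then
  # 60 bp of genome
  r2 <- paste0(substr(vec[["tdna"]], 711, 800), substr(flank, 1, 60))
  r1 <- dna_revcomp_test(substr(flank, 100, 249))
  pairs <- make_read_pairs("p1", r1, r2, border = "LB")
  cls <- classify_read_pairs(pairs, vec)
  expect_true(cls$pairs$accepted)
  rec2 <- cls$records[cls$records$which_read == 2, ]
  expect_equal(rec2$strand, "+")
  # aligned read interval covers the vector portion within 2 bp
  expect_lte(abs(rec2$qstart - 0), 2)
  expect_lte(abs(rec2$qend - 90), 2)

  # background amplicon: no vector sequence at all
  set.seed(5)
  bg <- make_read_pairs("bg", random_dna_test(150), random_dna_test(150))
  cbg <- classify_read_pairs(bg, vec)
  expect_false(cbg$pairs$accepted)
  expect_equal(cbg$pairs$reason, "no_vector_alignment")

  # a 40 bp repeat present twice in the vector: ambiguous placement
  rep40 <- substr(vec[["tdna"]], 100, 139)
  vec_rep <- c(tdna = paste0(vec[["tdna"]], strrep("T", 50), rep40))
  amb <- make_read_pairs("amb", r1, rep40)
  camb <- classify_read_pairs(amb, vec_rep)
  expect_false(camb$pairs$accepted)
  expect_equal(camb$pairs$reason, "ambiguous_placement")

  # too-short reads are rejected with the stated reason
  short <- make_read_pairs("s", "ACGT", "ACGTACGT")
  expect_equal(classify_read_pairs(short, vec)$pairs$reason, "too_short")
})

test_that("border-distal clips follow the alignment geometry for both
           borders", {
  vec <- make_vector(77)
  set.seed(6)
  flank <- random_dna_test(600)
  v <- vec[["tdna"]]

  # LB library (border at vector end): read 2 = vector tail + genome,
  # genomic part is the 3' clip
  r2_lb <- paste0(substr(v, 706, 800), substr(flank, 1, 55))
  p_lb <- make_read_pairs("lb1", dna_revcomp_test(substr(flank, 200, 349)),
                          r2_lb, border = "LB")
  cls <- classify_read_pairs(p_lb, vec)
  fr <- extract_genomic_fragments(cls, vec)
  f2 <- fr[fr$which_read == 2, ]
  expect_equal(f2$clip_side, "border_distal_3prime")
  expect_equal(f2$sequence, substr(flank, 1, 55))
  # read 1 has no vector alignment: whole unmapped mate
  f1 <- fr[fr$which_read == 1, ]
  expect_equal(f1$clip_side, "whole_unmapped_mate")
  expect_equal(nchar(f1$sequence), 150L)

  # RB library (border at vector start): read 2 = revcomp(vector head) +
  # genome; geometry puts the genomic part on the 3' clip again, but via
  # the minus strand
  r2_rb <- paste0(dna_revcomp_test(substr(v, 1, 95)),
                  dna_revcomp_test(substr(flank, 300, 354)))
  p_rb <- make_read_pairs("rb1", substr(flank, 100, 249), r2_rb,
                          border = "RB")
  cls_rb <- classify_read_pairs(p_rb, vec)
  rec2 <- cls_rb$records[cls_rb$records$which_read == 2, ]
  expect_equal(rec2$strand, "-")
  fr_rb <- extract_genomic_fragments(cls_rb, vec)
  f2rb <- fr_rb[fr_rb$which_read == 2, ]
  expect_equal(f2rb$clip_side, "border_distal_3prime")
  expect_equal(f2rb$sequence, dna_revcomp_test(substr(flank, 300, 354)))
})

test_that("fragments below the length floor are discarded and the floor is
           monotone", {
  vec <- make_vector(9)
  set.seed(10)
  flank <- random_dna_test(200)
  # 12 bp unaligned terminus: below the 20 bp floor
  r2 <- paste0(substr(vec[["tdna"]], 663, 800), substr(flank, 1, 12))
  p <- make_read_pairs("x", dna_revcomp_test(substr(flank, 13, 150)), r2,
                       border = "LB")
  cls <- classify_read_pairs(p, vec)
  fr <- extract_genomic_fragments(cls, vec, min_len = 20)
  expect_false(any(fr$which_read == 2))

  # monotonicity in min_len on a larger random scenario
  sc <- tiny_scenario(seed = 21, depth = 3)
  pairs <- reads_to_pairs(sc$lib$reads)
  cls2 <- classify_read_pairs(pairs, sc$constructs)
  n_prev <- Inf
  for (ml in c(20, 40, 60, 100)) {
    n <- nrow(extract_genomic_fragments(cls2, sc$constructs, min_len = ml))
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("fragment, aligned interval and discarded terminus tile the read", {
  sc <- tiny_scenario(seed = 33, depth = 4)
  pairs <- reads_to_pairs(sc$lib$reads)
  cls <- classify_read_pairs(pairs, sc$constructs)
  fr <- extract_genomic_fragments(cls, sc$constructs)
  fr2 <- fr[fr$which_read == 2, ]
  recs <- cls$records[cls$records$which_read == 2, ]
  for (i in seq_len(nrow(fr2))) {
    read <- pairs$read2_seq[pairs$id == fr2$read_id[i]]
    rec <- recs[recs$read_id == fr2$read_id[i], ]
    if (fr2$clip_side[i] == "border_distal_3prime") {
      expect_equal(paste0(substr(read, 1, rec$qend), fr2$sequence[i]), read)
    } else {
      expect_equal(paste0(fr2$sequence[i],
                          substr(read, rec$qstart + 1, nchar(read))), read)
    }
  }
})

test_that("noise-free fragments are exact substrings of the true flanks", {
  sc <- tiny_scenario(seed = 44, depth = 2)
  pairs <- reads_to_pairs(sc$lib$reads)
  cls <- classify_read_pairs(pairs, sc$constructs)
  fr <- extract_genomic_fragments(cls, sc$constructs)
  chrom <- sc$genome[["chr1A"]]  # pre-insertion reference; junction at 50000
  up <- substr(chrom, 48500, 50000)
  down <- substr(chrom, 50001, 51500)
  flanks <- c(up, down, dna_revcomp_test(up), dna_revcomp_test(down))
  # the truth record's own flanks match the modified genome around the
  # insertion
  expect_true(grepl(sc$ins$truth$flank_up, sc$ins$genome[["chr1A"]],
                    fixed = TRUE))
  clipped <- fr[fr$clip_side != "whole_unmapped_mate", ]
  expect_gt(nrow(clipped), 0)
  for (s in clipped$sequence) {
    expect_true(any(vapply(flanks, grepl, logical(1), pattern = s,
                           fixed = TRUE)))
  }
})

test_that("dedupe keeps the first representative per distinct sequence", {
  f <- data.frame(fragment_id = c("a", "b", "c"),
                  sequence = c("ACGT", "ACGT", "TTTT"),
                  read_id = c("r1", "r2", "r3"), which_read = 1L,
                  clip_side = "whole_unmapped_mate", line_id = "l",
                  border = "LB", walking_primer_id = "PST1",
                  library_id = "x", construct = "t",
                  stringsAsFactors = FALSE)
  d <- dedupe_fragments(f)
  expect_equal(d$fragment_id, c("a", "c"))
  expect_equal(nrow(dedupe_fragments(f[0, ])), 0L)

  # set-cardinality oracle on many fragments with planted duplicates
  set.seed(55)
  seqs <- replicate(2000, random_dna_test(30))
  seqs <- c(seqs, sample(seqs, 800, replace = TRUE))
  big <- f[rep(1, length(seqs)), ]
  big$sequence <- seqs
  big$fragment_id <- paste0("f", seq_along(seqs))
  expect_equal(nrow(dedupe_fragments(big)), length(unique(seqs)))
})

test_that("fragment FASTA headers round-trip provenance", {
  sc <- tiny_scenario(seed = 61, depth = 2)
  pairs <- reads_to_pairs(sc$lib$reads)
  cls <- classify_read_pairs(pairs, sc$constructs)
  fr <- dedupe_fragments(extract_genomic_fragments(cls, sc$constructs))
  fa <- tempfile(fileext = ".fa")
  write_fragments_fasta(fr, fa)
  back <- read_fragments_fasta(fa)
  expect_equal(back$sequence, fr$sequence)
  expect_equal(back$border, fr$border)
  expect_equal(back$clip_side, fr$clip_side)
  expect_equal(back$construct, fr$construct)
})
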