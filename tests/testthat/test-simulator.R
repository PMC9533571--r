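test_that("polyploid genome generation is reproducible and hits the
           divergence target", {
  cfg <- simulation_config(seed = 5, n_subgenomes = 3,
                           chromosomes_per_subgenome = 1,
                           chromosome_length = 100000,
                           homeolog_divergence = 0.02)
  g1 <- make_polyploid_genome(cfg)
  g2 <- make_polyploid_genome(cfg)
  expect_identical(g1$genome, g2$genome)
  expect_equal(names(g1$genome), c("chr1A", "chr1B", "chr1C"))

  # pairwise identity between homeologs: binomial expectation around the
  # configured between-subgenome rate
  pid <- function(a, b) {
    mean(strsplit(a, "")[[1]] == strsplit(b, "")[[1]]) * 100
  }
  p <- c(pid(g1$genome[["chr1A"]], g1$genome[["chr1B"]]),
         pid(g1$genome[["chr1A"]], g1$genome[["chr1C"]]),
         pid(g1$genome[["chr1B"]], g1$genome[["chr1C"]]))
  expect_true(all(p > 95.5 & p < 98.5))

  # zero divergence: byte-identical copies
  cfg0 <- simulation_config(seed = 5, n_subgenomes = 3,
                            chromosomes_per_subgenome = 1,
                            chromosome_length = 20000,
                            homeolog_divergence = 0)
  g0 <- make_polyploid_genome(cfg0)
  expect_identical(g0$genome[["chr1A"]], g0$genome[["chr1B"]])
})

test_that("construct insertion conserves length, mirrors orientations and
           records verbatim flanks", {
  cfg <- simulation_config(seed = 6, n_subgenomes = 1,
                           chromosomes_per_subgenome = 1,
                           chromosome_length = 50000)
  g <- make_polyploid_genome(cfg)
  td <- c(t1 = random_construct(1000, seed = 60))

  one <- insert_constructs(g$genome, td, data.frame(
    construct_id = "t1", chromosome = "chr1A", position = 20000,
    orientation = "RB-LB"))
  expect_equal(nchar(one$genome[["chr1A"]]), 51000)
  expect_equal(one$truth$position, 20000)

  fwd <- substr(one$genome[["chr1A"]], 20001, 21000)
  expect_equal(fwd, td[["t1"]])
  rev <- insert_constructs(g$genome, td, data.frame(
    construct_id = "t1", chromosome = "chr1A", position = 20000,
    orientation = "LB-RB"))
  expect_equal(substr(rev$genome[["chr1A"]], 20001, 21000),
               dna_revcomp_test(td[["t1"]]))

  # several random insertions: every truth flank is found verbatim
  # adjacent to the construct in the modified genome
  set.seed(61)
  specs <- data.frame(construct_id = "t1", chromosome = "chr1A",
                      position = sort(sample(5000:45000, 5)),
                      orientation = sample(c("RB-LB", "LB-RB"), 5,
                                           replace = TRUE))
  multi <- insert_constructs(g$genome, td, specs)
  for (i in seq_len(nrow(multi$truth))) {
    tr <- multi$truth[i, ]
    got_up <- substr(multi$genome[[tr$chromosome]],
                     tr$position - nchar(tr$flank_up) + 1, tr$position)
    expect_equal(got_up, tr$flank_up)
    ins_seq <- substr(multi$genome[[tr$chromosome]], tr$position + 1,
                      tr$position + tr$insert_length)
    expect_equal(ins_seq,
                 if (tr$orientation == "RB-LB") td[["t1"]]
                 else dna_revcomp_test(td[["t1"]]))
  }

  # border truncation shortens the insert from the right end
  tru <- insert_constructs(g$genome, td, data.frame(
    construct_id = "t1", chromosome = "chr1A", position = 20000,
    orientation = "RB-LB", trunc_rb = 100, trunc_lb = 50))
  expect_equal(tru$truth$insert_length, 850)

  expect_error(insert_constructs(g$genome, td, data.frame(
    construct_id = "t1", chromosome = "chr1A",
    position = c(1000, 1000), orientation = "RB-LB")), "overlapping")
})

test_that("noise-free libraries are deterministic with junction-spanning
           read 2", {
  sc <- tiny_scenario(seed = 71, depth = 5)
  lib <- sc$lib
  expect_gt(nrow(lib$amplicons), 0)
  # all read 2 of one amplicon are identical without noise
  for (a in unique(lib$reads$amp_id)) {
    r2 <- lib$reads$read2_seq[lib$reads$amp_id == a]
    expect_equal(length(unique(r2)), 1L)
  }
  # read 2 starts with construct sequence at the nested-primer offset
  td <- sc$constructs[["tdna1"]]
  amp <- lib$amplicons[1, ]
  r2 <- lib$reads$read2_seq[lib$reads$amp_id == amp$amp_id][1]
  border_part <- substr(r2, 1, amp$border_arm)
  expect_true(grepl(border_part, td, fixed = TRUE) ||
                grepl(border_part, dna_revcomp_test(td), fixed = TRUE))

  # same seed twice: identical output
  sc2 <- tiny_scenario(seed = 71, depth = 5)
  expect_identical(sc2$lib$reads, lib$reads)
})

test_that("short amplicons produce adapter read-through on both reads", {
  sc <- tiny_scenario(seed = 72, depth = 1)
  lib <- sc$lib
  cfg <- sc$cfg
  short <- lib$amplicons[lib$amplicons$insert_len < cfg$read_length, ]
  if (nrow(short) > 0) {
    r <- lib$reads[lib$reads$amp_id == short$amp_id[1], ][1, ]
    ad1 <- dna_revcomp_test(cfg$adapter_p7)
    ad2 <- dna_revcomp_test(cfg$adapter_p5)
    expect_true(grepl(substr(ad1, 1, 10), r$read1_seq, fixed = TRUE))
    expect_true(grepl(substr(ad2, 1, 10), r$read2_seq, fixed = TRUE))
    # trimming recovers the insert
    expect_equal(nchar(trim_adapter(r$read1_seq, ad1)), short$insert_len[1])
  } else {
    succeed()  # geometry produced no sub-read-length amplicon at this seed
  }
})

test_that("duplicates, background and truncation-silenced borders behave as
           configured", {
  cfg <- simulation_config(seed = 73, n_subgenomes = 1,
                           chromosomes_per_subgenome = 1,
                           chromosome_length = 1e5,
                           homeolog_divergence = 0, amplicon_depth = 10,
                           duplicate_rate = 0.2, background_fraction = 0.2,
                           error_rate = 0)
  g <- make_polyploid_genome(cfg)
  td <- c(t1 = random_construct(1200, seed = 70))
  ins <- insert_constructs(g$genome, td, data.frame(
    construct_id = "t1", chromosome = "chr1A", position = 50000,
    orientation = "RB-LB"))
  lib <- suppressWarnings(simulate_library(ins$genome, ins$truth, cfg))
  expect_gt(sum(grepl("_dup", lib$reads$id)), 0)
  expect_gt(sum(lib$reads$amp_id == "background"), 0)
  bg_frac <- mean(lib$reads$amp_id == "background")
  expect_gt(bg_frac, 0.1); expect_lt(bg_frac, 0.3)

  # truncating a border past the nested primer silences it
  ins2 <- insert_constructs(g$genome, td, data.frame(
    construct_id = "t1", chromosome = "chr1A", position = 50000,
    orientation = "RB-LB", trunc_rb = 100, trunc_lb = 0))
  expect_warning(lib2 <- simulate_library(ins2$genome, ins2$truth, cfg),
                 "nested primer site truncated")
  expect_false(any(lib2$amplicons$border == "RB"))
})

test_that("T2 simulation follows the selfing ratios and the lethal-locus
           conditional", {
  t2 <- simulate_t2(c("locusA"), n_plants = 4000, seed = 77)
  counts <- table(t2$truth$genotype)
  p <- counts / 4000
  sd3 <- function(q) 3 * sqrt(q * (1 - q) / 4000)
  expect_lt(abs(p[["heterozygous"]] - 0.5), sd3(0.5))
  expect_lt(abs(p[["homozygous"]] - 0.25), sd3(0.25))
  expect_lt(abs(p[["wildtype_null"]] - 0.25), sd3(0.25))

  # PCR outcomes map deterministically from genotype
  m <- merge(t2$sheet, t2$truth)
  expect_true(all(call_zygosity(m$pcrA, m$pcrB) == m$genotype))

  # homozygous-lethal locus: zero homozygotes, het:null within 3 SD of 2:1
  t2l <- simulate_t2(c("locusB"), n_plants = 4000, seed = 78,
                     homozygous_lethal = "locusB")
  cl <- table(factor(t2l$truth$genotype,
                     levels = c("heterozygous", "homozygous",
                                "wildtype_null")))
  expect_equal(cl[["homozygous"]], 0L)
  ph <- cl[["heterozygous"]] / 4000
  expect_lt(abs(ph - 2 / 3), 3 * sqrt((2 / 3) * (1 / 3) / 4000))

  # the summary flags the lethal signature as non-Mendelian
  s <- summarize_segregation(t2l$sheet)
  expect_true(s$non_mendelian)
})

test_that("amplicon truth and FASTQ output are mutually consistent", {
  sc <- tiny_scenario(seed = 79, depth = 3, error_rate = 0.003,
                      position = NULL)
  lib <- sc$lib
  # every signal read maps back to its truth amplicon: read 2 matches the
  # amplicon's junction-spanning template at the error rate
  amp <- lib$amplicons
  sig <- lib$reads[lib$reads$amp_id %in% amp$amp_id, ]
  mism <- vapply(seq_len(nrow(sig)), function(i) {
    a <- amp[amp$amp_id == sig$amp_id[i], ]
    insert <- substr(sc$ins$genome[[a$chromosome]], a$start, a$end)
    tmpl <- if (a$upstream) dna_revcomp_test(insert) else insert
    tmpl <- substr(tmpl, 1, nchar(sig$read2_seq[i]))
    obs <- substr(sig$read2_seq[i], 1, nchar(tmpl))
    sum(strsplit(obs, "")[[1]] != strsplit(tmpl, "")[[1]])
  }, numeric(1))
  expect_lt(mean(mism / 150), 0.01)   # ~0.3% error rate

  d <- tempfile()
  sheet <- write_library_fastq(lib$reads, d)
  expect_true(all(file.exists(sheet$fastq_r1)))
  back <- read_paired_fastq(sheet$fastq_r1[1], sheet$fastq_r2[1],
                            border = sheet$border[1])
  lib1 <- lib$reads[lib$reads$library_id == sheet$library_id[1], ]
  expect_equal(back$read2_seq, lib1$read2_seq)
  expect_equal(back$id, lib1$id)
  unlink(d, recursive = TRUE)
})

test_that("detectable positions have in-range motifs on both flanks", {
  cfg <- simulation_config(seed = 81, n_subgenomes = 1,
                           chromosomes_per_subgenome = 2,
                           chromosome_length = 2e5)
  g <- make_polyploid_genome(cfg)
  pos <- sample_detectable_positions(g$genome, cfg, 6, seed = 82)
  expect_equal(nrow(pos), 6)
  td <- c(t1 = random_construct(1200, seed = 83))
  specs <- data.frame(construct_id = "t1", chromosome = pos$chromosome,
                      position = pos$position, orientation = "RB-LB")
  ins <- insert_constructs(g$genome, td, specs)
  # no warnings: every insertion amplifies from both borders
  expect_no_warning(lib <- simulate_library(ins$genome, ins$truth, cfg))
  ok <- table(lib$amplicons$insertion_id, lib$amplicons$border)
  expect_true(all(ok > 0))
})
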