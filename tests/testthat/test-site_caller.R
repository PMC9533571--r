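mk_hits <- function(pos, chrom = "c1", border = "LB", which_read = 1L,
                    strand = "+", pident = 100, evalue = 1e-20,
                    qlen = 150L, primer = "PST1", qseqid = NULL,
                    construct = "tdna1") {
  n <- length(pos)
  data.frame(
    qseqid = qseqid %||% paste0("f", seq_len(n)),
    sseqid = chrom, pident = pident, length = qlen, mismatch = 0L,
    gapopen = 0L, qstart = 1L, qend = qlen,
    sstart = ifelse(rep_len(strand, n) == "+", pos, pos + qlen - 1L),
    send = ifelse(rep_len(strand, n) == "+", pos + qlen - 1L, pos),
    evalue = evalue, bitscore = 100, strand = strand, score = 300L,
    qlen = qlen, read_id = paste0("r", seq_len(n)), which_read = which_read,
    border = border, walking_primer_id = primer, line_id = "l1",
    library_id = "lib", construct = construct,
    stringsAsFactors = FALSE)
}

test_that("single-linkage clustering matches the brute-force oracle and is
           idempotent", {
  h <- mk_hits(c(100, 600, 1900))
  cl <- cluster_hits(h, gap = 1000)
  expect_equal(nrow(cl$hotspots), 2L)
  expect_equal(cl$hotspots$start, c(100, 1900))
  expect_equal(cl$hotspots$end[1], 600 + 149)

  expect_equal(nrow(cluster_hits(h[0, ], 1000)$hotspots), 0L)

  # brute-force single-linkage over all pairs on random positions
  set.seed(14)
  pos <- sort(sample(1:100000, 60))
  h2 <- mk_hits(pos, qlen = 50L)
  cl2 <- cluster_hits(h2, gap = 1000)
  brute_groups <- cumsum(c(TRUE, diff(pos) > 1000))
  expect_equal(nrow(cl2$hotspots), length(unique(brute_groups)))
  # idempotence: clustering the member hits of each hotspot changes nothing
  again <- cluster_hits(cl2$hits, gap = 1000)
  expect_equal(again$hotspots[names(again$hotspots) != "hotspot_id"],
               cl2$hotspots[names(cl2$hotspots) != "hotspot_id"])
})

test_that("LB and RB support within 1 kb pairs into one both-borders site", {
  h <- rbind(mk_hits(10000, border = "LB"),
             mk_hits(10800, border = "RB"))
  cl <- cluster_hits(h, 1000)
  s <- flag_and_rank(cl)
  expect_equal(nrow(s), 1L)
  expect_true(s$both_borders)

  # symmetric in LB/RB and invariant to input order
  h_swap <- rbind(mk_hits(10800, border = "RB"),
                  mk_hits(10000, border = "LB"))
  s2 <- flag_and_rank(cluster_hits(h_swap[2:1, ], 1000))
  expect_true(s2$both_borders)
  expect_equal(s2$start, s$start)

  # beyond 1 kb: two sites, neither both-borders
  h_far <- rbind(mk_hits(10000, border = "LB", qlen = 30L),
                 mk_hits(11200, border = "RB", qlen = 30L))
  s3 <- flag_and_rank(cluster_hits(h_far, 1000))
  expect_equal(nrow(s3), 2L)
  expect_false(any(s3$both_borders))
})

test_that("evidence hierarchy: both-borders outranks raw read support, and
           flags follow their thresholds", {
  # site A: LB+RB, 50 reads; site B: LB only, 5000 reads
  a <- rbind(mk_hits(rep(10000, 25), border = "LB", chrom = "c1"),
             mk_hits(rep(10500, 25), border = "RB", chrom = "c1"))
  b <- mk_hits(rep(500000, 5000), border = "LB", chrom = "c2",
               evalue = 1e-50, primer = "PST2")
  s <- flag_and_rank(cluster_hits(rbind(a, b), 1000))
  expect_equal(s$rank[s$chromosome == "c1"], 1L)
  expect_equal(s$rank[s$chromosome == "c2"], 2L)

  # flag thresholds
  weak <- mk_hits(rep(1000, 3), evalue = 1e-12, pident = 97, qlen = 40L)
  sw <- flag_and_rank(cluster_hits(weak, 1000))
  expect_false(sw$strong_stats)
  expect_false(sw$long_read)
  expect_false(sw$multi_library)
  strong_e <- mk_hits(rep(1000, 3), evalue = 1e-31, pident = 97, qlen = 40L)
  expect_true(flag_and_rank(cluster_hits(strong_e, 1000))$strong_stats)
  strong_id <- mk_hits(rep(1000, 3), evalue = 1e-12, pident = 99.5,
                       qlen = 40L)
  expect_true(flag_and_rank(cluster_hits(strong_id, 1000))$strong_stats)
  long <- mk_hits(rep(1000, 3), qlen = 60L, evalue = 1e-12, pident = 97)
  expect_true(flag_and_rank(cluster_hits(long, 1000))$long_read)

  # a hotspot at the same position in another line is not line-unique
  other <- cluster_hits(mk_hits(rep(1000, 5)), 1000)
  su <- flag_and_rank(cluster_hits(weak, 1000), other_lines = list(other))
  expect_false(su$line_unique)
  expect_true(sw$line_unique)
})

test_that("ranking equals an independent lexicographic sort oracle on
           randomized sites", {
  set.seed(19)
  hit_sets <- lapply(1:20, function(i) {
    chrom <- paste0("c", i)
    n <- sample(3:30, 1)
    borders <- if (runif(1) < 0.5) c("LB", "RB") else "LB"
    mk_hits(rep(1000 * i, n), chrom = chrom,
            border = sample(borders, n, replace = TRUE),
            evalue = 10^-sample(c(12, 35), n, replace = TRUE),
            pident = sample(c(96, 99.6), n, replace = TRUE),
            qlen = sample(c(40L, 80L), n, replace = TRUE),
            primer = sample(c("PST1", "PST2"), n, replace = TRUE))
  })
  h <- do.call(rbind, hit_sets)
  h$qseqid <- paste0(h$sseqid, "_", seq_len(nrow(h)))
  s <- flag_and_rank(cluster_hits(h, 1000))
  oracle <- s[order(-s$both_borders, -s$n_flags,
                    -(s$reads_LB + s$reads_RB), s$best_evalue,
                    s$chromosome, s$start), ]
  expect_equal(oracle$site_id, s$site_id[order(s$rank)])
})

test_that("homeolog groups resolve on identity margin and tie when
           indistinguishable", {
  # three hotspots sharing fragments: identities 99.8 / 97.0 / 96.8 with
  # counts 50 / 30 / 20 resolve to the first
  ids <- paste0("f", 1:50)
  h <- rbind(
    mk_hits(rep(5000, 50), chrom = "c1A", pident = 99.8, qseqid = ids),
    mk_hits(rep(5000, 30), chrom = "c1B", pident = 97.0, qseqid = ids[1:30]),
    mk_hits(rep(5000, 20), chrom = "c1C", pident = 96.8, qseqid = ids[1:20]))
  s <- annotate_sites(flag_and_rank(cluster_hits(h, 1000)))
  expect_equal(unique(s$homeolog_group), 1L)
  expect_equal(unique(s$homeolog_status), "resolved:c1A")
  expect_equal(sum(s$is_primary), 1L)
  expect_equal(s$chromosome[s$is_primary], "c1A")

  # identities within 0.1 point, similar counts: tie of all three
  h2 <- rbind(
    mk_hits(rep(5000, 30), chrom = "c1A", pident = 98.00, qseqid = ids[1:30]),
    mk_hits(rep(5000, 30), chrom = "c1B", pident = 98.05, qseqid = ids[1:30]),
    mk_hits(rep(5000, 29), chrom = "c1C", pident = 98.02, qseqid = ids[1:29]))
  s2 <- annotate_sites(flag_and_rank(cluster_hits(h2, 1000)))
  expect_equal(unique(s2$homeolog_status), "tie:c1A,c1B,c1C")
  expect_equal(sum(s2$is_primary), 1L)

  # a singleton group resolves trivially
  s3 <- annotate_sites(flag_and_rank(cluster_hits(mk_hits(rep(100, 5)), 1000)))
  expect_equal(s3$homeolog_status, "resolved:c1")

  # an outnumbered top-identity site does not resolve under the count guard
  h4 <- rbind(
    mk_hits(rep(5000, 10), chrom = "c1A", pident = 99.8, qseqid = ids[1:10]),
    mk_hits(rep(5000, 40), chrom = "c1B", pident = 97.0, qseqid = ids[1:40]))
  s4 <- annotate_sites(flag_and_rank(cluster_hits(h4, 1000)))
  expect_match(unique(s4$homeolog_status), "^tie:")
})

test_that("orientation follows the border/read/strand vote pattern", {
  # the right-border library maps read 1 to + and read 2 to -, the
  # left-border library the mirror image: RB-LB configuration
  rb_lb <- rbind(
    mk_hits(rep(1000, 5), border = "RB", which_read = 1L, strand = "+"),
    mk_hits(rep(1010, 5), border = "RB", which_read = 2L, strand = "-"),
    mk_hits(rep(1200, 5), border = "LB", which_read = 1L, strand = "-"),
    mk_hits(rep(1190, 5), border = "LB", which_read = 2L, strand = "+"))
  expect_equal(infer_orientation(rb_lb), "RB-LB")

  # mirror image
  lb_rb <- rb_lb
  lb_rb$strand <- ifelse(rb_lb$strand == "+", "-", "+")
  expect_equal(infer_orientation(lb_rb), "LB-RB")

  # conflicting evidence below the quorum: undetermined
  half <- rbind(rb_lb[1:10, ], lb_rb[1:10, ])
  expect_equal(infer_orientation(half), "undetermined")
  expect_equal(infer_orientation(rb_lb[0, ]), "undetermined")
})

test_that("primer windows flank the insertion point and clip at chromosome
           ends", {
  set.seed(23)
  g <- c(c1 = random_dna_test(30000))
  w <- primer_windows(10000, "c1", g)
  expect_equal(w$start, c(9500, 10250))
  expect_equal(w$end, c(9750, 10500))
  expect_equal(w$sequence[1], substr(g[["c1"]], 9500, 9750))

  expect_warning(w2 <- primer_windows(100, "c1", g), "omitted")
  expect_equal(w2$side, "downstream")
  expect_error(primer_windows(100, "nope", g), "unknown chromosome")
})

test_that("primer windows on a simulated insertion contain no construct
           sequence", {
  sc <- tiny_scenario(seed = 91, depth = 2)
  w <- primer_windows(50000, "chr1A", sc$genome)
  td <- sc$constructs[["tdna1"]]
  for (s in w$sequence) {
    expect_false(grepl(s, td, fixed = TRUE))
    expect_false(grepl(s, dna_revcomp_test(td), fixed = TRUE))
  }
})
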