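#' Simulation configuration
#'
#' Collects the parameters of the synthetic study the simulator emulates:
#' an allopolyploid genome of near-identical subgenomes, T-DNA insertions
#' with configurable orientation and border truncation, and a two-phase
#' genome-walking amplicon library sequenced as 2x150 bp paired reads.
#' Defaults describe a three-subgenome (hexaploid-like) genome at 2%
#' homeolog divergence, 100x amplicon depth and a 0.3% per-base
#' substitution error rate, with amplicons size-selected to 150-1200 bp.
#'
#' @param seed integer seed; every stochastic simulator call is
#'   reproducible given the configuration and seed
#' @param n_subgenomes number of subgenomes (default 3)
#' @param chromosomes_per_subgenome chromosomes per subgenome (default 3)
#' @param chromosome_length chromosome length in bp (default 5e5)
#' @param homeolog_divergence per-base substitution rate applied
#'   independently to each subgenome copy of the ancestral sequence
#'   (default 0.02; must be < 0.2)
#' @param walking_motifs named character vector of palindromic hexamer
#'   walking-primer motifs (names are primer ids)
#' @param amplicon_depth read pairs generated per amplicon per library
#'   (default 100)
#' @param read_length read length in bp (default 150)
#' @param error_rate per-base substitution sequencing error rate
#'   (default 0.003)
#' @param duplicate_rate fraction of additional exact PCR-duplicate read
#'   pairs appended after error simulation (default 0.05)
#' @param background_fraction fraction of final read pairs that are
#'   walking-primer mispriming products (motif-to-motif genomic amplicons
#'   with no transgene; default 0.05)
#' @param dimer_rate fraction of adapter-dimer read pairs (default 0)
#' @param adapter_p5,adapter_p7 5' tail sequences of the walking and
#'   nested border primers; their reverse complements appear as 3' adapter
#'   read-through in reads 1 and 2 respectively
#' @param size_range amplicon size-selection window in bp, tails included
#'   (default `c(150, 1200)`)
#' @param border_primer_offset distance in bp from each border end of the
#'   construct to the distal base of the nested border primer (default 70,
#'   within the 50-75 bp nested-primer placement that lets a 150 bp read 2
#'   span the border-genome junction with a usable genomic arm; border
#'   truncations larger than this remove the primer site and silence that
#'   border)
#' @param pooled_library also emit a pooled library combining all walking
#'   primers under one index? (default TRUE)
#' @param pooled_depth read pairs per amplicon in the pooled library
#'   (default `round(amplicon_depth / 4)`)
#' @param line_id transgenic line identifier (default "line1")
#' @return list of class `sim_config`
#' @export
simulation_config <- function(seed = 1L,
                              n_subgenomes = 3L,
                              chromosomes_per_subgenome = 3L,
                              chromosome_length = 5e5,
                              homeolog_divergence = 0.02,
                              walking_motifs = c(PST1 = "GTTAAC",
                                                 PST2 = "CCATGG",
                                                 PST3 = "CTCGAG",
                                                 PST4 = "GTCGAC"),
                              amplicon_depth = 100L,
                              read_length = 150L,
                              error_rate = 0.003,
                              duplicate_rate = 0.05,
                              background_fraction = 0.05,
                              dimer_rate = 0,
                              adapter_p5 = "CCTACACGACGCTCTTCCGATCT",
                              adapter_p7 = "AGACGTGTGCTCTTCCGATCT",
                              size_range = c(150, 1200),
                              border_primer_offset = 70L,
                              pooled_library = TRUE,
                              pooled_depth = NULL,
                              line_id = "line1") {
  rates <- c(homeolog_divergence, error_rate, duplicate_rate,
             background_fraction, dimer_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (homeolog_divergence >= 0.2) stop("homeolog_divergence must be < 0.2")
  if (is.null(names(walking_motifs))) stop("walking_motifs must be named")
  for (m in walking_motifs) check_dna(m, "walking motif", 4L)
  stopifnot(length(size_range) == 2, size_range[1] < size_range[2],
            n_subgenomes >= 1, chromosomes_per_subgenome >= 1,
            chromosome_length >= 1000, read_length >= 30,
            amplicon_depth >= 1)
  structure(list(
    seed = as.integer(seed), n_subgenomes = as.integer(n_subgenomes),
    chromosomes_per_subgenome = as.integer(chromosomes_per_subgenome),
    chromosome_length = chromosome_length,
    homeolog_divergence = homeolog_divergence,
    walking_motifs = toupper(walking_motifs),
    amplicon_depth = as.integer(amplicon_depth),
    read_length = as.integer(read_length),
    error_rate = error_rate, duplicate_rate = duplicate_rate,
    background_fraction = background_fraction, dimer_rate = dimer_rate,
    adapter_p5 = toupper(adapter_p5), adapter_p7 = toupper(adapter_p7),
    size_range = size_range,
    border_primer_offset = as.integer(border_primer_offset),
    pooled_library = pooled_library,
    pooled_depth = pooled_depth %||% max(1L, round(amplicon_depth / 4)),
    line_id = line_id
  ), class = "sim_config")
}

#' Simulate an allopolyploid genome of near-identical subgenomes
#'
#' One random ancestral sequence is generated per chromosome and copied
#' into each subgenome with independent substitutions at the configured
#' divergence rate (so homeologous copies differ at roughly twice that
#' rate). No indels are introduced: homeologous coordinates are orthologous
#' one-to-one, mimicking recently diverged, colinear subgenomes.
#' Chromosomes are named `chr<i><A/B/C/...>`.
#'
#' @param cfg a [simulation_config()]
#' @param seed RNG seed (defaults to `cfg$seed`)
#' @return list with `genome` (named character vector) and `homeolog_map`
#'   (data.frame: chromosome, ancestor, subgenome)
#' @export
make_polyploid_genome <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  local_seed(seed, {
    genome <- character(0)
    map <- list()
    for (i in seq_len(cfg$chromosomes_per_subgenome)) {
      anc <- random_dna(cfg$chromosome_length)
      for (s in seq_len(cfg$n_subgenomes)) {
        nm <- sprintf("chr%d%s", i, LETTERS[s])
        # half the divergence per copy, so two copies differ at about the
        # configured between-subgenome rate
        genome[[nm]] <- mutate_dna(anc, cfg$homeolog_divergence / 2)
        map[[length(map) + 1L]] <- data.frame(
          chromosome = nm, ancestor = paste0("anc", i),
          subgenome = LETTERS[s], stringsAsFactors = FALSE)
      }
    }
    list(genome = genome, homeolog_map = do.call(rbind, map))
  })
}

# independent substitutions at `rate`; each hit base becomes one of the
# other three uniformly
mutate_dna <- function(seq, rate) {
  n <- nchar(seq)
  k <- rbinom(1, n, rate)
  if (k == 0) return(seq)
  pos <- sort(sample.int(n, k))
  old <- strsplit(substring(seq, 1, n), "")[[1]][pos]
  bases <- c("A", "C", "G", "T")
  new <- vapply(old, function(b) sample(setdiff(bases, b), 1), character(1),
                USE.NAMES = FALSE)
  x <- Biostrings::DNAString(seq)
  x <- Biostrings::replaceLetterAt(x, pos, paste(new, collapse = ""))
  as.character(x)
}

#' Splice T-DNA constructs into a genome
#'
#' Each insertion splices the (optionally border-truncated) construct into
#' the chromosome immediately after `position`, in the requested
#' orientation. Construct sequences are taken as written in RB-to-LB
#' orientation; `RB-LB` inserts the construct forward (right border facing
#' the upstream, lower-coordinate flank), `LB-RB` inserts its reverse
#' complement. Downstream coordinates shift by the inserted length and
#' truth records are emitted in post-insertion coordinates.
#'
#' @param genome named character vector (or `DNAStringSet` / FASTA path)
#' @param constructs named character vector or `DNAStringSet` of construct
#'   (T-DNA) sequences, written RB first
#' @param specs data.frame with columns `construct_id`, `chromosome`,
#'   `position` (1-based; insertion occurs after this base), `orientation`
#'   (`"RB-LB"` or `"LB-RB"`) and optionally `trunc_rb`, `trunc_lb`
#'   (bp removed from the respective border end; default 0)
#' @return list with `genome` (modified) and `truth` (data.frame:
#'   `insertion_id`, `construct_id`, `chromosome`, `position` = 1-based
#'   junction coordinate of the last upstream-flank base in post-insertion
#'   coordinates, `insert_length`, `orientation`, `trunc_rb`, `trunc_lb`,
#'   `flank_up`, `flank_down` = up to 1 kb of genomic sequence on either
#'   side of the insertion)
#' @export
insert_constructs <- function(genome, constructs, specs) {
  genome <- as_genome(genome)
  constructs <- as_genome(constructs)
  req <- c("construct_id", "chromosome", "position", "orientation")
  if (!all(req %in% names(specs))) {
    stop("specs must have columns: ", paste(req, collapse = ", "))
  }
  specs$trunc_rb <- specs$trunc_rb %||% 0L
  specs$trunc_lb <- specs$trunc_lb %||% 0L
  stopifnot(all(specs$orientation %in% c("RB-LB", "LB-RB")),
            all(specs$construct_id %in% names(constructs)),
            all(specs$chromosome %in% names(genome)))
  if (anyDuplicated(specs[c("chromosome", "position")])) {
    stop("overlapping insertions: duplicate chromosome/position")
  }
  bad <- specs$position < 1 |
    specs$position >= nchar(genome[specs$chromosome])
  if (any(bad)) stop("insertion position outside chromosome bounds")

  truth <- list()
  specs <- specs[order(specs$chromosome, specs$position), , drop = FALSE]
  for (chrom in unique(specs$chromosome)) {
    d <- specs[specs$chromosome == chrom, , drop = FALSE]
    shift <- 0L
    for (i in seq_len(nrow(d))) {
      cs <- constructs[[d$construct_id[i]]]
      L <- nchar(cs)
      if (d$trunc_rb[i] + d$trunc_lb[i] >= L) {
        stop("truncations remove the whole construct")
      }
      ins <- substr(cs, d$trunc_rb[i] + 1L, L - d$trunc_lb[i])
      if (d$orientation[i] == "LB-RB") ins <- dna_revcomp(ins)
      p <- d$position[i] + shift
      g <- genome[[chrom]]
      genome[[chrom]] <- paste0(substr(g, 1, p), ins,
                                substr(g, p + 1, nchar(g)))
      truth[[length(truth) + 1L]] <- data.frame(
        insertion_id = sprintf("ins%d", length(truth) + 1L),
        construct_id = d$construct_id[i], chromosome = chrom,
        position = p, insert_length = nchar(ins),
        orientation = d$orientation[i],
        trunc_rb = d$trunc_rb[i], trunc_lb = d$trunc_lb[i],
        flank_up = substr(g, max(1, p - 999), p),
        flank_down = substr(g, p + 1, min(nchar(g), p + 1000)),
        stringsAsFactors = FALSE)
      shift <- shift + nchar(ins)
    }
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  list(genome = genome, truth = truth)
}

#' Simulate the two-phase genome-walking amplicon library
#'
#' For each insertion and each border, amplicons run from the nested
#' border-primer position inside the T-DNA across the junction into the
#' flank, ending at every walking-motif occurrence whose amplicon length
#' (border arm + genomic arm + adapter tails) falls inside the
#' size-selection window. Read 2 starts at the transgene end of the
#' amplicon, read 1 at the walking end; amplicons with inserts shorter
#' than the read length produce adapter read-through. Substitution errors,
#' exact PCR duplicates, walking-primer mispriming background amplicons
#' and (optionally) adapter dimers are added at the configured rates.
#' Borders whose nested-primer site was removed by truncation, or with no
#' in-range motif, yield zero amplicons with a warning -- the signature of
#' an undetectable insertion.
#'
#' @param genome modified genome from [insert_constructs()]
#' @param truth truth table from [insert_constructs()]
#' @param cfg a [simulation_config()]
#' @param seed RNG seed (defaults to `cfg$seed`)
#' @return list with `reads` (data.frame: `id`, `library_id`, `line_id`,
#'   `border`, `walking_primer_id`, `read1_seq`, `read2_seq`,
#'   `read1_qual`, `read2_qual`, `amp_id`) and `amplicons` (truth table:
#'   one row per amplicon with arms, lengths and coordinates)
#' @export
simulate_library <- function(genome, truth, cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  genome <- as_genome(genome)
  tail_len <- nchar(cfg$adapter_p5) + nchar(cfg$adapter_p7)
  rl <- cfg$read_length
  ad_r1 <- dna_revcomp(cfg$adapter_p7)  # read 1 runs into the border-side tail
  ad_r2 <- dna_revcomp(cfg$adapter_p5)  # read 2 into the walking-side tail

  amps <- list()
  for (i in seq_len(nrow(truth))) {
    tr <- truth[i, ]
    cseq <- genome[[tr$chromosome]]
    clen <- nchar(cseq)
    for (border in c("RB", "LB")) {
      trunc <- if (border == "RB") tr$trunc_rb else tr$trunc_lb
      border_arm <- cfg$border_primer_offset - trunc
      if (border_arm < 25) {
        warning("insertion ", tr$insertion_id, " border ", border,
                ": nested primer site truncated; no amplicons")
        next
      }
      upstream <- (tr$orientation == "RB-LB") == (border == "RB")
      max_arm <- cfg$size_range[2] - tail_len - border_arm
      min_arm <- max(cfg$size_range[1] - tail_len - border_arm, 6)
      if (max_arm < min_arm) {
        warning("insertion ", tr$insertion_id, " border ", border,
                ": no amplicon length window; no amplicons")
        next
      }
      p <- tr$position
      ds <- p + tr$insert_length + 1
      found <- FALSE
      for (primer in names(cfg$walking_motifs)) {
        motif <- cfg$walking_motifs[[primer]]
        k <- nchar(motif)
        if (upstream) {
          w0 <- max(1, p - max_arm - k); w1 <- p
        } else {
          w0 <- ds; w1 <- min(clen, ds + max_arm + k)
        }
        if (w1 - w0 + 1 < k) next
        occ <- gregexpr(motif, substr(cseq, w0, w1), fixed = TRUE)[[1]]
        if (occ[1] == -1L) next
        g <- as.integer(occ) + w0 - 1L   # 1-based motif starts
        arm <- if (upstream) p - g + 1L else g + k - 1L - ds + 1L
        keep <- arm >= min_arm & arm <= max_arm
        for (j in which(keep)) {
          if (upstream) {
            a0 <- g[j]; a1 <- p + border_arm
          } else {
            a0 <- ds - border_arm; a1 <- g[j] + k - 1L
          }
          amps[[length(amps) + 1L]] <- data.frame(
            amp_id = sprintf("amp%d", length(amps) + 1L),
            insertion_id = tr$insertion_id, construct_id = tr$construct_id,
            chromosome = tr$chromosome, junction = p, border = border,
            primer = primer, upstream = upstream,
            genomic_arm = arm[j], border_arm = border_arm,
            insert_len = border_arm + arm[j],
            amp_len = border_arm + arm[j] + tail_len,
            start = a0, end = a1,
            orientation = tr$orientation, stringsAsFactors = FALSE)
          found <- TRUE
        }
      }
      if (!found) {
        warning("insertion ", tr$insertion_id, " border ", border,
                ": no walking motif within amplifiable range")
      }
    }
  }
  amplicons <- if (length(amps)) do.call(rbind, amps) else NULL

  local_seed(seed, {
    reads <- simulate_reads_from_amplicons(amplicons, genome, cfg,
                                           rl, ad_r1, ad_r2)
    n_signal <- nrow(reads)
    # background: mispriming amplicons between two motif sites
    f <- cfg$background_fraction
    if (f > 0 && n_signal > 0) {
      n_bg <- round(f / (1 - f) * n_signal)
      bg <- simulate_background_reads(genome, cfg, n_bg, rl, ad_r1, ad_r2,
                                      tail_len)
      reads <- rbind(reads, bg)
    }
    if (cfg$dimer_rate > 0 && nrow(reads) > 0) {
      n_dim <- round(cfg$dimer_rate * nrow(reads))
      if (n_dim > 0) {
        mk <- function(ad) substr(paste0(ad, strrep("A", rl)), 1, rl)
        libs <- unique(reads[c("library_id", "line_id", "border",
                               "walking_primer_id")])
        pick <- libs[sample.int(nrow(libs), n_dim, replace = TRUE), ,
                     drop = FALSE]
        dim_reads <- data.frame(
          id = sprintf("dimer%d", seq_len(n_dim)), pick,
          read1_seq = mk(ad_r1), read2_seq = mk(ad_r2),
          read1_qual = strrep("?", rl), read2_qual = strrep("?", rl),
          amp_id = "dimer", stringsAsFactors = FALSE)
        rownames(dim_reads) <- NULL
        reads <- rbind(reads, dim_reads[names(reads)])
      }
    }
    # sequencing errors
    if (cfg$error_rate > 0 && nrow(reads) > 0) {
      reads$read1_seq <- mutate_reads(reads$read1_seq, cfg$error_rate)
      reads$read2_seq <- mutate_reads(reads$read2_seq, cfg$error_rate)
    }
    # exact PCR duplicates (post-error copies)
    if (cfg$duplicate_rate > 0 && nrow(reads) > 0) {
      n_dup <- round(cfg$duplicate_rate * nrow(reads))
      if (n_dup > 0) {
        src <- sample.int(nrow(reads), n_dup, replace = TRUE)
        dups <- reads[src, , drop = FALSE]
        dups$id <- paste0(dups$id, "_dup", seq_len(n_dup))
        reads <- rbind(reads, dups)
      }
    }
    rownames(reads) <- NULL
    list(reads = reads, amplicons = amplicons)
  })
}

simulate_reads_from_amplicons <- function(amplicons, genome, cfg, rl,
                                          ad_r1, ad_r2) {
  empty <- data.frame(id = character(), library_id = character(),
                      line_id = character(), border = character(),
                      walking_primer_id = character(),
                      read1_seq = character(), read2_seq = character(),
                      read1_qual = character(), read2_qual = character(),
                      amp_id = character(), stringsAsFactors = FALSE)
  if (is.null(amplicons) || nrow(amplicons) == 0L) return(empty)
  q <- strrep("?", rl)  # constant Q30
  rows <- list()
  for (i in seq_len(nrow(amplicons))) {
    a <- amplicons[i, ]
    insert <- substr(genome[[a$chromosome]], a$start, a$end)
    # read 2 reads outward from the border: on the upstream flank that is
    # the minus strand of the reference, downstream the plus strand
    r2_template <- if (a$upstream) dna_revcomp(insert) else insert
    r1_template <- dna_revcomp(r2_template)
    mk <- function(tmpl, ad) {
      if (nchar(tmpl) >= rl) substr(tmpl, 1, rl)
      else substr(paste0(tmpl, ad, strrep("A", rl)), 1, rl)
    }
    r1 <- mk(r1_template, ad_r1)
    r2 <- mk(r2_template, ad_r2)
    depths <- c(stats::setNames(cfg$amplicon_depth, a$primer),
                if (cfg$pooled_library) c(pooled = cfg$pooled_depth))
    for (primer in names(depths)) {
      d <- depths[[primer]]
      lib <- paste(cfg$line_id, a$border, primer, sep = "_")
      rows[[length(rows) + 1L]] <- data.frame(
        id = sprintf("%s_%s_%d", a$amp_id, lib, seq_len(d)),
        library_id = lib, line_id = cfg$line_id, border = a$border,
        walking_primer_id = primer,
        read1_seq = r1, read2_seq = r2, read1_qual = q, read2_qual = q,
        amp_id = a$amp_id, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

simulate_background_reads <- function(genome, cfg, n_bg, rl, ad_r1, ad_r2,
                                      tail_len) {
  q <- strrep("?", rl)
  # all motif occurrences genome-wide, per motif
  occ <- lapply(cfg$walking_motifs, function(m) {
    res <- lapply(names(genome), function(ch) {
      o <- gregexpr(m, genome[[ch]], fixed = TRUE)[[1]]
      if (o[1] == -1L) return(NULL)
      data.frame(chromosome = ch, start = as.integer(o),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
  })
  smin <- cfg$size_range[1] - tail_len
  smax <- cfg$size_range[2] - tail_len
  depth_bg <- max(1L, round(cfg$amplicon_depth / 2))
  rows <- list(); total <- 0L; b <- 0L; tries <- 0L
  while (total < n_bg && tries < 20L * max(1L, n_bg)) {
    tries <- tries + 1L
    primer <- sample(names(cfg$walking_motifs), 1)
    oo <- occ[[primer]]
    if (is.null(oo) || nrow(oo) < 2L) next
    i <- sample.int(nrow(oo), 1)
    k <- nchar(cfg$walking_motifs[[primer]])
    same <- oo[oo$chromosome == oo$chromosome[i], , drop = FALSE]
    span <- same$start + k - 1L - oo$start[i] + 1L
    ok <- which(span >= max(smin, 2 * k) & span <= smax)
    if (!length(ok)) next
    j <- ok[sample.int(length(ok), 1)]
    insert <- substr(genome[[oo$chromosome[i]]], oo$start[i],
                     same$start[j] + k - 1L)
    if (runif(1) < 0.5) insert <- dna_revcomp(insert)
    mk <- function(tmpl, ad) {
      if (nchar(tmpl) >= rl) substr(tmpl, 1, rl)
      else substr(paste0(tmpl, ad, strrep("A", rl)), 1, rl)
    }
    b <- b + 1L
    d <- min(depth_bg, n_bg - total)
    border <- sample(c("LB", "RB"), 1)
    lib <- paste(cfg$line_id, border, primer, sep = "_")
    rows[[b]] <- data.frame(
      id = sprintf("bg%d_%d", b, seq_len(d)),
      library_id = lib, line_id = cfg$line_id, border = border,
      walking_primer_id = primer,
      read1_seq = mk(dna_revcomp(insert), ad_r1),
      read2_seq = mk(insert, ad_r2),
      read1_qual = q, read2_qual = q,
      amp_id = "background", stringsAsFactors = FALSE)
    total <- total + d
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- simulate_reads_from_amplicons(NULL, genome, cfg, rl, ad_r1, ad_r2)
  }
  rownames(out) <- NULL
  out
}

# substitution errors per read at `rate`; positions and replacement bases
# drawn from the current RNG stream
mutate_reads <- function(seqs, rate) {
  n_err <- rbinom(length(seqs), nchar(seqs), rate)
  hit <- which(n_err > 0)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    s <- strsplit(seqs[i], "")[[1]]
    pos <- sample.int(length(s), n_err[i])
    for (p in pos) {
      alt <- bases[bases != s[p]]
      s[p] <- alt[sample.int(3, 1)]
    }
    seqs[i] <- paste(s, collapse = "")
  }
  seqs
}

#' Simulate a segregating T2 population with PCR A/B outcomes
#'
#' Each plant draws a genotype independently at each locus at the selfed
#' hemizygote ratio 1/2 het : 1/4 homozygous : 1/4 null. Loci listed in
#' `homozygous_lethal` remove homozygotes before sampling (2/3 het : 1/3
#' null among survivors -- the signature of a lethal insertion). PCR A/B
#' outcomes are derived deterministically from the genotype:
#' het -> `+/+`, homozygous -> `+/-`, null -> `-/+`.
#'
#' @param loci character vector of locus ids (or a truth table from
#'   [insert_constructs()], whose insertion ids are used)
#' @param n_plants number of T2 individuals
#' @param seed RNG seed
#' @param homozygous_lethal character vector of lethal locus ids
#' @return list with `sheet` (data.frame: `plant_id`, `locus_id`, `pcrA`,
#'   `pcrB`) and `truth` (data.frame: `plant_id`, `locus_id`, `genotype`)
#' @export
simulate_t2 <- function(loci, n_plants, seed = 1L,
                        homozygous_lethal = character()) {
  if (is.data.frame(loci)) loci <- loci$insertion_id
  stopifnot(n_plants >= 1, length(loci) >= 1)
  local_seed(seed, {
    grid <- expand.grid(plant_id = sprintf("plant%04d", seq_len(n_plants)),
                        locus_id = loci, stringsAsFactors = FALSE)
    lethal <- grid$locus_id %in% homozygous_lethal
    geno <- character(nrow(grid))
    geno[!lethal] <- sample(c("heterozygous", "homozygous", "wildtype_null"),
                            sum(!lethal), replace = TRUE,
                            prob = c(0.5, 0.25, 0.25))
    geno[lethal] <- sample(c("heterozygous", "wildtype_null"),
                           sum(lethal), replace = TRUE, prob = c(2, 1) / 3)
    sheet <- data.frame(
      plant_id = grid$plant_id, locus_id = grid$locus_id,
      pcrA = ifelse(geno == "wildtype_null", "-", "+"),
      pcrB = ifelse(geno == "homozygous", "-", "+"),
      stringsAsFactors = FALSE)
    truth <- data.frame(plant_id = grid$plant_id, locus_id = grid$locus_id,
                        genotype = geno, stringsAsFactors = FALSE)
    list(sheet = sheet, truth = truth)
  })
}

#' Write a simulated library to paired FASTQ files plus a library sheet
#'
#' One gzipped FASTQ pair per library, named `<library_id>_R1.fastq.gz` /
#' `_R2.fastq.gz`, and a `library_sheet.tsv` mapping files to line,
#' border and walking primer.
#'
#' @param reads read table from [simulate_library()]
#' @param dir output directory (created if needed)
#' @return the sheet data.frame, invisibly
#' @export
write_library_fastq <- function(reads, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sheets <- list()
  for (lib in unique(reads$library_id)) {
    d <- reads[reads$library_id == lib, , drop = FALSE]
    f1 <- file.path(dir, paste0(lib, "_R1.fastq.gz"))
    f2 <- file.path(dir, paste0(lib, "_R2.fastq.gz"))
    w <- function(seqs, quals, path) {
      x <- Biostrings::QualityScaledDNAStringSet(
        Biostrings::DNAStringSet(stats::setNames(seqs, d$id)),
        Biostrings::PhredQuality(quals))
      Biostrings::writeQualityScaledXStringSet(x, path, compress = TRUE)
    }
    w(d$read1_seq, d$read1_qual, f1)
    w(d$read2_seq, d$read2_qual, f2)
    sheets[[lib]] <- data.frame(
      library_id = lib, fastq_r1 = f1, fastq_r2 = f2,
      line_id = d$line_id[1], border = d$border[1],
      walking_primer_id = d$walking_primer_id[1], stringsAsFactors = FALSE)
  }
  sheet <- do.call(rbind, sheets)
  rownames(sheet) <- NULL
  write.table(sheet, file.path(dir, "library_sheet.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(sheet)
}

#' Sample insertion positions with in-range walking motifs on both flanks
#'
#' Detection requires a walking-motif occurrence within amplifiable range
#' of the junction; an insertion without one is invisible to the assay.
#' This helper samples junction positions (uniformly, under the
#' configuration's amplicon-size window and border-primer offset) such
#' that both the upstream and the downstream flank carry at least one
#' in-range motif occurrence, so that both border libraries can amplify.
#' Positions are kept at least `min_spacing` apart and `edge` bp from the
#' chromosome ends.
#'
#' @param genome genome to plant into (pre-insertion)
#' @param cfg a [simulation_config()]
#' @param n number of positions
#' @param chromosomes chromosomes to sample from (default: all)
#' @param seed RNG seed
#' @param min_spacing minimum distance between sampled positions on the
#'   same chromosome (default 10000)
#' @param edge minimum distance from chromosome ends (default 5000)
#' @return data.frame with `chromosome` and `position`
#' @export
sample_detectable_positions <- function(genome, cfg, n,
                                        chromosomes = NULL, seed = cfg$seed,
                                        min_spacing = 10000, edge = 5000) {
  genome <- as_genome(genome)
  chromosomes <- chromosomes %||% names(genome)
  tail_len <- nchar(cfg$adapter_p5) + nchar(cfg$adapter_p7)
  border_arm <- cfg$border_primer_offset
  max_arm <- cfg$size_range[2] - tail_len - border_arm
  min_arm <- max(cfg$size_range[1] - tail_len - border_arm, 6)
  occs <- lapply(genome[chromosomes], function(s) {
    sort(unique(unlist(lapply(cfg$walking_motifs, function(m) {
      o <- gregexpr(m, s, fixed = TRUE)[[1]]
      if (o[1] == -1L) integer(0) else as.integer(o)
    }))))
  })
  k <- nchar(cfg$walking_motifs[1])
  ok_pos <- function(ch, p) {
    g <- occs[[ch]]
    up <- any(g >= p - max_arm + 1 & g + k - 1 <= p & g >= p - max_arm &
                p - g + 1 >= min_arm)
    e <- g + k - 1
    down <- any(e >= p + min_arm & e <= p + max_arm)
    up && down
  }
  local_seed(seed, {
    out <- data.frame(chromosome = character(), position = integer(),
                      stringsAsFactors = FALSE)
    tries <- 0L
    while (nrow(out) < n && tries < 10000L) {
      tries <- tries + 1L
      ch <- sample(chromosomes, 1)
      clen <- nchar(genome[[ch]])
      if (clen <= 2 * edge) next
      p <- sample.int(clen - 2L * edge, 1) + edge
      near <- out$chromosome == ch & abs(out$position - p) < min_spacing
      if (any(near) || !ok_pos(ch, p)) next
      out <- rbind(out, data.frame(chromosome = ch, position = p,
                                   stringsAsFactors = FALSE))
    }
    if (nrow(out) < n) stop("could not find ", n, " detectable positions")
    out
  })
}

#' Generate a random T-DNA construct sequence
#'
#' Convenience generator for simulations: a random sequence written in
#' RB-to-LB orientation. The first and last 25 bp stand in for the border
#' repeats; the nested border primers are assumed to bind at the
#' configured `border_primer_offset` from each end.
#'
#' @param length construct length in bp (default 1200)
#' @param seed RNG seed
#' @return a single DNA string
#' @export
random_construct <- function(length = 1200, seed = 1L) {
  local_seed(seed, random_dna(length))
}
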