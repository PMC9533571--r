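#' Cluster genome hits into hotspots
#'
#' Single-linkage chaining of hits per chromosome on sorted hit start
#' positions: consecutive hits whose start positions differ by at most
#' `gap` join the same hotspot. Strands and borders are pooled (the two
#' border libraries flank the same insertion point and must co-cluster).
#' Clustering is idempotent: re-clustering a clustered result changes
#' nothing.
#'
#' @param hits hits data.frame from [search_genome()] (needs `sseqid`,
#'   `sstart`, `send`; provenance columns are used when present)
#' @param gap maximum inter-hit start distance in bp (default 1000)
#' @return list with `hotspots` (one row each: `hotspot_id`, `chromosome`,
#'   `start`, `end` 1-based inclusive, `n_hits`, `reads_LB`, `reads_RB`,
#'   `libraries`, `best_evalue`, `best_identity`, `max_read_len`) and
#'   `hits` (the input with a `hotspot_id` column), both ordered by
#'   chromosome then interval start
#' @export
cluster_hits <- function(hits, gap = 1000) {
  if (is.null(hits) || nrow(hits) == 0L) {
    return(list(hotspots = empty_hotspots(), hits = cbind(empty_hits(),
                hotspot_id = character())))
  }
  hits$.start <- pmin(hits$sstart, hits$send)
  hits$.end <- pmax(hits$sstart, hits$send)
  hits <- hits[order(hits$sseqid, hits$.start, hits$.end), , drop = FALSE]
  new_spot <- c(TRUE, hits$sseqid[-1] != hits$sseqid[-nrow(hits)] |
                  diff(hits$.start) > gap)
  spot <- cumsum(new_spot)
  hits$hotspot_id <- sprintf("hs_%s_%d", hits$sseqid, spot)

  has <- function(col) !is.null(hits[[col]])
  hs <- do.call(rbind, lapply(split(hits, spot), function(d) {
    data.frame(
      hotspot_id = d$hotspot_id[1],
      chromosome = d$sseqid[1],
      start = min(d$.start), end = max(d$.end),
      n_hits = nrow(d),
      reads_LB = if (has("border")) sum(d$border == "LB", na.rm = TRUE) else NA_integer_,
      reads_RB = if (has("border")) sum(d$border == "RB", na.rm = TRUE) else NA_integer_,
      libraries = if (has("walking_primer_id")) {
        paste(sort(unique(d$walking_primer_id)), collapse = ",")
      } else NA_character_,
      best_evalue = min(d$evalue),
      best_identity = max(d$pident),
      max_read_len = if (has("qlen")) max(d$qlen) else max(d$length),
      stringsAsFactors = FALSE
    )
  }))
  hs <- hs[order(hs$chromosome, hs$start), , drop = FALSE]
  rownames(hs) <- NULL
  hits$.start <- NULL; hits$.end <- NULL
  list(hotspots = hs, hits = hits)
}

empty_hotspots <- function() {
  data.frame(hotspot_id = character(), chromosome = character(),
             start = integer(), end = integer(), n_hits = integer(),
             reads_LB = integer(), reads_RB = integer(),
             libraries = character(), best_evalue = numeric(),
             best_identity = numeric(), max_read_len = integer(),
             stringsAsFactors = FALSE)
}

#' Flag and rank candidate insertion sites
#'
#' Builds candidate sites from hotspots (merging adjacent hotspots within
#' `gap` when they carry complementary borders), sets the hierarchical
#' evidence flags, and assigns a deterministic rank:
#'
#' * `both_borders` -- the site has left- and right-border support within
#'   `gap` bp (the strongest evidence: the two libraries independently
#'   recover the two sides of the same junction);
#' * `multi_library` -- hits from more than one walking-primer library;
#' * `strong_stats` -- best e-value below `strong_evalue` (default 1e-30)
#'   or best identity above `strong_identity` (default 99);
#' * `long_read` -- at least one supporting fragment of >=
#'   `long_read_bp` (default 60) bp;
#' * `line_unique` -- no hotspot of any other line overlaps within `gap`.
#'
#' Sites are ordered by `both_borders` (desc), then the number of true
#' flags among the remaining four (desc), then total supporting reads
#' (desc), then best e-value (asc), then chromosome and start for
#' determinism.
#'
#' @param clustered output of [cluster_hits()] for the focal line
#' @param other_lines list of [cluster_hits()] outputs (or hotspot tables)
#'   for every other line, used for the cross-line uniqueness flag
#' @param gap pairing / uniqueness radius in bp (default 1000)
#' @param strong_evalue,strong_identity,long_read_bp flag thresholds
#' @param count_pooled should the pooled library count towards
#'   `multi_library`? (default TRUE)
#' @return data.frame of candidate sites ordered by rank, with a
#'   `site_id`, interval, per-border read counts, flags, `n_flags` and
#'   `rank`; the hit-to-site mapping is in `attr(, "hits")`
#' @export
flag_and_rank <- function(clustered, other_lines = list(), gap = 1000,
                          strong_evalue = 1e-30, strong_identity = 99,
                          long_read_bp = 60, count_pooled = TRUE) {
  hs <- clustered$hotspots
  if (nrow(hs) == 0L) return(empty_sites())
  hits <- clustered$hits

  # pair adjacent complementary-border hotspots into one site
  site_no <- integer(nrow(hs))
  cur <- 0L
  for (i in seq_len(nrow(hs))) {
    if (i > 1L && hs$chromosome[i] == hs$chromosome[i - 1L] &&
        (hs$start[i] - hs$end[i - 1L]) <= gap &&
        complementary_borders(hs[i - 1L, ], hs[i, ])) {
      site_no[i] <- site_no[i - 1L]
    } else {
      cur <- cur + 1L
      site_no[i] <- cur
    }
  }

  other_hs <- lapply(other_lines, function(o) {
    if (is.list(o) && !is.null(o$hotspots)) o$hotspots else o
  })

  sites <- do.call(rbind, lapply(split(seq_len(nrow(hs)), site_no), function(ii) {
    d <- hs[ii, , drop = FALSE]
    libs <- sort(unique(unlist(strsplit(d$libraries, ","))))
    n_libs <- if (count_pooled) length(libs)
              else length(setdiff(libs, "pooled"))
    reads_LB <- sum(d$reads_LB); reads_RB <- sum(d$reads_RB)
    start <- min(d$start); end <- max(d$end)
    chrom <- d$chromosome[1]
    overlaps_other <- any(vapply(other_hs, function(o) {
      any(o$chromosome == chrom & o$start <= end + gap &
            o$end >= start - gap)
    }, logical(1)))
    data.frame(
      site_id = sprintf("site_%s_%d", chrom, start),
      chromosome = chrom, start = start, end = end,
      hotspot_ids = paste(d$hotspot_id, collapse = ","),
      n_hits = sum(d$n_hits), reads_LB = reads_LB, reads_RB = reads_RB,
      libraries = paste(libs, collapse = ","),
      best_evalue = min(d$best_evalue),
      best_identity = max(d$best_identity),
      max_read_len = max(d$max_read_len),
      both_borders = reads_LB > 0 & reads_RB > 0,
      multi_library = n_libs > 1L,
      strong_stats = min(d$best_evalue) < strong_evalue |
        max(d$best_identity) > strong_identity,
      long_read = max(d$max_read_len) >= long_read_bp,
      line_unique = !overlaps_other,
      stringsAsFactors = FALSE
    )
  }))
  sites$n_flags <- with(sites, multi_library + strong_stats + long_read +
                          line_unique)
  ord <- with(sites, order(-both_borders, -n_flags, -(reads_LB + reads_RB),
                           best_evalue, chromosome, start))
  sites <- sites[ord, , drop = FALSE]
  sites$rank <- seq_len(nrow(sites))
  rownames(sites) <- NULL

  hs_to_site <- stats::setNames(
    rep(sites$site_id, lengths(strsplit(sites$hotspot_ids, ","))),
    unlist(strsplit(sites$hotspot_ids, ",")))
  hits$site_id <- unname(hs_to_site[hits$hotspot_id])
  attr(sites, "hits") <- hits
  sites
}

complementary_borders <- function(a, b) {
  if (is.na(a$reads_LB) || is.na(b$reads_LB)) return(FALSE)
  (a$reads_LB > 0 & b$reads_RB > 0) | (a$reads_RB > 0 & b$reads_LB > 0)
}

empty_sites <- function() {
  out <- data.frame(site_id = character(), chromosome = character(),
                    start = integer(), end = integer(),
                    hotspot_ids = character(), n_hits = integer(),
                    reads_LB = integer(), reads_RB = integer(),
                    libraries = character(), best_evalue = numeric(),
                    best_identity = numeric(), max_read_len = integer(),
                    both_borders = logical(), multi_library = logical(),
                    strong_stats = logical(), long_read = logical(),
                    line_unique = logical(), n_flags = integer(),
                    rank = integer(), stringsAsFactors = FALSE)
  attr(out, "hits") <- NULL
  out
}

#' Group candidate sites into homeolog groups
#'
#' In an allopolyploid, one insertion typically produces 2-3 candidate
#' sites -- the true locus and its homeologous copies -- supported by
#' largely the same fragments. Sites are grouped when they share at least
#' `min_share` of the smaller site's supporting fragment set (transitively).
#'
#' @param sites site table from [flag_and_rank()]
#' @param hits hit table carrying `site_id` and `qseqid` (defaults to
#'   `attr(sites, "hits")`)
#' @param min_share minimum shared-fragment fraction (default 0.5)
#' @return `sites` with a `homeolog_group` integer column
#' @export
group_homeologs <- function(sites, hits = attr(sites, "hits"),
                            min_share = 0.5) {
  if (nrow(sites) == 0L) { sites$homeolog_group <- integer(0); return(sites) }
  frag_sets <- lapply(sites$site_id, function(s)
    unique(hits$qseqid[hits$site_id == s]))
  n <- nrow(sites)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    shared <- length(intersect(frag_sets[[i]], frag_sets[[j]]))
    m <- min(length(frag_sets[[i]]), length(frag_sets[[j]]))
    if (m > 0 && shared / m >= min_share) {
      parent[find(j)] <- find(i)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  sites$homeolog_group <- match(roots, unique(roots))
  sites
}

#' Resolve homeologous candidate groups to a single locus where possible
#'
#' Within each homeolog group, compares the supporting-hit statistics of
#' the member sites side by side. The group resolves to the site whose mean
#' hit identity exceeds every other member's by more than `id_margin`
#' percentage points, provided its supporting read count is at least
#' `count_ratio` times the best count among the other members; otherwise
#' all members are kept as a tie. Singleton groups resolve trivially.
#'
#' When homeologs have diverged, fragments from the true locus match it at
#' essentially the sequencing error rate while matching the homeologous
#' copies at the (lower) homeolog identity, so the identity margin is the
#' primary discriminator; the count condition only guards against resolving
#' to an outnumbered site. With undiverged (identical) homeologs all
#' statistics coincide and the group stays a tie.
#'
#' @param sites site table with `homeolog_group` (see [group_homeologs()])
#' @param hits hit table with `site_id` (defaults to `attr(sites, "hits")`)
#' @param id_margin identity margin in percentage points (default 0.5)
#' @param count_ratio minimum read-count ratio over the runner-up
#'   (default 1, i.e. the resolved site must not be outnumbered)
#' @return `sites` with a `homeolog_status` column: `resolved:<chromosome>`
#'   or `tie:<chr1,chr2,...>`
#' @export
resolve_homeologs <- function(sites, hits = attr(sites, "hits"),
                              id_margin = 0.5, count_ratio = 1) {
  if (nrow(sites) == 0L) { sites$homeolog_status <- character(0); return(sites) }
  if (is.null(sites$homeolog_group)) sites <- group_homeologs(sites, hits)
  status <- character(nrow(sites))
  for (g in unique(sites$homeolog_group)) {
    ii <- which(sites$homeolog_group == g)
    if (length(ii) == 1L) {
      status[ii] <- paste0("resolved:", sites$chromosome[ii])
      next
    }
    mean_id <- vapply(ii, function(i)
      mean(hits$pident[hits$site_id == sites$site_id[i]]), numeric(1))
    counts <- sites$n_hits[ii]
    top <- which.max(mean_id)
    others <- setdiff(seq_along(ii), top)
    margin_ok <- all(mean_id[top] - mean_id[others] > id_margin)
    count_ok <- counts[top] >= count_ratio * max(counts[others])
    status[ii] <- if (margin_ok && count_ok) {
      paste0("resolved:", sites$chromosome[ii[top]])
    } else {
      paste0("tie:", paste(sort(sites$chromosome[ii]), collapse = ","))
    }
  }
  sites$homeolog_status <- status
  sites
}

#' Infer T-DNA orientation at a candidate site
#'
#' Each informative supporting hit (one carrying `border`, `which_read` and
#' `strand`) votes for one of the two junction configurations. With the
#' amplicon geometry of the two-phase walking PCR -- read 2 reads outward
#' from the border into the flank, read 1 back from the walking-motif end --
#' an insertion whose right border faces the lower-coordinate (upstream)
#' flank yields right-border-library read-1 hits on the plus strand and
#' read-2 hits on the minus strand, with the mirror pattern in the
#' left-border library; this configuration is called `RB-LB`. The mirrored
#' vote pattern is called `LB-RB`. The orientation is reported only when at
#' least `quorum` of informative hits agree; conflicting or absent evidence
#' yields `undetermined`.
#'
#' @param site_hits hits supporting one site
#' @param quorum minimum agreeing fraction (default 0.8)
#' @return one of `"RB-LB"`, `"LB-RB"`, `"undetermined"`
#' @export
infer_orientation <- function(site_hits, quorum = 0.8) {
  h <- site_hits
  ok <- !is.na(h$border) & !is.na(h$which_read) & !is.na(h$strand) &
    h$border %in% c("LB", "RB") & h$which_read %in% c(1L, 2L)
  h <- h[ok, , drop = FALSE]
  if (nrow(h) == 0L) return("undetermined")
  rb_lb <- (h$border == "RB" & h$which_read == 1L & h$strand == "+") |
    (h$border == "RB" & h$which_read == 2L & h$strand == "-") |
    (h$border == "LB" & h$which_read == 1L & h$strand == "-") |
    (h$border == "LB" & h$which_read == 2L & h$strand == "+")
  frac <- max(mean(rb_lb), mean(!rb_lb))
  if (frac < quorum) return("undetermined")
  if (mean(rb_lb) >= mean(!rb_lb)) "RB-LB" else "LB-RB"
}

#' Estimate the junction coordinate of a site from its supporting hits
#'
#' Read-2 fragments begin at the junction -- the read crosses from the
#' T-DNA into the flank, so the fragment's first base (its first subject
#' coordinate) sits at the junction regardless of amplicon length. The
#' estimate is the median first subject coordinate of read-2 hits.
#' (Read-1 fragments start at the walking-motif end and reach the junction
#' only on short amplicons, so they are used only as a fallback, via the
#' coordinate where the fragment ends.)
#'
#' @param site_hits hits supporting one site
#' @return numeric genomic coordinate (1-based)
#' @export
estimate_junction <- function(site_hits) {
  h <- site_hits
  coords <- h$sstart[!is.na(h$which_read) & h$which_read == 2L]
  if (!length(coords)) {
    coords <- h$send[!is.na(h$which_read) & h$which_read == 1L]
  }
  if (!length(coords)) coords <- c(h$sstart, h$send)
  round(median(coords))
}

#' Genomic windows for verification-primer design
#'
#' Returns the upstream and downstream windows at `flank[1]`-`flank[2]` bp
#' (default 250-500) on either side of an insertion point, clipped at the
#' chromosome ends, with their sequences for external primer design.
#' A window falling entirely off the chromosome is omitted with a warning.
#'
#' @param position 1-based insertion-point coordinate
#' @param chromosome chromosome name
#' @param genome the reference genome
#' @param flank numeric length-2 offsets in bp
#' @return data.frame with `side` (`upstream`/`downstream`), `chromosome`,
#'   `start`, `end` (1-based inclusive) and `sequence`
#' @export
primer_windows <- function(position, chromosome, genome,
                           flank = c(250, 500)) {
  genome <- as_genome(genome)
  if (!chromosome %in% names(genome)) stop("unknown chromosome: ", chromosome)
  clen <- nchar(genome[[chromosome]])
  stopifnot(length(flank) == 2, flank[1] > 0, flank[2] > flank[1])
  wins <- data.frame(
    side = c("upstream", "downstream"),
    start = c(position - flank[2], position + flank[1]),
    end = c(position - flank[1], position + flank[2]),
    stringsAsFactors = FALSE
  )
  wins$start <- pmax(wins$start, 1)
  wins$end <- pmin(wins$end, clen)
  gone <- wins$start > wins$end
  if (any(gone)) {
    warning("insertion point within flank distance of a chromosome end; ",
            paste(wins$side[gone], collapse = " and "), " window omitted")
    wins <- wins[!gone, , drop = FALSE]
  }
  wins$chromosome <- chromosome
  wins$sequence <- substr(rep(genome[[chromosome]], nrow(wins)),
                          wins$start, wins$end)
  wins[, c("side", "chromosome", "start", "end", "sequence")]
}

#' Annotate candidate sites with orientation, junction and homeolog status
#'
#' Convenience wrapper running [group_homeologs()], [resolve_homeologs()],
#' [infer_orientation()] and [estimate_junction()] over a ranked site
#' table.
#'
#' @param sites site table from [flag_and_rank()]
#' @param hits hit table with `site_id` (defaults to `attr(sites, "hits")`)
#' @param id_margin,count_ratio passed to [resolve_homeologs()]
#' @param quorum passed to [infer_orientation()]
#' @return `sites` with `homeolog_group`, `homeolog_status`, `orientation`,
#'   `junction`, `transgene_id`, `is_primary` and `primary_rank` columns.
#'   One site per homeolog group is marked primary -- the resolved locus,
#'   or the best-ranked member of a tie -- and primary sites carry a dense
#'   re-ranking in `primary_rank`, giving one candidate per putative
#'   insertion.
#' @export
annotate_sites <- function(sites, hits = attr(sites, "hits"),
                           id_margin = 0.5, count_ratio = 1, quorum = 0.8) {
  sites <- group_homeologs(sites, hits)
  sites <- resolve_homeologs(sites, hits, id_margin, count_ratio)
  sites$orientation <- vapply(sites$site_id, function(s)
    infer_orientation(hits[hits$site_id == s, , drop = FALSE], quorum),
    character(1))
  sites$junction <- vapply(sites$site_id, function(s)
    estimate_junction(hits[hits$site_id == s, , drop = FALSE]), numeric(1))
  sites$transgene_id <- if (is.null(hits$construct)) NA_character_ else {
    vapply(sites$site_id, function(s) {
      cc <- hits$construct[hits$site_id == s]
      cc <- cc[!is.na(cc)]
      if (!length(cc)) NA_character_ else names(which.max(table(cc)))
    }, character(1))
  }
  # one primary candidate per homeolog group: the resolved locus, or the
  # best-ranked member of a tie
  sites$is_primary <- FALSE
  for (g in unique(sites$homeolog_group)) {
    ii <- which(sites$homeolog_group == g)
    st <- sites$homeolog_status[ii[1]]
    pick <- if (startsWith(st, "resolved:")) {
      ii[match(sub("^resolved:", "", st), sites$chromosome[ii])]
    } else {
      ii[which.min(sites$rank[ii])]
    }
    if (is.na(pick)) pick <- ii[which.min(sites$rank[ii])]
    sites$is_primary[pick] <- TRUE
  }
  sites$primary_rank <- NA_integer_
  prim <- which(sites$is_primary)
  sites$primary_rank[prim[order(sites$rank[prim])]] <-
    seq_along(prim)
  attr(sites, "hits") <- hits
  sites
}

#' Write candidate sites as TSV (1-based inclusive) and BED (0-based
#' half-open)
#' @param sites annotated site table
#' @param file output TSV path
#' @export
write_sites_tsv <- function(sites, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("# coordinates: 1-based inclusive", con)
  out <- sites
  attr(out, "hits") <- NULL
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_sites_tsv
#' @export
write_sites_bed <- function(sites, file) {
  gr <- GenomicRanges::GRanges(
    seqnames = sites$chromosome,
    ranges = IRanges::IRanges(start = sites$start, end = sites$end),
    name = sites$site_id, score = pmin(sites$n_hits, 1000))
  rtracklayer::export(gr, file, format = "BED")
  invisible(file)
}
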