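#' Call zygosity from a two-PCR (anchored/flanking) result pair
#'
#' Genotypes a plant at one insertion locus from the outcomes of the
#' T-DNA-anchored PCR ("A": one genomic primer plus one transgene primer,
#' positive only when the junction is present) and the T-DNA-flanking PCR
#' ("B": two genomic primers across the insertion point, positive only when
#' an insertion-free allele exists, the full T-DNA being too long to
#' amplify). The truth table is exhaustive:
#'
#' * `(+, +)` -> heterozygous (junction and native allele both present)
#' * `(+, -)` -> homozygous (junction only)
#' * `(-, +)` -> wildtype_null (native allele only; null segregant)
#' * `(-, -)` -> indeterminate (assay failure)
#'
#' @param A,B character vectors of `"+"`/`"-"` results (recycled together)
#' @return character vector of genotypes: `"heterozygous"`, `"homozygous"`,
#'   `"wildtype_null"` or `"indeterminate"`
#' @examples
#' call_zygosity("+", "+")
#' call_zygosity(c("+", "-"), c("-", "+"))
#' @export
call_zygosity <- function(A, B) {
  n <- max(length(A), length(B))
  A <- rep_len(as.character(A), n)
  B <- rep_len(as.character(B), n)
  bad <- !(A %in% c("+", "-")) | !(B %in% c("+", "-"))
  if (any(bad)) {
    stop("invalid PCR symbols (must be '+' or '-') at position(s): ",
         paste(which(bad), collapse = ", "))
  }
  ifelse(A == "+" & B == "+", "heterozygous",
    ifelse(A == "+" & B == "-", "homozygous",
      ifelse(A == "-" & B == "+", "wildtype_null", "indeterminate")))
}

#' Summarise segregation at insertion loci from PCR A/B sheets
#'
#' Counts genotypes per locus and reports percentages on two denominators:
#' the carrier denominator (heterozygous + homozygous plants; the
#' `table_style` columns, including the wildtype percentage, use this
#' denominator, matching the common reporting convention for
#' transgene-positive totals) and the all-typed-plants denominator.
#' A chi-square goodness-of-fit against `expected_ratio` (het:hmz:null,
#' default 2:1:1 -- selfed progeny of a hemizygote) is computed excluding
#' indeterminate plants; loci with `p < 0.05` are flagged `non_mendelian`,
#' the signature of e.g. a homozygous-lethal insertion.
#'
#' @param results data.frame with columns `plant_id`, `locus_id`, `pcrA`,
#'   `pcrB` (one row per plant per locus)
#' @param expected_ratio numeric length-3 het:hmz:null ratio for the
#'   goodness-of-fit test
#' @return data.frame, one row per locus, with genotype counts,
#'   `n_carriers`, `table_style` percentages (carrier denominator),
#'   `pct_*_all` percentages (all typed plants), `chi_square`, `p_value`
#'   and `non_mendelian`
#' @export
summarize_segregation <- function(results, expected_ratio = c(2, 1, 1)) {
  req <- c("plant_id", "locus_id", "pcrA", "pcrB")
  if (!all(req %in% names(results))) {
    stop("results must have columns: ", paste(req, collapse = ", "))
  }
  stopifnot(length(expected_ratio) == 3, all(expected_ratio >= 0))
  results$genotype <- call_zygosity(results$pcrA, results$pcrB)
  dup <- duplicated(results[c("plant_id", "locus_id")])
  if (any(dup)) stop("duplicate plant/locus rows in results")

  out <- lapply(split(results, results$locus_id), function(d) {
    het <- sum(d$genotype == "heterozygous")
    hmz <- sum(d$genotype == "homozygous")
    wt <- sum(d$genotype == "wildtype_null")
    ind <- sum(d$genotype == "indeterminate")
    n_typed <- het + hmz + wt
    if (n_typed == 0L) {
      stop("locus ", d$locus_id[1], " has zero typed plants")
    }
    carriers <- het + hmz
    pr <- expected_ratio / sum(expected_ratio)
    if (all(pr > 0)) {
      cs <- suppressWarnings(chisq.test(c(het, hmz, wt), p = pr))
      chi <- unname(cs$statistic); pv <- unname(cs$p.value)
    } else {
      # degenerate expectation (e.g. 2:0:1): compute the statistic only over
      # classes with non-zero expectation
      keep <- pr > 0
      obs <- c(het, hmz, wt)
      exp_ct <- sum(obs[keep]) * pr[keep] / sum(pr[keep])
      chi <- sum((obs[keep] - exp_ct)^2 / exp_ct)
      pv <- pchisq(chi, df = sum(keep) - 1, lower.tail = FALSE)
    }
    data.frame(
      locus_id = d$locus_id[1],
      n = nrow(d), het = het, hmz = hmz, wt_null = wt, indeterminate = ind,
      n_carriers = carriers,
      pct_het_table_style = if (carriers) 100 * het / carriers else NA_real_,
      pct_hmz_table_style = if (carriers) 100 * hmz / carriers else NA_real_,
      pct_wt_table_style = if (carriers) 100 * wt / carriers else NA_real_,
      pct_het_all = 100 * het / n_typed,
      pct_hmz_all = 100 * hmz / n_typed,
      pct_wt_all = 100 * wt / n_typed,
      chi_square = chi, p_value = pv,
      non_mendelian = pv < 0.05,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Probability of recovering a fully homozygous individual when stacking
#' independent hemizygous loci
#'
#' Under independent Mendelian segregation of a selfed hemizygote, each
#' locus is homozygous for the insertion in 1/4 of progeny, so the chance
#' that one individual is homozygous at all `k` loci is `(1/4)^k`.
#'
#' @param k number of independent hemizygous loci (>= 0)
#' @return percentage: `100 * (1/4)^k`
#' @examples
#' stacking_homozygosity_prob(1) # 25
#' stacking_homozygosity_prob(2) # 6.25
#' @export
stacking_homozygosity_prob <- function(k) {
  if (any(!is.finite(k)) || any(k < 0) || any(k != floor(k))) {
    stop("k must be a non-negative integer")
  }
  100 * (1 / 4)^k
}

#' Expected enrichment of border-containing template after the linear PCR
#' phase
#'
#' During the high-annealing-temperature linear phase only the
#' transgene-specific border primer binds, adding one copy of the starting
#' number of border-containing fragments per cycle while background is not
#' amplified. After `n_cycles` cycles the border-containing template is
#' therefore enriched `1 + n_cycles`-fold over background (about 19x for the
#' default 18-cycle phase) before exponential walking-primer amplification
#' begins.
#'
#' @param n_cycles number of linear-phase cycles (default 18)
#' @return fold enrichment, `1 + n_cycles`
#' @export
linear_phase_enrichment <- function(n_cycles = 18) {
  if (any(!is.finite(n_cycles)) || any(n_cycles < 0)) {
    stop("n_cycles must be non-negative")
  }
  1 + n_cycles
}

#' Read a zygosity sheet TSV
#'
#' Expects tab-separated columns `plant_id`, `locus_id`, `pcrA`, `pcrB`.
#' Invalid PCR symbols are reported with their line numbers.
#' @param path file path
#' @return data.frame
#' @export
read_zygosity_sheet <- function(path) {
  d <- read.table(path, sep = "\t", header = TRUE, colClasses = "character",
                  comment.char = "#")
  req <- c("plant_id", "locus_id", "pcrA", "pcrB")
  if (!all(req %in% names(d))) {
    stop("zygosity sheet must have columns: ", paste(req, collapse = ", "))
  }
  bad <- which(!(d$pcrA %in% c("+", "-")) | !(d$pcrB %in% c("+", "-")))
  if (length(bad)) {
    stop("invalid PCR symbols on sheet line(s): ",
         paste(bad + 1L, collapse = ", "))  # +1 for the header line
  }
  d
}
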