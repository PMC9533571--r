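`%||%` <- function(a, b) if (is.null(a)) b else a

#' Coerce a genome argument to a named character vector of uppercase sequences
#'
#' Accepts a `DNAStringSet`, a named character vector, or a path to a FASTA
#' file. Names are truncated at the first whitespace.
#' @param genome genome in any of the accepted forms
#' @return named character vector of uppercase DNA sequences
#' @keywords internal
as_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome) &&
      is.null(names(genome))) {
    genome <- Biostrings::readDNAStringSet(genome)
  }
  if (is(genome, "XStringSet")) {
    out <- as.character(genome)
    names(out) <- names(genome)
  } else if (is.character(genome)) {
    out <- genome
  } else {
    stop("genome must be a DNAStringSet, a named character vector, ",
         "or a FASTA path")
  }
  if (length(out) == 0L) stop("genome is empty")
  if (is.null(names(out)) || anyNA(names(out)) || any(names(out) == "")) {
    stop("genome sequences must be named")
  }
  names(out) <- sub("\\s.*$", "", names(out))
  toupper(out)
}

#' Reverse complement of character DNA sequences
#' @param x character vector of DNA sequences
#' @return character vector
#' @keywords internal
dna_revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

check_dna <- function(x, what = "sequence", min_len = 1L) {
  if (length(x) != 1L || is.na(x) || !nzchar(x)) {
    stop(what, " must be a non-empty string")
  }
  x <- toupper(x)
  if (grepl("[^ACGT]", x)) stop(what, " contains non-ACGT characters")
  if (nchar(x) < min_len) stop(what, " must be at least ", min_len, " bp")
  x
}

#' Run code with a temporary RNG seed, restoring the caller's RNG state
#' @keywords internal
local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a random DNA sequence
#' @param n length in bp
#' @return a single character string; uses the current RNG stream
#' @keywords internal
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
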