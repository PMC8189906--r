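#' @import data.table
#' @importFrom stats rpois rbinom runif dbinom median wilcox.test p.adjust
#'   cor.test qgamma var
#' @importFrom utils head tail
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Run code under a named, seed-derived random substream
#'
#' All generators in the package draw their randomness from a single integer
#' seed through named substreams, so that re-running one generator reproduces
#' its output regardless of the order in which the others ran.  The substream
#' seed is a deterministic 31-bit hash of (seed, name).  The caller's RNG
#' state is saved and restored.
#'
#' @param seed integer master seed
#' @param name substream name (e.g. "trio", "site_calls")
#' @param code expression to evaluate under the substream
#' @return the value of `code`
#' @keywords internal
with_substream <- function(seed, name, code) {
  h <- sum(utf8ToInt(name) * (seq_along(utf8ToInt(name)) * 131))
  sub <- (as.numeric(seed) * 48271 + h) %% 2147483629 + 1
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(sub))
  code
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

seq_len_bp <- function(s) nchar(s)

check_alphabet <- function(s, what = "sequence") {
  if (grepl("[^ACGTN]", s))
    stop(what, " contains symbols outside the ACGTN alphabet", call. = FALSE)
  invisible(TRUE)
}

#' Split a sequence into individual bases
#' @keywords internal
seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a FASTA file into a named character vector
#'
#' @param path FASTA file
#' @return named character vector of uppercase sequences
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write a named character vector of sequences to FASTA
#'
#' @param seqs named character vector
#' @param path output path
#' @param width line width
#' @export
write_fasta <- function(seqs, path, width = 80L) {
  stopifnot(!is.null(names(seqs)))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path, width = width)
  invisible(path)
}
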