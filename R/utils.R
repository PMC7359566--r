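#' @importFrom Biostrings DNAStringSet DNAString reverseComplement readDNAStringSet
#'   writeXStringSet PDict vcountPDict vwhichPDict pairwiseAlignment
#'   nucleotideSubstitutionMatrix score nmatch pid
#' @importFrom S4Vectors mcols mcols<-
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges seqnames start end strand
#' @importFrom stats rnbinom rbinom rnorm runif median quantile t.test ks.test
#'   p.adjust prcomp pt pnorm sd var setNames
#' @importFrom utils write.table read.delim head tail packageVersion
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Evaluate an expression under a fixed RNG seed
#'
#' Saves and restores the global RNG state so that seeded internals do not
#' disturb the caller's random number stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

#' Generate a random DNA sequence
#'
#' Draws bases uniformly and independently from A, C, G, T using the current
#' RNG stream.
#'
#' @param n Sequence length in nucleotides.
#' @return A single character string of length `n`.
#' @keywords internal
random_dna <- function(n) {
  if (n <= 0) return("")
  paste(DNA_BASES[sample.int(4L, n, replace = TRUE)], collapse = "")
}

#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## Fast per-string reverse complement without Biostrings overhead; used in
## inner loops on plain character data.
revcomp1 <- function(x) {
  rawToChar(rev(charToRaw(chartr("ACGTNacgtn", "TGCANtgcan", x))))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x == round(x)
}
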