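## Small shared helpers. Kept base-R and dependency-free on purpose.

#' Round half away from zero at a fixed number of decimals
#'
#' Printed tables in surveillance reports use commercial ("half-up") rounding,
#' not banker's rounding, so `round()` is not a drop-in.
#'
#' @param x numeric vector
#' @param digits decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Hamming distance between equal-length strings
#'
#' @param a,b character scalars of equal nchar
#' @return integer count of differing positions
#' @export
hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(charToRaw(a) != charToRaw(b))
}

## Vectorised Hamming distance of one string against many (all equal length).
hamming_many <- function(x, pool) {
  xr <- charToRaw(x)
  vapply(pool, function(p) sum(charToRaw(p) != xr), integer(1), USE.NAMES = FALSE)
}

## Reverse complement for plain character vectors (delegates to Biostrings).
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## Translate a 3-letter codon (transcript sense) to one amino-acid letter.
translate_codon <- function(codon) {
  as.character(Biostrings::translate(Biostrings::DNAStringSet(codon),
                                     no.init.codon = TRUE))
}

## Complement single bases without reversing.
complement_base <- function(x) chartr("ACGTN", "TGCAN", x)

## Deterministic RNG scope: every stochastic operation in the package funnels
## through this so a seed given once pins the whole artefact.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

## Random DNA of length n (uniform bases), assumes an active RNG scope.
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
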