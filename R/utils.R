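#' @importFrom methods new validObject is setClass setGeneric setMethod
#'   setValidity show slot
#' @importFrom stats lm coef complete.cases cutree hclust as.dist cor
#'   phyper rpois runif rbinom sample.int setNames
#' @importFrom utils read.delim write.table combn head tail
#' @importFrom stats rpois var
#' @importClassesFrom Biostrings DNAString
#' @import GenomicRanges
NULL

VALID_BASES <- c("A", "C", "G", "T", "N")

## GC fraction with N counting as non-GC (denominator = full length).
gcFraction <- function(x) {
  if (is(x, "DNAString") || is(x, "DNAStringSet")) x <- as.character(x)
  x <- toupper(paste(x, collapse = ""))
  n <- nchar(x)
  if (n == 0L) return(NA_real_)
  v <- strsplit(x, "", fixed = TRUE)[[1L]]
  sum(v == "G" | v == "C") / n
}

## Split a string into a character vector of single bases (upper case).
seqChars <- function(x) {
  if (is(x, "DNAString")) x <- as.character(x)
  strsplit(toupper(x), "", fixed = TRUE)[[1L]]
}

checkBases <- function(x, what = "sequence") {
  v <- seqChars(x)
  bad <- setdiff(unique(v), VALID_BASES)
  if (length(bad))
    stop(what, " contains characters outside {A,C,G,T,N}: ",
         paste(bad, collapse = ", "))
  invisible(v)
}

revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

## Extract a subsequence from a circular genome; `end` may exceed the
## genome length, in which case the slice wraps through position 1.
circularSubseq <- function(seq, start, end) {
  seq <- as.character(seq)
  n <- nchar(seq)
  if (end <= n) return(substr(seq, start, end))
  paste0(substr(seq, start, n), substr(seq, 1L, end - n))
}

## Normalise a possibly-wrapping interval (1-based closed, end may exceed
## genome length) to an IRanges of one or two on-circle ranges.
unwrapInterval <- function(start, end, n) {
  if (end <= n) return(IRanges::IRanges(start, end))
  IRanges::IRanges(c(start, 1L), c(n, end - n))
}

## Approximate a fraction by a small-denominator rational for exact
## integer threshold arithmetic; falls back to scaled doubles.
asRational <- function(g, max_den = 10000L) {
  for (q in seq_len(max_den)) {
    p <- round(g * q)
    if (abs(g * q - p) < 1e-9) return(c(p = p, q = q))
  }
  c(p = round(g * 1e6), q = 1e6)
}
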