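## Conserved-column identity statistics and pairwise alignment identity.

.asAlignmentMatrix <- function(x) {
  if (is.matrix(x)) {
    m <- toupper(x)
  } else if (is(x, "DNAMultipleAlignment") || is(x, "AAMultipleAlignment") ||
             is(x, "XStringSet")) {
    ch <- as.character(x)
    m <- do.call(rbind, strsplit(toupper(ch), "", fixed = TRUE))
  } else if (is.character(x)) {
    if (length(unique(nchar(x))) != 1L)
      stop("aligned sequences must have equal lengths")
    m <- do.call(rbind, strsplit(toupper(x), "", fixed = TRUE))
  } else stop("cannot interpret alignment of class ", class(x)[1])
  m
}

#' Proportion of completely conserved alignment columns
#'
#' A column counts as conserved iff every row carries the same non-gap
#' residue; the denominator is the full alignment length, so columns
#' containing any gap (including all-gap columns) count against
#' identity.
#'
#' @param x an alignment: character matrix, equal-length character
#'   vector of aligned sequences, or a Biostrings multiple alignment.
#' @return fraction in [0, 1].
#' @export
conservedIdentity <- function(x) {
  m <- .asAlignmentMatrix(x)
  if (nrow(m) < 2L) stop("need at least 2 aligned sequences")
  if (ncol(m) == 0L) stop("alignment has zero columns")
  cons <- vapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    !any(col %in% c("-", ".")) && length(unique(col)) == 1L
  }, logical(1))
  sum(cons) / ncol(m)
}

#' Hypergeometric enrichment of high-identity sequences
#'
#' One-sided test of whether group A contains more high-identity
#' entries (identity strictly greater than \code{threshold}) than
#' expected if the high-identity entries were distributed at random
#' over the pooled population A + B. Exact upper tail,
#' P(X >= observed).
#'
#' @param group_a,group_b numeric identity vectors in [0, 1].
#' @param threshold success cutoff (default 0.9, i.e. identity > 90\%).
#' @return list with p_value, successes_a, successes_total, n_a, n_total.
#' @export
highIdentityEnrichment <- function(group_a, group_b, threshold = 0.9) {
  if (!length(group_a) || !length(group_b)) stop("empty group")
  stopifnot(all(group_a >= 0 & group_a <= 1),
            all(group_b >= 0 & group_b <= 1))
  k <- sum(group_a > threshold)
  K <- k + sum(group_b > threshold)
  N <- length(group_a) + length(group_b)
  n <- length(group_a)
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  list(p_value = p, successes_a = k, successes_total = K,
       n_a = n, n_total = N)
}

## Needleman-Wunsch global alignment with match +1, mismatch -1,
## linear gap -2, via Biostrings. Alphabet-agnostic (nucleotide or
## amino acid): the substitution matrix is built from the letters seen.
nwAlign <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  letters_ <- sort(unique(strsplit(paste0(a, b), "", fixed = TRUE)[[1L]]))
  mat <- matrix(-1, length(letters_), length(letters_),
                dimnames = list(letters_, letters_))
  diag(mat) <- 1
  al <- Biostrings::pairwiseAlignment(Biostrings::BString(a),
                                      Biostrings::BString(b),
                                      type = "global",
                                      substitutionMatrix = mat,
                                      gapOpening = 0, gapExtension = 2)
  c(a = as.character(Biostrings::alignedPattern(al)),
    b = as.character(Biostrings::alignedSubject(al)))
}

#' Pairwise sequence identity
#'
#' Ungapped mode compares sequences of equal length position by
#' position; global mode first aligns them by Needleman-Wunsch
#' (match +1, mismatch -1, gap -2) and then scores conserved columns
#' over the full alignment length.
#'
#' @param a,b sequences (nucleotide or amino acid strings).
#' @param mode \code{"ungapped"} or \code{"global"}.
#' @return fraction in [0, 1].
#' @export
pairwiseIdentity <- function(a, b, mode = c("ungapped", "global")) {
  mode <- match.arg(mode)
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  if (mode == "ungapped") {
    if (nchar(a) != nchar(b))
      stop("ungapped identity requires equal-length sequences")
    va <- strsplit(toupper(a), "")[[1L]]
    vb <- strsplit(toupper(b), "")[[1L]]
    return(sum(va == vb) / length(va))
  }
  al <- nwAlign(a, b)
  conservedIdentity(unname(al))
}

#' Read an aligned FASTA file as an alignment matrix
#'
#' @param path aligned FASTA.
#' @param alphabet \code{"nucleotide"} or \code{"amino_acid"}.
#' @return character matrix with sequence ids as row names.
#' @export
readAlignmentFasta <- function(path, alphabet = c("nucleotide",
                                                  "amino_acid")) {
  alphabet <- match.arg(alphabet)
  ss <- Biostrings::readBStringSet(path)
  m <- .asAlignmentMatrix(as.character(ss))
  rownames(m) <- vapply(strsplit(names(ss), "\\s+"), `[`, character(1), 1L)
  m
}

#' Ingest an externally computed dN/dS table
#'
#' The package does not estimate dN/dS; this reads a TSV of
#' externally computed omega values (columns: gene, lineage, omega)
#' for inclusion in reports.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
readOmegaTable <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("gene", "lineage", "omega")
  if (!all(req %in% names(tab)))
    stop("omega table needs columns: ", paste(req, collapse = ", "))
  tab$omega <- as.numeric(tab$omega)
  tab
}
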