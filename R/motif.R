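## IUPAC motif scanning (e.g. the transcription-initiation motif
## WTATAAGTA upstream of transcriptional units).

#' Scan a genome for an IUPAC motif
#'
#' Reports all (possibly overlapping) exact IUPAC matches. On circular
#' genomes matches may wrap the origin (reported with end > genome
#' length). Minus-strand matches are positions where the reverse
#' complement of the motif occurs on the given sequence; coordinates
#' always refer to the forward strand.
#'
#' @param x a \linkS4class{MitoGenome} or nucleotide string.
#' @param motif IUPAC motif string (e.g. \code{"WTATAAGTA"}).
#' @param strand \code{"+"}, \code{"-"} or \code{"both"}.
#' @param topology used when \code{x} is a string.
#' @return data.frame with start, end, strand, match.
#' @export
scanMotif <- function(x, motif, strand = c("both", "+", "-"),
                      topology = c("circular", "linear")) {
  strand <- match.arg(strand)
  if (is(x, "MitoGenome")) {
    seq <- as.character(genomeSeq(x)); topology <- topology(x)
  } else {
    topology <- match.arg(topology)
    seq <- toupper(as.character(x))
  }
  motif <- toupper(motif)
  bad <- setdiff(strsplit(motif, "")[[1L]],
                 names(Biostrings::IUPAC_CODE_MAP))
  if (length(bad))
    stop("invalid IUPAC code(s) in motif: ", paste(bad, collapse = ", "))
  n <- nchar(seq)
  m <- nchar(motif)
  subject <- if (topology == "circular" && n > 1L)
    paste0(seq, substr(seq, 1L, min(m - 1L, n))) else seq
  scan1 <- function(pat, str) {
    if (nchar(subject) < m) return(data.frame(start = integer(),
                                              end = integer(),
                                              strand = character(),
                                              match = character()))
    hits <- Biostrings::matchPattern(Biostrings::DNAString(pat),
                                     Biostrings::DNAString(subject),
                                     fixed = FALSE)
    st <- Biostrings::start(hits)
    keep <- st <= n   # wrap duplicates start beyond the origin copy
    data.frame(start = st[keep], end = st[keep] + m - 1L,
               strand = rep(str, sum(keep)),
               match = as.character(hits)[keep],
               stringsAsFactors = FALSE)
  }
  out <- list()
  if (strand %in% c("+", "both")) out$fwd <- scan1(motif, "+")
  if (strand %in% c("-", "both"))
    out$rev <- scan1(revComp(motif), "-")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$start, res$strand), , drop = FALSE]
}
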