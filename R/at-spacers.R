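## AT-spacer detection and dinucleotide statistics.

#' Detect AT spacers in intergenic regions
#'
#' Within each intergenic interval, GC clusters containing at least one
#' all-G/C tetranucleotide are excised; every remaining maximal
#' fragment longer than \code{min_len} bp with GC fraction below
#' \code{max_gc} is reported as an AT spacer.
#'
#' @param g a \linkS4class{MitoGenome}.
#' @param intergenic intergenic intervals as an \code{IRanges}
#'   (default: complement of the annotated genes, introns, free-standing
#'   ORFs and ori elements via \code{\link{intergenicRegions}} --
#'   consistent with the partition precedence, under which ORFs and
#'   oris outrank AT spacers).
#' @param clusters GC clusters (default: \code{\link{detectGCClusters}}
#'   on the genome).
#' @param min_len spacers must be strictly longer than this (default 20).
#' @param max_gc spacers must have GC strictly below this (default 0.1).
#' @return data.frame with genome_id, start, end, length, gc, sequence.
#' @export
detectATSpacers <- function(g, intergenic = NULL, clusters = NULL,
                            min_len = 20L, max_gc = 0.1) {
  stopifnot(is(g, "MitoGenome"))
  seq <- as.character(genomeSeq(g))
  n <- nchar(seq)
  if (is.null(intergenic))
    intergenic <- intergenicRegions(
      g, include = c(GENE_KINDS, "intron", "intergenic_orf", "ori"))
  if (is.null(clusters)) clusters <- detectGCClusters(g)
  ## only clusters holding >= 1 G/C tetranucleotide are excised
  if (nrow(clusters)) {
    has4 <- grepl("[GC]{4}", clusters$sequence)
    clusters <- clusters[has4, , drop = FALSE]
  }
  excl <- .toIRanges(clusters, n, topology(g))
  frags <- IRanges::setdiff(intergenic, excl)
  ## fragments never span two intergenic intervals (setdiff keeps them
  ## inside); score each
  rows <- list()
  for (i in seq_along(frags)) {
    s <- IRanges::start(frags)[i]; e <- IRanges::end(frags)[i]
    len <- e - s + 1L
    if (len <= min_len) next
    sub <- substr(seq, s, e)
    gc <- gcFraction(sub)
    if (gc >= max_gc) next
    rows[[length(rows) + 1L]] <- data.frame(
      genome_id = genomeID(g), start = s, end = e, length = len,
      gc = gc, sequence = sub, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(genome_id = character(), start = integer(),
                      end = integer(), length = integer(), gc = numeric(),
                      sequence = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(out$start), , drop = FALSE]
}

#' (AT+TA)/(AA+TT) dinucleotide ratio of AT spacers
#'
#' Counts overlapping dinucleotides pooled over all spacer sequences
#' (each spacer of length L contributes L-1 dinucleotides; no wrap).
#'
#' @param spacers data.frame from \code{\link{detectATSpacers}} or a
#'   character vector of spacer sequences.
#' @return the ratio, or \code{NA_real_} when the denominator
#'   (AA + TT count) is zero.
#' @export
dinucleotideRatio <- function(spacers) {
  seqs <- if (is.data.frame(spacers)) spacers$sequence
          else as.character(spacers)
  if (!length(seqs)) stop("need at least one spacer")
  counts <- c(AT = 0L, TA = 0L, AA = 0L, TT = 0L)
  for (s in seqs) {
    v <- seqChars(s)
    if (length(v) < 2L) next
    di <- paste0(v[-length(v)], v[-1L])
    for (nm in names(counts)) counts[nm] <- counts[nm] + sum(di == nm)
  }
  den <- counts[["AA"]] + counts[["TT"]]
  if (den == 0L) return(NA_real_)
  (counts[["AT"]] + counts[["TA"]]) / den
}
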