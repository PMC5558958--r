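## Five-part genome partition and size accounting.

.toIRanges <- function(x, n, topology) {
  ## Accept a cluster/spacer data.frame (start, end; end may exceed n on
  ## circular genomes, meaning the element wraps) or an IRanges.
  if (is.null(x)) return(IRanges::IRanges())
  if (is(x, "IRanges")) return(x)
  if (is.data.frame(x)) {
    if (!nrow(x)) return(IRanges::IRanges())
    out <- IRanges::IRanges()
    for (i in seq_len(nrow(x))) {
      s <- x$start[i]; e <- x$end[i]
      if (e > n && topology != "circular")
        stop("interval beyond linear genome end: ", s, "..", e)
      out <- c(out, unwrapInterval(s, min(e, s + n - 1L), n))
    }
    return(out)
  }
  stop("cannot interpret intervals of class ", class(x)[1])
}

#' Build the exclusive five-part partition of a genome
#'
#' Classifies every base pair of a genome into genes, introns or
#' intergenic sequence, and subdivides the intergenic portion into
#' free-standing ORFs, ori elements, GC clusters, AT spacers and
#' residual sequence. Overlaps are resolved by the fixed precedence
#' gene > intron > ORF > ori > GC cluster > AT spacer > residual, so
#' each base pair is counted exactly once and the two accounting
#' identities hold exactly (e.g. a GC cluster nested inside an ori is
#' credited to the ori).
#'
#' @param g a \linkS4class{MitoGenome}; ORF and ori annotations are
#'   taken from its features.
#' @param clusters GC clusters for this genome, as returned by
#'   \code{\link{detectGCClusters}} (or any data.frame with start/end),
#'   or NULL.
#' @param spacers AT spacers, as returned by
#'   \code{\link{detectATSpacers}}, or NULL.
#' @return a \linkS4class{GenomePartition}.
#' @export
buildPartition <- function(g, clusters = NULL, spacers = NULL) {
  stopifnot(is(g, "MitoGenome"))
  n <- genomeLength(g)
  f <- g@features
  kind <- S4Vectors::mcols(f)$kind
  if (!is.null(clusters) && is.data.frame(clusters) && nrow(clusters) &&
      "genome_id" %in% names(clusters) &&
      !all(clusters$genome_id == g@id))
    stop("clusters were computed on a different genome")
  if (!is.null(spacers) && is.data.frame(spacers) && nrow(spacers) &&
      "genome_id" %in% names(spacers) &&
      !all(spacers$genome_id == g@id))
    stop("spacers were computed on a different genome")
  layer <- list(
    genes      = IRanges::reduce(IRanges::ranges(f[kind %in% GENE_KINDS])),
    introns    = IRanges::reduce(IRanges::ranges(f[kind == "intron"])),
    orf        = IRanges::reduce(IRanges::ranges(f[kind == "intergenic_orf"])),
    ori        = IRanges::reduce(IRanges::ranges(f[kind == "ori"])),
    gc_cluster = IRanges::reduce(.toIRanges(clusters, n, g@topology)),
    at_spacer  = IRanges::reduce(.toIRanges(spacers, n, g@topology)))
  remaining <- IRanges::IRanges(1L, n)
  out <- list()
  for (nm in names(layer)) {
    got <- IRanges::intersect(layer[[nm]], remaining)
    out[[nm]] <- got
    remaining <- IRanges::setdiff(remaining, got)
  }
  out$residual <- remaining
  sizes <- vapply(out, function(ir) sum(IRanges::width(ir)), numeric(1))
  part_sizes <- c(genes = sizes[["genes"]], introns = sizes[["introns"]],
                  intergenic = n - sizes[["genes"]] - sizes[["introns"]])
  intergenic_sizes <- c(orf = sizes[["orf"]], ori = sizes[["ori"]],
                        gc_cluster = sizes[["gc_cluster"]],
                        at_spacer = sizes[["at_spacer"]],
                        residual = sizes[["residual"]])
  new("GenomePartition", genome_id = g@id, genome_length = n,
      part_sizes = part_sizes, intergenic_sizes = intergenic_sizes,
      intervals = out)
}

#' Ordinary least-squares summary of genome-size variation
#'
#' Regresses total genome size on a per-genome predictor (intergenic
#' size, GC-cluster count, ...) and reports slope, intercept and
#' R-squared: how much of the size variation the predictor explains.
#'
#' @param predictor numeric vector (one value per genome).
#' @param genome_size numeric vector of total genome sizes.
#' @return list with \code{slope}, \code{intercept}, \code{r_squared}.
#' @export
variationRegression <- function(predictor, genome_size) {
  stopifnot(length(predictor) == length(genome_size))
  if (length(predictor) < 3L)
    stop("need at least 3 genomes for a regression")
  if (stats::var(predictor) == 0)
    stop("zero variance in predictor")
  fit <- lm(genome_size ~ predictor)
  rss <- sum(fit$residuals^2)
  tss <- sum((genome_size - mean(genome_size))^2)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = if (tss == 0) 1 else 1 - rss / tss)
}

#' Fraction of genome-size variation explained by intergenic size
#'
#' @param partitions list of \linkS4class{GenomePartition} objects.
#' @param reference_id optional id of the minimum-intergenic reference
#'   genome; if given, it must be present among the partitions.
#' @return list with \code{slope}, \code{intercept}, \code{r_squared}
#'   plus \code{n} (number of genomes).
#' @export
intergenicVariation <- function(partitions, reference_id = NULL) {
  ids <- vapply(partitions, genomeID, character(1))
  if (!is.null(reference_id) && !reference_id %in% ids)
    stop("reference genome '", reference_id, "' not among partitions")
  inter <- vapply(partitions, function(p) partSizes(p)[["intergenic"]],
                  numeric(1))
  total <- vapply(partitions, genomeLength, numeric(1))
  c(variationRegression(inter, total), list(n = length(ids)))
}

#' Write partition size tables as TSV
#'
#' One row per genome: genome size, genes, introns, intergenic, and the
#' intergenic sub-part sizes.
#'
#' @param partitions list of \linkS4class{GenomePartition}.
#' @param path output TSV path.
#' @return the table, invisibly.
#' @export
writePartitionTSV <- function(partitions, path) {
  tab <- do.call(rbind, lapply(partitions, function(p) {
    ps <- partSizes(p); is_ <- intergenicSizes(p)
    data.frame(genome = genomeID(p), size = genomeLength(p),
               genes = ps[["genes"]], introns = ps[["introns"]],
               intergenic = ps[["intergenic"]], orf = is_[["orf"]],
               ori = is_[["ori"]], gc_cluster = is_[["gc_cluster"]],
               at_spacer = is_[["at_spacer"]],
               residual = is_[["residual"]], stringsAsFactors = FALSE)
  }))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}
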