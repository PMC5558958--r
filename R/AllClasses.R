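## Central S4 containers.
##
## Feature kinds understood by the partition logic. Unknown kinds are
## preserved verbatim on input and fall into the intergenic residual
## during partitioning.
GENE_KINDS <- c("gene_exon", "trna", "rrna", "rnap")
KNOWN_KINDS <- c(GENE_KINDS, "intron", "intergenic_orf", "ori",
                 "gc_cluster", "at_spacer")

#' MitoGenome: an annotated (usually circular) mitochondrial genome
#'
#' Holds one nucleotide sequence together with its feature annotations.
#' Features are stored as a \link[GenomicRanges]{GRanges} with metadata
#' columns \code{feature_id} (grouping multi-interval features such as
#' origin-wrapping genes or multi-exon genes), \code{kind} (e.g.
#' \code{gene_exon}, \code{trna}, \code{rrna}, \code{rnap},
#' \code{intron}, \code{intergenic_orf}, \code{ori}) and
#' \code{gene_name}. Coordinates are 1-based closed, the native R
#' convention; features that wrap the origin of a circular genome are
#' stored as two ranges sharing one \code{feature_id}.
#'
#' @slot id genome identifier.
#' @slot sequence a \link[Biostrings]{DNAString} over A,C,G,T,N.
#' @slot topology \code{"circular"} or \code{"linear"}.
#' @slot features \code{GRanges} of annotations.
#'
#' @seealso \code{\link{readGenome}}, \code{\link{buildPartition}}
#' @export
setClass("MitoGenome",
  representation(id = "character", sequence = "DNAString",
                 topology = "character", features = "GRanges"))

setValidity("MitoGenome", function(object) {
  msg <- character()
  if (length(object@id) != 1L || !nzchar(object@id))
    msg <- c(msg, "id must be a single non-empty string")
  n <- length(object@sequence)
  if (n == 0L)
    msg <- c(msg, "sequence must be non-empty")
  if (!object@topology %in% c("circular", "linear"))
    msg <- c(msg, "topology must be 'circular' or 'linear'")
  f <- object@features
  if (length(f)) {
    req <- c("feature_id", "kind", "gene_name")
    miss <- setdiff(req, colnames(S4Vectors::mcols(f)))
    if (length(miss))
      msg <- c(msg, paste("features lack metadata columns:",
                          paste(miss, collapse = ", ")))
    if (!length(miss)) {
      if (any(GenomicRanges::start(f) < 1L) ||
          any(GenomicRanges::end(f) > n))
        msg <- c(msg, "feature intervals fall outside the sequence")
      ## intervals of one feature must be disjoint
      sp <- split(IRanges::IRanges(GenomicRanges::start(f),
                                   GenomicRanges::end(f)),
                  S4Vectors::mcols(f)$feature_id)
      bad <- vapply(sp, function(ir)
        length(IRanges::reduce(ir)) != length(ir), logical(1))
      if (any(bad))
        msg <- c(msg, paste("overlapping intervals within feature(s):",
                            paste(names(sp)[bad], collapse = ", ")))
    }
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn MitoGenome construct a genome from parts
#' @param id,sequence,topology,features see slots.
#' @export
MitoGenome <- function(id, sequence, topology = c("circular", "linear"),
                       features = NULL) {
  topology <- match.arg(topology)
  if (is.character(sequence)) {
    if (!nzchar(sequence)) stop("empty sequence for genome '", id, "'")
    checkBases(sequence)
    sequence <- Biostrings::DNAString(sequence)
  }
  if (is.null(features)) {
    features <- GenomicRanges::GRanges(seqnames = character(),
      ranges = IRanges::IRanges(), strand = character(),
      feature_id = character(), kind = character(), gene_name = character())
  }
  new("MitoGenome", id = id, sequence = sequence, topology = topology,
      features = features)
}

#' GenomePartition: exclusive cover of a genome into architectural parts
#'
#' Every base pair of the genome is assigned to exactly one of
#' genes / introns / intergenic; the intergenic portion is further split
#' into ORF, ori, GC cluster, AT spacer and residual sub-parts. The two
#' accounting identities (parts sum to genome length; sub-parts sum to
#' the intergenic size) hold exactly, by construction and by validity.
#'
#' @slot genome_id genome identifier.
#' @slot genome_length total length in bp.
#' @slot part_sizes named numeric: genes, introns, intergenic (bp).
#' @slot intergenic_sizes named numeric: orf, ori, gc_cluster,
#'   at_spacer, residual (bp).
#' @slot intervals named list of \code{IRanges}, one per part/sub-part.
#' @export
setClass("GenomePartition",
  representation(genome_id = "character", genome_length = "integer",
                 part_sizes = "numeric", intergenic_sizes = "numeric",
                 intervals = "list"))

setValidity("GenomePartition", function(object) {
  msg <- character()
  ps <- object@part_sizes
  is_ <- object@intergenic_sizes
  if (!identical(sort(names(ps)), sort(c("genes", "introns", "intergenic"))))
    msg <- c(msg, "part_sizes must be named genes/introns/intergenic")
  if (!identical(sort(names(is_)),
                 sort(c("orf", "ori", "gc_cluster", "at_spacer", "residual"))))
    msg <- c(msg, "intergenic_sizes misnamed")
  if (!length(msg)) {
    if (sum(ps) != object@genome_length)
      msg <- c(msg, sprintf("parts sum to %d, genome length is %d",
                            sum(ps), object@genome_length))
    if (sum(is_) != ps[["intergenic"]])
      msg <- c(msg, "intergenic sub-parts do not sum to intergenic size")
  }
  if (length(msg)) msg else TRUE
})

#' GeneOrder: signed circular order of orthologous markers
#'
#' @slot genome_id genome identifier.
#' @slot markers character vector of marker (gene or block) names in
#'   genomic order.
#' @slot signs integer vector of +1/-1 strand signs, parallel to markers.
#' @export
setClass("GeneOrder",
  representation(genome_id = "character", markers = "character",
                 signs = "integer"))

setValidity("GeneOrder", function(object) {
  msg <- character()
  if (length(object@markers) < 2L)
    msg <- c(msg, "a gene order needs at least 2 markers")
  if (anyDuplicated(object@markers))
    msg <- c(msg, "marker names must be unique within a genome")
  if (length(object@signs) != length(object@markers) ||
      !all(object@signs %in% c(-1L, 1L)))
    msg <- c(msg, "signs must be +1/-1 and parallel to markers")
  if (length(msg)) msg else TRUE
})

#' @describeIn GeneOrder construct from marker names and signs
#' @param genome_id,markers,signs see slots. Signs may be given as
#'   \code{"+"}/\code{"-"}.
#' @export
GeneOrder <- function(genome_id, markers, signs = rep(1L, length(markers))) {
  if (is.character(signs)) signs <- ifelse(signs == "-", -1L, 1L)
  new("GeneOrder", genome_id = genome_id,
      markers = as.character(markers), signs = as.integer(signs))
}

#' BranchRateSolution: branch-specific gene-order-loss estimates
#'
#' Result of apportioning pairwise gene-order loss (GOL) to the branches
#' of a phylogeny by (non-negative) least squares. The \code{branches}
#' table mirrors the usual reporting layout: branch label, fitted bsGOL,
#' branch length, rate = bsGOL / length (NA on zero-length branches),
#' and an identifiability flag (FALSE when no leaf pair crosses the
#' branch).
#'
#' @slot branches data.frame with columns branch, bsGOL, branch_length,
#'   rate, identifiable.
#' @slot objective attained value of the least-squares objective.
#' @slot method \code{"nnls"} or \code{"unconstrained"}.
#' @export
setClass("BranchRateSolution",
  representation(branches = "data.frame", objective = "numeric",
                 method = "character"))

setValidity("BranchRateSolution", function(object) {
  msg <- character()
  req <- c("branch", "bsGOL", "branch_length", "rate", "identifiable")
  if (!all(req %in% names(object@branches)))
    msg <- c(msg, "branches table lacks required columns")
  if (object@objective < -1e-9)
    msg <- c(msg, "objective must be non-negative")
  if (length(msg)) msg else TRUE
})
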