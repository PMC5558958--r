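#' Accessors for mitoarch S4 classes
#'
#' @param x a \linkS4class{MitoGenome}, \linkS4class{GenomePartition},
#'   \linkS4class{GeneOrder} or \linkS4class{BranchRateSolution}.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("genomeID", function(x) standardGeneric("genomeID"))
#' @rdname accessors
#' @export
setGeneric("genomeSeq", function(x) standardGeneric("genomeSeq"))
#' @rdname accessors
#' @export
setGeneric("topology", function(x) standardGeneric("topology"))
#' @rdname accessors
#' @export
setGeneric("features", function(x) standardGeneric("features"))
#' @rdname accessors
#' @export
setGeneric("genomeLength", function(x) standardGeneric("genomeLength"))
#' @rdname accessors
#' @export
setGeneric("partSizes", function(x) standardGeneric("partSizes"))
#' @rdname accessors
#' @export
setGeneric("intergenicSizes", function(x) standardGeneric("intergenicSizes"))
#' @rdname accessors
#' @export
setGeneric("partIntervals", function(x) standardGeneric("partIntervals"))
#' @rdname accessors
#' @export
setGeneric("markers", function(x) standardGeneric("markers"))
#' @rdname accessors
#' @export
setGeneric("signs", function(x) standardGeneric("signs"))
#' @rdname accessors
#' @export
setGeneric("branchTable", function(x) standardGeneric("branchTable"))
#' @rdname accessors
#' @export
setGeneric("objectiveValue", function(x) standardGeneric("objectiveValue"))

#' @rdname accessors
#' @export
setMethod("genomeID", "MitoGenome", function(x) x@id)
#' @rdname accessors
#' @export
setMethod("genomeSeq", "MitoGenome", function(x) x@sequence)
#' @rdname accessors
#' @export
setMethod("topology", "MitoGenome", function(x) x@topology)
#' @rdname accessors
#' @export
setMethod("features", "MitoGenome", function(x) x@features)
#' @rdname accessors
#' @export
setMethod("genomeLength", "MitoGenome", function(x) length(x@sequence))

#' @rdname accessors
#' @export
setMethod("genomeID", "GenomePartition", function(x) x@genome_id)
#' @rdname accessors
#' @export
setMethod("genomeLength", "GenomePartition", function(x) x@genome_length)
#' @rdname accessors
#' @export
setMethod("partSizes", "GenomePartition", function(x) x@part_sizes)
#' @rdname accessors
#' @export
setMethod("intergenicSizes", "GenomePartition", function(x) x@intergenic_sizes)
#' @rdname accessors
#' @export
setMethod("partIntervals", "GenomePartition", function(x) x@intervals)

#' @rdname accessors
#' @export
setMethod("genomeID", "GeneOrder", function(x) x@genome_id)
#' @rdname accessors
#' @export
setMethod("markers", "GeneOrder", function(x) x@markers)
#' @rdname accessors
#' @export
setMethod("signs", "GeneOrder", function(x) x@signs)

#' @rdname accessors
#' @export
setMethod("branchTable", "BranchRateSolution", function(x) x@branches)
#' @rdname accessors
#' @export
setMethod("objectiveValue", "BranchRateSolution", function(x) x@objective)

setMethod("show", "MitoGenome", function(object) {
  cat(sprintf("MitoGenome '%s': %d bp, %s, %d feature interval(s)\n",
              object@id, length(object@sequence), object@topology,
              length(object@features)))
  k <- S4Vectors::mcols(object@features)$kind
  if (length(k)) {
    tab <- table(k)
    cat("  kinds:", paste(sprintf("%s=%d", names(tab), tab),
                          collapse = ", "), "\n")
  }
})

setMethod("show", "GenomePartition", function(object) {
  ps <- object@part_sizes
  cat(sprintf("GenomePartition '%s' (%d bp): genes=%d introns=%d intergenic=%d\n",
              object@genome_id, object@genome_length,
              ps[["genes"]], ps[["introns"]], ps[["intergenic"]]))
  is_ <- object@intergenic_sizes
  cat("  intergenic:", paste(sprintf("%s=%d", names(is_), is_),
                             collapse = " "), "\n")
})

setMethod("show", "GeneOrder", function(object) {
  cat(sprintf("GeneOrder '%s' (circular, %d markers):\n",
              object@genome_id, length(object@markers)))
  cat(" ", paste0(ifelse(object@signs < 0, "-", "+"), object@markers,
                  collapse = " "), "\n")
})

setMethod("show", "BranchRateSolution", function(object) {
  cat(sprintf("BranchRateSolution (%s): %d branches, objective L = %.6g\n",
              object@method, nrow(object@branches), object@objective))
})
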