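## Gene-order conservation (GOC/GOL) and DCJ rearrangement distance.

#' Extract the signed gene order of an annotated genome
#'
#' Markers (by default genes: exons, tRNAs, rRNAs, RNase-P RNA) sorted
#' by the start of their first interval along the genome; signs from
#' the annotated strand.
#'
#' @param g a \linkS4class{MitoGenome}.
#' @param kinds feature kinds treated as markers.
#' @return a \linkS4class{GeneOrder}.
#' @export
geneOrderFromGenome <- function(g, kinds = GENE_KINDS) {
  f <- g@features
  f <- f[S4Vectors::mcols(f)$kind %in% kinds]
  if (!length(f)) stop("genome '", genomeID(g), "' has no marker features")
  ## first interval per feature
  df <- data.frame(gene = S4Vectors::mcols(f)$gene_name,
                   fid = S4Vectors::mcols(f)$feature_id,
                   start = GenomicRanges::start(f),
                   strand = as.character(GenomicRanges::strand(f)),
                   stringsAsFactors = FALSE)
  agg <- do.call(rbind, lapply(split(df, df$gene), function(d)
    data.frame(gene = d$gene[1L], start = min(d$start),
               strand = d$strand[1L], stringsAsFactors = FALSE)))
  agg <- agg[order(agg$start), , drop = FALSE]
  GeneOrder(genomeID(g), agg$gene, ifelse(agg$strand == "-", -1L, 1L))
}

## Unordered, sign-blind adjacency set of a circular order restricted
## to a marker subset. Returned as canonical "a|b" strings.
.adjacencies <- function(order, keep = NULL) {
  m <- markers(order)
  if (!is.null(keep)) m <- m[m %in% keep]
  k <- length(m)
  if (k < 2L) stop("fewer than 2 shared markers")
  nxt <- c(m[-1L], m[1L])
  unique(vapply(seq_len(k), function(i)
    paste(sort(c(m[i], nxt[i])), collapse = "|"), character(1)))
}

#' Gene order conservation between two genomes
#'
#' GOC = number of orthologue adjacencies shared between the two
#' circular orders divided by the number of shared orthologues, after
#' restricting both orders to their common marker set. Adjacencies are
#' unordered neighbour pairs, blind to strand sign. GOL = 1 - GOC.
#'
#' @param a,b \linkS4class{GeneOrder} objects.
#' @return list with goc, gol, n_orthologues, n_contiguous.
#' @export
goc <- function(a, b) {
  shared <- intersect(markers(a), markers(b))
  if (length(shared) < 2L) stop("fewer than 2 shared markers")
  aa <- .adjacencies(a, shared)
  ab <- .adjacencies(b, shared)
  n_contig <- length(intersect(aa, ab))
  list(goc = n_contig / length(shared), gol = 1 - n_contig / length(shared),
       n_orthologues = length(shared), n_contiguous = n_contig)
}

#' Pairwise GOC/GOL matrices for a set of genomes
#'
#' @param orders list of \linkS4class{GeneOrder} objects.
#' @return list with symmetric matrices \code{goc} (unit diagonal) and
#'   \code{gol} (= 1 - goc), dimnames = genome ids.
#' @export
gocMatrix <- function(orders) {
  ids <- vapply(orders, genomeID, character(1))
  if (anyDuplicated(ids)) stop("duplicate genome ids")
  k <- length(orders)
  G <- matrix(1, k, k, dimnames = list(ids, ids))
  if (k > 1L) for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    G[i, j] <- G[j, i] <- goc(orders[[i]], orders[[j]])$goc
  }
  list(goc = G, gol = 1 - G)
}

## Signed-extremity adjacency set of a circular order: each marker m
## has a tail (m_t) and head (m_h); reading left to right, +m runs
## tail->head. Adjacencies pair the right extremity of each marker
## with the left extremity of its successor.
.extremityAdjacencies <- function(order) {
  m <- markers(order); s <- signs(order)
  right <- ifelse(s > 0, paste0(m, "_h"), paste0(m, "_t"))
  left <- ifelse(s > 0, paste0(m, "_t"), paste0(m, "_h"))
  k <- length(m)
  lapply(seq_len(k), function(i)
    sort(c(right[i], left[if (i == k) 1L else i + 1L])))
}

#' DCJ distance between two signed circular gene orders
#'
#' Minimal number of double-cut-and-join operations transforming one
#' single circular chromosome into the other, computed from the
#' adjacency graph: d = N - C, with N markers and C cycles in the
#' union of the two adjacency matchings.
#'
#' @param a,b \linkS4class{GeneOrder} objects over the same marker set.
#' @return integer distance.
#' @export
dcjDistance <- function(a, b) {
  if (!setequal(markers(a), markers(b)))
    stop("marker sets differ between the two genomes")
  N <- length(markers(a))
  adjA <- .extremityAdjacencies(a)
  adjB <- .extremityAdjacencies(b)
  ## walk cycles in the union of the two perfect matchings
  mateOf <- function(adj) {
    env <- new.env(parent = emptyenv())
    for (p in adj) { assign(p[1L], p[2L], env); assign(p[2L], p[1L], env) }
    env
  }
  mA <- mateOf(adjA); mB <- mateOf(adjB)
  verts <- unlist(lapply(adjA, identity))
  visited <- new.env(parent = emptyenv())
  cycles <- 0L
  for (v in verts) {
    if (!is.null(visited[[v]])) next
    cycles <- cycles + 1L
    cur <- v
    repeat {  # alternate one A edge and one B edge per step
      visited[[cur]] <- TRUE
      nxt <- mA[[cur]]
      visited[[nxt]] <- TRUE
      cur <- mB[[nxt]]
      if (cur == v) break
    }
  }
  as.integer(N - cycles)
}

#' Write gene orders as TSV
#'
#' One row per marker: genome, position, marker, strand.
#'
#' @param orders list of \linkS4class{GeneOrder}.
#' @param path output path.
#' @return the table, invisibly.
#' @export
writeGeneOrderTSV <- function(orders, path) {
  tab <- do.call(rbind, lapply(orders, function(o)
    data.frame(genome = genomeID(o), position = seq_along(markers(o)),
               marker = markers(o),
               strand = ifelse(signs(o) < 0, "-", "+"),
               stringsAsFactors = FALSE)))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}

#' Read gene orders from TSV
#'
#' @param path TSV with columns genome, position, marker, strand.
#' @return list of \linkS4class{GeneOrder}.
#' @export
readGeneOrderTSV <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  lapply(split(tab, tab$genome), function(d) {
    d <- d[order(d$position), , drop = FALSE]
    GeneOrder(d$genome[1L], d$marker, d$strand)
  })
}
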