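## Branch-specific gene-order loss: design matrix over tree branches
## and (non-negative) least-squares apportionment of pairwise GOL.

.asPhylo <- function(tree) {
  if (is(tree, "phylo")) return(tree)
  if (is.character(tree) && length(tree) == 1L) {
    if (file.exists(tree)) return(ape::read.tree(tree))
    return(ape::read.tree(text = tree))
  }
  stop("tree must be a phylo object, a Newick string or a file path")
}

## Unroot with a guard: trees with fewer than 2 leaves are rejected,
## 2-leaf trees are left as read (ape cannot unroot them).
.unrootSafe <- function(tr) {
  if (length(tr$tip.label) < 2L) stop("tree must have at least 2 leaves")
  if (length(tr$tip.label) == 2L) return(tr)
  ape::unroot(tr)
}

#' Stable labels for the branches of an unrooted tree
#'
#' A branch leading to a leaf is labelled with the leaf name; internal
#' branches are labelled \code{e<child node number>} in ape's edge
#' ordering of the unrooted tree.
#'
#' @param tree a phylo object (will be unrooted).
#' @return character vector, one label per edge of the unrooted tree.
#' @export
branchLabels <- function(tree) {
  tr <- .unrootSafe(.asPhylo(tree))
  child <- tr$edge[, 2L]
  ifelse(child <= length(tr$tip.label), tr$tip.label[child],
         paste0("e", child))
}

#' Pair-by-branch design matrix of a phylogeny
#'
#' Boolean matrix with one row per unordered leaf pair and one column
#' per branch of the unrooted tree; entry 1 iff the branch lies on the
#' path between the two leaves. For n leaves on an unrooted binary
#' tree this is choose(n, 2) rows by 2n - 3 columns (105 x 27 for 15
#' taxa).
#'
#' @param tree a phylo object, Newick string or file.
#' @return 0/1 matrix with rownames "A|B" and colnames from
#'   \code{\link{branchLabels}}; branch lengths attached as attribute
#'   \code{branch_lengths}.
#' @export
buildDesignMatrix <- function(tree) {
  tr <- .unrootSafe(.asPhylo(tree))
  tips <- tr$tip.label
  if (anyDuplicated(tips)) stop("duplicate leaf labels")
  n <- length(tips)
  B <- nrow(tr$edge)
  labels <- branchLabels(tr)
  ## edge lookup keyed by unordered node pair
  ekey <- paste(pmin(tr$edge[, 1L], tr$edge[, 2L]),
                pmax(tr$edge[, 1L], tr$edge[, 2L]))
  pairs <- combn(n, 2L)
  M <- matrix(0L, ncol(pairs), B,
              dimnames = list(paste(tips[pairs[1L, ]], tips[pairs[2L, ]],
                                    sep = "|"), labels))
  for (p in seq_len(ncol(pairs))) {
    path <- ape::nodepath(tr, pairs[1L, p], pairs[2L, p])
    k <- paste(pmin(path[-length(path)], path[-1L]),
               pmax(path[-length(path)], path[-1L]))
    M[p, match(k, ekey)] <- 1L
  }
  attr(M, "branch_lengths") <- setNames(
    if (is.null(tr$edge.length)) rep(NA_real_, B) else tr$edge.length,
    labels)
  M
}

#' Solve for branch-specific GOL by (non-negative) least squares
#'
#' Minimises L = sum_i (sum_j b_ij x_j - GOL_i)^2 over branch values
#' x_j, by default under x >= 0 (negative per-branch gene-order loss
#' is meaningless); \code{method = "unconstrained"} returns the
#' minimum-norm unconstrained solution for comparison. Branch rates
#' are x_j divided by branch length, NA (flagged) on zero-length
#' branches; branches crossed by no pair (all-zero design column) are
#' flagged unidentifiable and assigned 0.
#'
#' @param design 0/1 matrix from \code{\link{buildDesignMatrix}}.
#' @param gol numeric vector of pairwise GOL values in [0, 1], in
#'   design row order (a named vector or the \code{gol} matrix of
#'   \code{\link{gocMatrix}} is matched by row name).
#' @param branch_lengths per-branch lengths (default: taken from the
#'   design matrix attribute).
#' @param method \code{"nnls"} (default) or \code{"unconstrained"}.
#' @return a \linkS4class{BranchRateSolution}.
#' @export
solveBsgol <- function(design, gol,
                       branch_lengths = attr(design, "branch_lengths"),
                       method = c("nnls", "unconstrained")) {
  method <- match.arg(method)
  if (is.matrix(gol)) {
    ids <- strsplit(rownames(design), "|", fixed = TRUE)
    gol <- vapply(ids, function(p) gol[p[1L], p[2L]], numeric(1))
  } else if (!is.null(names(gol))) {
    gol <- gol[rownames(design)]
  }
  if (length(gol) != nrow(design))
    stop("gol length does not match design rows")
  if (any(is.na(gol)) || any(gol < -1e-12) || any(gol > 1 + 1e-12))
    stop("GOL values must lie in [0, 1]")
  D <- unname(as.matrix(design))
  ident <- colSums(D) > 0L
  x <- numeric(ncol(D))
  if (method == "nnls") {
    fit <- pracma::lsqnonneg(D[, ident, drop = FALSE], as.numeric(gol))
    x[ident] <- fit$x
  } else {
    x[ident] <- as.numeric(MASS::ginv(D[, ident, drop = FALSE]) %*% gol)
  }
  L <- sum((D %*% x - gol)^2)
  if (is.null(branch_lengths)) branch_lengths <- rep(NA_real_, ncol(D))
  rate <- ifelse(!is.na(branch_lengths) & branch_lengths > 0,
                 x / branch_lengths, NA_real_)
  tab <- data.frame(branch = colnames(design), bsGOL = x,
                    branch_length = as.numeric(branch_lengths),
                    rate = rate, identifiable = ident,
                    stringsAsFactors = FALSE, row.names = NULL)
  new("BranchRateSolution", branches = tab, objective = L, method = method)
}

#' End-to-end branch-rate estimation from gene orders and a tree
#'
#' Computes all pairwise GOL values among the given gene orders,
#' builds the design matrix of the tree, and solves for branch-specific
#' GOL.
#'
#' @param orders list of \linkS4class{GeneOrder}, ids matching the
#'   tree's leaf labels.
#' @param tree phylo object, Newick string or file.
#' @param method passed to \code{\link{solveBsgol}}.
#' @return a \linkS4class{BranchRateSolution}.
#' @export
bsgolFromOrders <- function(orders, tree, method = "nnls") {
  M <- buildDesignMatrix(tree)
  gm <- gocMatrix(orders)
  solveBsgol(M, gm$gol, method = method)
}

#' Write a branch-rate table as TSV
#'
#' Columns Branch, bsGOL, Branch_Length, Rate (the usual reporting
#' layout for branch-specific rearrangement rates).
#'
#' @param solution a \linkS4class{BranchRateSolution}.
#' @param path output path.
#' @return the table, invisibly.
#' @export
writeBsgolTSV <- function(solution, path) {
  tab <- branchTable(solution)
  out <- data.frame(Branch = tab$branch, bsGOL = tab$bsGOL,
                    Branch_Length = tab$branch_length, Rate = tab$rate,
                    Identifiable = tab$identifiable)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
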