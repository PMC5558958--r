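## Grouping GC clusters into families with consensus sequences.
##
## Five-step procedure: (1) pool every cluster with its reverse
## complement; (2) all-vs-all global-alignment distances (1 - conserved
## identity) and a UPGMA tree; (3) cut the tree into groups at a fixed
## height, dropping a reverse-complement entry whenever its forward
## mate sits in the same group; (4) greedy retention of groups in
## decreasing size order, discarding a group once more than
## `overlap_cutoff` of its member clusters already belong to retained
## groups; (5) per-group column-majority consensus.

.alignmentDistance <- function(seqs) {
  m <- length(seqs)
  D <- matrix(0, m, m, dimnames = list(names(seqs), names(seqs)))
  if (m < 2L) return(D)
  letters_ <- sort(unique(unlist(strsplit(unlist(seqs), "", fixed = TRUE))))
  mat <- matrix(-1, length(letters_), length(letters_),
                dimnames = list(letters_, letters_))
  diag(mat) <- 1
  pool <- Biostrings::BStringSet(unlist(seqs))
  for (i in seq_len(m - 1L)) {
    ## one vectorised NW call per subject against all later patterns;
    ## identity = matching columns / alignment length (nmatch / nchar)
    al <- Biostrings::pairwiseAlignment(pool[(i + 1L):m], pool[[i]],
                                        type = "global",
                                        substitutionMatrix = mat,
                                        gapOpening = 0, gapExtension = 2)
    ids <- Biostrings::nmatch(al) / Biostrings::nchar(al)
    D[i, (i + 1L):m] <- D[(i + 1L):m, i] <- 1 - ids
  }
  D
}

## Center-star alignment of a group: every member is pairwise-aligned
## to the longest member, and member residues are stacked on the
## reference columns (insertions relative to the reference are
## dropped). Deterministic.
.starColumns <- function(seqs) {
  ref_i <- order(-nchar(seqs), seqs)[1L]
  ref <- seqs[[ref_i]]
  L <- nchar(ref)
  M <- matrix("-", nrow = length(seqs), ncol = L)
  for (k in seq_along(seqs)) {
    if (k == ref_i) { M[k, ] <- strsplit(ref, "")[[1L]]; next }
    al <- nwAlign(ref, seqs[[k]])
    ra <- strsplit(al[["a"]], "")[[1L]]
    sa <- strsplit(al[["b"]], "")[[1L]]
    pos <- cumsum(ra != "-")
    keep <- ra != "-"
    M[k, pos[keep]] <- sa[keep]
  }
  M
}

.majorityConsensus <- function(M) {
  cons <- apply(M, 2L, function(col) {
    tab <- sort(table(col), decreasing = TRUE)
    cands <- names(tab)[tab == max(tab)]
    sort(cands)[1L]  # ties broken alphabetically ('-' sorts first)
  })
  paste(cons[cons != "-"], collapse = "")
}

#' Group GC clusters into consensus families
#'
#' Clusters and their reverse complements are pooled, compared
#' all-vs-all by global alignment, clustered by UPGMA, and cut into
#' groups at distance \code{1 - identity_cutoff}; reverse-complement
#' entries co-occurring with their forward mate are dropped, groups are
#' retained greedily by decreasing size subject to the overlap rule,
#' and each family receives a column-majority consensus.
#'
#' @param clusters data.frame as from \code{\link{detectGCClusters}};
#'   row names or a \code{cluster_id} column identify members.
#' @param identity_cutoff alignment identity at which two clusters can
#'   share a family (default 0.6, i.e. UPGMA cut height 0.4).
#' @param overlap_cutoff discard a group when more than this fraction
#'   of its members already belong to retained groups (default 0.8).
#' @return list with \code{families} (family_id, size, consensus,
#'   consensus_rc) and \code{members} (family_id, cluster_id,
#'   orientation).
#' @export
groupGCClusters <- function(clusters, identity_cutoff = 0.6,
                            overlap_cutoff = 0.8) {
  if (identity_cutoff <= 0 || identity_cutoff >= 1)
    stop("identity_cutoff must lie in (0, 1)")
  if (is.data.frame(clusters)) {
    seqs <- clusters$sequence
    ids <- if ("cluster_id" %in% names(clusters)) clusters$cluster_id
           else sprintf("c%03d", seq_len(nrow(clusters)))
  } else {
    seqs <- as.character(clusters)
    ids <- if (!is.null(names(clusters))) names(clusters)
           else sprintf("c%03d", seq_along(clusters))
  }
  if (!length(seqs)) stop("no clusters to group")
  pool <- c(setNames(seqs, paste0(ids, "|F")),
            setNames(vapply(seqs, revComp, character(1), USE.NAMES = FALSE),
                     paste0(ids, "|R")))
  D <- .alignmentDistance(as.list(pool))
  if (length(pool) > 1L) {
    hc <- hclust(as.dist(D), method = "average")  # UPGMA
    grp <- cutree(hc, h = 1 - identity_cutoff)
  } else {
    grp <- setNames(1L, names(pool))
  }
  groups <- split(names(grp), grp)
  ## drop an RC entry when its forward mate shares the group
  groups <- lapply(groups, function(members) {
    base <- sub("\\|[FR]$", "", members)
    isR <- grepl("\\|R$", members)
    drop <- isR & base %in% base[!isR]
    members[!drop]
  })
  ## greedy retention, decreasing size, deterministic tie-break
  sizes <- vapply(groups, length, integer(1))
  first_member <- vapply(groups, function(m) sort(m)[1L], character(1))
  ord <- order(-sizes, first_member)
  retained <- list()
  seen <- character()
  for (gi in ord) {
    members <- groups[[gi]]
    base <- unique(sub("\\|[FR]$", "", members))
    if (length(seen) &&
        length(intersect(base, seen)) / length(base) > overlap_cutoff)
      next
    retained[[length(retained) + 1L]] <- members
    seen <- union(seen, base)
  }
  fam_rows <- list(); mem_rows <- list()
  for (k in seq_along(retained)) {
    members <- sort(retained[[k]])
    fam <- sprintf("F%02d", k)
    gseqs <- pool[members]
    cons <- if (length(gseqs) == 1L) unname(gseqs[[1L]])
            else .majorityConsensus(.starColumns(gseqs))
    fam_rows[[k]] <- data.frame(family_id = fam, size = length(members),
                                consensus = cons,
                                consensus_rc = revComp(cons),
                                stringsAsFactors = FALSE)
    mem_rows[[k]] <- data.frame(family_id = fam,
                                cluster_id = sub("\\|[FR]$", "", members),
                                orientation = ifelse(grepl("\\|R$", members),
                                                     "R", "F"),
                                stringsAsFactors = FALSE)
  }
  list(families = do.call(rbind, fam_rows),
       members = do.call(rbind, mem_rows))
}

#' Is a GC cluster palindromic-like?
#'
#' True iff the global-alignment identity between the cluster sequence
#' and its own reverse complement reaches \code{threshold}. A perfect
#' DNA palindrome scores 1.
#'
#' @param x cluster sequence (string) or a one-row cluster data.frame.
#' @param threshold identity cutoff (default 0.8).
#' @return logical.
#' @export
isPalindromicLike <- function(x, threshold = 0.8) {
  seq <- if (is.data.frame(x)) x$sequence[1L] else as.character(x)
  if (nchar(seq) < 8L) stop("cluster length must be >= 8")
  pairwiseIdentity(seq, revComp(seq), mode = "global") >= threshold
}

#' Main (large) families
#'
#' Size filter used when reporting family tables: only families with at
#' least \code{min_size} members.
#'
#' @param families result of \code{\link{groupGCClusters}}.
#' @param min_size minimum member count (default 8).
#' @return the filtered \code{families} data.frame.
#' @export
mainFamilies <- function(families, min_size = 8L) {
  fam <- families$families
  fam[fam$size >= min_size, , drop = FALSE]
}
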