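## Two-pass GC-cluster detection.
##
## A position is covered in a pass iff it lies inside at least one
## window satisfying that pass's (minimum length, minimum GC) rule;
## clusters are maximal covered runs. This "coverage" definition is
## unambiguous and directly checkable against an exhaustive
## all-substrings oracle. Pass 1 (length >= 16, GC >= 0.75) clusters
## are masked before pass 2 (length >= 8, GC >= 0.85), whose windows
## may abut but not cross masked positions. Finally clusters from both
## passes separated by a gap of less than `join_gap` bp are joined
## transitively. Circular genomes are scanned on the doubled sequence
## with window length capped at the genome length.

## Coverage of a 0/1 GC indicator vector by qualifying windows.
## Exact integer arithmetic: a window [i, j] qualifies iff
## q * gc(i, j) - p * len >= 0 where mingc = p/q. Implemented with a
## sparse-table range-maximum over prefix scores and a vectorised
## binary search for, per window start, the furthest qualifying end.
.windowCoverage <- function(gc, minlen, mingc, maxlen = length(gc)) {
  m <- length(gc)
  covered <- logical(m)
  if (m < minlen) return(covered)
  maxlen <- min(maxlen, m)
  if (maxlen < minlen) return(covered)
  pq <- asRational(mingc)
  P <- pq[["q"]] * c(0, cumsum(gc)) - pq[["p"]] * (0:m)  # P[k+1] = score S_k
  ## sparse table: Tlist[[k]][i] = max P[i .. i + 2^(k-1) - 1]
  K <- floor(log2(m + 1))
  Tlist <- vector("list", K + 1L)
  Tlist[[1L]] <- P
  half <- 1L
  for (k in seq_len(K)) {
    prev <- Tlist[[k]]
    np <- length(prev) - half
    Tlist[[k + 1L]] <- pmax(prev[seq_len(np)], prev[seq_len(np) + half])
    half <- half * 2L
  }
  rmq <- function(x, y) {  # max P[x..y] elementwise over vectors x <= y
    k <- floor(log2(y - x + 1))
    w <- 2L^k
    ## group by k to index the right table level
    out <- numeric(length(x))
    for (kk in unique(k)) {
      sel <- k == kk
      tab <- Tlist[[kk + 1L]]
      out[sel] <- pmax(tab[x[sel]], tab[y[sel] - w[sel] + 1L])
    }
    out
  }
  a <- 0:(m - minlen)                    # window start offsets (S index)
  lo <- a + minlen
  hi <- pmin(a + maxlen, m)
  Pa <- P[a + 1L]
  ex <- rmq(lo + 1L, hi + 1L) >= Pa
  if (!any(ex)) return(covered)
  a <- a[ex]; lo <- lo[ex]; hi <- hi[ex]; Pa <- Pa[ex]
  ## furthest end b in [lo, hi] with P[b+1] >= Pa (it exists)
  l <- lo; h <- hi
  while (any(l < h)) {
    mid <- (l + h + 1L) %/% 2L
    ok <- rmq(mid + 1L, h + 1L) >= Pa
    l <- ifelse(ok, mid, l)
    h <- ifelse(ok, h, mid - 1L)
  }
  ir <- IRanges::reduce(IRanges::IRanges(a + 1L, l))
  for (i in seq_along(ir))
    covered[IRanges::start(ir)[i]:IRanges::end(ir)[i]] <- TRUE
  covered
}

## Maximal TRUE runs on a circle; a run spanning the origin is returned
## with end > n (end - n on the circle).
.circularRuns <- function(covered) {
  n <- length(covered)
  if (!any(covered)) return(data.frame(start = integer(), end = integer()))
  if (all(covered)) return(data.frame(start = 1L, end = n))
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  if (covered[1L] && covered[n] && nrow(runs) > 1L) {
    ## fuse the first and last run across the origin
    runs$end[nrow(runs)] <- runs$end[1L] + n
    runs <- runs[-1L, , drop = FALSE]
  }
  rownames(runs) <- NULL
  runs
}

#' Detect GC clusters in an AT-rich genome
#'
#' Two-pass sliding-coverage detection of GC-rich elements: pass 1
#' marks every position lying in a window of length at least
#' \code{min_len1} with GC fraction at least \code{min_gc1}; pass 2
#' rescans the unmasked remainder with the stricter, shorter rule
#' (\code{min_len2}/\code{min_gc2}), never crossing pass-1 clusters;
#' clusters from both passes closer than \code{join_gap} bp are then
#' joined transitively. N bases count as non-GC. On circular genomes
#' windows may wrap the origin (cluster length capped at the genome
#' length); a wrapping cluster is reported with \code{end} greater than
#' the genome length.
#'
#' @param x a \linkS4class{MitoGenome} or a nucleotide string.
#' @param topology used when \code{x} is a string.
#' @param min_len1,min_gc1 pass-1 window rule (default 16 bp, 0.75).
#' @param min_len2,min_gc2 pass-2 window rule (default 8 bp, 0.85).
#' @param join_gap clusters separated by fewer than this many bp are
#'   joined (default 10, i.e. gaps of up to 9 bp close).
#' @return data.frame with columns genome_id, start, end, length, pass
#'   (\code{pass1}, \code{pass2} or \code{joined}), gc, sequence,
#'   sorted by start.
#' @export
detectGCClusters <- function(x, topology = c("circular", "linear"),
                             min_len1 = 16L, min_gc1 = 0.75,
                             min_len2 = 8L, min_gc2 = 0.85,
                             join_gap = 10L) {
  if (is(x, "MitoGenome")) {
    seq <- as.character(genomeSeq(x)); topology <- topology(x)
    gid <- genomeID(x)
  } else {
    topology <- match.arg(topology)
    seq <- toupper(as.character(x)); gid <- "seq"
  }
  empty <- data.frame(genome_id = character(), start = integer(),
                      end = integer(), length = integer(),
                      pass = character(), gc = numeric(),
                      sequence = character(), stringsAsFactors = FALSE)
  n <- nchar(seq)
  if (n == 0L) return(empty)
  v <- checkBases(seq)
  gc <- as.integer(v == "G" | v == "C")
  circular <- topology == "circular"
  coverPass <- function(gcvec, minlen, mingc) {
    if (circular) {
      cd <- .windowCoverage(c(gcvec, gcvec), minlen, mingc, maxlen = n)
      cd[seq_len(n)] | cd[n + seq_len(n)]
    } else {
      .windowCoverage(gcvec, minlen, mingc)
    }
  }
  cov1 <- coverPass(gc, min_len1, min_gc1)
  ## pass 2 on unmasked stretches; windows may not cross masked bases
  cov2 <- logical(n)
  if (!any(cov1)) {
    cov2 <- coverPass(gc, min_len2, min_gc2)
  } else if (!all(cov1)) {
    free <- if (circular) .circularRuns(!cov1) else .linearRuns(!cov1)
    for (i in seq_len(nrow(free))) {
      s <- free$start[i]; e <- free$end[i]
      idx <- ((s:e) - 1L) %% n + 1L
      cv <- .windowCoverage(gc[idx], min_len2, min_gc2)
      cov2[idx[cv]] <- TRUE
    }
  }
  runs1 <- if (circular) .circularRuns(cov1) else .linearRuns(cov1)
  runs2 <- if (circular) .circularRuns(cov2) else .linearRuns(cov2)
  if (nrow(runs1)) runs1$pass <- "pass1"
  if (nrow(runs2)) runs2$pass <- "pass2"
  cl <- rbind(runs1, runs2)
  if (!nrow(cl)) return(empty)
  cl <- cl[order(cl$start, cl$end), , drop = FALSE]
  cl <- .joinClusters(cl, n, circular, join_gap)
  cl$length <- cl$end - cl$start + 1L
  cl$sequence <- vapply(seq_len(nrow(cl)), function(i)
    circularSubseq(seq, cl$start[i], cl$end[i]), character(1))
  cl$gc <- vapply(cl$sequence, gcFraction, numeric(1), USE.NAMES = FALSE)
  cl$genome_id <- gid
  rownames(cl) <- NULL
  cl[, c("genome_id", "start", "end", "length", "pass", "gc", "sequence")]
}

.linearRuns <- function(covered) {
  if (!any(covered)) return(data.frame(start = integer(), end = integer()))
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

## Transitive joining of clusters whose gap is < join_gap bp; on
## circular genomes the wrap gap between the last and first cluster is
## also considered. Input sorted by start; wrap clusters have end > n.
.joinClusters <- function(cl, n, circular, join_gap) {
  if (nrow(cl) <= 1L) return(cl)
  out <- cl[1L, , drop = FALSE]
  for (i in 2L:nrow(cl)) {
    last <- nrow(out)
    gap <- cl$start[i] - out$end[last] - 1L
    if (gap < join_gap) {
      if (cl$end[i] > out$end[last]) out$end[last] <- cl$end[i]
      if (out$pass[last] != cl$pass[i]) out$pass[last] <- "joined"
      else if (gap >= 0L) out$pass[last] <- "joined"
    } else {
      out <- rbind(out, cl[i, , drop = FALSE])
    }
  }
  if (circular && nrow(out) > 1L) {
    ## wrap gap: from last cluster's on-circle end to first cluster start
    repeat {
      m <- nrow(out)
      gap <- out$start[1L] + n - out$end[m] - 1L
      if (gap >= join_gap || m == 1L) break
      out$end[m] <- out$end[1L] + n
      out$pass[m] <- "joined"
      out <- out[-1L, , drop = FALSE]
      if (out$end[nrow(out)] - out$start[nrow(out)] + 1L >= n) {
        out$end[nrow(out)] <- out$start[nrow(out)] + n - 1L
        break
      }
    }
  }
  rownames(out) <- NULL
  out
}
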