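## Independent brute-force oracles used to validate the fast
## implementations, plus shared fixtures.

## --- exhaustive GC-cluster oracle ------------------------------------
## Marks every position lying in any qualifying substring (enumerated
## directly), pass by pass, then joins naively.
oracleCover <- function(gc, minlen, mingc, circular) {
  n <- length(gc)
  vec <- if (circular) c(gc, gc) else gc
  m <- length(vec)
  cov <- rep(FALSE, m)
  cs <- c(0, cumsum(vec))
  cap <- if (circular) n else m
  for (i in seq_len(m)) {
    maxj <- min(m, i + cap - 1L)
    if (maxj - i + 1L < minlen) next
    js <- i:maxj
    len <- js - i + 1L
    ok <- len >= minlen & (cs[js + 1L] - cs[i]) >= mingc * len - 1e-9
    if (any(ok)) cov[i:max(js[ok])] <- TRUE
  }
  if (circular) cov[seq_len(n)] | cov[n + seq_len(n)] else cov
}

oracleRuns <- function(cov, circular) {
  n <- length(cov)
  if (!any(cov)) return(data.frame(start = integer(), end = integer()))
  if (all(cov)) return(data.frame(start = 1L, end = n))
  r <- rle(cov)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  if (circular && cov[1L] && cov[n] && nrow(runs) > 1L) {
    runs$end[nrow(runs)] <- runs$end[1L] + n
    runs <- runs[-1L, , drop = FALSE]
  }
  runs
}

oracleJoin <- function(runs, n, circular, gap = 10L) {
  runs <- runs[order(runs$start), , drop = FALSE]
  repeat {
    if (nrow(runs) <= 1L) break
    merged <- FALSE
    for (i in seq_len(nrow(runs) - 1L)) {
      g <- runs$start[i + 1L] - runs$end[i] - 1L
      if (g < gap) {
        runs$end[i] <- max(runs$end[i], runs$end[i + 1L])
        runs <- runs[-(i + 1L), , drop = FALSE]
        merged <- TRUE
        break
      }
    }
    if (!merged && circular && nrow(runs) > 1L) {
      g <- runs$start[1L] + n - runs$end[nrow(runs)] - 1L
      if (g < gap) {
        runs$end[nrow(runs)] <- runs$end[1L] + n
        runs <- runs[-1L, , drop = FALSE]
        if (runs$end[nrow(runs)] - runs$start[nrow(runs)] + 1L >= n)
          runs$end[nrow(runs)] <- runs$start[nrow(runs)] + n - 1L
        merged <- TRUE
      }
    }
    if (!merged) break
  }
  rownames(runs) <- NULL
  runs
}

## Full two-pass + join oracle; returns intervals sorted by start.
oracleClusters <- function(seq, topology = "circular",
                           min_len1 = 16L, min_gc1 = 0.75,
                           min_len2 = 8L, min_gc2 = 0.85,
                           join_gap = 10L) {
  v <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  gc <- as.integer(v %in% c("G", "C"))
  n <- length(gc)
  circular <- topology == "circular"
  cov1 <- oracleCover(gc, min_len1, min_gc1, circular)
  cov2 <- rep(FALSE, n)
  if (!any(cov1)) {
    cov2 <- oracleCover(gc, min_len2, min_gc2, circular)
  } else if (!all(cov1)) {
    free <- oracleRuns(!cov1, circular)
    for (i in seq_len(nrow(free))) {
      idx <- ((free$start[i]:free$end[i]) - 1L) %% n + 1L
      cv <- oracleCover(gc[idx], min_len2, min_gc2, circular = FALSE)
      cov2[idx[cv]] <- TRUE
    }
  }
  runs <- rbind(oracleRuns(cov1, circular), oracleRuns(cov2, circular))
  if (!nrow(runs)) return(runs)
  oracleJoin(runs, n, circular, join_gap)
}

randomSeq <- function(n, gc = 0.4) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

## --- exhaustive DCJ oracle -------------------------------------------
## Genomes as adjacency sets over marker extremities; a DCJ operation
## recombines two adjacencies; BFS gives exact minimal distances.
adjKey <- function(adj) {
  paste(sort(vapply(adj, function(p) paste(sort(p), collapse = ","),
                    character(1))), collapse = ";")
}

adjFromOrder <- function(markers, sg) {
  k <- length(markers)
  right <- ifelse(sg > 0, paste0(markers, "_h"), paste0(markers, "_t"))
  left <- ifelse(sg > 0, paste0(markers, "_t"), paste0(markers, "_h"))
  lapply(seq_len(k), function(i)
    c(right[i], left[if (i == k) 1L else i + 1L]))
}

dcjNeighbors <- function(adj) {
  out <- list()
  k <- length(adj)
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    a <- adj[[i]]; b <- adj[[j]]
    rest <- adj[-c(i, j)]
    out[[length(out) + 1L]] <- c(rest, list(c(a[1], b[1]), c(a[2], b[2])))
    out[[length(out) + 1L]] <- c(rest, list(c(a[1], b[2]), c(a[2], b[1])))
  }
  out
}

dcjBFS <- function(adj_from) {
  dist <- new.env(parent = emptyenv())
  assign(adjKey(adj_from), 0L, dist)
  frontier <- list(adj_from)
  d <- 0L
  while (length(frontier)) {
    d <- d + 1L
    nxt <- list()
    for (st in frontier) {
      for (nb in dcjNeighbors(st)) {
        k <- adjKey(nb)
        if (is.null(dist[[k]])) {
          dist[[k]] <- d
          nxt[[length(nxt) + 1L]] <- nb
        }
      }
    }
    frontier <- nxt
  }
  dist
}

## All signed circular orders of n markers, canonicalised by fixing
## marker 1 first with positive sign.
allSignedOrders <- function(n) {
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  out <- list()
  for (p in perms(2:n)) {
    for (s in 0:(2^(n - 1L) - 1L)) {
      sg <- c(1L, ifelse(bitwAnd(s, 2^(0:(n - 2L))) > 0, -1L, 1L))
      out[[length(out) + 1L]] <- list(markers = as.character(c(1L, p)),
                                      signs = sg)
    }
  }
  out
}

## --- hypergeometric tail by enumeration ------------------------------
oracleHyperTail <- function(k, K, N, n) {
  ## P(X >= k) for X = #successes when drawing n of N with K successes
  total <- choose(N, n)
  sum(vapply(k:min(K, n), function(x)
    choose(K, x) * choose(N - K, n - x), numeric(1))) / total
}

## --- shared simulation fixture ---------------------------------------
.fixture_env <- new.env(parent = emptyenv())
sharedSim <- function() {
  if (is.null(.fixture_env$sim))
    .fixture_env$sim <- simulateGenomes(simConfig(seed = 42L))
  .fixture_env$sim
}

## Small annotated genome built by hand: 1000 bp circular, one 600 bp
## gene; sequences deterministic.
tinyGenome <- function(id = "tiny", n = 1000L, gene_at = c(101L, 700L)) {
  set.seed(99)
  seq <- randomSeq(n, gc = 0.2)
  gr <- GenomicRanges::GRanges(
    seqnames = id,
    ranges = IRanges::IRanges(gene_at[1], gene_at[2]), strand = "+",
    feature_id = "g1|gene_exon", kind = "gene_exon", gene_name = "g1")
  MitoGenome(id, seq, "circular", gr)
}
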