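test_that("GOC is 1 for identical or fully reversed circular orders", {
  a <- GeneOrder("a", paste0("g", 1:7))
  expect_equal(goc(a, a)$goc, 1)
  rev_a <- GeneOrder("r", rev(markers(a)), -rev(signs(a)))
  expect_equal(goc(a, rev_a)$goc, 1)  # adjacency sets are sign-blind
})

test_that("a single adjacent swap halves four-marker GOC", {
  a <- GeneOrder("a", c("g1", "g2", "g3", "g4"))
  b <- GeneOrder("b", c("g1", "g2", "g4", "g3"))
  r <- goc(a, b)
  expect_equal(r$n_orthologues, 4L)
  expect_equal(r$n_contiguous, 2L)  # {g1,g2} and {g3,g4} survive
  expect_equal(r$goc, 0.5)
  expect_equal(r$gol, 0.5)
})

test_that("orders are restricted to shared markers before adjacency extraction", {
  a <- GeneOrder("a", c("g1", "g2", "x", "g3"))
  b <- GeneOrder("b", c("g1", "g2", "g3", "y"))
  r <- goc(a, b)
  expect_equal(r$n_orthologues, 3L)
  expect_equal(r$goc, 1)  # after dropping x and y the circles agree
  expect_error(goc(GeneOrder("a", c("p", "q")),
                   GeneOrder("b", c("r", "s"))), "shared")
})

test_that("GOC matrices are symmetric with unit diagonal", {
  set.seed(4)
  orders <- lapply(1:4, function(i) {
    m <- paste0("g", 1:8)
    GeneOrder(paste0("G", i), sample(m), sample(c(-1L, 1L), 8, TRUE))
  })
  gm <- gocMatrix(orders)
  expect_equal(gm$goc, t(gm$goc))
  expect_equal(unname(diag(gm$goc)), rep(1, 4))
  expect_true(all(gm$goc >= 0 & gm$goc <= 1))
  expect_equal(gm$gol, 1 - gm$goc)
})

test_that("one rearrangement changes GOC by at most 2/N against a reference", {
  set.seed(8)
  ref <- GeneOrder("ref", paste0("g", 1:10))
  cur_m <- markers(ref); cur_s <- signs(ref)
  for (step in 1:30) {
    before <- goc(ref, GeneOrder("c", cur_m, cur_s))$goc
    s <- sample.int(10, 1); len <- sample.int(9, 1)
    r <- if (runif(1) < 0.5) {
      mitoarch:::.applyInversion(cur_m, cur_s, s, len)
    } else {
      ins <- sample.int(10 - len + 1, 1) - 1
      mitoarch:::.applyTransposition(cur_m, cur_s, s, len, ins)
    }
    cur_m <- r$ord; cur_s <- r$sg
    after <- goc(ref, GeneOrder("c", cur_m, cur_s))$goc
    expect_lte(after, before + 2 / 10 + 1e-12)
  }
})

test_that("DCJ distance matches hand-derived small cases", {
  x <- GeneOrder("x", c("1", "2", "3"))
  expect_equal(dcjDistance(x, x), 0L)
  y <- GeneOrder("y", c("1", "2", "3"), c(1L, -1L, 1L))
  expect_equal(dcjDistance(x, y), 1L)  # one inversion
  expect_error(dcjDistance(x, GeneOrder("z", c("1", "2", "4"))),
               "marker sets")
})

test_that("DCJ equals BFS shortest path over all signed circular 4-marker orders", {
  orders <- allSignedOrders(4L)
  a <- GeneOrder("a", as.character(1:4))
  dist <- dcjBFS(adjFromOrder(markers(a), signs(a)))
  for (o in orders) {
    b <- GeneOrder("b", o$markers, o$signs)
    want <- dist[[adjKey(adjFromOrder(o$markers, o$signs))]]
    expect_equal(dcjDistance(a, b), want,
                 info = paste(paste0(ifelse(o$signs < 0, "-", "+"),
                                     o$markers), collapse = " "))
  }
})

test_that("DCJ is a metric on the 4-marker order space", {
  orders <- allSignedOrders(4L)
  gs <- lapply(seq_along(orders), function(i)
    GeneOrder(paste0("o", i), orders[[i]]$markers, orders[[i]]$signs))
  set.seed(12)
  idx <- sample(length(gs), 8)
  for (i in idx) for (j in idx) {
    dij <- dcjDistance(gs[[i]], gs[[j]])
    expect_equal(dij, dcjDistance(gs[[j]], gs[[i]]))
    if (i == j) expect_equal(dij, 0L)
    for (k in sample(idx, 3)) {
      expect_lte(dij,
                 dcjDistance(gs[[i]], gs[[k]]) +
                   dcjDistance(gs[[k]], gs[[j]]))
    }
  }
})

test_that("gene orders extracted from annotated genomes follow genomic position and strand", {
  sim <- sharedSim()
  g <- sim$genomes[[1L]]
  ord <- geneOrderFromGenome(g)
  truth <- sim$truth$orders[[genomeID(g)]]
  ## same circular order up to rotation: compare adjacency sets
  expect_equal(goc(ord, truth)$goc, 1)
  expect_equal(sort(markers(ord)), sort(markers(truth)))
})

test_that("gene-order TSV round trip preserves orders", {
  d <- withr::local_tempdir()
  orders <- list(GeneOrder("A", c("x", "y", "z"), c(1L, -1L, 1L)),
                 GeneOrder("B", c("z", "x", "y"), c(-1L, 1L, 1L)))
  writeGeneOrderTSV(orders, file.path(d, "o.tsv"))
  back <- readGeneOrderTSV(file.path(d, "o.tsv"))
  expect_equal(markers(back$A), c("x", "y", "z"))
  expect_equal(signs(back$B), c(-1L, 1L, 1L))
})
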