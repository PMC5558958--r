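smallTree <- "((A:0.1,B:0.12):0.05,(C:0.08,D:0.15):0.04);"

test_that("identical seeds reproduce byte-identical output", {
  cfg <- simConfig(seed = 17L, tree = smallTree)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  writeSimulation(simulateGenomes(cfg), d1)
  writeSimulation(simulateGenomes(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
  ## and a different seed changes the sequences
  other <- simulateGenomes(simConfig(seed = 18L, tree = smallTree))
  one <- simulateGenomes(cfg)
  expect_false(identical(as.character(genomeSeq(other$genomes[[1]])),
                         as.character(genomeSeq(one$genomes[[1]]))))
})

test_that("zero rearrangement intensity preserves the root gene order everywhere", {
  sim <- simulateGenomes(simConfig(
    seed = 5L, tree = smallTree,
    rearrangement = list(inv_intensity = 0, trans_intensity = 0)))
  orders <- sim$truth$orders
  for (a in orders) for (b in orders)
    expect_equal(goc(a, b)$goc, 1)
  expect_true(all(sim$truth$events$inversions == 0))
  expect_true(all(sim$truth$events$transpositions == 0))
})

test_that("events on a single branch separate exactly the pairs crossing it", {
  tr <- ape::unroot(ape::read.tree(text = smallTree))
  M <- buildDesignMatrix(tr)
  target <- "A"  # the branch leading to leaf A
  hits <- 0L
  set.seed(90)
  for (r in 1:50) {
    sim <- simulateGeneOrders(
      tr, markers = 20,
      inv_intensity = setNames(c(50, 0, 0, 0, 0),
                               c(target, setdiff(colnames(M), target))),
      trans_intensity = 0)
    gm <- gocMatrix(sim$orders)
    for (rn in rownames(M)) {
      p <- strsplit(rn, "|", fixed = TRUE)[[1L]]
      crosses <- M[rn, target] == 1L
      if (!crosses)
        expect_equal(gm$gol[p[1], p[2]], 0)
      else if (gm$gol[p[1], p[2]] > 0) hits <- hits + 1L
    }
  }
  expect_gt(hits, 0L)  # crossing pairs do lose order
})

test_that("generated genomes hit the target AT fraction within 2 points", {
  sim <- sharedSim()
  for (g in sim$genomes[1:5]) {
    expect_gte(genomeLength(g), 50000L)
    at <- 1 - mitoarch:::gcFraction(as.character(genomeSeq(g)))
    expect_lt(abs(at - 0.80), 0.02)
  }
})

test_that("simulation truth is consistent with the emitted sequences", {
  sim <- sharedSim()
  g <- sim$genomes[[1L]]
  seq <- as.character(genomeSeq(g))
  tr <- sim$truth$clusters[sim$truth$clusters$genome_id == genomeID(g), ]
  fams <- simConfig()$gc_cluster$families
  for (i in seq_len(min(nrow(tr), 20L))) {
    planted <- substr(seq, tr$start[i], tr$end[i])
    cons <- fams[[tr$family[i]]]
    expect_equal(nchar(planted), nchar(cons))
    ## low point-mutation rate: planted copies stay close to consensus
    expect_gte(pairwiseIdentity(planted, cons), 0.9)
  }
  sp <- sim$truth$spacers[sim$truth$spacers$genome_id == genomeID(g), ]
  for (i in seq_len(min(nrow(sp), 10L))) {
    frag <- substr(seq, sp$start[i], sp$end[i])
    expect_lt(mitoarch:::gcFraction(frag), 0.1)
    expect_gt(nchar(frag), 20L)
  }
})

test_that("planted GC clusters are recovered with F1 >= 0.9", {
  sim <- sharedSim()
  ids <- names(sim$genomes)[1:3]
  pred <- do.call(rbind, lapply(ids, function(id)
    detectGCClusters(sim$genomes[[id]])))
  tr <- sim$truth$clusters[sim$truth$clusters$genome_id %in% ids, ]
  sc <- scoreIntervals(tr, pred)
  expect_gte(sc$f1, 0.9)
})

test_that("interval scoring behaves on forced cases", {
  tr <- data.frame(genome_id = "g", start = c(10L, 100L),
                   end = c(40L, 130L))
  expect_equal(scoreIntervals(tr, tr),
               list(precision = 1, recall = 1, f1 = 1, n_truth = 2L,
                    n_predicted = 2L, n_matched = 2L))
  empty <- tr[0, ]
  expect_equal(scoreIntervals(tr, empty)$recall, 0)
  half <- scoreIntervals(tr, tr[1, ])
  expect_equal(half$precision, 1)
  expect_equal(half$recall, 0.5)
  ## reciprocal overlap below 0.8 does not match
  off <- data.frame(genome_id = "g", start = 10L, end = 80L)
  expect_equal(scoreIntervals(tr, off)$n_matched, 0L)
})

test_that("the adjusted Rand index agrees with an independent implementation", {
  skip_if_not_installed("mclust")
  set.seed(61)
  for (r in 1:10) {
    n <- sample(10:40, 1)
    a <- sample(letters[1:4], n, replace = TRUE)
    b <- sample(letters[1:3], n, replace = TRUE)
    expect_equal(adjustedRand(a, b), mclust::adjustedRandIndex(a, b))
  }
  expect_equal(adjustedRand(1:5, 1:5), 1)
})

test_that("degenerate simulation configs are rejected", {
  expect_error(simulateGenomes(simConfig(seed = 1, tree = "(A:1);")),
               "2 leaves")
  expect_error(simConfig(target_at_fraction = 1.2), "target_at")
})
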