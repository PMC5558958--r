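test_that("the design matrix has one row per leaf pair and one column per unrooted branch", {
  M <- buildDesignMatrix(defaultTree())
  expect_equal(dim(M), c(choose(15, 2), 2 * 15 - 3))
  expect_true(all(M %in% c(0L, 1L)))
  ## every leaf branch is crossed by exactly n-1 = 14 pairs
  tips <- ape::read.tree(text = defaultTree())$tip.label
  expect_true(all(colSums(M[, tips]) == 14L))
})

test_that("a three-leaf star gives a 3x3 design with two branches per pair", {
  M <- buildDesignMatrix("(A:1,B:1,C:1);")
  expect_equal(dim(M), c(3L, 3L))
  expect_true(all(rowSums(M) == 2L))
})

test_that("row sums equal independently computed path edge counts", {
  tr <- ape::unroot(ape::read.tree(text = defaultTree()))
  M <- buildDesignMatrix(tr)
  tru <- tr; tru$edge.length <- rep(1, nrow(tr$edge))
  D <- ape::cophenetic.phylo(tru)  # unit lengths: path edge counts
  for (rn in sample(rownames(M), 20)) {
    p <- strsplit(rn, "|", fixed = TRUE)[[1L]]
    expect_equal(sum(M[rn, ]), D[p[1], p[2]])
  }
})

test_that("duplicate leaf labels are rejected", {
  expect_error(buildDesignMatrix("((A:1,A:1):1,B:2);"), "duplicate")
})

test_that("zero GOL yields the zero solution with zero objective", {
  M <- buildDesignMatrix(defaultTree())
  sol <- solveBsgol(M, setNames(rep(0, nrow(M)), rownames(M)))
  expect_true(all(branchTable(sol)$bsGOL == 0))
  expect_equal(objectiveValue(sol), 0)
})

test_that("the three-leaf system solves exactly by hand", {
  M <- buildDesignMatrix("(A:1,B:1,C:1);")
  gol <- setNames(c(0.2, 0.3, 0.4), c("A|B", "A|C", "B|C"))
  sol <- solveBsgol(M, gol)
  tab <- branchTable(sol)
  x <- setNames(tab$bsGOL, tab$branch)
  expect_equal(unname(x[c("A", "B", "C")]), c(0.05, 0.15, 0.25),
               tolerance = 1e-10)
  expect_equal(objectiveValue(sol), 0, tolerance = 1e-12)
  expect_equal(tab$rate, tab$bsGOL / tab$branch_length)
})

test_that("GOL values outside [0,1] and mismatched dimensions are rejected", {
  M <- buildDesignMatrix("(A:1,B:1,C:1);")
  expect_error(solveBsgol(M, setNames(c(0.2, 1.4, 0.1), rownames(M))),
               "\\[0, 1\\]")
  expect_error(solveBsgol(M, c(0.1, 0.2)), "length")
})

test_that("branches crossed by no pair are flagged unidentifiable", {
  M <- buildDesignMatrix("(A:1,B:1,C:1);")
  M2 <- cbind(M, phantom = 0L)
  attr(M2, "branch_lengths") <- c(attr(M, "branch_lengths"), phantom = 1)
  sol <- solveBsgol(M2, setNames(c(0.2, 0.3, 0.4), rownames(M)))
  tab <- branchTable(sol)
  expect_false(tab$identifiable[tab$branch == "phantom"])
  expect_equal(tab$bsGOL[tab$branch == "phantom"], 0)
  expect_true(all(tab$identifiable[tab$branch != "phantom"]))
})

test_that("zero-length branches give flagged (NA) rates", {
  M <- buildDesignMatrix("(A:0,B:1,C:1);")
  sol <- solveBsgol(M, setNames(c(0.2, 0.3, 0.4), rownames(M)))
  tab <- branchTable(sol)
  expect_true(is.na(tab$rate[tab$branch == "A"]))
  expect_false(any(is.na(tab$rate[tab$branch != "A"])))
})

test_that("the NNLS objective beats trivial feasible alternatives", {
  set.seed(77)
  M <- buildDesignMatrix(defaultTree())
  gol <- setNames(pmin(1, pmax(0, runif(nrow(M), 0, 0.5))), rownames(M))
  sol <- solveBsgol(M, gol)
  D <- unname(as.matrix(M))
  obj <- function(x) sum((D %*% x - gol)^2)
  expect_lte(objectiveValue(sol), obj(rep(0, ncol(M))) + 1e-9)
  xu <- as.numeric(MASS::ginv(D) %*% gol)
  expect_lte(objectiveValue(sol), obj(pmax(xu, 0)) + 1e-9)
  ## unconstrained solution attains an objective no worse than NNLS
  solu <- solveBsgol(M, gol, method = "unconstrained")
  expect_lte(objectiveValue(solu), objectiveValue(sol) + 1e-9)
})
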