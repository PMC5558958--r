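flankA <- "ACGTACGTAC"
flankB <- "TTGCAATGCA"

test_that("identical flanks in the same host gene form one locus", {
  recs <- intronRecords(species = c("s1", "s2"), host_gene = "cox1",
                        insertion_site = c(168L, 170L),
                        flank5 = flankA, flank3 = flankB)
  loci <- assignIntronLoci(recs)
  expect_equal(length(unique(loci$locus_id)), 1L)
  expect_equal(unique(loci$locus_id), "cox1_1")
})

test_that("flank identity 0.9 links, the host-gene guard separates", {
  f5_mut <- sub("^AC", "GG", flankA)  # 2 mismatches in 20 -> 0.9
  recs <- intronRecords(species = c("s1", "s2"), host_gene = "cox1",
                        insertion_site = c(100L, 400L),  # far apart
                        flank5 = c(flankA, f5_mut), flank3 = flankB)
  loci <- assignIntronLoci(recs)
  expect_equal(length(unique(loci$locus_id)), 1L)

  recs2 <- intronRecords(species = c("s1", "s2"),
                         host_gene = c("cox1", "cob"),
                         insertion_site = c(100L, 100L),
                         flank5 = flankA, flank3 = flankB)
  loci2 <- assignIntronLoci(recs2)
  expect_equal(length(unique(loci2$locus_id)), 2L)
})

test_that("nearby sites rescue moderately diverged flanks, distant sites do not", {
  ## identity 0.75: 5 mismatches in 20 (cutoff 0.8, relaxed 0.7)
  f5_div <- paste0("CTACG", substr(flankA, 6, 10))
  base <- function(site2) intronRecords(
    species = c("s1", "s2"), host_gene = "cox1",
    insertion_site = c(200L, site2),
    flank5 = c(flankA, f5_div), flank3 = flankB)
  expect_equal(length(unique(assignIntronLoci(base(230L))$locus_id)), 1L)
  expect_equal(length(unique(assignIntronLoci(base(231L))$locus_id)), 2L)
})

test_that("a component with two introns from one species is split at the weakest link", {
  ## s1 has two introns; a bridging s2 intron links both
  f_mid <- sub("^A", "G", flankA)                 # 19/20 to flankA
  f_far <- sub("^ACG", "GGA", flankA)             # 17/20 to flankA
  recs <- intronRecords(
    species = c("s1", "s2", "s1"), host_gene = "cox1",
    insertion_site = c(100L, 102L, 104L),
    flank5 = c(flankA, f_mid, f_far), flank3 = flankB)
  loci <- assignIntronLoci(recs)
  per_locus <- split(loci$species, loci$locus_id)
  expect_true(all(vapply(per_locus, function(x) !anyDuplicated(x),
                         logical(1))))
  ## the bridge stays with its closer mate
  s2_locus <- loci$locus_id[loci$species == "s2"]
  s1_close <- loci$locus_id[loci$species == "s1" &
                            loci$insertion_site == 100L]
  expect_equal(s2_locus, s1_close)
})

test_that("locus assignment is invariant to input order", {
  set.seed(31)
  recs <- intronRecords(
    species = rep(c("s1", "s2", "s3"), each = 3),
    host_gene = rep(c("cox1", "cox1", "cob"), times = 3),
    insertion_site = rep(c(100L, 500L, 300L), times = 3),
    flank5 = rep(c(flankA, flankB, "AAAAATTTTT"), times = 3),
    flank3 = rep(c(flankB, flankA, "TTTTTAAAAA"), times = 3))
  ref <- assignIntronLoci(recs)
  for (r in 1:5) {
    perm <- recs[sample(nrow(recs)), ]
    got <- assignIntronLoci(perm)
    expect_equal(got[order(got$intron_id, got$species), "locus_id"],
                 ref[order(ref$intron_id, ref$species), "locus_id"])
  }
})

test_that("malformed flanks are rejected", {
  expect_error(intronRecords("s1", "cox1", 10L, "ACGT", flankB), "10 bp")
  recs <- intronRecords("s1", "cox1", 10L, flankA, flankB)
  recs$flank5 <- "ACG"
  expect_error(assignIntronLoci(recs), "10 bp")
})

test_that("presence matrices and lineage counts reflect memberships", {
  recs <- intronRecords(
    species = c("s1", "s2", "s3", "s1"), host_gene = "cox1",
    insertion_site = c(100L, 100L, 100L, 500L),
    flank5 = c(flankA, flankA, flankA, flankB),
    flank3 = c(flankB, flankB, flankB, flankA))
  loci <- assignIntronLoci(recs)
  pm <- presenceMatrix(loci, species_list = c("s1", "s2", "s3", "s4"),
                       lineages = list(L1 = c("s1", "s2"),
                                       L2 = c("s3", "s4"),
                                       L3 = "s4"))
  expect_equal(dim(pm$matrix), c(2L, 4L))
  expect_equal(unname(rowSums(pm$matrix)), c(3, 1))
  expect_equal(unname(pm$lineage_counts), c(2L, 1L, 0L))
  ## empty input
  empty <- presenceMatrix(assignIntronLoci(recs[0, ]),
                          species_list = "s1")
  expect_equal(nrow(empty$matrix), 0L)
})

test_that("locus identity uses conserved columns and flags single members", {
  expect_equal(locusIdentity(c("MKVLL", "MKVLL")), 1)
  aln <- c(paste0(strrep("A", 83), strrep("C", 17)),
           paste0(strrep("A", 83), strrep("G", 17)))
  expect_equal(locusIdentity(aln), 0.83)
  expect_true(is.na(locusIdentity("MKVLL")))
})

test_that("planted intron loci are recovered from simulated genomes", {
  sim <- sharedSim()
  recs <- sim$truth$introns
  loci <- assignIntronLoci(recs)
  expect_gte(adjustedRand(loci$locus_id, loci$true_locus), 0.9)
  ## and the per-species uniqueness invariant holds
  per_locus <- split(loci$species, loci$locus_id)
  expect_true(all(vapply(per_locus, function(x) !anyDuplicated(x),
                         logical(1))))
})

test_that("intron records extracted from annotated genomes carry coding-coordinate sites", {
  sim <- sharedSim()
  g <- sim$genomes[[1L]]
  recs <- intronRecordsFromGenome(g)
  truth <- sim$truth$introns[sim$truth$introns$species == genomeID(g), ]
  if (nrow(truth)) {
    m <- merge(recs, truth, by = c("species", "host_gene",
                                   "insertion_site"))
    expect_equal(nrow(m), nrow(truth))
  }
  ## flanks read straight from the (unmutated-flank) genome sequence
  expect_true(all(nchar(recs$flank5) == 10L))
})

test_that("locus recovery stays high at flank mutation rate 0.1", {
  sim <- simulateGenomes(simConfig(
    seed = 271L,
    tree = "((A:0.2,B:0.2):0.1,(C:0.2,D:0.2):0.1);",
    intron = list(flank_mut_rate = 0.1, presence_prob = 0.6)))
  loci <- assignIntronLoci(sim$truth$introns)
  expect_gte(adjustedRand(loci$locus_id, loci$true_locus), 0.9)
})
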