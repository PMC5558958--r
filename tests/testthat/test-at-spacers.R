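mkGenome <- function(seq, genes = NULL) {
  gr <- if (is.null(genes)) NULL else GenomicRanges::GRanges(
    seqnames = "s", ranges = IRanges::IRanges(genes[, 1], genes[, 2]),
    strand = "+",
    feature_id = paste0("g", seq_len(nrow(genes)), "|gene_exon"),
    kind = "gene_exon", gene_name = paste0("g", seq_len(nrow(genes))))
  MitoGenome("s", seq, "circular", gr)
}

test_that("pure-AT intergenic stretches longer than 20 bp are spacers", {
  ## 30 bp AT stretch between two genes
  seq <- paste0(strrep("G", 40), strrep("AT", 15), strrep("G", 30))
  g <- mkGenome(seq, rbind(c(1, 40), c(71, 100)))
  sp <- detectATSpacers(g, intergenic = IRanges::IRanges(41L, 70L),
                        clusters = data.frame())
  expect_equal(nrow(sp), 1L)
  expect_equal(sp$start, 41L)
  expect_equal(sp$end, 70L)
  expect_equal(sp$length, 30L)
})

test_that("the >20 bp and GC<0.1 rules are strict", {
  seq <- paste0(strrep("G", 40), strrep("A", 20), strrep("G", 40))
  g <- mkGenome(seq, rbind(c(1, 40), c(61, 100)))
  sp <- detectATSpacers(g, intergenic = IRanges::IRanges(41L, 60L),
                        clusters = data.frame())
  expect_equal(nrow(sp), 0L)  # exactly 20 bp is not enough

  ## 25 bp with 3 G: GC = 0.12 >= 0.1 -> rejected
  frag <- paste0(strrep("A", 10), "G", "AAAAG", "AAAAG", "AAAA")
  expect_equal(nchar(frag), 25L)
  seq2 <- paste0(strrep("G", 40), frag, strrep("G", 35))
  g2 <- mkGenome(seq2, rbind(c(1, 40), c(66, 100)))
  sp2 <- detectATSpacers(g2, intergenic = IRanges::IRanges(41L, 65L),
                         clusters = data.frame())
  expect_equal(nrow(sp2), 0L)

  ## 25 bp with 2 G: GC = 0.08 < 0.1 -> accepted
  frag3 <- paste0(strrep("A", 11), "G", strrep("A", 6), "G",
                  strrep("A", 6))
  seq3 <- paste0(strrep("G", 40), frag3, strrep("G", 35))
  g3 <- mkGenome(seq3, rbind(c(1, 40), c(66, 100)))
  sp3 <- detectATSpacers(g3, intergenic = IRanges::IRanges(41L, 65L),
                         clusters = data.frame())
  expect_equal(nrow(sp3), 1L)
})

test_that("only clusters holding a G/C tetranucleotide are excised", {
  ## intergenic 41..140: AT with a GC cluster in the middle
  mid <- "GCCGGCGCCG"  # contains GCCG
  seq <- paste0(strrep("G", 40), strrep("A", 45), mid, strrep("A", 45),
                strrep("G", 40))
  g <- mkGenome(seq, rbind(c(1, 40), c(141, 180)))
  cl <- data.frame(genome_id = "s", start = 86L, end = 95L,
                   sequence = mid)
  sp <- detectATSpacers(g, intergenic = IRanges::IRanges(41L, 140L),
                        clusters = cl)
  expect_equal(nrow(sp), 2L)  # split into two 45 bp spacers
  expect_equal(sp$length, c(45L, 45L))

  ## same interval but cluster without any G/C 4-mer: not excised, and
  ## its GC pushes the whole fragment over the limit
  cl2 <- data.frame(genome_id = "s", start = 86L, end = 95L,
                    sequence = "GCATGCATGC")
  sp2 <- detectATSpacers(g, intergenic = IRanges::IRanges(41L, 140L),
                         clusters = cl2)
  expect_equal(nrow(sp2), 0L)
})

test_that("planted spacers in simulated genomes are recovered", {
  sim <- sharedSim()
  ids <- names(sim$genomes)[1:3]
  pred <- do.call(rbind, lapply(ids, function(id)
    detectATSpacers(sim$genomes[[id]])))
  tr <- sim$truth$spacers[sim$truth$spacers$genome_id %in% ids, ]
  sc <- scoreIntervals(tr, pred)
  expect_gte(sc$recall, 0.8)
  expect_gte(sc$precision, 0.8)
})

test_that("dinucleotide ratio counts overlapping pairs and flags empty denominators", {
  expect_equal(dinucleotideRatio("AATT"), 0.5)  # AT=1, TA=0, AA=1, TT=1
  expect_true(is.na(dinucleotideRatio("ATATAT")))  # no AA/TT
  expect_equal(dinucleotideRatio("AAAA"), 0)
  ## pooling across spacers, no wrap between them
  expect_equal(dinucleotideRatio(c("AAT", "TAA")),
               (1 + 1) / (1 + 1))  # AT,TA over AA,AA
  expect_error(dinucleotideRatio(character()), "at least one")
})
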