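test_that("FASTA + feature-table reading follows the 1-based inclusive convention", {
  d <- withr::local_tempdir()
  seq <- strrep("ACGT", 100)  # 400 bp
  writeLines(c(">gX topology=circular", seq), file.path(d, "gX.fasta"))
  write.table(data.frame(gene = "cox1", kind = "gene_exon", strand = "+",
                         start = 1, end = 300),
              file.path(d, "gX.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  g <- readGenome(file.path(d, "gX.fasta"))
  f <- features(g)
  expect_equal(genomeLength(g), 400L)
  expect_equal(topology(g), "circular")
  expect_equal(GenomicRanges::start(f), 1L)
  expect_equal(GenomicRanges::end(f), 300L)
  expect_equal(sum(GenomicRanges::width(f)), 300L)
})

test_that("origin-wrapping features are split into two intervals totalling their length", {
  d <- withr::local_tempdir()
  writeLines(c(">gW topology=circular", strrep("A", 100)),
             file.path(d, "gW.fasta"))
  write.table(data.frame(gene = "trnX", kind = "trna", strand = "+",
                         start = 91, end = 10),
              file.path(d, "gW.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  g <- readGenome(file.path(d, "gW.fasta"))
  f <- features(g)
  expect_equal(length(f), 2L)
  expect_equal(sum(GenomicRanges::width(f)), 20L)
  expect_setequal(GenomicRanges::start(f), c(91L, 1L))
  expect_setequal(GenomicRanges::end(f), c(100L, 10L))
})

test_that("degenerate annotation inputs are rejected with informative errors", {
  d <- withr::local_tempdir()
  writeLines(c(">e topology=circular", ""), file.path(d, "e.fasta"))
  write.table(data.frame(gene = character(), kind = character(),
                         strand = character(), start = integer(),
                         end = integer()),
              file.path(d, "e.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(readGenome(file.path(d, "e.fasta")), "empty")

  writeLines(c(">g topology=circular", strrep("A", 50)),
             file.path(d, "g.fasta"))
  write.table(data.frame(gene = "x", kind = "gene_exon", strand = "+",
                         start = 10, end = 60),
              file.path(d, "g.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(readGenome(file.path(d, "g.fasta")), "60")

  write.table(data.frame(gene = c("y", "y"), kind = "gene_exon",
                         strand = "+", start = c(1, 5), end = c(10, 20)),
              file.path(d, "g.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(readGenome(file.path(d, "g.fasta")), "overlap")
})

test_that("a minimal GenBank flat file parses locations, strands and topology", {
  d <- withr::local_tempdir()
  gb <- c(
    "LOCUS       mt001                 120 bp    DNA     circular",
    "FEATURES             Location/Qualifiers",
    "     source          1..120",
    "     CDS             11..40",
    "                     /gene=\"cox1\"",
    "     tRNA            complement(61..90)",
    "                     /gene=\"trnW\"",
    "     CDS             join(101..120,1..6)",
    "                     /gene=\"cox2\"",
    "ORIGIN",
    paste0("        1 ", paste(rep("acgtaatgca", 6), collapse = " ")),
    paste0("       61 ", paste(rep("acgtaatgca", 6), collapse = " ")),
    "//")
  writeLines(gb, file.path(d, "mt.gb"))
  g <- readGenome(file.path(d, "mt.gb"), dialect = "genbank")
  expect_equal(genomeLength(g), 120L)
  expect_equal(topology(g), "circular")
  f <- features(g)
  mc <- S4Vectors::mcols(f)
  expect_equal(unname(mc$gene_name[mc$kind == "trna"]), "trnW")
  expect_equal(as.character(GenomicRanges::strand(f[mc$gene_name == "trnW"])),
               "-")
  cox2 <- f[mc$gene_name == "cox2"]
  expect_equal(length(cox2), 2L)
  expect_equal(sum(GenomicRanges::width(cox2)), 26L)
})

test_that("write/read round trip reproduces sequence, intervals and strands", {
  sim <- sharedSim()
  g <- sim$genomes[[1L]]
  d <- withr::local_tempdir()
  writeGenome(g, file.path(d, "g.fasta"))
  g2 <- readGenome(file.path(d, "g.fasta"))
  expect_equal(as.character(genomeSeq(g2)), as.character(genomeSeq(g)))
  expect_equal(topology(g2), topology(g))
  ord <- function(x) {
    f <- features(x)
    df <- data.frame(start = GenomicRanges::start(f),
                     end = GenomicRanges::end(f),
                     strand = as.character(GenomicRanges::strand(f)),
                     kind = S4Vectors::mcols(f)$kind,
                     gene = S4Vectors::mcols(f)$gene_name)
    df[order(df$start, df$end, df$gene), ]
  }
  a <- ord(g); b <- ord(g2)
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("intergenic regions complement the genic annotation exactly", {
  g <- tinyGenome()
  ir <- intergenicRegions(g)
  expect_equal(sum(IRanges::width(ir)), 1000L - 600L)
  expect_false(any(IRanges::overlapsAny(
    ir, IRanges::IRanges(101L, 700L))))
})
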