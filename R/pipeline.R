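## End-to-end orchestration: genomes in, supplementary-style tables out.

#' Read a plain-text key=value run configuration
#'
#' Lines of \code{key = value}; '#' comments and blank lines ignored.
#' Comma-separated values become vectors. Unknown keys are rejected.
#'
#' @param path config file.
#' @return named list.
#' @export
readRunConfig <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  known <- c("genomes", "tree", "out_dir", "alignments_dir",
             "stages", "min_len1", "min_gc1", "min_len2", "min_gc2",
             "join_gap", "identity_cutoff", "overlap_cutoff",
             "flank_identity_cutoff", "site_window", "min_family_size")
  cfg <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) < 2L) stop("cannot parse config line: ", ln)
    key <- trimws(kv[1L])
    if (!key %in% known) stop("unknown config key: ", key)
    val <- trimws(paste(kv[-1L], collapse = "="))
    val <- trimws(strsplit(val, ",", fixed = TRUE)[[1L]])
    num <- suppressWarnings(as.numeric(val))
    cfg[[key]] <- if (!any(is.na(num))) num else val
  }
  cfg
}

.stageLog <- function(verbose, ...) if (verbose) message(...)

#' Run the full genome-architecture pipeline
#'
#' Runs partitioning, GC-cluster detection and family grouping, AT
#' spacers, gene-order conservation, branch-specific GOL rates, intron
#' locus assignment and (optionally) alignment identities over a set
#' of annotated genomes, writing one TSV per summary table plus a
#' manifest of completed stages. Re-running with identical inputs
#' reproduces identical outputs (no randomness).
#'
#' @param genomes named list of \linkS4class{MitoGenome}, or a
#'   character vector of FASTA paths (each with its feature TSV
#'   alongside, see \code{\link{readGenome}}).
#' @param tree phylo/Newick/file; required for the branch-rate stage.
#' @param out_dir output directory.
#' @param stages subset of
#'   \code{c("partition","clusters","families","spacers","gene_order",
#'   "bsgol","introns","identity")}.
#' @param alignments_dir optional directory of aligned FASTA files
#'   (one per gene) for the identity stage.
#' @param params list of stage parameter overrides (detection
#'   thresholds, cutoffs; see the stage functions).
#' @param verbose emit progress messages.
#' @return (invisibly) list of result tables; side effect: TSVs +
#'   \code{manifest.tsv} in \code{out_dir}.
#' @export
runPipeline <- function(genomes, tree = NULL, out_dir = "mitoarch_out",
                        stages = c("partition", "clusters", "families",
                                   "spacers", "gene_order", "bsgol",
                                   "introns", "identity"),
                        alignments_dir = NULL, params = list(),
                        verbose = TRUE) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (is.character(genomes))
    genomes <- lapply(genomes, readGenome)
  if (length(genomes) < 2L) stop("need at least 2 genomes")
  names(genomes) <- vapply(genomes, genomeID, character(1))
  if ("bsgol" %in% stages && is.null(tree))
    stop("missing input: tree (required for the bsgol stage)")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(key, default) if (!is.null(params[[key]])) params[[key]]
                              else default
  done <- character(); out <- list()
  finish <- function() {
    write.table(data.frame(stage = done, status = "ok"),
                file.path(out_dir, "manifest.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  on.exit(finish())

  clusters <- lapply(genomes, function(g) detectGCClusters(
    g, min_len1 = p("min_len1", 16L), min_gc1 = p("min_gc1", 0.75),
    min_len2 = p("min_len2", 8L), min_gc2 = p("min_gc2", 0.85),
    join_gap = p("join_gap", 10L)))
  spacers <- lapply(genomes, detectATSpacers)

  if ("clusters" %in% stages) {
    .stageLog(verbose, "stage clusters: two-pass GC scan on ",
              length(genomes), " genomes")
    tab <- do.call(rbind, unname(clusters))
    write.table(tab[, setdiff(names(tab), "sequence")],
                file.path(out_dir, "gc_clusters.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    ## region split (exon/intron/intergenic), by cluster midpoint
    reg <- do.call(rbind, lapply(names(genomes), function(id) {
      g <- genomes[[id]]; cl <- clusters[[id]]
      n <- genomeLength(g)
      f <- features(g); kind <- S4Vectors::mcols(f)$kind
      exon <- IRanges::reduce(IRanges::ranges(f[kind %in% GENE_KINDS]))
      intr <- IRanges::reduce(IRanges::ranges(f[kind == "intron"]))
      mid <- ((cl$start + (cl$end - cl$start) %/% 2L) - 1L) %% n + 1L
      where <- vapply(mid, function(m) {
        if (any(IRanges::start(exon) <= m & IRanges::end(exon) >= m))
          "exon"
        else if (any(IRanges::start(intr) <= m & IRanges::end(intr) >= m))
          "intron" else "intergenic"
      }, character(1))
      data.frame(genome = id, exon = sum(where == "exon"),
                 intron = sum(where == "intron"),
                 intergenic = sum(where == "intergenic"),
                 sum = length(where), stringsAsFactors = FALSE)
    }))
    write.table(reg, file.path(out_dir, "gc_cluster_regions.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    out$clusters <- tab; out$cluster_regions <- reg
    done <- c(done, "clusters")
  }

  if ("partition" %in% stages) {
    .stageLog(verbose, "stage partition: five-part accounting")
    parts <- lapply(names(genomes), function(id)
      buildPartition(genomes[[id]], clusters[[id]], spacers[[id]]))
    out$partition <- writePartitionTSV(
      parts, file.path(out_dir, "partition.tsv"))
    reg <- intergenicVariation(parts)
    write.table(data.frame(predictor = "intergenic_size",
                           slope = reg$slope, intercept = reg$intercept,
                           r_squared = reg$r_squared, n = reg$n),
                file.path(out_dir, "size_variation.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    out$size_variation <- reg
    done <- c(done, "partition")
  }

  if ("families" %in% stages) {
    .stageLog(verbose, "stage families: per-genome cluster grouping")
    fam_rows <- list()
    for (id in names(genomes)) {
      cl <- clusters[[id]]
      if (!nrow(cl)) next
      cl$cluster_id <- sprintf("%s_c%03d", id, seq_len(nrow(cl)))
      fams <- groupGCClusters(cl,
        identity_cutoff = p("identity_cutoff", 0.6),
        overlap_cutoff = p("overlap_cutoff", 0.8))
      pal <- mean(vapply(cl$sequence, function(s)
        isPalindromicLike(s), logical(1)))
      main <- mainFamilies(fams, p("min_family_size", 8L))
      fam_rows[[id]] <- data.frame(
        genome = id, num = nrow(cl), palindromic = pal,
        family_num = nrow(main),
        consensus = paste(fams$families$consensus, collapse = ","),
        stringsAsFactors = FALSE)
    }
    out$families <- do.call(rbind, fam_rows)
    write.table(out$families, file.path(out_dir, "gc_families.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    done <- c(done, "families")
  }

  if ("spacers" %in% stages) {
    .stageLog(verbose, "stage spacers: AT-spacer detection")
    tab <- do.call(rbind, unname(spacers))
    write.table(tab[, setdiff(names(tab), "sequence")],
                file.path(out_dir, "at_spacers.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    ratio <- vapply(spacers, function(s)
      if (nrow(s)) dinucleotideRatio(s) else NA_real_, numeric(1))
    write.table(data.frame(genome = names(ratio),
                           at_ta_over_aa_tt = unname(ratio)),
                file.path(out_dir, "dinucleotide_ratio.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    out$spacers <- tab; out$dinucleotide_ratio <- ratio
    done <- c(done, "spacers")
  }

  orders <- NULL
  if (any(c("gene_order", "bsgol") %in% stages))
    orders <- lapply(genomes, geneOrderFromGenome)

  if ("gene_order" %in% stages) {
    .stageLog(verbose, "stage gene_order: GOC/GOL matrices")
    gm <- gocMatrix(orders)
    write.table(data.frame(genome = rownames(gm$goc), gm$goc),
                file.path(out_dir, "goc_matrix.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(data.frame(genome = rownames(gm$gol), gm$gol),
                file.path(out_dir, "gol_matrix.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    out$goc <- gm
    done <- c(done, "gene_order")
  }

  if ("bsgol" %in% stages) {
    .stageLog(verbose, "stage bsgol: branch-specific GOL rates")
    sol <- bsgolFromOrders(orders, tree)
    out$bsgol <- writeBsgolTSV(sol, file.path(out_dir, "bsgol.tsv"))
    done <- c(done, "bsgol")
  }

  if ("introns" %in% stages) {
    .stageLog(verbose, "stage introns: locus assignment")
    recs <- do.call(rbind, lapply(genomes, intronRecordsFromGenome))
    if (!is.null(recs) && nrow(recs)) {
      loci <- assignIntronLoci(recs,
        flank_identity_cutoff = p("flank_identity_cutoff", 0.8),
        site_window = p("site_window", 30L))
      pm <- presenceMatrix(loci, species_list = names(genomes))
      write.table(data.frame(locus = rownames(pm$matrix), pm$matrix),
                  file.path(out_dir, "intron_presence.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      out$intron_loci <- loci; out$intron_presence <- pm$matrix
    } else {
      write.table(data.frame(locus = character()),
                  file.path(out_dir, "intron_presence.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
    done <- c(done, "introns")
  }

  if ("identity" %in% stages && !is.null(alignments_dir)) {
    .stageLog(verbose, "stage identity: conserved-column identities")
    files <- list.files(alignments_dir, pattern = "\\.(fa|fasta|aln)$",
                        full.names = TRUE)
    tab <- do.call(rbind, lapply(files, function(f) {
      m <- readAlignmentFasta(f)
      data.frame(gene = tools::file_path_sans_ext(basename(f)),
                 identity = conservedIdentity(m), n_seq = nrow(m),
                 stringsAsFactors = FALSE)
    }))
    if (!is.null(tab)) {
      write.table(tab, file.path(out_dir, "identity.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      out$identity <- tab
    }
    done <- c(done, "identity")
  }
  invisible(out)
}
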