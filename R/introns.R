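## Cross-species intron locus assignment by flanking-exon conservation.

#' Construct a table of intron records
#'
#' One row per observed intron: species, host gene, insertion site in
#' intron-free coding-sequence coordinates (an intron "inserted in the
#' 168th nucleotide" sits between coding positions 168 and 169),
#' group (I/II/unknown), ORF flag and the 10-bp exonic flanks either
#' side of the insertion point.
#'
#' @param species,host_gene,insertion_site,flank5,flank3 vectors of
#'   equal length.
#' @param group,has_orf optional annotations.
#' @return data.frame of intron records.
#' @export
intronRecords <- function(species, host_gene, insertion_site,
                          flank5, flank3,
                          group = "unknown", has_orf = NA) {
  n <- length(species)
  df <- data.frame(species = species, host_gene = host_gene,
                   insertion_site = as.integer(insertion_site),
                   group = rep_len(group, n), has_orf = rep_len(has_orf, n),
                   flank5 = toupper(flank5), flank3 = toupper(flank3),
                   stringsAsFactors = FALSE)
  if (any(nchar(df$flank5) != 10L) || any(nchar(df$flank3) != 10L))
    stop("flanks must be exactly 10 bp")
  if (any(df$insertion_site < 1L))
    stop("insertion sites must be >= 1")
  df$intron_id <- sprintf("%s_%s_%d", df$species, df$host_gene,
                          df$insertion_site)
  df
}

#' Extract intron records from an annotated genome
#'
#' For each annotated intron, the insertion site is the number of
#' exonic coding bases preceding it, and the flanks are the 10 exonic
#' bases either side of the insertion point (in coding orientation).
#'
#' @param g a \linkS4class{MitoGenome} with gene_exon/rrna and intron
#'   features.
#' @return data.frame of intron records (possibly empty).
#' @export
intronRecordsFromGenome <- function(g) {
  f <- g@features
  mc <- S4Vectors::mcols(f)
  seq <- as.character(genomeSeq(g))
  out <- list()
  for (gene in unique(mc$gene_name[mc$kind == "intron"])) {
    ex <- f[mc$gene_name == gene & mc$kind %in% GENE_KINDS]
    intr <- f[mc$gene_name == gene & mc$kind == "intron"]
    if (!length(ex)) next
    strand <- as.character(GenomicRanges::strand(ex))[1L]
    exd <- data.frame(start = GenomicRanges::start(ex),
                      end = GenomicRanges::end(ex))
    exd <- exd[order(exd$start), , drop = FALSE]
    coding <- paste(vapply(seq_len(nrow(exd)), function(i)
      substr(seq, exd$start[i], exd$end[i]), character(1)), collapse = "")
    if (strand == "-") coding <- revComp(coding)
    for (k in seq_along(intr)) {
      is_ <- GenomicRanges::start(intr)[k]
      ## coding bases preceding the intron (genomic orientation)
      pre <- sum(pmax(0L, pmin(exd$end, is_ - 1L) - exd$start + 1L))
      site <- if (strand == "-") nchar(coding) - pre else pre
      if (site < 10L || site + 10L > nchar(coding)) next
      out[[length(out) + 1L]] <- intronRecords(
        species = genomeID(g), host_gene = gene, insertion_site = site,
        flank5 = substr(coding, site - 9L, site),
        flank3 = substr(coding, site + 1L, site + 10L))
    }
  }
  if (!length(out))
    return(data.frame(species = character(), host_gene = character(),
                      insertion_site = integer(), group = character(),
                      has_orf = logical(), flank5 = character(),
                      flank3 = character(), intron_id = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Assign introns across species to homologous loci
#'
#' Single-linkage clustering of intron records: two introns link iff
#' they share the host gene AND either their concatenated 20-bp flank
#' identity reaches \code{flank_identity_cutoff}, or the identity
#' reaches \code{flank_identity_cutoff - 0.1} while their coding-
#' coordinate insertion sites differ by at most \code{site_window}
#' (flank conservation dominates; nearby position alone rescues only
#' moderately diverged flanks). Connected components become loci; any
#' component holding two introns of one species is split at its
#' weakest (lowest-identity) link until each species appears at most
#' once per locus. Locus ordinals follow mean insertion site within
#' each host gene. Deterministic and invariant to input order.
#'
#' @param introns data.frame from \code{\link{intronRecords}}.
#' @param flank_identity_cutoff default 0.8.
#' @param site_window default 30 nt.
#' @return data.frame: the intron records plus a \code{locus_id}
#'   column (host gene + ordinal).
#' @export
assignIntronLoci <- function(introns, flank_identity_cutoff = 0.8,
                             site_window = 30L) {
  if (!nrow(introns)) {
    introns$locus_id <- character(0)
    return(introns)
  }
  if (any(nchar(introns$flank5) != 10L) || any(nchar(introns$flank3) != 10L))
    stop("flanks must be exactly 10 bp")
  ## canonical internal order for determinism
  o <- order(introns$host_gene, introns$species, introns$insertion_site,
             introns$flank5, introns$flank3)
  df <- introns[o, , drop = FALSE]
  n <- nrow(df)
  cat20 <- paste0(df$flank5, df$flank3)
  edges <- list()
  for (i in seq_len(max(0L, n - 1L))) for (j in (i + 1L):n) {
    if (df$host_gene[i] != df$host_gene[j]) next
    id <- pairwiseIdentity(cat20[i], cat20[j], mode = "ungapped")
    near <- abs(df$insertion_site[i] - df$insertion_site[j]) <= site_window
    if (id >= flank_identity_cutoff ||
        (id >= flank_identity_cutoff - 0.1 && near))
      edges[[length(edges) + 1L]] <- c(i = i, j = j, w = id)
  }
  E <- if (length(edges)) do.call(rbind, edges) else
    matrix(numeric(), 0L, 3L, dimnames = list(NULL, c("i", "j", "w")))
  comp <- .componentsWithSplit(n, E, df$species)
  ## ordinals by mean insertion site within host gene
  df$.comp <- comp
  locus_of <- character(n)
  for (gene in unique(df$host_gene)) {
    sel <- df$host_gene == gene
    means <- tapply(df$insertion_site[sel], df$.comp[sel], mean)
    ord <- rank(means, ties.method = "first")
    locus_of[sel] <- sprintf("%s_%d", gene, ord[as.character(df$.comp[sel])])
  }
  df$locus_id <- locus_of
  df$.comp <- NULL
  df[order(df$locus_id, df$species), , drop = FALSE]
}

## Connected components under single linkage, splitting any component
## that contains one species twice by removing its weakest edge
## (ties broken on the smaller vertex pair) until valid.
.componentsWithSplit <- function(n, E, species) {
  active <- rep(TRUE, nrow(E))
  compute <- function() {
    comp <- seq_len(n)
    find <- function(x) { while (comp[x] != x) x <- comp[x]; x }
    if (nrow(E)) for (r in which(active)) {
      a <- find(E[r, "i"]); b <- find(E[r, "j"])
      if (a != b) comp[max(a, b)] <- min(a, b)
    }
    vapply(seq_len(n), find, numeric(1))
  }
  repeat {
    comp <- compute()
    bad <- NULL
    for (cc in unique(comp)) {
      idx <- which(comp == cc)
      if (anyDuplicated(species[idx])) { bad <- cc; break }
    }
    if (is.null(bad)) return(comp)
    rows <- which(active)
    rows <- rows[comp[E[rows, "i"]] == bad]
    if (!length(rows)) return(comp)  # duplicate within a singleton: impossible
    w <- E[rows, "w"]
    cand <- rows[w == min(w)]
    ## deterministic tie-break: smallest (i, j)
    pick <- cand[order(E[cand, "i"], E[cand, "j"])][1L]
    active[pick] <- FALSE
  }
}

#' Presence/absence matrix of intron loci
#'
#' @param loci data.frame from \code{\link{assignIntronLoci}}.
#' @param species_list column order (default: species seen, sorted).
#' @param lineages optional named list of species vectors; per-lineage
#'   counts report the number of loci present in at least one member.
#' @return list with \code{matrix} (loci x species, 0/1) and
#'   \code{lineage_counts}.
#' @export
presenceMatrix <- function(loci, species_list = NULL, lineages = NULL) {
  if (!nrow(loci)) {
    m <- matrix(0L, 0L, length(species_list),
                dimnames = list(NULL, species_list))
    return(list(matrix = m,
                lineage_counts = setNames(integer(length(lineages)),
                                          names(lineages))))
  }
  if (is.null(species_list)) species_list <- sort(unique(loci$species))
  lids <- unique(loci$locus_id)
  m <- matrix(0L, length(lids), length(species_list),
              dimnames = list(lids, species_list))
  for (r in seq_len(nrow(loci)))
    if (loci$species[r] %in% species_list)
      m[loci$locus_id[r], loci$species[r]] <- 1L
  counts <- NULL
  if (!is.null(lineages)) {
    counts <- vapply(lineages, function(sp) {
      sp <- intersect(sp, colnames(m))
      if (!length(sp)) return(0L)
      sum(rowSums(m[, sp, drop = FALSE]) > 0L)
    }, integer(1))
  }
  list(matrix = m, lineage_counts = counts)
}

#' Identity of a locus across its members
#'
#' Conserved-column identity over aligned member sequences (amino-acid
#' ORF alignments for ORF-bearing introns, nucleotide alignments
#' otherwise). Loci with fewer than two members are not computable
#' (returns NA, the table's '-').
#'
#' @param aligned character vector of aligned member sequences (equal
#'   lengths) or an alignment matrix.
#' @param mode \code{"orf_amino_acid"} or \code{"nucleotide"}
#'   (informational; the column statistic is the same).
#' @return fraction, or NA_real_ when not computable.
#' @export
locusIdentity <- function(aligned, mode = c("nucleotide",
                                            "orf_amino_acid")) {
  mode <- match.arg(mode)
  k <- if (is.matrix(aligned)) nrow(aligned) else length(aligned)
  if (k < 2L) return(NA_real_)
  conservedIdentity(aligned)
}
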