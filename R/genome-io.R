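## Genome / annotation input and output.
##
## External coordinates follow the GenBank convention: 1-based inclusive.
## Internally features are 1-based closed IRanges inside GRanges; a
## feature wrapping the origin of a circular genome is stored as two
## ranges with one feature_id.

## Map external annotation labels to internal kinds.
.kindFromKey <- function(key, gene = "") {
  key <- tolower(key)
  g <- tolower(gene)
  if (key %in% c("trna")) return("trna")
  if (key %in% c("rrna")) return("rrna")
  if (key %in% c("intron")) return("intron")
  if (key %in% c("rep_origin", "ori")) return("ori")
  if (key %in% c("cds", "gene", "gene_exon", "exon")) {
    if (grepl("^orf", g)) return("intergenic_orf")
    if (g %in% c("rpm1", "rnpb")) return("rnap")
    if (g %in% c("rnl", "rns")) return("rrna")
    if (grepl("^trn", g)) return("trna")
    return("gene_exon")
  }
  if (key %in% KNOWN_KINDS) return(key)
  key  # unknown kinds preserved with their label
}

.featureGRanges <- function(df, genome_length, topology, genome_id) {
  ## df: feature_id, kind, gene_name, strand, start, end (1-based incl.,
  ## start > end on a circular genome means the feature wraps).
  rows <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    s <- df$start[i]; e <- df$end[i]
    if (s < 1L || e < 1L || s > genome_length || e > genome_length)
      stop(sprintf(
        "feature '%s' (%s) has coordinates %d..%d outside 1..%d",
        df$gene_name[i], df$feature_id[i], s, e, genome_length))
    if (s <= e) {
      ir <- IRanges::IRanges(s, e)
    } else {
      if (topology != "circular")
        stop(sprintf("feature '%s' wraps (%d..%d) on a linear genome",
                     df$gene_name[i], s, e))
      ir <- IRanges::IRanges(c(s, 1L), c(genome_length, e))
    }
    rows[[i]] <- GenomicRanges::GRanges(
      seqnames = genome_id, ranges = ir,
      strand = rep(df$strand[i], length(ir)),
      feature_id = rep(df$feature_id[i], length(ir)),
      kind = rep(df$kind[i], length(ir)),
      gene_name = rep(df$gene_name[i], length(ir)))
  }
  if (!length(rows))
    return(GenomicRanges::GRanges(feature_id = character(),
                                  kind = character(),
                                  gene_name = character()))
  do.call(c, rows)
}

## Check exons of each gene feature for overlap (reject, per contract).
.checkExonOverlap <- function(gr) {
  if (!length(gr)) return(invisible(TRUE))
  keep <- S4Vectors::mcols(gr)$kind %in% GENE_KINDS
  g <- gr[keep]
  if (!length(g)) return(invisible(TRUE))
  sp <- split(IRanges::ranges(g), S4Vectors::mcols(g)$gene_name)
  for (nm in names(sp)) {
    ir <- sp[[nm]]
    if (length(ir) > 1L && length(IRanges::reduce(ir)) != length(ir))
      stop("overlapping exons within gene '", nm, "'")
  }
  invisible(TRUE)
}

#' Read an annotated mitochondrial genome
#'
#' Reads either a minimal GenBank flat file (LOCUS/FEATURES/ORIGIN) or a
#' FASTA file accompanied by a tab-separated feature table with columns
#' \code{gene}, \code{kind}, \code{strand}, \code{start}, \code{end}
#' (1-based inclusive; \code{start > end} denotes a feature wrapping the
#' origin of a circular genome; repeated \code{gene}+\code{kind} rows
#' form the exons of one multi-interval feature).
#'
#' @param path path to the GenBank file or the FASTA file.
#' @param dialect \code{"genbank"} or \code{"fasta+tsv"}; \code{"auto"}
#'   guesses from the file extension.
#' @param features_path for \code{fasta+tsv}, the TSV path (default:
#'   \code{path} with extension replaced by \code{.tsv}).
#' @param topology for \code{fasta+tsv}; GenBank files carry it in LOCUS.
#' @return a \linkS4class{MitoGenome}.
#' @export
readGenome <- function(path, dialect = c("auto", "genbank", "fasta+tsv"),
                       features_path = NULL,
                       topology = c("circular", "linear")) {
  dialect <- match.arg(dialect)
  topology <- match.arg(topology)
  if (dialect == "auto") {
    ext <- tolower(tools::file_ext(path))
    dialect <- if (ext %in% c("gb", "gbk", "genbank")) "genbank"
               else "fasta+tsv"
  }
  if (dialect == "genbank") return(.readGenbank(path))
  .readFastaTsv(path, features_path, topology)
}

.readFastaTsv <- function(path, features_path, topology) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) != 1L)
    stop("expected exactly one sequence in ", path)
  id <- strsplit(names(ss)[1], "\\s+")[[1L]][1L]
  if (grepl("topology=linear", names(ss)[1])) topology <- "linear"
  if (grepl("topology=circular", names(ss)[1])) topology <- "circular"
  seq <- toupper(as.character(ss[[1L]]))
  if (nchar(seq) == 0L) stop("empty sequence in ", path)
  checkBases(seq)
  if (is.null(features_path))
    features_path <- paste0(tools::file_path_sans_ext(path), ".tsv")
  tab <- read.delim(features_path, stringsAsFactors = FALSE)
  req <- c("gene", "kind", "strand", "start", "end")
  if (!all(req %in% names(tab)))
    stop("feature table must have columns: ", paste(req, collapse = ", "))
  ## rows sharing gene+kind are exons of one feature
  fid <- paste(tab$gene, tab$kind, sep = "|")
  df <- data.frame(feature_id = fid, kind = mapply(.kindFromKey, tab$kind,
                                                   tab$gene),
                   gene_name = tab$gene, strand = tab$strand,
                   start = as.integer(tab$start), end = as.integer(tab$end),
                   stringsAsFactors = FALSE)
  ## collapse multi-row features: each row becomes >=1 interval
  gr <- .featureGRanges(df, nchar(seq), topology, id)
  .checkExonOverlap(gr)
  MitoGenome(id, seq, topology, gr)
}

## Minimal GenBank flat-file reader: LOCUS line (length, topology),
## FEATURES table locations (n..m, complement(...), join(...)), ORIGIN
## sequence block. No installed R package parses this format, hence the
## hand-written reader; it covers the subset this package emits/needs.
.readGenbank <- function(path) {
  lines <- readLines(path)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (!length(locus)) stop("no LOCUS line in ", path)
  topo <- if (grepl("circular", locus[1], ignore.case = TRUE))
    "circular" else "linear"
  id <- strsplit(trimws(sub("^LOCUS", "", locus[1])), "\\s+")[[1L]][1L]
  o <- grep("^ORIGIN", lines)
  if (!length(o)) stop("no ORIGIN block in ", path)
  seq_lines <- lines[(o[1] + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  seq <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (nchar(seq) == 0L) stop("empty sequence in ", path)
  checkBases(seq)
  f0 <- grep("^FEATURES", lines)
  feats <- list()
  if (length(f0)) {
    block <- lines[(f0[1] + 1L):(o[1] - 1L)]
    ## a new feature starts at column 6 with a key
    starts <- grep("^ {5}\\S", block)
    for (k in seq_along(starts)) {
      from <- starts[k]
      to <- if (k < length(starts)) starts[k + 1L] - 1L else length(block)
      chunk <- block[from:to]
      key <- sub("^\\s*(\\S+).*", "\\1", chunk[1])
      loc <- sub("^\\s*\\S+\\s+", "", chunk[1])
      ## location may continue on lines without a '/'
      i <- 2L
      while (i <= length(chunk) && !grepl("^\\s+/", chunk[i])) {
        loc <- paste0(loc, trimws(chunk[i])); i <- i + 1L
      }
      quals <- chunk[grepl("^\\s+/", chunk)]
      getq <- function(nm) {
        hit <- grep(paste0("^\\s*/", nm, "="), quals, value = TRUE)
        if (!length(hit)) return(NA_character_)
        gsub("\"", "", sub(paste0("^\\s*/", nm, "="), "", hit[1]))
      }
      gene <- getq("gene")
      if (is.na(gene)) gene <- getq("product")
      if (is.na(gene)) gene <- getq("label")
      if (is.na(gene)) gene <- key
      if (key %in% c("source")) next
      feats[[length(feats) + 1L]] <-
        list(key = key, loc = loc, gene = gene)
    }
  }
  df_rows <- list()
  for (ft in feats) {
    p <- .parseGenbankLocation(ft$loc)
    kind <- .kindFromKey(ft$key, ft$gene)
    fid <- paste(ft$gene, kind, length(df_rows) + 1L, sep = "|")
    for (iv in p$intervals) {
      if (iv[1] > nchar(seq) || iv[2] > nchar(seq))
        stop(sprintf("feature '%s' coordinate %d beyond sequence end %d",
                     ft$gene, max(iv), nchar(seq)))
      df_rows[[length(df_rows) + 1L]] <- data.frame(
        feature_id = fid, kind = kind, gene_name = ft$gene,
        strand = p$strand, start = iv[1], end = iv[2],
        stringsAsFactors = FALSE)
    }
  }
  gr <- if (length(df_rows)) {
    df <- do.call(rbind, df_rows)
    ## intervals already split; construct directly (wrap already explicit)
    g <- GenomicRanges::GRanges(seqnames = id,
      ranges = IRanges::IRanges(df$start, df$end), strand = df$strand,
      feature_id = df$feature_id, kind = df$kind, gene_name = df$gene_name)
    g
  } else {
    GenomicRanges::GRanges(feature_id = character(), kind = character(),
                           gene_name = character())
  }
  .checkExonOverlap(gr)
  MitoGenome(id, seq, topo, gr)
}

.parseGenbankLocation <- function(loc) {
  loc <- gsub("\\s", "", loc)
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  parts <- strsplit(loc, ",", fixed = TRUE)[[1L]]
  ivs <- lapply(parts, function(p) {
    m <- regmatches(p, regexec("^<?(\\d+)\\.\\.>?(\\d+)$", p))[[1L]]
    if (length(m) == 3L) return(as.integer(m[2:3]))
    if (grepl("^\\d+$", p)) return(rep(as.integer(p), 2L))
    stop("cannot parse GenBank location part: ", p)
  })
  list(strand = strand, intervals = ivs)
}

#' Write a genome as FASTA plus a feature TSV
#'
#' Inverse of \code{\link{readGenome}}'s \code{fasta+tsv} dialect: the
#' FASTA header carries the topology, and multi-interval features are
#' written back as wrapping rows (start > end) where they wrap the
#' origin, so that a read/write round trip reproduces intervals exactly.
#'
#' @param g a \linkS4class{MitoGenome}.
#' @param fasta_path,tsv_path output paths.
#' @return invisibly, the two paths.
#' @export
writeGenome <- function(g, fasta_path, tsv_path = NULL) {
  if (is.null(tsv_path))
    tsv_path <- paste0(tools::file_path_sans_ext(fasta_path), ".tsv")
  ss <- Biostrings::DNAStringSet(g@sequence)
  names(ss) <- paste0(g@id, " topology=", g@topology)
  Biostrings::writeXStringSet(ss, fasta_path, width = 70L)
  f <- g@features
  n <- genomeLength(g)
  rows <- list()
  if (length(f)) {
    for (fid in unique(S4Vectors::mcols(f)$feature_id)) {
      sub <- f[S4Vectors::mcols(f)$feature_id == fid]
      st <- GenomicRanges::start(sub); en <- GenomicRanges::end(sub)
      kind <- S4Vectors::mcols(sub)$kind[1]
      gene <- S4Vectors::mcols(sub)$gene_name[1]
      strand <- as.character(GenomicRanges::strand(sub))[1]
      ## re-fuse an origin-wrapping pair into one start>end row
      if (length(sub) == 2L && g@topology == "circular" &&
          en[1] == n && st[2] == 1L) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene = gene, kind = kind, strand = strand,
          start = st[1], end = en[2], stringsAsFactors = FALSE)
      } else {
        o <- order(st)
        rows[[length(rows) + 1L]] <- data.frame(
          gene = gene, kind = kind, strand = strand,
          start = st[o], end = en[o], stringsAsFactors = FALSE)
      }
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(), kind = character(),
               strand = character(), start = integer(), end = integer())
  write.table(tab, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta = fasta_path, tsv = tsv_path))
}

#' Intergenic intervals of a genome
#'
#' The complement, on the circle (or line), of all gene and intron
#' intervals: the raw material for GC-cluster / AT-spacer context and
#' the "intergenic" part of the genome partition.
#'
#' @param g a \linkS4class{MitoGenome}.
#' @param include named kinds counted as genic; defaults to gene exons,
#'   tRNA, rRNA, RNase-P RNA and introns.
#' @return an \code{IRanges} of intergenic intervals (1-based closed).
#' @export
intergenicRegions <- function(g, include = c(GENE_KINDS, "intron")) {
  n <- genomeLength(g)
  f <- g@features
  keep <- S4Vectors::mcols(f)$kind %in% include
  ir <- IRanges::reduce(IRanges::ranges(f[keep]))
  IRanges::setdiff(IRanges::IRanges(1L, n), ir)
}
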