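## Synthetic annotated mitochondrial genomes with known architecture
## and rearrangement history.

#' The standard yeast mitochondrial gene complement
#'
#' 35 genes: 8 protein-coding (cox1-3, cob, atp6/8/9, var1), 2 rRNAs
#' (rnl, rns), the RNase P RNA (rpm1) and 24 tRNAs, with typical
#' lengths, listed in the canonical block order.
#'
#' @return data.frame with columns gene, kind, length.
#' @export
yeastGeneComplement <- function() {
  trna <- function(x) data.frame(gene = paste0("trn", x), kind = "trna",
                                 length = 75L, stringsAsFactors = FALSE)
  rbind(
    data.frame(gene = "rnl", kind = "rrna", length = 4439L),
    trna(c("T2", "C", "H", "L", "Q", "K", "R1", "G", "D", "S1", "R2",
           "A", "I", "Y", "N", "M1")),
    data.frame(gene = "cox2", kind = "gene_exon", length = 750L),
    trna(c("F", "T1", "V")),
    data.frame(gene = "cox3", kind = "gene_exon", length = 810L),
    trna("M2"),
    data.frame(gene = "rpm1", kind = "rnap", length = 450L),
    trna("P"),
    data.frame(gene = "cox1", kind = "gene_exon", length = 1530L),
    data.frame(gene = "atp8", kind = "gene_exon", length = 147L),
    data.frame(gene = "atp6", kind = "gene_exon", length = 780L),
    trna("E"),
    data.frame(gene = "cob", kind = "gene_exon", length = 1158L),
    data.frame(gene = "rns", kind = "rrna", length = 1649L),
    trna("W"),
    data.frame(gene = "atp9", kind = "gene_exon", length = 231L),
    trna("S2"),
    data.frame(gene = "var1", kind = "gene_exon", length = 1200L))
}

#' The seven syntenic blocks of the yeast mitochondrial genome
#'
#' Runs of genes inherited as units (transcriptional blocks); jointly
#' they contain all 35 genes of the complement.
#'
#' @return named list of character vectors.
#' @export
syntenicBlocks <- function() {
  list(
    block1 = c("rnl", paste0("trn", c("T2", "C", "H", "L", "Q", "K", "R1",
                                      "G", "D", "S1", "R2", "A", "I", "Y",
                                      "N", "M1")), "cox2"),
    block2 = c("trnF", "trnT1", "trnV", "cox3"),
    block3 = c("trnM2", "rpm1", "trnP"),
    block4 = c("cox1", "atp8", "atp6"),
    block5 = c("trnE", "cob"),
    block6 = c("rns", "trnW"),
    block7 = c("atp9", "trnS2", "var1"))
}

#' Default 15-taxon phylogeny for simulations
#'
#' A Newick tree shaped like the usual yeast mitochondrial phylogeny:
#' a five-species sensu-stricto clade plus ten relatives, with branch
#' lengths in substitutions/site-scale units. Unrooted it has 27
#' branches.
#'
#' @return Newick string.
#' @export
defaultTree <- function() {
  paste0("((Scer:0.05,Spar:0.06):0.03,((Smik:0.07,(Skud:0.06,",
         "Suva:0.08):0.02):0.03,((((Cgla:0.25,Ndel:0.22):0.08,",
         "(Ccas:0.20,Nbac:0.28):0.06):0.05,(Ncas:0.18,Kser:0.16):0.07)",
         ":0.04,(((Lklu:0.12,Lthe:0.10):0.04,Ldas:0.11):0.03,",
         "Lmey:0.13):0.10):0.05):0.02);")
}

## Default GC-cluster family consensus sequences: a GC-rich core
## (one A/T every 8th base, so every 16-mer core window carries 14 GC
## -- two mutations above the 0.75 detection threshold) flanked by
## short A/T margins, as in published cluster consensus sequences
## whose edges fade into the AT background. The margins absorb the
## boundary creep of window-coverage detection, so the detected extent
## closely matches the planted element. famP is a perfect DNA
## palindrome.
.defaultClusterFamilies <- function() {
  c(famA = paste0("AATAT", "GGCCGCGACCGGCGCTGCGGCCGACGCCGGCTGGCGCGCA",
                  "TATAA"),
    famB = paste0("AATA", "CCGGCGCTGGCCGCCACGGGCGGTCCGCGCGA", "ATAA"),
    famC = paste0("TAAT", "GCGCGGGTCGCCGCCAGGCGGGCT", "TTAA"),
    famP = paste0("AT", "GGGCCGCGTATACGCGGCCC", "AT"))
}

## Default intron loci: ten candidate loci in cox1, seven in cob, one
## in rnl, at fixed intron-free coding offsets.
.defaultIntronLoci <- function() {
  rbind(
    data.frame(host_gene = "cox1", ordinal = 1:10,
               site = c(168L, 312L, 450L, 579L, 708L, 852L, 996L,
                        1125L, 1254L, 1380L),
               group = c("II", "II", "I", "I", "I", "I", "I", "I", "I",
                         "II"),
               has_orf = c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, TRUE,
                           TRUE, TRUE, FALSE),
               length = c(2100L, 2450L, 1500L, 1320L, 1800L, 1650L,
                          1750L, 1600L, 1450L, 1150L),
               stringsAsFactors = FALSE),
    data.frame(host_gene = "cob", ordinal = 1:7,
               site = c(131L, 287L, 429L, 575L, 712L, 850L, 985L),
               group = c("I", "I", "II", "I", "I", "I", "I"),
               has_orf = c(FALSE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE),
               length = c(1250L, 1400L, 1300L, 1500L, 1350L, 1200L,
                          1100L),
               stringsAsFactors = FALSE),
    data.frame(host_gene = "rnl", ordinal = 1L, site = 2716L,
               group = "I", has_orf = TRUE, length = 1100L,
               stringsAsFactors = FALSE))
}

#' Simulation configuration
#'
#' Defaults emulate a compact AT-rich yeast mitochondrial genome:
#' ~80\% AT background, the 35-gene complement in block order, 1-8 ori
#' elements, free-standing intergenic ORFs, GC-cluster insertions
#' drawn from consensus families, near-pure-AT spacers, optional
#' introns in cox1/cob/rnl, and gene orders evolved along the tree by
#' Poisson numbers of inversions and transpositions per branch.
#'
#' @param seed RNG seed (integer).
#' @param tree Newick string, file or phylo object.
#' @param target_at_fraction background AT fraction outside inserted
#'   elements (default 0.80).
#' @param ... overrides of nested defaults, e.g.
#'   \code{rearrangement = list(inv_intensity = 0)}; unnamed parts of a
#'   nested list keep their defaults.
#' @return config list of class \code{mitoarch_sim_config}.
#' @export
simConfig <- function(seed = 1L, tree = defaultTree(),
                      target_at_fraction = 0.80, ...) {
  cfg <- list(
    seed = as.integer(seed),
    tree = tree,
    target_at_fraction = target_at_fraction,
    genes = yeastGeneComplement(),
    intergenic = list(filler_len_range = c(450L, 1600L),
                      spacer_slot_prob = 0.2,
                      spacer_len_range = c(150L, 800L),
                      spacer_gc = 0.02,
                      orf_count_range = c(0L, 3L),
                      orf_len_range = c(300L, 900L)),
    ori = list(count_range = c(1L, 8L), length = 280L),
    gc_cluster = list(families = .defaultClusterFamilies(),
                      root_count_range = c(30L, 60L),
                      mut_rate = 0.01, gain_rate = 8, loss_rate = 0.2),
    intron = list(loci = .defaultIntronLoci(), presence_prob = 0.35,
                  flank_mut_rate = 0.02),
    mut = list(subst_rate = 0.01),
    rearrangement = list(inv_intensity = 1.0, trans_intensity = 1.5))
  ov <- list(...)
  for (nm in names(ov)) {
    if (is.list(cfg[[nm]]) && is.list(ov[[nm]]) &&
        !is.data.frame(ov[[nm]])) {
      for (k in names(ov[[nm]])) cfg[[nm]][[k]] <- ov[[nm]][[k]]
    } else cfg[[nm]] <- ov[[nm]]
  }
  stopifnot(cfg$target_at_fraction > 0, cfg$target_at_fraction < 1,
            cfg$intron$presence_prob >= 0, cfg$intron$presence_prob <= 1,
            nrow(cfg$genes) > 0L)
  class(cfg) <- "mitoarch_sim_config"
  cfg
}

.randSeq <- function(n, gc) {
  if (n <= 0L) return("")
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

## Random composition of `total` into `parts` pieces, each >= min_part
## (falling back to a near-even split when total is too small).
.randComposition <- function(total, parts, min_part = 20L) {
  if (parts == 1L) return(total)
  spare <- total - parts * min_part
  if (spare < parts) {
    lens <- rep(total %/% parts, parts)
    lens[seq_len(total %% parts)] <- lens[seq_len(total %% parts)] + 1L
    return(lens)
  }
  cuts <- sort(sample.int(spare - 1L, parts - 1L))
  min_part + diff(c(0L, cuts, spare))
}

.mutateSeq <- function(seq, p) {
  n <- nchar(seq)
  if (n == 0L || p <= 0) return(seq)
  k <- rbinom(1L, n, min(1, p))
  if (k == 0L) return(seq)
  pos <- sample.int(n, k)
  v <- strsplit(seq, "", fixed = TRUE)[[1L]]
  for (i in pos) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1L)
  paste(v, collapse = "")
}

## Arc helpers on circular orders (vectors of gene names + signs).
.applyInversion <- function(ord, sg, s, len) {
  U <- length(ord)
  idx <- ((s - 1L + 0:(len - 1L)) %% U) + 1L
  ord[idx] <- rev(ord[idx])
  sg[idx] <- -rev(sg[idx])
  list(ord = ord, sg = sg)
}

.applyTransposition <- function(ord, sg, s, len, ins) {
  U <- length(ord)
  idx <- ((s - 1L + 0:(len - 1L)) %% U) + 1L
  rest <- setdiff(seq_len(U), idx)
  ro <- ord[rest]; rs <- sg[rest]
  ## ins in 0..length(rest): insert after position ins of the remainder
  ord2 <- append(ro, ord[idx], after = ins)
  sg2 <- append(rs, sg[idx], after = ins)
  list(ord = ord2, sg = sg2)
}

## One evolutionary step along a branch of length bl for a signed
## order; returns new order plus event counts.
.evolveOrder <- function(ord, sg, bl, inv_i, trans_i) {
  U <- length(ord)
  k_inv <- rpois(1L, inv_i * bl)
  k_tr <- rpois(1L, trans_i * bl)
  todo <- sample(rep(c("inv", "tr"), c(k_inv, k_tr)))
  for (ev in todo) {
    s <- sample.int(U, 1L)
    len <- sample.int(U - 1L, 1L)
    if (ev == "inv") {
      r <- .applyInversion(ord, sg, s, len)
    } else {
      ins <- sample.int(U - len + 1L, 1L) - 1L
      r <- .applyTransposition(ord, sg, s, len, ins)
    }
    ord <- r$ord; sg <- r$sg
  }
  list(ord = ord, sg = sg, inv = k_inv, trans = k_tr)
}

.branchIntensity <- function(spec, label) {
  if (length(spec) == 1L && is.null(names(spec))) return(as.numeric(spec))
  if (label %in% names(spec)) return(as.numeric(spec[[label]]))
  0
}

#' Evolve signed gene orders along a tree
#'
#' Lightweight gene-order-only simulation: the root order is the
#' identity over the given markers; along each branch, Poisson
#' (intensity x branch length) numbers of inversions (random arc,
#' signs flipped) and transpositions (random arc excised and
#' reinserted) are applied. Intensities may be scalars or named
#' vectors over \code{\link{branchLabels}}.
#'
#' @param tree phylo/Newick.
#' @param markers marker names (or an integer count).
#' @param inv_intensity,trans_intensity events per unit branch length.
#' @return list: \code{orders} (leaf \linkS4class{GeneOrder}s),
#'   \code{node_orders} (all nodes, signed marker strings),
#'   \code{events} (per-branch data.frame: branch, inversions,
#'   transpositions, branch_length).
#' @export
simulateGeneOrders <- function(tree, markers = 20L, inv_intensity = 1.0,
                               trans_intensity = 1.5) {
  tr <- .unrootSafe(.asPhylo(tree))
  if (is.numeric(markers) && length(markers) == 1L)
    markers <- sprintf("m%02d", seq_len(markers))
  labels <- branchLabels(tr)
  ntip <- length(tr$tip.label)
  root <- ntip + 1L
  kids <- split(seq_len(nrow(tr$edge)), tr$edge[, 1L])
  orders <- list(); node_orders <- list()
  ev <- data.frame(branch = labels, inversions = 0L, transpositions = 0L,
                   branch_length = tr$edge.length,
                   stringsAsFactors = FALSE)
  recurse <- function(node, ord, sg) {
    node_orders[[paste0("n", node)]] <<-
      paste0(ifelse(sg < 0, "-", "+"), ord)
    for (e in kids[[as.character(node)]]) {
      child <- tr$edge[e, 2L]
      st <- .evolveOrder(ord, sg, tr$edge.length[e],
                         .branchIntensity(inv_intensity, labels[e]),
                         .branchIntensity(trans_intensity, labels[e]))
      ev$inversions[e] <<- st$inv
      ev$transpositions[e] <<- st$trans
      if (child <= ntip) {
        tipn <- tr$tip.label[child]
        orders[[tipn]] <<- GeneOrder(tipn, st$ord, st$sg)
        node_orders[[tipn]] <<- paste0(ifelse(st$sg < 0, "-", "+"), st$ord)
      } else {
        recurse(child, st$ord, st$sg)
      }
    }
  }
  recurse(root, markers, rep(1L, length(markers)))
  list(orders = orders, node_orders = node_orders, events = ev)
}

#' Simulate annotated mitochondrial genomes along a tree
#'
#' Builds a root genome from the configured gene complement plus
#' AT-rich intergenic sequence carrying planted spacers, ori elements,
#' free-standing ORFs and GC-cluster insertions; evolves it along the
#' (unrooted) tree by per-branch point substitutions, GC-cluster gain
#' and loss, and gene-order rearrangements; samples intron presence
#' per leaf; and assembles one annotated \linkS4class{MitoGenome} per
#' leaf together with full ground truth. Identical seeds give
#' identical output.
#'
#' @param cfg a \code{\link{simConfig}}.
#' @return list with \code{genomes} (named list of
#'   \linkS4class{MitoGenome}; gene, intron, ori and ORF features
#'   annotated, GC clusters and AT spacers left for detection),
#'   \code{truth} (orders, node_orders, events, clusters, spacers,
#'   introns) and \code{config}.
#' @export
simulateGenomes <- function(cfg = simConfig()) {
  stopifnot(inherits(cfg, "mitoarch_sim_config"))
  set.seed(cfg$seed)
  tr <- .unrootSafe(.asPhylo(cfg$tree))
  labels <- branchLabels(tr)
  ntip <- length(tr$tip.label)
  root <- ntip + 1L
  kids <- split(seq_len(nrow(tr$edge)), tr$edge[, 1L])
  gc_bg <- 1 - cfg$target_at_fraction
  genes <- cfg$genes
  G <- nrow(genes)

  ## ---- root state ----
  gene_seq <- setNames(vapply(genes$length, .randSeq, character(1),
                              gc = gc_bg), genes$gene)
  loci <- cfg$intron$loci
  loci$locus_id <- sprintf("%s_%d", loci$host_gene, loci$ordinal)
  intron_seq <- setNames(vapply(loci$length, .randSeq, character(1),
                                gc = gc_bg), loci$locus_id)
  ## slots: one intergenic region after each gene
  slots <- vector("list", G)
  names(slots) <- genes$gene
  rng <- function(r) if (r[1] >= r[2]) r[1] else sample(r[1]:r[2], 1L)
  ## a fraction of slots are AT spacers: whole intergenic regions of
  ## near-pure A/T, as between most yeast mitochondrial genes
  for (i in seq_len(G))
    slots[[i]] <- list(elems = list(),
                       spacer = runif(1) < cfg$intergenic$spacer_slot_prob)
  ## oris, free ORFs and root GC clusters into random slots
  n_ori <- rng(cfg$ori$count_range)
  ori_slots <- sample.int(G, min(n_ori, G))
  for (s in ori_slots) {
    core <- .randSeq(cfg$ori$length, 0.05)  # near-pure AT ori core
    slots[[s]]$elems[[length(slots[[s]]$elems) + 1L]] <-
      list(type = "ori", family = NA_character_, seq = core)
  }
  n_orf <- rng(cfg$intergenic$orf_count_range)
  for (s in sample.int(G, min(n_orf, G)))
    slots[[s]]$elems[[length(slots[[s]]$elems) + 1L]] <-
      list(type = "intergenic_orf", family = NA_character_,
           seq = .randSeq(rng(cfg$intergenic$orf_len_range), gc_bg))
  fams <- cfg$gc_cluster$families
  n_cl <- rng(cfg$gc_cluster$root_count_range)
  for (k in seq_len(n_cl)) {
    s <- sample.int(G, 1L)
    f <- sample(names(fams), 1L)
    slots[[s]]$elems[[length(slots[[s]]$elems) + 1L]] <-
      list(type = "gc_cluster", family = f,
           seq = .mutateSeq(fams[[f]], cfg$gc_cluster$mut_rate))
  }
  ## shuffle element order within each slot, then draw fillers
  for (i in seq_len(G)) {
    el <- slots[[i]]$elems
    sp <- slots[[i]]$spacer
    if (length(el) > 1L) el <- el[sample.int(length(el))]
    total <- rng(if (sp) cfg$intergenic$spacer_len_range
                 else cfg$intergenic$filler_len_range)
    nf <- length(el) + 1L
    lens <- .randComposition(total, nf)  # keep elements >= 20 bp apart
    slots[[i]] <- list(elems = el, spacer = sp,
                       fillers = vapply(lens, .randSeq, character(1),
                                        gc = if (sp) cfg$intergenic$spacer_gc
                                             else gc_bg))
  }
  state0 <- list(ord = genes$gene, sg = rep(1L, G), gene_seq = gene_seq,
                 intron_seq = intron_seq, slots = slots)

  ## ---- evolve along the tree ----
  ev <- data.frame(branch = labels, inversions = 0L, transpositions = 0L,
                   branch_length = tr$edge.length, stringsAsFactors = FALSE)
  leaves <- list(); node_orders <- list()
  evolveBranch <- function(st, bl, label) {
    p <- cfg$mut$subst_rate * bl
    st$gene_seq <- vapply(st$gene_seq, .mutateSeq, character(1), p = p)
    st$intron_seq <- vapply(st$intron_seq, .mutateSeq, character(1), p = p)
    for (i in seq_along(st$slots)) {
      sl <- st$slots[[i]]
      sl$fillers <- vapply(sl$fillers, .mutateSeq, character(1), p = p,
                           USE.NAMES = FALSE)
      drop <- logical(length(sl$elems))
      for (k in seq_along(sl$elems)) {
        sl$elems[[k]]$seq <- .mutateSeq(sl$elems[[k]]$seq, p)
        if (sl$elems[[k]]$type == "gc_cluster" &&
            runif(1) < min(1, cfg$gc_cluster$loss_rate * bl))
          drop[k] <- TRUE
      }
      if (any(drop)) {
        for (k in rev(which(drop))) {
          sl$fillers[k] <- paste0(sl$fillers[k], sl$fillers[k + 1L])
          sl$fillers <- sl$fillers[-(k + 1L)]
          sl$elems <- sl$elems[-k]
        }
      }
      st$slots[[i]] <- sl
    }
    gains <- rpois(1L, cfg$gc_cluster$gain_rate * bl)
    for (g in seq_len(gains)) {
      s <- sample.int(length(st$slots), 1L)
      f <- sample(names(fams), 1L)
      sl <- st$slots[[s]]
      elig <- which(nchar(sl$fillers) >= 45L)  # keep 20 bp clearance
      if (!length(elig)) next
      fi <- if (length(elig) == 1L) elig else sample(elig, 1L)
      fl <- sl$fillers[fi]
      cut <- sample(20L:(nchar(fl) - 20L), 1L)
      new_el <- list(type = "gc_cluster", family = f,
                     seq = .mutateSeq(fams[[f]], cfg$gc_cluster$mut_rate))
      sl$elems <- append(sl$elems, list(new_el), after = fi - 1L)
      sl$fillers <- append(sl$fillers[-fi],
                           c(substr(fl, 1L, cut),
                             substr(fl, cut + 1L, nchar(fl))),
                           after = fi - 1L)
      st$slots[[s]] <- sl
    }
    r <- .evolveOrder(st$ord, st$sg, bl,
                      .branchIntensity(cfg$rearrangement$inv_intensity,
                                       label),
                      .branchIntensity(cfg$rearrangement$trans_intensity,
                                       label))
    st$ord <- r$ord; st$sg <- r$sg
    list(state = st, inv = r$inv, trans = r$trans)
  }
  recurse <- function(node, st) {
    node_orders[[paste0("n", node)]] <<-
      paste0(ifelse(st$sg < 0, "-", "+"), st$ord)
    for (e in kids[[as.character(node)]]) {
      child <- tr$edge[e, 2L]
      res <- evolveBranch(st, tr$edge.length[e], labels[e])
      ev$inversions[e] <<- res$inv
      ev$transpositions[e] <<- res$trans
      if (child <= ntip) {
        leaves[[tr$tip.label[child]]] <<- res$state
        node_orders[[tr$tip.label[child]]] <<-
          paste0(ifelse(res$state$sg < 0, "-", "+"), res$state$ord)
      } else recurse(child, res$state)
    }
  }
  recurse(root, state0)

  ## ---- assemble leaves ----
  genomes <- list(); orders <- list()
  truth_cl <- list(); truth_sp <- list(); truth_in <- list()
  kind_of <- setNames(genes$kind, genes$gene)
  for (leaf in tr$tip.label) {
    st <- leaves[[leaf]]
    present <- loci[runif(nrow(loci)) < cfg$intron$presence_prob, ,
                    drop = FALSE]
    pieces <- character(); pos <- 0L
    feat <- list(); tcl <- list(); tsp <- list()
    addFeat <- function(gene, kind, strand, start, end, fid)
      feat[[length(feat) + 1L]] <<- data.frame(
        feature_id = fid, kind = kind, gene_name = gene, strand = strand,
        start = start, end = end, stringsAsFactors = FALSE)
    for (u in seq_along(st$ord)) {
      gene <- st$ord[u]; sgn <- st$sg[u]
      strand <- if (sgn < 0) "-" else "+"
      coding <- st$gene_seq[[gene]]
      gloci <- present[present$host_gene == gene, , drop = FALSE]
      gloci <- gloci[order(gloci$site), , drop = FALSE]
      ## plus-orientation segment layout: exon/intron alternation
      segs <- list()
      prev <- 0L
      for (r in seq_len(nrow(gloci))) {
        segs[[length(segs) + 1L]] <- list(type = "exon",
          seq = substr(coding, prev + 1L, gloci$site[r]))
        segs[[length(segs) + 1L]] <- list(type = "intron",
          seq = st$intron_seq[[gloci$locus_id[r]]],
          locus = gloci$locus_id[r])
        prev <- gloci$site[r]
      }
      segs[[length(segs) + 1L]] <- list(type = "exon",
        seq = substr(coding, prev + 1L, nchar(coding)))
      region <- paste(vapply(segs, `[[`, character(1), "seq"),
                      collapse = "")
      if (sgn < 0) {
        region <- revComp(region)
        segs <- rev(segs)
        segs <- lapply(segs, function(sg_) {
          sg_$seq <- revComp(sg_$seq); sg_ })
      }
      off <- pos
      for (sg_ in segs) {
        w <- nchar(sg_$seq)
        if (w == 0L) { next }
        if (sg_$type == "exon") {
          addFeat(gene, kind_of[[gene]], strand, off + 1L, off + w,
                  paste0(gene, "|", kind_of[[gene]]))
        } else {
          addFeat(gene, "intron", strand, off + 1L, off + w,
                  paste0(gene, "|intron|", sg_$locus))
        }
        off <- off + w
      }
      pieces <- c(pieces, region)
      pos <- pos + nchar(region)
      ## intergenic slot of this gene
      sl <- st$slots[[gene]]
      addFiller <- function(f) {
        if (sl$spacer && nchar(f) > 20L)
          tsp[[length(tsp) + 1L]] <<- data.frame(
            genome_id = leaf, start = pos + 1L, end = pos + nchar(f),
            stringsAsFactors = FALSE)
        pieces <<- c(pieces, f); pos <<- pos + nchar(f)
      }
      for (k in seq_along(sl$elems)) {
        addFiller(sl$fillers[k])
        el <- sl$elems[[k]]
        w <- nchar(el$seq)
        if (el$type == "ori") {
          addFeat(paste0("ori", k, "_", gene), "ori", "+", pos + 1L,
                  pos + w, paste0("ori|", gene, "|", k))
        } else if (el$type == "intergenic_orf") {
          addFeat(paste0("orf_", gene, "_", k), "intergenic_orf", "+",
                  pos + 1L, pos + w, paste0("orf|", gene, "|", k))
        } else if (el$type == "gc_cluster") {
          tcl[[length(tcl) + 1L]] <- data.frame(
            genome_id = leaf, start = pos + 1L, end = pos + w,
            family = el$family, stringsAsFactors = FALSE)
        }
        pieces <- c(pieces, el$seq); pos <- pos + w
      }
      addFiller(sl$fillers[length(sl$fillers)])
    }
    seq <- paste(pieces, collapse = "")
    fdf <- do.call(rbind, feat)
    gr <- .featureGRanges(fdf, nchar(seq), "circular", leaf)
    genomes[[leaf]] <- MitoGenome(leaf, seq, "circular", gr)
    orders[[leaf]] <- GeneOrder(leaf, st$ord, st$sg)
    truth_cl[[leaf]] <- if (length(tcl)) do.call(rbind, tcl) else NULL
    truth_sp[[leaf]] <- if (length(tsp)) do.call(rbind, tsp) else NULL
    ## truth intron records with flank noise
    if (nrow(present)) {
      recs <- lapply(seq_len(nrow(present)), function(r) {
        gene <- present$host_gene[r]; site <- present$site[r]
        coding <- st$gene_seq[[gene]]
        f5 <- .mutateSeq(substr(coding, site - 9L, site),
                         cfg$intron$flank_mut_rate)
        f3 <- .mutateSeq(substr(coding, site + 1L, site + 10L),
                         cfg$intron$flank_mut_rate)
        cbind(intronRecords(leaf, gene, site, f5, f3,
                            group = present$group[r],
                            has_orf = present$has_orf[r]),
              true_locus = present$locus_id[r])
      })
      truth_in[[leaf]] <- do.call(rbind, recs)
    }
  }
  list(genomes = genomes,
       truth = list(orders = orders, node_orders = node_orders,
                    events = ev,
                    clusters = do.call(rbind, unname(truth_cl)),
                    spacers = do.call(rbind, unname(truth_sp)),
                    introns = do.call(rbind, unname(truth_in))),
       config = cfg)
}

#' Write simulated genomes and truth to a directory
#'
#' FASTA + feature TSV per genome (readable back with
#' \code{\link{readGenome}}), the tree, and truth tables as TSV.
#'
#' @param sim result of \code{\link{simulate}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (g in sim$genomes)
    writeGenome(g, file.path(dir, paste0(genomeID(g), ".fasta")))
  ape::write.tree(.unrootSafe(.asPhylo(sim$config$tree)),
                  file.path(dir, "tree.nwk"))
  wr <- function(x, f) if (!is.null(x))
    write.table(x, file.path(dir, f), sep = "\t", quote = FALSE,
                row.names = FALSE)
  wr(sim$truth$events, "truth_events.tsv")
  wr(sim$truth$clusters, "truth_clusters.tsv")
  wr(sim$truth$spacers, "truth_spacers.tsv")
  wr(sim$truth$introns, "truth_introns.tsv")
  writeGeneOrderTSV(sim$truth$orders, file.path(dir, "truth_orders.tsv"))
  invisible(dir)
}

#' Precision/recall of detected elements against simulation truth
#'
#' Intervals match when their reciprocal overlap reaches
#' \code{min_overlap} (both directions); matching is greedy one-to-one
#' by decreasing overlap.
#'
#' @param truth,predicted data.frames with genome_id, start, end.
#' @param min_overlap reciprocal-overlap threshold (default 0.8).
#' @return list with precision, recall, f1, n_truth, n_predicted,
#'   n_matched.
#' @export
scoreIntervals <- function(truth, predicted, min_overlap = 0.8) {
  nt <- if (is.null(truth)) 0L else nrow(truth)
  np <- if (is.null(predicted)) 0L else nrow(predicted)
  if (nt == 0L || np == 0L) {
    return(list(precision = if (np == 0L) NA_real_ else 0,
                recall = if (nt == 0L) NA_real_ else 0, f1 = 0,
                n_truth = nt, n_predicted = np, n_matched = 0L))
  }
  cand <- list()
  for (i in seq_len(nt)) {
    sel <- which(predicted$genome_id == truth$genome_id[i])
    for (j in sel) {
      ov <- min(truth$end[i], predicted$end[j]) -
        max(truth$start[i], predicted$start[j]) + 1L
      if (ov <= 0L) next
      wt <- truth$end[i] - truth$start[i] + 1L
      wp <- predicted$end[j] - predicted$start[j] + 1L
      rec <- min(ov / wt, ov / wp)
      if (rec >= min_overlap)
        cand[[length(cand) + 1L]] <- c(i = i, j = j, rec = rec)
    }
  }
  matched <- 0L
  if (length(cand)) {
    cm <- do.call(rbind, cand)
    cm <- cm[order(-cm[, "rec"]), , drop = FALSE]
    ti <- logical(nt); pj <- logical(np)
    for (r in seq_len(nrow(cm))) {
      i <- cm[r, "i"]; j <- cm[r, "j"]
      if (!ti[i] && !pj[j]) { ti[i] <- pj[j] <- TRUE; matched <- matched + 1L }
    }
  }
  precision <- matched / np
  recall <- matched / nt
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1,
       n_truth = nt, n_predicted = np, n_matched = matched)
}

#' Adjusted Rand index between two partitions
#'
#' Used to score recovered intron-locus memberships against planted
#' truth.
#'
#' @param a,b label vectors of equal length.
#' @return ARI (1 = identical partitions).
#' @export
adjustedRand <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  exp_ <- si * sj / choose(n, 2)
  max_ <- (si + sj) / 2
  if (max_ == exp_) return(1)
  (sij - exp_) / (max_ - exp_)
}
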