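## Clade simulator: evolves an annotated ancestral genome along a rooted tree,
## recording every planted event. Genomes are per-chromosome segment tables:
##   seg    ancestral segment id (novel segments get branch-scoped ids)
##   type   "gene" or "igs" (intergenic spacer)
##   family gene family id (NA for igs)
##   strand +1/-1 (genes; GFF strand)
##   orient +1/-1, orientation of the segment relative to its ancestral copy
##   seq    forward-strand genomic sequence
## Structural variants are planted in ancestral intergenic segments, at most
## one per segment per root-to-leaf lineage, so every SV has well-defined
## ancestor coordinates and alignment anchors can be derived exactly.

#' Construct a simulation configuration
#'
#' See [SimConfig-class] for the meaning of every parameter. Defaults give a
#' small clade (8 genomes, 3 chromosomes x 100 genes) with moderate gene
#' turnover, occasional rearrangements and all six SV classes.
#'
#' @param n_genomes,n_chromosomes,genes_per_chromosome,gene_length_bp,intergenic_bp
#'   genome layout.
#' @param tree rooted `phylo` with branch lengths, or `"random"`.
#' @param tree_depth root-to-leaf depth for random (Yule) trees.
#' @param rate_gene_gain,rate_gene_loss,rate_duplication events per
#'   branch-length unit.
#' @param rate_inversion,rate_fission,rate_fusion,rate_translocation expected
#'   events per branch.
#' @param sv_rates named numeric over the six SV types (events per branch).
#' @param sv_size_range,sv_in_genes,hotspot_spec,substitution_rate,
#'   promoter_deletion_spec,promoter_bp,seed see [SimConfig-class].
#' @return a validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(n_genomes = 3, genes_per_chromosome = 10, seed = 1)
#' @export
simConfig <- function(n_genomes = 8, n_chromosomes = 3,
                      genes_per_chromosome = 100, gene_length_bp = 300,
                      intergenic_bp = 2000, tree = "random", tree_depth = 1,
                      rate_gene_gain = 4, rate_gene_loss = 8,
                      rate_duplication = 0, rate_inversion = 0.5,
                      rate_fission = 0.25, rate_fusion = 0.25,
                      rate_translocation = 0.25,
                      sv_rates = c(insertion = 3, deletion = 3,
                                   tandem_expansion = 3, tandem_contraction = 3,
                                   repeat_expansion = 3, repeat_contraction = 3),
                      sv_size_range = c(50, 600), sv_in_genes = FALSE,
                      hotspot_spec = data.frame(), substitution_rate = 0.02,
                      promoter_deletion_spec = list(), promoter_bp = 1500,
                      seed = 1) {
  full <- c(insertion = 0, deletion = 0, tandem_expansion = 0,
            tandem_contraction = 0, repeat_expansion = 0,
            repeat_contraction = 0)
  full[names(sv_rates)] <- sv_rates
  new("SimConfig", n_genomes = n_genomes, n_chromosomes = n_chromosomes,
      genes_per_chromosome = genes_per_chromosome,
      gene_length_bp = gene_length_bp, intergenic_bp = intergenic_bp,
      tree = tree, tree_depth = tree_depth, rate_gene_gain = rate_gene_gain,
      rate_gene_loss = rate_gene_loss, rate_duplication = rate_duplication,
      rate_inversion = rate_inversion, rate_fission = rate_fission,
      rate_fusion = rate_fusion, rate_translocation = rate_translocation,
      sv_rates = full, sv_size_range = sv_size_range,
      sv_in_genes = sv_in_genes, hotspot_spec = hotspot_spec,
      substitution_rate = substitution_rate,
      promoter_deletion_spec = promoter_deletion_spec,
      promoter_bp = promoter_bp, seed = seed)
}

## ---- ancestral genome ----------------------------------------------------

build_ancestor <- function(cfg) {
  fam_counter <- 0L
  chroms <- list()
  for (c in seq_len(cfg@n_chromosomes)) {
    n <- cfg@genes_per_chromosome
    segs <- list()
    segs[[1L]] <- list(seg = sprintf("c%d.i%03d", c, 0L), type = "igs",
                       family = NA_character_, strand = 1L, orient = 1L,
                       seq = random_dna(cfg@intergenic_bp))
    for (g in seq_len(n)) {
      fam_counter <- fam_counter + 1L
      segs[[2L * g]] <- list(seg = sprintf("c%d.g%03d", c, g), type = "gene",
                             family = sprintf("F%05d", fam_counter),
                             strand = if (runif(1) < 0.5) 1L else -1L,
                             orient = 1L, seq = random_dna(cfg@gene_length_bp))
      segs[[2L * g + 1L]] <- list(seg = sprintf("c%d.i%03d", c, g),
                                  type = "igs", family = NA_character_,
                                  strand = 1L, orient = 1L,
                                  seq = random_dna(cfg@intergenic_bp))
    }
    chroms[[sprintf("chr%d", c)]] <- do.call(
      rbind, lapply(segs, function(s) as.data.frame(s, stringsAsFactors = FALSE)))
  }
  list(id = "ancestor", chroms = chroms, n_families = fam_counter)
}

## ancestor coordinate layout: 0-based half-open per segment
ancestor_layout <- function(anc) {
  rows <- lapply(names(anc$chroms), function(cn) {
    df <- anc$chroms[[cn]]
    len <- nchar(df$seq)
    data.frame(seg = df$seg, chrom = cn,
               start = cumsum(c(0L, len[-length(len)])),
               end = cumsum(len), len = len,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

## ---- tree handling -------------------------------------------------------

prepare_tree <- function(cfg) {
  if (is.character(cfg@tree)) {
    tree <- ape::rphylo(cfg@n_genomes, birth = 1, death = 0)
    depth <- max(ape::node.depth.edgelength(tree))
    tree$edge.length <- tree$edge.length * cfg@tree_depth / depth
    tree$tip.label <- sprintf("G%d", seq_len(cfg@n_genomes))
  } else {
    tree <- cfg@tree
  }
  if (is.null(tree$node.label) || anyNA(tree$node.label) ||
      any(tree$node.label == ""))
    tree$node.label <- sprintf("N%d", seq_len(tree$Nnode))
  tree
}

node_label <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  if (node <= n_tip) tree$tip.label[node] else tree$node.label[node - n_tip]
}

## ---- event application ---------------------------------------------------

gene_rows <- function(df) which(df$type == "gene")

apply_inversion <- function(df, i, j) {
  pos <- gene_rows(df)
  a <- pos[i]; b <- pos[j]
  slice <- df[a:b, , drop = FALSE]
  slice <- slice[rev(seq_len(nrow(slice))), , drop = FALSE]
  slice$seq <- vapply(slice$seq, revcomp_chr, "")
  slice$strand <- -slice$strand
  slice$orient <- -slice$orient
  rbind(df[seq_len(a - 1L), , drop = FALSE], slice,
        df[seq_len(nrow(df)) > b, , drop = FALSE])
}

evolve_branch <- function(genome, t_len, branch, cfg, st) {
  rec <- st$rec
  ## gene losses (a promoter-scan target family is immune, mirroring the
  ## presence of the scanned gene across the studied species)
  n_loss <- rpois(1L, cfg@rate_gene_loss * t_len)
  for (k in seq_len(n_loss)) {
    all_genes <- do.call(rbind, lapply(names(genome$chroms), function(cn) {
      df <- genome$chroms[[cn]]
      idx <- gene_rows(df)
      idx <- idx[!(df$family[idx] %in% st$protected_family)]
      if (length(idx)) data.frame(chrom = cn, row = idx) else NULL
    }))
    if (is.null(all_genes) || nrow(all_genes) == 0L) break
    pick <- all_genes[sample_int(nrow(all_genes)), ]
    fam <- genome$chroms[[pick$chrom]]$family[pick$row]
    genome$chroms[[pick$chrom]] <-
      genome$chroms[[pick$chrom]][-pick$row, , drop = FALSE]
    rec$family_events[[length(rec$family_events) + 1L]] <-
      data.frame(branch = branch, type = "loss", family = fam)
  }
  ## gene gains: each creates a new single-member family
  n_gain <- rpois(1L, cfg@rate_gene_gain * t_len)
  for (k in seq_len(n_gain)) {
    st$fam_counter <- st$fam_counter + 1L
    fam <- sprintf("F%05d", st$fam_counter)
    cn <- names(genome$chroms)[sample_int(length(genome$chroms))]
    df <- genome$chroms[[cn]]
    at <- sample_int(nrow(df) + 1L) - 1L   # insert after row `at`
    newrow <- data.frame(seg = sprintf("new.%s.%d", branch, st$fam_counter),
                         type = "gene", family = fam,
                         strand = if (runif(1) < 0.5) 1L else -1L, orient = 1L,
                         seq = random_dna(cfg@gene_length_bp),
                         stringsAsFactors = FALSE)
    genome$chroms[[cn]] <- rbind(df[seq_len(at), , drop = FALSE], newrow,
                                 df[seq_len(nrow(df)) > at, , drop = FALSE])
    rec$family_events[[length(rec$family_events) + 1L]] <-
      data.frame(branch = branch, type = "gain", family = fam)
  }
  ## duplications (default rate 0)
  n_dup <- rpois(1L, cfg@rate_duplication * t_len)
  for (k in seq_len(n_dup)) {
    cands <- do.call(rbind, lapply(names(genome$chroms), function(cn) {
      df <- genome$chroms[[cn]]
      idx <- gene_rows(df)
      idx <- idx[!(df$family[idx] %in% st$protected_family)]
      if (length(idx)) data.frame(chrom = cn, row = idx) else NULL
    }))
    if (is.null(cands)) break
    pick <- cands[sample_int(nrow(cands)), ]
    src <- genome$chroms[[pick$chrom]][pick$row, , drop = FALSE]
    src$seg <- sprintf("dup.%s.%d", branch, k)
    cn <- names(genome$chroms)[sample_int(length(genome$chroms))]
    df <- genome$chroms[[cn]]
    at <- sample_int(nrow(df) + 1L) - 1L
    genome$chroms[[cn]] <- rbind(df[seq_len(at), , drop = FALSE], src,
                                 df[seq_len(nrow(df)) > at, , drop = FALSE])
    rec$family_events[[length(rec$family_events) + 1L]] <-
      data.frame(branch = branch, type = "duplication", family = src$family)
  }
  ## chromosomal rearrangements (per-branch rates)
  n_inv <- rpois(1L, cfg@rate_inversion)
  n_fis <- rpois(1L, cfg@rate_fission)
  n_fus <- rpois(1L, cfg@rate_fusion)
  n_tra <- rpois(1L, cfg@rate_translocation)
  events <- sample(rep(c("inversion", "fission", "fusion", "translocation"),
                       c(n_inv, n_fis, n_fus, n_tra)))
  for (ev in events) {
    genome <- apply_rearrangement(genome, ev, branch, cfg, st)
  }
  ## structural variants
  for (type in SV_TYPES) {
    n_sv <- rpois(1L, cfg@sv_rates[[type]])
    for (k in seq_len(n_sv)) {
      genome <- plant_sv(genome, type, branch, cfg, st)
    }
  }
  ## Jukes-Cantor substitutions
  mu <- cfg@substitution_rate * t_len
  if (mu > 0) {
    for (cn in names(genome$chroms)) {
      genome$chroms[[cn]]$seq <-
        vapply(genome$chroms[[cn]]$seq, mutate_seq, "", rate = mu)
    }
  }
  genome
}

apply_rearrangement <- function(genome, ev, branch, cfg, st) {
  rec <- st$rec
  note <- function(type, chrom, chrom2 = NA_character_,
                   gene_from = NA_integer_, gene_to = NA_integer_) {
    rec$rearrangements[[length(rec$rearrangements) + 1L]] <-
      data.frame(branch = branch, type = type, chrom = chrom, chrom2 = chrom2,
                 gene_from = gene_from, gene_to = gene_to)
  }
  ## gene-rank positions whose neighborhood must stay intact: a promoter-scan
  ## target keeps its upstream spacer (breakpoints are redrawn around it)
  protected_ranks <- function(df) {
    pos <- gene_rows(df)
    hit <- which(df$family[pos] %in% st$protected_family)
    if (!length(hit)) return(integer())
    unique(pmax(1L, c(hit - 1L, hit, hit + 1L)))
  }
  gene_counts <- vapply(genome$chroms, function(df) length(gene_rows(df)), 0L)
  if (ev == "inversion") {
    ok <- names(gene_counts)[gene_counts >= 2L]
    if (!length(ok)) return(genome)
    cn <- ok[sample_int(length(ok))]
    g <- gene_counts[[cn]]
    guard <- protected_ranks(genome$chroms[[cn]])
    for (try in 1:10) {
      ij <- sort(sample_int(g, 2L))
      if (!any(guard >= ij[1] & guard <= ij[2])) {
        genome$chroms[[cn]] <- apply_inversion(genome$chroms[[cn]],
                                               ij[1], ij[2])
        note("inversion", cn, gene_from = ij[1], gene_to = ij[2])
        break
      }
    }
  } else if (ev == "fission") {
    ok <- names(gene_counts)[gene_counts >= 2L]
    if (!length(ok)) return(genome)
    cn <- ok[sample_int(length(ok))]
    df <- genome$chroms[[cn]]
    pos <- gene_rows(df)
    guard <- protected_ranks(df)
    for (try in 1:10) {
      k <- sample_int(length(pos) - 1L)         # split between gene k and k+1
      if (any(guard %in% c(k, k + 1L))) next
      cut <- pos[k + 1L] - 1L                   # last row staying on cn
      st$chrom_counter <- st$chrom_counter + 1L
      new_cn <- sprintf("chr%d", st$chrom_counter)
      genome$chroms[[new_cn]] <- df[seq_len(nrow(df)) > cut, , drop = FALSE]
      genome$chroms[[cn]] <- df[seq_len(cut), , drop = FALSE]
      note("fission", cn, new_cn, gene_from = k)
      break
    }
  } else if (ev == "fusion") {
    if (length(genome$chroms) < 2L) return(genome)
    pair <- sample(names(genome$chroms), 2L)
    junction <- data.frame(seg = sprintf("join.%s.%d", branch,
                                         length(rec$rearrangements) + 1L),
                           type = "igs", family = NA_character_, strand = 1L,
                           orient = 1L, seq = random_dna(cfg@intergenic_bp),
                           stringsAsFactors = FALSE)
    genome$chroms[[pair[1]]] <- rbind(genome$chroms[[pair[1]]], junction,
                                      genome$chroms[[pair[2]]])
    genome$chroms[[pair[2]]] <- NULL
    note("fusion", pair[1], pair[2])
  } else if (ev == "translocation") {
    ok <- names(gene_counts)[gene_counts >= 1L]
    if (length(genome$chroms) < 2L || !length(ok)) return(genome)
    src <- ok[sample_int(length(ok))]
    dst <- sample(setdiff(names(genome$chroms), src), 1L)
    g <- gene_counts[[src]]
    guard <- protected_ranks(genome$chroms[[src]])
    for (try in 1:10) {
      i <- sample_int(g)
      j <- min(g, i + rpois(1L, 1L))
      if (any(guard >= i & guard <= j)) next
      pos <- gene_rows(genome$chroms[[src]])
      a <- pos[i]; b <- pos[j]
      slice <- genome$chroms[[src]][a:b, , drop = FALSE]
      genome$chroms[[src]] <-
        genome$chroms[[src]][-(a:b), , drop = FALSE]
      dfd <- genome$chroms[[dst]]
      at <- sample_int(nrow(dfd) + 1L) - 1L
      genome$chroms[[dst]] <- rbind(dfd[seq_len(at), , drop = FALSE], slice,
                                    dfd[seq_len(nrow(dfd)) > at,
                                        , drop = FALSE])
      note("translocation", src, dst, gene_from = i, gene_to = j)
      break
    }
  }
  genome
}

SV_DELETION_LIKE <- c("deletion", "tandem_contraction", "repeat_contraction")

plant_sv <- function(genome, type, branch, cfg, st) {
  rec <- st$rec
  s <- as.integer(round(runif(1, cfg@sv_size_range[1], cfg@sv_size_range[2])))
  lay <- st$layout
  ## candidates: ancestral segments, unused on this lineage, long enough
  cand <- do.call(rbind, lapply(names(genome$chroms), function(cn) {
    df <- genome$chroms[[cn]]
    keep <- df$seg %in% lay$seg & !(df$seg %in% st$used_segs) &
      nchar(df$seq) >= 2L * s + 2L
    if (!cfg@sv_in_genes) keep <- keep & df$type == "igs"
    if (!any(keep)) return(NULL)
    data.frame(chrom = cn, row = which(keep), seg = df$seg[keep],
               stringsAsFactors = FALSE)
  }))
  if (is.null(cand) || nrow(cand) == 0L)
    stopf("branch %s: no segment can host a %s of %d bp", branch, type, s)
  w <- rep(1, nrow(cand))
  if (nrow(cfg@hotspot_spec)) {
    li <- match(cand$seg, lay$seg)
    mid <- (lay$start[li] + lay$end[li]) / 2
    for (h in seq_len(nrow(cfg@hotspot_spec))) {
      hs <- cfg@hotspot_spec[h, ]
      hit <- lay$chrom[li] == hs$chrom & mid >= hs$start & mid < hs$end
      w[hit] <- w[hit] * hs$multiplier
    }
  }
  pick <- cand[sample_int(nrow(cand), prob = w), ]
  df <- genome$chroms[[pick$chrom]]
  seq <- df$seq[pick$row]
  L <- nchar(seq)
  o <- sample_int(L - 2L * s + 1L) + s - 1L    # offset in [s, L - s]
  df$seq[pick$row] <- switch(
    type,
    insertion = paste0(substr(seq, 1L, o), random_dna(s),
                       substr(seq, o + 1L, L)),
    repeat_expansion = paste0(substr(seq, 1L, o), random_dna(s),
                              substr(seq, o + 1L, L)),
    tandem_expansion = paste0(substr(seq, 1L, o),
                              substr(seq, o - s + 1L, o),
                              substr(seq, o + 1L, L)),
    paste0(substr(seq, 1L, o), substr(seq, o + s + 1L, L))  # deletion-like
  )
  genome$chroms[[pick$chrom]] <- df
  ## ancestor coordinates of the event
  orient <- df$orient[pick$row]
  anc_off <- if (type %in% SV_DELETION_LIKE) {
    if (orient == 1L) o else L - o - s
  } else {
    if (orient == 1L) o else L - o
  }
  li <- match(pick$seg, lay$seg)
  anc_start <- lay$start[li] + anc_off
  anc_end <- anc_start + if (type %in% SV_DELETION_LIKE) s else 0L
  st$used_segs <- c(st$used_segs, pick$seg)
  rec$svs[[length(rec$svs) + 1L]] <-
    data.frame(branch = branch, type = type, seg = pick$seg,
               chrom = lay$chrom[li], start = anc_start, end = anc_end,
               size = s, seg_offset = anc_off)
  genome
}

## ---- promoter helpers ----------------------------------------------------

## locate a family's gene and its strand-aware upstream intergenic segment
locate_promoter <- function(genome, family, promoter_bp) {
  for (cn in names(genome$chroms)) {
    df <- genome$chroms[[cn]]
    hit <- which(df$type == "gene" & df$family == family)
    if (!length(hit)) next
    if (length(hit) > 1L)
      stopf("family %s has %d copies in %s", family, length(hit), genome$id)
    r <- hit[1L]
    if (df$strand[r] == 1L) {
      up <- rev(which(df$type == "igs" & seq_len(nrow(df)) < r))
      if (!length(up)) return(NULL)
      return(list(chrom = cn, igs_row = up[1L], side = "end", gene_row = r))
    } else {
      dn <- which(df$type == "igs" & seq_len(nrow(df)) > r)
      if (!length(dn)) return(NULL)
      return(list(chrom = cn, igs_row = dn[1L], side = "start", gene_row = r))
    }
  }
  NULL
}

## promoter as read 5'->3' towards the gene
extract_promoter <- function(genome, family, promoter_bp) {
  loc <- locate_promoter(genome, family, promoter_bp)
  if (is.null(loc)) return(NULL)
  seq <- genome$chroms[[loc$chrom]]$seq[loc$igs_row]
  L <- nchar(seq)
  w <- min(promoter_bp, L)
  if (loc$side == "end") substr(seq, L - w + 1L, L)
  else revcomp_chr(substr(seq, 1L, w))
}

apply_promoter_deletion <- function(genome, family, del_bp, promoter_bp, rec) {
  loc <- locate_promoter(genome, family, promoter_bp)
  if (is.null(loc)) {
    warnf("promoter deletion skipped: family %s has no upstream spacer in %s",
          family, genome$id)
    return(genome)
  }
  df <- genome$chroms[[loc$chrom]]
  seq <- df$seq[loc$igs_row]
  L <- nchar(seq)
  w <- min(promoter_bp, L)
  margin <- min(100L, (w - del_bp) %/% 3L)
  if (w < del_bp + 2L * margin + 2L)
    stopf("promoter of %s too short for a %d bp deletion", family, del_bp)
  off <- sample_int(w - del_bp - 2L * margin + 1L) + margin - 1L
  if (loc$side == "end") {
    p0 <- L - w          # 0-based start of promoter within the spacer
    a <- p0 + off        # deletion [a, a + del_bp) in spacer coords
  } else {
    a <- w - off - del_bp
  }
  df$seq[loc$igs_row] <- paste0(substr(seq, 1L, a),
                                substr(seq, a + del_bp + 1L, L))
  genome$chroms[[loc$chrom]] <- df
  gid <- df$gene_id[loc$gene_row] %||% NA_character_
  rec$promoter_indels[[length(rec$promoter_indels) + 1L]] <-
    data.frame(genome = genome$id, family = family,
               length = del_bp, offset = off)
  genome
}

## ---- main entry ----------------------------------------------------------

#' Simulate a clade of annotated genomes with planted truth
#'
#' Evolves an ancestral genome root-to-leaf along the configured tree. Gene
#' families are gained (as new single-member families) and lost; chromosomes
#' undergo inversion, fission, fusion and translocation; intergenic sequence
#' accumulates six classes of structural variant (optionally concentrated in
#' hotspot intervals); sequences drift under Jukes-Cantor substitutions; and
#' species-specific promoter deletions can be planted. Every realized event
#' is recorded in the returned [TruthSet]. The seed in the configuration
#' fully determines the output.
#'
#' @param config a [SimConfig-class] from [simConfig()].
#' @return a [CladeSim-class] object.
#' @examples
#' sim <- simulateClade(simConfig(n_genomes = 3, n_chromosomes = 1,
#'                                genes_per_chromosome = 12, seed = 7))
#' sim
#' @export
simulateClade <- function(config) {
  validObject(config)
  set.seed(config@seed)
  anc <- build_ancestor(config)
  layout <- ancestor_layout(anc)
  tree <- prepare_tree(config)

  rec <- new.env(parent = emptyenv())
  rec$family_events <- list(); rec$rearrangements <- list()
  rec$svs <- list(); rec$promoter_indels <- list()

  st <- new.env(parent = emptyenv())
  st$rec <- rec
  st$layout <- layout
  st$fam_counter <- anc$n_families
  st$chrom_counter <- config@n_chromosomes
  st$protected_family <- if (length(config@promoter_deletion_spec))
    config@promoter_deletion_spec$family else character()

  reserved <- character()
  pds <- config@promoter_deletion_spec
  if (length(pds)) {
    loc <- locate_promoter(anc, pds$family, config@promoter_bp)
    if (is.null(loc)) stopf("promoter target family %s not found", pds$family)
    df <- anc$chroms[[loc$chrom]]
    nb <- c(loc$igs_row, loc$gene_row + (loc$gene_row - loc$igs_row))
    reserved <- df$seg[nb[nb >= 1L & nb <= nrow(df)]]
  }

  n_tip <- length(tree$tip.label)
  tree2 <- stats::reorder(tree, "cladewise")
  genomes_at <- list()
  used_at <- list()
  root <- n_tip + 1L
  genomes_at[[root]] <- anc
  used_at[[root]] <- reserved
  leaves <- list()
  for (e in seq_len(nrow(tree2$edge))) {
    par <- tree2$edge[e, 1L]; child <- tree2$edge[e, 2L]
    branch <- node_label(tree, child)
    st$used_segs <- used_at[[par]]
    g <- genomes_at[[par]]
    g$id <- branch
    g <- evolve_branch(g, tree2$edge.length[e], branch, config, st)
    genomes_at[[child]] <- g
    used_at[[child]] <- st$used_segs
    if (child <= n_tip) leaves[[branch]] <- g
  }
  leaves <- leaves[tree$tip.label]

  ## leaf finalization: opaque gene ids + promoter deletions + family truth
  fam_rows <- list()
  for (id in names(leaves)) {
    g <- leaves[[id]]
    counter <- 0L
    for (cn in names(g$chroms)) {
      df <- g$chroms[[cn]]
      idx <- gene_rows(df)
      ids <- rep(NA_character_, nrow(df))
      if (length(idx)) {
        ids[idx] <- sprintf("%s_g%05d", id, counter + seq_along(idx))
        counter <- counter + length(idx)
        fam_rows[[length(fam_rows) + 1L]] <-
          data.frame(genome = id, gene_id = ids[idx], family_id = df$family[idx])
      }
      df$gene_id <- ids
      g$chroms[[cn]] <- df
    }
    if (length(pds) && id %in% pds$genomes) {
      g <- apply_promoter_deletion(g, pds$family, pds$length_bp,
                                   config@promoter_bp, rec)
    }
    leaves[[id]] <- g
  }

  bindrows <- function(lst, proto) {
    out <- if (length(lst)) do.call(rbind, lst) else proto
    rownames(out) <- NULL
    out
  }
  truth <- new("TruthSet",
    families = bindrows(fam_rows, data.frame(
      genome = character(), gene_id = character(), family_id = character())),
    family_events = bindrows(rec$family_events, data.frame(
      branch = character(), type = character(), family = character())),
    rearrangement_events = bindrows(rec$rearrangements, data.frame(
      branch = character(), type = character(), chrom = character(),
      chrom2 = character(), gene_from = integer(), gene_to = integer())),
    sv_events = bindrows(rec$svs, data.frame(
      branch = character(), type = character(), seg = character(),
      chrom = character(), start = integer(), end = integer(),
      size = integer(), seg_offset = integer())),
    hotspot_intervals = if (nrow(config@hotspot_spec)) config@hotspot_spec
      else data.frame(chrom = character(), start = numeric(),
                      end = numeric(), multiplier = numeric()),
    promoter_indels = bindrows(rec$promoter_indels, data.frame(
      genome = character(), family = character(), length = integer(),
      offset = integer())),
    tree = tree)

  anc$layout <- layout
  new("CladeSim", config = config, tree = tree, ancestor = anc,
      genomes = leaves, truth = truth)
}

## ---- derived views -------------------------------------------------------

genome_object <- function(sim, genome) {
  if (identical(genome, "ancestor")) return(sim@ancestor)
  if (!genome %in% names(sim@genomes)) stopf("unknown genome '%s'", genome)
  sim@genomes[[genome]]
}

#' Assembled chromosome sequences of a simulated genome
#' @param sim a [CladeSim-class].
#' @param genome a genome id (or `"ancestor"`).
#' @return a [Biostrings::DNAStringSet] named by chromosome.
#' @export
assemblySeqs <- function(sim, genome) {
  g <- genome_object(sim, genome)
  seqs <- vapply(g$chroms, function(df) paste(df$seq, collapse = ""), "")
  Biostrings::DNAStringSet(seqs)
}

#' Gene annotation table of a simulated genome
#'
#' @inheritParams assemblySeqs
#' @return data.frame with gene_id, chrom, start, end (1-based inclusive,
#'   GFF3 convention) and strand.
#' @export
geneAnnotations <- function(sim, genome) {
  g <- genome_object(sim, genome)
  rows <- lapply(names(g$chroms), function(cn) {
    df <- g$chroms[[cn]]
    len <- nchar(df$seq)
    end0 <- cumsum(len)
    start0 <- end0 - len
    idx <- gene_rows(df)
    if (!length(idx)) return(NULL)
    id <- if ("gene_id" %in% names(df)) df$gene_id[idx] else df$seg[idx]
    data.frame(gene_id = id, chrom = cn, start = start0[idx] + 1L,
               end = end0[idx], strand = ifelse(df$strand[idx] == 1L, "+", "-"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Coding sequences of a simulated genome or clade
#'
#' @param sim a [CladeSim-class].
#' @param genome a genome id, `"ancestor"`, or `NULL` for all leaves.
#' @return a `DNAStringSet` named by gene id (strand-corrected), or a named
#'   list of them.
#' @export
cdsSequences <- function(sim, genome = NULL) {
  if (is.null(genome)) {
    out <- lapply(names(sim@genomes), function(id) cdsSequences(sim, id))
    names(out) <- names(sim@genomes)
    return(out)
  }
  g <- genome_object(sim, genome)
  seqs <- character(); ids <- character()
  for (cn in names(g$chroms)) {
    df <- g$chroms[[cn]]
    idx <- gene_rows(df)
    if (!length(idx)) next
    s <- df$seq[idx]
    neg <- df$strand[idx] == -1L
    s[neg] <- vapply(s[neg], revcomp_chr, "")
    seqs <- c(seqs, s)
    ids <- c(ids, if ("gene_id" %in% names(df)) df$gene_id[idx] else df$seg[idx])
  }
  setNames(Biostrings::DNAStringSet(seqs), ids)
}

#' Promoter sequences of one gene family across genomes
#'
#' Extracts the strand-aware upstream promoter (up to `width` bp of the
#' intergenic spacer 5' of the gene) for each genome carrying the family.
#'
#' @param sim a [CladeSim-class].
#' @param family family id (as in the truth set).
#' @param genomes genome ids (default all leaves).
#' @param width promoter width; defaults to the configured `promoter_bp`.
#' @return `DNAStringSet` named by genome; genomes lacking the family are
#'   dropped.
#' @export
promoterSequences <- function(sim, family, genomes = genomeIds(sim),
                              width = sim@config@promoter_bp) {
  out <- character()
  for (id in genomes) {
    p <- extract_promoter(sim@genomes[[id]], family, width)
    if (!is.null(p)) out[[id]] <- p
  }
  Biostrings::DNAStringSet(out)
}

#' Write a simulated clade as FASTA + GFF3
#'
#' One `<genome>.fa` and `<genome>.gff3` per leaf (plus the ancestor when
#' requested), written deterministically.
#'
#' @param sim a [CladeSim-class].
#' @param dir output directory (created if needed).
#' @param include_ancestor also emit the ancestral genome.
#' @return invisibly, the vector of files written.
#' @export
writeClade <- function(sim, dir, include_ancestor = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- names(sim@genomes)
  if (include_ancestor) ids <- c(ids, "ancestor")
  files <- character()
  for (id in ids) {
    fa <- file.path(dir, paste0(id, ".fa"))
    seqs <- assemblySeqs(sim, id)
    Biostrings::writeXStringSet(seqs, fa, width = 80L)
    gff <- file.path(dir, paste0(id, ".gff3"))
    ann <- geneAnnotations(sim, id)
    con <- file(gff, "w")
    writeLines("##gff-version 3", con)
    for (cn in names(seqs))
      writeLines(sprintf("##sequence-region %s 1 %d", cn,
                         Biostrings::width(seqs)[match(cn, names(seqs))]), con)
    if (!is.null(ann) && nrow(ann)) {
      writeLines(sprintf("%s\tpanclade\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                         ann$chrom, ann$start, ann$end, ann$strand,
                         ann$gene_id), con)
    }
    close(con)
    files <- c(files, fa, gff)
  }
  invisible(files)
}

#' Planted SVs affecting one leaf genome
#'
#' Gathers the SV events on the root-to-leaf path of `genome` (events on
#' internal branches apply to every descendant leaf). Coordinates are on the
#' ancestor, 0-based half-open.
#'
#' @param truth a [TruthSet-class].
#' @param genome a leaf genome id.
#' @export
svTruthForGenome <- function(truth, genome) {
  path <- branch_path(truth@tree, genome)
  ev <- truth@sv_events
  ev[ev$branch %in% path, , drop = FALSE]
}

## labels of all branches (child nodes) on the root-to-leaf path
branch_path <- function(tree, leaf) {
  n_tip <- length(tree$tip.label)
  node <- match(leaf, tree$tip.label)
  if (is.na(node)) stopf("unknown leaf '%s'", leaf)
  path <- character()
  repeat {
    path <- c(path, node_label(tree, node))
    par <- tree$edge[tree$edge[, 2L] == node, 1L]
    if (!length(par)) break
    node <- par
  }
  path
}
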