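## Collinearity: single-copy anchors between genome pairs, chained into
## blocks by greedy longest monotone subsequence extraction in gene-rank
## space, then encoded as signed marker genomes against a pivot.

## per-genome gene ranks along chromosomes
gene_ranks <- function(ann) {
  ann <- ann[order(ann$chrom, ann$start), , drop = FALSE]
  ann$rank <- stats::ave(seq_len(nrow(ann)), ann$chrom, FUN = seq_along)
  ann
}

#' Single-copy anchors between two genomes
#'
#' An anchor is a gene family with exactly one member in each of the two
#' genomes; its coordinates are gene ranks along chromosomes.
#'
#' @param families membership data.frame from [clusterGeneFamilies()].
#' @param annotations named list of per-genome annotation data.frames
#'   (gene_id, chrom, start, end, strand), e.g. from [geneAnnotations()].
#' @param pair character vector of two genome ids (A, B).
#' @return data.frame of anchors sorted by (chrom_a, rank_a).
#' @export
findAnchors <- function(families, annotations, pair) {
  stopifnot(length(pair) == 2L)
  for (g in pair) if (!g %in% names(annotations))
    stopf("genome '%s' absent from annotations", g)
  fa <- families[families$genome == pair[1L], ]
  fb <- families[families$genome == pair[2L], ]
  single_a <- names(which(table(fa$family_id) == 1L))
  single_b <- names(which(table(fb$family_id) == 1L))
  shared <- intersect(single_a, single_b)
  fa <- fa[fa$family_id %in% shared, ]
  fb <- fb[fb$family_id %in% shared, ]
  ra <- gene_ranks(annotations[[pair[1L]]])
  rb <- gene_ranks(annotations[[pair[2L]]])
  ia <- match(fa$gene_id, ra$gene_id)
  ib <- match(fb$gene_id[match(fa$family_id, fb$family_id)], rb$gene_id)
  keep <- !is.na(ia) & !is.na(ib)
  out <- data.frame(
    family_id = fa$family_id[keep],
    chrom_a = ra$chrom[ia[keep]], rank_a = ra$rank[ia[keep]],
    strand_a = ra$strand[ia[keep]],
    chrom_b = rb$chrom[ib[keep]], rank_b = rb$rank[ib[keep]],
    strand_b = rb$strand[ib[keep]], stringsAsFactors = FALSE)
  out <- out[order(out$chrom_a, out$rank_a), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## best monotone chain under a gap cap; returns indices into df order
best_chain <- function(ra, rb, orientation, max_gap) {
  n <- length(ra)
  dp <- rep(1L, n); prev <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (ra[i] <= ra[j] || (ra[i] - ra[j]) > max_gap) next
      if (orientation > 0) {
        ok <- rb[i] > rb[j] && (rb[i] - rb[j]) <= max_gap
      } else {
        ok <- rb[i] < rb[j] && (rb[j] - rb[i]) <= max_gap
      }
      if (ok && dp[j] + 1L > dp[i]) {
        dp[i] <- dp[j] + 1L
        prev[i] <- j
      }
    }
  }
  end <- which.max(dp)
  chain <- integer()
  while (!is.na(end)) {
    chain <- c(end, chain)
    end <- prev[end]
  }
  chain
}

#' Chain anchors into collinearity blocks
#'
#' Within each chromosome pair, the longest strictly monotone run of anchors
#' (increasing on genome A; increasing or decreasing on genome B, fixing the
#' block orientation) with rank gaps at most `max_gap` on both genomes is
#' extracted greedily and repeatedly until no chain of at least `min_anchors`
#' anchors remains. Deterministic; ties prefer forward orientation, then the
#' chain starting at the smaller A-rank.
#'
#' @param anchors data.frame from [findAnchors()].
#' @param min_anchors minimum anchors per block (>= 2).
#' @param max_gap maximum rank gap between consecutive anchors in a chain.
#' @return list with `blocks` (block table with spans in gene-rank
#'   coordinates) and `anchors` (the input annotated with `block_id`).
#' @export
chainAnchors <- function(anchors, min_anchors = 5, max_gap = 25) {
  if (min_anchors < 2) stopf("min_anchors must be >= 2")
  anchors$block_id <- NA_integer_
  blocks <- list()
  bid <- 0L
  pairs <- unique(anchors[, c("chrom_a", "chrom_b")])
  pairs <- pairs[order(pairs$chrom_a, pairs$chrom_b), , drop = FALSE]
  for (p in seq_len(nrow(pairs))) {
    sel <- which(anchors$chrom_a == pairs$chrom_a[p] &
                 anchors$chrom_b == pairs$chrom_b[p] &
                 is.na(anchors$block_id))
    repeat {
      if (length(sel) < min_anchors) break
      ra <- anchors$rank_a[sel]; rb <- anchors$rank_b[sel]
      ord <- order(ra)
      fwd <- best_chain(ra[ord], rb[ord], +1, max_gap)
      rev_ <- best_chain(ra[ord], rb[ord], -1, max_gap)
      use_fwd <- length(fwd) >= length(rev_)
      chain <- if (use_fwd) fwd else rev_
      if (length(chain) < min_anchors) break
      rows <- sel[ord[chain]]
      bid <- bid + 1L
      anchors$block_id[rows] <- bid
      blocks[[bid]] <- data.frame(
        block_id = bid, chrom_a = pairs$chrom_a[p], chrom_b = pairs$chrom_b[p],
        orientation = if (use_fwd) "+" else "-", n_anchors = length(rows),
        start_a = min(anchors$rank_a[rows]), end_a = max(anchors$rank_a[rows]),
        start_b = min(anchors$rank_b[rows]), end_b = max(anchors$rank_b[rows]),
        stringsAsFactors = FALSE)
      sel <- setdiff(sel, rows)
    }
  }
  blocks <- if (length(blocks)) do.call(rbind, blocks) else
    data.frame(block_id = integer(), chrom_a = character(),
               chrom_b = character(), orientation = character(),
               n_anchors = integer(), start_a = integer(), end_a = integer(),
               start_b = integer(), end_b = integer())
  list(blocks = blocks, anchors = anchors)
}

#' Flag collinearity blocks off the dominant chromosome pairing
#'
#' For each A-chromosome the dominant partner is the B-chromosome receiving
#' the most chained anchors; blocks on any other pairing are flagged
#' disordered. Ties resolve to the lexicographically smaller B-chromosome.
#'
#' @param chained result of [chainAnchors()] for one genome pair.
#' @return the block table with a logical `disordered` column;
#'   `attr(,"n_disordered")` carries the count.
#' @export
flagDisorderedBlocks <- function(chained) {
  blocks <- chained$blocks
  anchors <- chained$anchors[!is.na(chained$anchors$block_id), , drop = FALSE]
  if (!nrow(blocks)) {
    blocks$disordered <- logical()
    attr(blocks, "n_disordered") <- 0L
    return(blocks)
  }
  tab <- as.data.frame(table(anchors$chrom_a, anchors$chrom_b),
                       stringsAsFactors = FALSE)
  names(tab) <- c("chrom_a", "chrom_b", "n")
  tab <- tab[tab$n > 0L, ]
  tab <- tab[order(tab$chrom_a, -tab$n, tab$chrom_b), ]
  dominant <- tab$chrom_b[!duplicated(tab$chrom_a)]
  names(dominant) <- tab$chrom_a[!duplicated(tab$chrom_a)]
  blocks$disordered <- blocks$chrom_b != dominant[blocks$chrom_a]
  attr(blocks, "n_disordered") <- sum(blocks$disordered)
  blocks
}

#' Encode genomes as signed orders of pivot-defined marker blocks
#'
#' Given pairwise collinearity blocks of every genome against one pivot
#' genome, the pivot's gene-rank axis is cut at all block boundaries; the
#' atomic segments covered by a block in every genome (the universal marker
#' set) become the shared blocks, numbered along the pivot. Each genome is
#' then expressed per chromosome as an ordered list of signed marker ids
#' (sign = orientation relative to the pivot).
#'
#' @param chained_list named list (by genome id, pivot excluded) of
#'   [chainAnchors()] results for pivot-vs-genome comparisons, with the pivot
#'   as genome A.
#' @param pivot pivot genome id.
#' @return list with `markers` (named list of [MarkerGenome-class], pivot
#'   first) and `segments` (marker id to pivot interval map).
#' @export
buildMarkerGenomes <- function(chained_list, pivot) {
  genomes <- names(chained_list)
  ## breakpoints on the pivot rank axis
  allb <- do.call(rbind, lapply(genomes, function(g) {
    b <- chained_list[[g]]$blocks
    if (nrow(b)) cbind(b, genome = g) else NULL
  }))
  if (is.null(allb) || !nrow(allb))
    stopf("no collinearity blocks; try a smaller min_anchors")
  segs <- list()
  for (cn in sort(unique(allb$chrom_a))) {
    bb <- allb[allb$chrom_a == cn, ]
    cuts <- sort(unique(c(bb$start_a, bb$end_a + 1L)))
    for (k in seq_len(length(cuts) - 1L)) {
      segs[[length(segs) + 1L]] <- data.frame(
        chrom = cn, from = cuts[k], to = cuts[k + 1L] - 1L,
        stringsAsFactors = FALSE)
    }
  }
  segs <- do.call(rbind, segs)
  segs <- segs[order(segs$chrom, segs$from), , drop = FALSE]

  ## per genome: covering block and local geometry of each segment
  place <- list()
  for (g in genomes) {
    ch <- chained_list[[g]]
    anc <- ch$anchors[!is.na(ch$anchors$block_id), , drop = FALSE]
    rows <- lapply(seq_len(nrow(segs)), function(s) {
      a <- anc[anc$chrom_a == segs$chrom[s] & anc$rank_a >= segs$from[s] &
               anc$rank_a <= segs$to[s], , drop = FALSE]
      if (!nrow(a)) return(NULL)
      ## covering block: the one with most anchors inside the segment
      tb <- sort(table(a$block_id), decreasing = TRUE)
      bidx <- as.integer(names(tb)[1L])
      a <- a[a$block_id == bidx, , drop = FALSE]
      blk <- ch$blocks[ch$blocks$block_id == bidx, ]
      ## segment must lie inside the block span
      if (segs$from[s] < blk$start_a || segs$to[s] > blk$end_a) return(NULL)
      a <- a[order(a$rank_a), , drop = FALSE]
      if (nrow(a) >= 2L) {
        ori <- if (a$rank_b[nrow(a)] >= a$rank_b[1L]) 1L else -1L
      } else {
        ori <- if (blk$orientation == "+") 1L else -1L
      }
      data.frame(seg = s, genome = g, chrom_b = blk$chrom_b,
                 pos = median(a$rank_b), ori = ori, stringsAsFactors = FALSE)
    })
    place[[g]] <- do.call(rbind, rows)
  }

  covered <- Reduce(intersect, lapply(place, function(df) df$seg))
  if (!length(covered))
    stopf("empty universal marker set; try a smaller min_anchors")
  covered <- sort(covered)
  marker_of_seg <- setNames(seq_along(covered), covered)

  segments <- segs[covered, , drop = FALSE]
  segments$marker <- seq_along(covered)
  rownames(segments) <- NULL

  markers <- list()
  ## pivot genome: identity order along its chromosomes
  piv_chroms <- list()
  for (cn in unique(segments$chrom))
    piv_chroms[[cn]] <- segments$marker[segments$chrom == cn]
  markers[[pivot]] <- new("MarkerGenome", genome_id = pivot,
                          chromosomes = piv_chroms)
  for (g in genomes) {
    df <- place[[g]]
    df <- df[df$seg %in% covered, , drop = FALSE]
    df$marker <- marker_of_seg[as.character(df$seg)]
    chroms <- list()
    for (cn in sort(unique(df$chrom_b))) {
      sub <- df[df$chrom_b == cn, , drop = FALSE]
      sub <- sub[order(sub$pos, sub$marker), , drop = FALSE]
      chroms[[cn]] <- as.integer(sub$marker * sub$ori)
    }
    markers[[g]] <- new("MarkerGenome", genome_id = g, chromosomes = chroms)
  }
  list(markers = markers, segments = segments)
}
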