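## Species phylogeny from single-copy gene families: Jukes-Cantor corrected
## distances from global pairwise alignments, neighbor-joining with outgroup
## rooting, and divergence-time calibration.

#' Select families single-copy in every genome
#'
#' @param members family membership table from [clusterGeneFamilies()].
#' @param cds named list (by genome) of `DNAStringSet`s named by gene id.
#' @return list with `families` (ids) and `seqs`: per family, a
#'   `DNAStringSet` with one sequence per genome (named by genome id).
#' @export
selectSingleCopy <- function(members, cds) {
  genomes <- names(cds)
  tab <- table(members$family_id, members$genome)
  ok <- rownames(tab)[apply(tab, 1L, function(x)
    all(x[genomes] == 1L))]
  if (!length(ok))
    stopf("no single-copy universal families; consider relaxing clustering")
  seqs <- lapply(setNames(nm = sort(ok)), function(f) {
    mm <- members[members$family_id == f, ]
    mm <- mm[match(genomes, mm$genome), ]
    s <- Biostrings::DNAStringSet(vapply(seq_len(nrow(mm)), function(i)
      as.character(cds[[mm$genome[i]]][[mm$gene_id[i]]]), ""))
    names(s) <- genomes
    s
  })
  list(families = sort(ok), seqs = seqs)
}

## p-distance components from global pairwise alignments of two parallel
## sequence sets: total mismatches and compared sites (gap columns excluded)
aligned_p_sets <- function(xs, ys, gap_opening = 0, gap_extension = 2) {
  mismatch <- 0; sites <- 0
  ## equal-length pairs: the optimal global alignment under these scores is
  ## gapless at the divergences considered, so compare positionally
  wx <- Biostrings::width(xs); wy <- Biostrings::width(ys)
  fast <- wx == wy
  if (any(fast)) {
    cx <- as.character(xs[fast]); cy <- as.character(ys[fast])
    for (k in seq_along(cx)) {
      a <- strsplit(cx[k], "", fixed = TRUE)[[1L]]
      b <- strsplit(cy[k], "", fixed = TRUE)[[1L]]
      mismatch <- mismatch + sum(a != b)
      sites <- sites + length(a)
    }
  }
  if (any(!fast)) {
    pa <- Biostrings::pairwiseAlignment(
      xs[!fast], ys[!fast], type = "global",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -1, baseOnly = TRUE),
      gapOpening = gap_opening, gapExtension = gap_extension)
    ap <- as.character(Biostrings::alignedPattern(pa))
    as_ <- as.character(Biostrings::alignedSubject(pa))
    for (k in seq_along(ap)) {
      a <- strsplit(ap[k], "", fixed = TRUE)[[1L]]
      b <- strsplit(as_[k], "", fixed = TRUE)[[1L]]
      keep <- a != "-" & b != "-"
      mismatch <- mismatch + sum(a[keep] != b[keep])
      sites <- sites + sum(keep)
    }
  }
  c(mismatch = mismatch, sites = sites)
}

#' Jukes-Cantor distance matrix from single-copy families
#'
#' For each genome pair, per-family p-distances from global pairwise
#' alignments are combined as a site-weighted mean (equal to the p-distance
#' of the concatenated alignment), then corrected with the Jukes-Cantor
#' formula `d = -(3/4) log(1 - 4p/3)`. Pairs with `p >= 0.75` (where the
#' correction is undefined) are set to `ceiling` with a warning.
#'
#' @param scs result of [selectSingleCopy()].
#' @param ceiling distance assigned to saturated pairs.
#' @return symmetric distance matrix with zero diagonal.
#' @export
distanceMatrix <- function(scs, ceiling = 5) {
  genomes <- names(scs$seqs[[1L]])
  n <- length(genomes)
  if (n < 2L) stopf("need at least 2 genomes")
  mism <- matrix(0, n, n, dimnames = list(genomes, genomes))
  sites <- matrix(0, n, n, dimnames = list(genomes, genomes))
  per_genome <- lapply(setNames(nm = genomes), function(g)
    Biostrings::DNAStringSet(vapply(scs$seqs, function(fs)
      as.character(fs[[g]]), "")))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      ms <- aligned_p_sets(per_genome[[i]], per_genome[[j]])
      mism[i, j] <- ms[["mismatch"]]
      sites[i, j] <- ms[["sites"]]
    }
  }
  d <- matrix(0, n, n, dimnames = list(genomes, genomes))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      p <- mism[i, j] / max(1, sites[i, j])
      if (p >= 0.75) {
        warnf("p-distance %.3f saturated for %s/%s: using ceiling %g",
              p, genomes[i], genomes[j], ceiling)
        dd <- ceiling
      } else {
        dd <- -0.75 * log(1 - 4 * p / 3)
      }
      d[i, j] <- dd; d[j, i] <- dd
    }
  }
  d
}

#' Neighbor-joining tree rooted on an outgroup
#'
#' Standard neighbor-joining with negative branch lengths clamped to zero,
#' rooted on the outgroup's pendant edge (split at its midpoint).
#'
#' @param dm symmetric distance matrix with genome names.
#' @param outgroup a leaf name in `dm`.
#' @return rooted `phylo`.
#' @export
njTree <- function(dm, outgroup) {
  if (!isSymmetric(unname(dm))) stopf("distance matrix must be symmetric")
  if (!outgroup %in% rownames(dm)) stopf("outgroup not in distance matrix")
  if (nrow(dm) == 2L) {
    other <- setdiff(rownames(dm), outgroup)
    tr <- ape::read.tree(text = sprintf("(%s:%g,%s:%g);", outgroup,
                                        dm[1, 2] / 2, other, dm[1, 2] / 2))
    return(tr)
  }
  tr <- ape::nj(dm)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr <- ape::root(tr, outgroup = outgroup, resolve.root = TRUE)
  ## place the root on the outgroup edge so that the mean root-to-leaf depth
  ## matches on both sides (clock-consistent rooting)
  n_tip <- length(tr$tip.label)
  root_node <- n_tip + 1L
  ce <- which(tr$edge[, 1L] == root_node)
  if (length(ce) == 2L) {
    out_edge <- ce[tr$edge[ce, 2L] == match(outgroup, tr$tip.label)]
    in_edge <- setdiff(ce, out_edge)
    if (length(out_edge) == 1L) {
      tot <- sum(tr$edge.length[ce])
      h <- mean_path_heights(tr)
      m <- h[tr$edge[in_edge, 2L]]     # mean depth of the ingroup node
      e_out <- min(max((tot + m) / 2, 0), tot)
      tr$edge.length[out_edge] <- e_out
      tr$edge.length[in_edge] <- tot - e_out
    }
  }
  tr
}

## node heights as mean path length to descendant leaves
mean_path_heights <- function(tr) {
  n_tip <- length(tr$tip.label)
  n_node <- n_tip + tr$Nnode
  h <- numeric(n_node)
  cnt <- integer(n_node)
  tr2 <- stats::reorder(tr, "postorder")
  sum_d <- numeric(n_node)
  cnt[seq_len(n_tip)] <- 1L
  for (e in seq_len(nrow(tr2$edge))) {
    par <- tr2$edge[e, 1L]; ch <- tr2$edge[e, 2L]
    len <- tr2$edge.length[e]
    sum_d[par] <- sum_d[par] + sum_d[ch] + cnt[ch] * len
    cnt[par] <- cnt[par] + cnt[ch]
  }
  h <- ifelse(cnt > 0, sum_d / pmax(cnt, 1L), 0)
  h[seq_len(n_tip)] <- 0
  h
}

#' Calibrate node ages on a rooted tree
#'
#' Node depths are taken as the mean root-to-leaf path length through each
#' node, scaled so that the calibration node has the stated age; leaves have
#' age zero and ultrametricity follows by construction (per-leaf
#' proportional stretching). Edge lengths of the returned tree are in age
#' units.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param calibration_node an internal node number, or a character vector of
#'   tip labels whose MRCA is the calibration node.
#' @param calibration_age_mya positive age assigned to the calibration node.
#' @return a [CalibratedTree-class].
#' @export
calibrateAges <- function(tree, calibration_node, calibration_age_mya) {
  if (calibration_age_mya <= 0) stopf("calibration age must be positive")
  n_tip <- length(tree$tip.label)
  if (is.character(calibration_node)) {
    calibration_node <- if (length(calibration_node) == 1L)
      match(calibration_node, tree$tip.label)
    else ape::getMRCA(tree, calibration_node)
  }
  if (is.na(calibration_node) || calibration_node <= n_tip)
    stopf("calibration node must be an internal node")
  h <- mean_path_heights(tree)
  if (h[calibration_node] <= 0)
    stopf("calibration node has zero depth")
  ages <- h * calibration_age_mya / h[calibration_node]
  ## enforce child age < parent age along the tree
  tr2 <- stats::reorder(tree, "cladewise")
  for (e in seq_len(nrow(tr2$edge))) {
    par <- tr2$edge[e, 1L]; ch <- tr2$edge[e, 2L]
    if (ch > n_tip && ages[ch] > ages[par]) ages[ch] <- ages[par]
  }
  out <- tree
  for (e in seq_len(nrow(out$edge))) {
    out$edge.length[e] <- ages[out$edge[e, 1L]] - ages[out$edge[e, 2L]]
  }
  names(ages) <- c(tree$tip.label,
                   sprintf("node%d", seq.int(n_tip + 1L, n_tip + tree$Nnode)))
  new("CalibratedTree", tree = out, ages = ages,
      calibration = list(node = calibration_node,
                         age = calibration_age_mya))
}

#' Age of the most recent common ancestor of a set of tips
#' @param ct a [CalibratedTree-class].
#' @param tips tip labels.
#' @return age in the calibrated units.
#' @export
mrcaAge <- function(ct, tips) {
  node <- ape::getMRCA(ct@tree, tips)
  unname(ct@ages[node])
}
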