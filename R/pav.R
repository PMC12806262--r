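## Presence/absence variation: PAV matrix construction, occupancy
## partitioning, accumulation curves, genome clustering, term enrichment.

#' Build a PAV matrix from a family membership table
#'
#' @param members data.frame (family_id, genome, gene_id) as returned by
#'   [clusterGeneFamilies()].
#' @param genomes genome ids defining the matrix columns (defaults to the
#'   genomes observed in `members`; pass explicitly if some genome
#'   contributed no genes).
#' @return a [PAVMatrix-class].
#' @export
buildPavMatrix <- function(members, genomes = NULL) {
  if (is.null(genomes)) genomes <- sort(unique(members$genome))
  fams <- unique(members$family_id)
  m <- matrix(0L, nrow = length(fams), ncol = length(genomes),
              dimnames = list(fams, genomes))
  m[cbind(match(members$family_id, fams), match(members$genome, genomes))] <- 1L
  new("PAVMatrix", presence = m, members = members)
}

#' Partition gene families by occupancy
#'
#' Families present in all genomes are `core`, in exactly one genome
#' `specific`, otherwise `variable`. The three counts always sum to the
#' family total.
#'
#' @param pav a [PAVMatrix-class].
#' @return named integer vector `c(core, variable, specific, total)`.
#' @examples
#' m <- buildPavMatrix(data.frame(
#'   family_id = c("f1", "f1", "f2"), genome = c("A", "B", "A"),
#'   gene_id = c("a1", "b1", "a2")))
#' classifyOccupancy(m)
#' @export
classifyOccupancy <- function(pav) {
  stopifnot(is(pav, "PAVMatrix"))
  m <- presence(pav)
  if (nrow(m) == 0L) stopf("empty PAV matrix")
  occ <- rowSums(m)
  if (any(occ == 0L)) stopf("zero-occupancy family row")
  n <- ncol(m)
  core <- sum(occ == n)
  spec <- if (n == 1L) core else sum(occ == 1L)
  if (n == 1L) spec <- 0L  # with one genome, everything is core
  c(core = core, variable = nrow(m) - core - spec, specific = spec,
    total = nrow(m))
}

#' Per-family occupancy class labels
#' @inheritParams classifyOccupancy
#' @return factor (`core`/`variable`/`specific`) named by family id.
#' @export
familyClass <- function(pav) {
  m <- presence(pav)
  occ <- rowSums(m)
  cls <- ifelse(occ == ncol(m), "core", ifelse(occ == 1L & ncol(m) > 1L,
                                               "specific", "variable"))
  factor(setNames(cls, rownames(m)), levels = c("core", "variable", "specific"))
}

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_permutations(n - 1L)) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos)
    }
  }
  out
}

#' Pan- and core-genome accumulation curves
#'
#' For each ordering of the genomes, `pan(k)` is the number of families seen
#' in the first `k` genomes and `core(k)` the number present in all of them.
#' Orderings are sampled uniformly (seeded) or enumerated exhaustively.
#'
#' @param pav a [PAVMatrix-class].
#' @param n_orderings number of sampled genome orderings, or `"all"` for
#'   exhaustive enumeration (requires `n! <= 10000`).
#' @param seed RNG seed for sampled orderings.
#' @return data.frame with per-k mean and sd of pan and core sizes.
#' @export
accumulationCurves <- function(pav, n_orderings = 100, seed = 1) {
  m <- presence(pav)
  if (nrow(m) == 0L) stopf("empty PAV matrix")
  n <- ncol(m)
  if (identical(n_orderings, "all")) {
    if (factorial(n) > 10000) stopf("exhaustive enumeration needs n! <= 10000")
    perms <- all_permutations(n)
  } else {
    stopifnot(n_orderings >= 1)
    set.seed(seed)
    perms <- lapply(seq_len(n_orderings), function(i) sample.int(n))
  }
  pan <- matrix(0L, length(perms), n)
  core <- matrix(0L, length(perms), n)
  for (i in seq_along(perms)) {
    A <- m[, perms[[i]], drop = FALSE]
    any_so_far <- A[, 1L]
    all_so_far <- A[, 1L]
    pan[i, 1L] <- sum(any_so_far); core[i, 1L] <- sum(all_so_far)
    for (j in seq_len(n)[-1L]) {
      any_so_far <- any_so_far | A[, j]
      all_so_far <- all_so_far & A[, j]
      pan[i, j] <- sum(any_so_far); core[i, j] <- sum(all_so_far)
    }
  }
  data.frame(k = seq_len(n),
             pan_mean = colMeans(pan), pan_sd = apply(pan, 2L, sd),
             core_mean = colMeans(core), core_sd = apply(core, 2L, sd))
}

#' Cluster genomes by their PAV profiles
#'
#' Average-linkage hierarchical clustering on the Jaccard distance between
#' genome presence/absence columns. Columns are ordered lexicographically by
#' genome id first, which fixes the dendrogram when distances tie.
#'
#' @param pav a [PAVMatrix-class] with at least two genomes.
#' @return a rooted `phylo` dendrogram (leaves = genome ids); write with
#'   [ape::write.tree()] for Newick output.
#' @export
clusterGenomesByPav <- function(pav) {
  m <- presence(pav)
  if (ncol(m) < 2L) stopf("need at least 2 genomes")
  m <- m[, order(colnames(m)), drop = FALSE]
  d <- dist(t(m), method = "binary")   # 1 - |A&B| / |A|B|
  hc <- hclust(d, method = "average")
  ape::as.phylo(hc)
}

#' Jaccard distances between genome PAV columns
#' @inheritParams clusterGenomesByPav
#' @return a symmetric matrix of Jaccard distances.
#' @export
pavDistances <- function(pav) {
  m <- presence(pav)
  as.matrix(dist(t(m[, order(colnames(m)), drop = FALSE]), method = "binary"))
}

#' Functional term enrichment by the hypergeometric test
#'
#' One-sided (upper tail) hypergeometric enrichment of each term in
#' `gene_set` against `background`, with Benjamini-Hochberg FDR control.
#' Terms with no annotated background gene are skipped.
#'
#' @param gene_set character vector of gene ids (must be a subset of
#'   `background`).
#' @param annotation data.frame with columns `gene` and `term`.
#' @param background character vector of gene ids forming the universe.
#' @return data.frame (term, n_background, n_set, fold, p, q), sorted by q
#'   then p.
#' @examples
#' ann <- data.frame(gene = c("g1", "g2", "g3", "g4"),
#'                   term = c("T1", "T1", "T1", "T2"))
#' enrichTerms(c("g1", "g2"), ann, paste0("g", 1:10))
#' @export
enrichTerms <- function(gene_set, annotation, background) {
  stopifnot(all(c("gene", "term") %in% names(annotation)))
  if (!all(gene_set %in% background))
    stopf("gene_set contains genes absent from the background")
  empty <- data.frame(term = character(), n_background = integer(),
                      n_set = integer(), fold = numeric(), p = numeric(),
                      q = numeric())
  if (!length(gene_set)) {
    warnf("empty gene set: returning no enrichment results")
    return(empty)
  }
  ann <- annotation[annotation$gene %in% background, , drop = FALSE]
  if (!nrow(ann)) stopf("annotation covers no background gene")
  N <- length(unique(background))
  n <- length(unique(gene_set))
  terms <- unique(ann$term)
  rows <- lapply(terms, function(tm) {
    hits <- unique(ann$gene[ann$term == tm])
    K <- length(hits)
    x <- sum(gene_set %in% hits)
    if (K == 0L) return(NULL)
    p <- phyper(x - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, n_background = K, n_set = x,
               fold = (x / n) / (K / N), p = p)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty)
  out$q <- p.adjust(out$p, method = "BH")
  out <- out[order(out$q, out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
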