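## Gene family clustering across genomes: k-mer Jaccard similarity with
## single-linkage connected components. Candidate pairs are pre-screened with
## sparse long-k seed matches so that only plausibly homologous pairs pay for
## an exact Jaccard computation.

kmer_codes <- function(seq, k) {
  b <- match(strsplit(seq, "", fixed = TRUE)[[1L]], DNA_BASES) - 1
  L <- length(b)
  if (L < k || anyNA(b)) {
    b <- b[!is.na(b)]
    if (length(b) < k) return(numeric())
    L <- length(b)
  }
  m <- stats::embed(b, k)[, k:1, drop = FALSE]
  unique(drop(m %*% 4^((k - 1):0)))
}

## strided seed k-mers (candidate screen only)
seed_codes <- function(seq, k, stride) {
  b <- match(strsplit(seq, "", fixed = TRUE)[[1L]], DNA_BASES) - 1
  L <- length(b)
  if (L < k) return(numeric())
  starts <- seq.int(1L, L - k + 1L, by = stride)
  vapply(starts, function(s) sum(b[s:(s + k - 1L)] * 4^((k - 1):0)), 0)
}

## union-find with path compression
uf_new <- function(n) seq_len(n)
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' Cluster genes into families across genomes
#'
#' Genes from all genomes are partitioned into families by single-linkage
#' clustering of the k-mer Jaccard similarity between coding sequences:
#' two genes are linked when their k-mer sets satisfy
#' `|intersection| / |union| >= jaccard_min`. Candidate pairs are screened
#' with sparse seed matches of length `seed_k` before the exact Jaccard is
#' computed, which does not affect results at the divergence scales the
#' screen is designed for (see the methods vignette).
#'
#' @param cds named list (by genome id) of `DNAStringSet`s named by gene id,
#'   as returned by [cdsSequences()].
#' @param k k-mer length for the Jaccard similarity.
#' @param jaccard_min linkage threshold.
#' @param seed_k,seed_stride candidate screen parameters.
#' @return data.frame (family_id, genome, gene_id); each gene belongs to
#'   exactly one family, and family ids are deterministic given input order.
#' @export
clusterGeneFamilies <- function(cds, k = 8, jaccard_min = 0.5,
                                seed_k = 16, seed_stride = 8) {
  genome <- rep(names(cds), vapply(cds, length, 0L))
  gene <- unlist(lapply(cds, names), use.names = FALSE)
  seqs <- unlist(lapply(cds, as.character), use.names = FALSE)
  n <- length(seqs)
  if (n == 0L)
    return(data.frame(family_id = character(), genome = character(),
                      gene_id = character()))
  for (gm in names(cds)) {
    if (anyDuplicated(names(cds[[gm]])))
      stopf("duplicate gene id in genome %s", gm)
  }
  if (any(nchar(seqs) == 0L)) stopf("empty gene sequence in input")

  ksets <- lapply(seqs, kmer_codes, k = k)
  ## candidate generation
  short <- which(nchar(seqs) < seed_k)
  seeds <- lapply(seqs, seed_codes, k = seed_k, stride = seed_stride)
  code <- unlist(seeds, use.names = FALSE)
  idx <- rep.int(seq_len(n), lengths(seeds))
  pairs <- NULL
  if (length(code)) {
    grp <- split(idx, code)
    grp <- grp[lengths(grp) >= 2L]
    if (length(grp)) {
      pl <- lapply(grp, function(g) {
        g <- unique(g)
        if (length(g) < 2L) return(NULL)
        t(combn(sort(g), 2L))
      })
      pairs <- unique(do.call(rbind, pl))
    }
  }
  if (length(short) >= 2L) {           # genes too short for the seed screen
    pairs <- unique(rbind(pairs, t(combn(sort(short), 2L))))
  }

  parent <- uf_new(n)
  if (!is.null(pairs) && nrow(pairs)) {
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1L]; j <- pairs[r, 2L]
      ri <- uf_find(parent, i); rj <- uf_find(parent, j)
      if (ri == rj) next
      a <- ksets[[i]]; b <- ksets[[j]]
      if (!length(a) || !length(b)) next
      ninter <- sum(a %in% b)
      jac <- ninter / (length(a) + length(b) - ninter)
      if (jac >= jaccard_min) {
        root <- min(ri, rj)
        parent[max(ri, rj)] <- root
        parent[i] <- root; parent[j] <- root
      }
    }
  }
  root <- vapply(seq_len(n), function(i) uf_find(parent, i), 0L)
  fam <- match(root, unique(root[order(seq_len(n))]))
  data.frame(family_id = sprintf("FAM%06d", fam), genome = genome,
             gene_id = gene, stringsAsFactors = FALSE)
}
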