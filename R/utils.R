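#' @importFrom methods new validObject is slot setValidity show
#' @importFrom stats dist hclust as.dist cophenetic p.adjust phyper runif
#'   rpois setNames cor median sd quantile
#' @importFrom utils head tail write.table read.table combn
#' @useDynLib panclade, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

DNA_BASES <- c("A", "C", "G", "T")

## sample() without the length-1 surprise
sample_int <- function(n, size = 1L, replace = FALSE, prob = NULL) {
  sample.int(n, size = size, replace = replace, prob = prob)
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## Jukes-Cantor point substitutions: `n_hits` Poisson-like hits, each site
## replaced by a uniformly chosen different base (multiple hits allowed).
mutate_seq <- function(seq, rate) {
  L <- nchar(seq)
  if (L == 0L || rate <= 0) return(seq)
  n_hits <- rpois(1L, rate * L)
  if (n_hits == 0L) return(seq)
  v <- strsplit(seq, "", fixed = TRUE)[[1L]]
  pos <- sample.int(L, n_hits, replace = TRUE)
  for (p in pos) {
    v[p] <- sample(setdiff(DNA_BASES, v[p]), 1L)
  }
  paste(v, collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Rand index between two partitions
#'
#' Fraction of object pairs on which two partitions agree (both together or
#' both apart). Computed from the contingency table, so it scales to large
#' partitions.
#'
#' @param a,b partition labels (same length, any atomic type).
#' @return A number in \[0, 1\].
#' @examples
#' randIndex(c(1, 1, 2, 2), c("x", "x", "y", "z"))
#' @export
randIndex <- function(a, b) {
  if (length(a) != length(b)) stopf("partitions have different lengths")
  n <- length(a)
  if (n < 2L) return(1)
  tab <- table(a, b)
  ch2 <- function(x) sum(x * (x - 1) / 2)
  sum_ij <- ch2(as.numeric(tab))
  sum_a <- ch2(as.numeric(rowSums(tab)))
  sum_b <- ch2(as.numeric(colSums(tab)))
  total <- n * (n - 1) / 2
  (total + 2 * sum_ij - sum_a - sum_b) / total
}

## deterministic per-purpose seed derived from a master seed (kept < 2^31)
derive_seed <- function(seed, salt) {
  (as.numeric(seed) * 7919 + salt * 104729) %% 2147483647
}
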