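## R-facing wrappers around the exhaustive C++ search oracles.

as_chrom_list <- function(x) {
  chroms <- x
  if (is(x, "MarkerGenome")) chroms <- x@chromosomes
  if (is(x, "AncestorGenome")) chroms <- x@cars
  lapply(unname(chroms), as.integer)
}

#' DCJ distance by breadth-first search over operations
#'
#' Exhaustive reference implementation: the minimum number of double-cut-
#' and-join operations transforming `a` into `b`, found by breadth-first
#' search over the operation space (circular intermediates allowed). Useful
#' only for small genomes; validates [dcjDistance()].
#'
#' @param a,b [MarkerGenome-class] objects (or bare chromosome lists) on the
#'   same block universe.
#' @param max_states search budget guard.
#' @return integer distance.
#' @export
dcjDistanceBfs <- function(a, b, max_states = 2e6) {
  ca <- as_chrom_list(a); cb <- as_chrom_list(b)
  n <- max(abs(unlist(c(ca, cb))))
  .dcj_bfs_cpp(ca, list(cb), as.integer(n), as.integer(max_states))[[1L]]
}

#' Exhaustive genome-median search
#'
#' Enumerates every linear multichromosomal arrangement of the block
#' universe and returns the minimum achievable total DCJ distance to the
#' input genomes, together with one optimal arrangement. Exponential in the
#' block count; intended for validating [inferMedianGenome()] on toy
#' instances (about 5 blocks or fewer).
#'
#' @param markers list of [MarkerGenome-class] objects (or chromosome lists).
#' @return list with `total` (optimal total distance) and `genome` (one
#'   optimal arrangement as a chromosome list).
#' @export
medianBruteForce <- function(markers) {
  cl <- lapply(markers, as_chrom_list)
  n <- max(abs(unlist(cl)))
  if (n > 8) stopf("brute-force median is limited to 8 blocks")
  .median_brute_force_cpp(cl, as.integer(n))
}
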