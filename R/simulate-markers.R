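## Marker-level clade simulation: evolves signed block orders (no sequence)
## along a tree. Used to exercise ancestral-genome inference with exactly
## controlled rearrangement histories.

marker_inversion <- function(chroms, cn, i, j) {
  v <- chroms[[cn]]
  chroms[[cn]] <- c(v[seq_len(i - 1L)], -rev(v[i:j]),
                    v[seq_len(length(v)) > j])
  chroms
}

marker_apply <- function(chroms, ev, next_chrom) {
  ## ev: list(type, chrom, chrom2, i, j, flip)
  if (ev$type == "inversion") {
    chroms <- marker_inversion(chroms, ev$chrom, ev$i, ev$j)
  } else if (ev$type == "fission") {
    v <- chroms[[ev$chrom]]
    chroms[[ev$chrom2]] <- v[(ev$i + 1L):length(v)]
    chroms[[ev$chrom]] <- v[seq_len(ev$i)]
  } else if (ev$type == "fusion") {
    w <- chroms[[ev$chrom2]]
    if (isTRUE(ev$flip)) w <- -rev(w)
    chroms[[ev$chrom]] <- c(chroms[[ev$chrom]], w)
    chroms[[ev$chrom2]] <- NULL
  } else if (ev$type == "translocation") {
    v <- chroms[[ev$chrom]]
    slice <- v[ev$i:ev$j]
    chroms[[ev$chrom]] <- v[-(ev$i:ev$j)]
    w <- chroms[[ev$chrom2]]
    at <- ev$at
    chroms[[ev$chrom2]] <- append(w, slice, after = at)
    if (!length(chroms[[ev$chrom]])) chroms[[ev$chrom]] <- NULL
  }
  chroms
}

draw_marker_event <- function(chroms, probs, next_chrom) {
  sizes <- lengths(chroms)
  ok <- character()
  if (any(sizes >= 2L)) ok <- c(ok, "inversion", "fission")
  if (length(chroms) >= 2L) ok <- c(ok, "fusion")
  if (length(chroms) >= 2L && any(sizes >= 2L)) ok <- c(ok, "translocation")
  ok <- intersect(names(probs)[probs > 0], ok)
  if (!length(ok)) return(NULL)
  type <- if (length(ok) == 1L) ok else
    sample(ok, 1L, prob = probs[ok] / sum(probs[ok]))
  if (type == "inversion") {
    cand <- names(chroms)[sizes >= 2L]
    cn <- if (length(cand) == 1L) cand else sample(cand, 1L)
    ij <- sort(sample_int(length(chroms[[cn]]), 2L))
    list(type = type, chrom = cn, chrom2 = NA, i = ij[1], j = ij[2])
  } else if (type == "fission") {
    cand <- names(chroms)[sizes >= 2L]
    cn <- if (length(cand) == 1L) cand else sample(cand, 1L)
    list(type = type, chrom = cn, chrom2 = sprintf("chr%d", next_chrom),
         i = sample_int(length(chroms[[cn]]) - 1L))
  } else if (type == "fusion") {
    pair <- sample(names(chroms), 2L)
    list(type = type, chrom = pair[1], chrom2 = pair[2],
         flip = runif(1) < 0.5)
  } else {
    cand <- names(chroms)[sizes >= 1L]
    cn <- if (length(cand) == 1L) cand else sample(cand, 1L)
    dst <- sample(setdiff(names(chroms), cn), 1L)
    n <- length(chroms[[cn]])
    i <- sample_int(n); j <- min(n, i + rpois(1L, 0.5))
    list(type = type, chrom = cn, chrom2 = dst, i = i, j = j,
         at = sample_int(length(chroms[[dst]]) + 1L) - 1L)
  }
}

#' Simulate marker-genome (signed block order) evolution along a tree
#'
#' A lightweight companion to [simulateClade()] operating directly on signed
#' block orders: the ancestor carries blocks `1..n_blocks` spread over
#' `n_chromosomes` chromosomes, and each branch applies a fixed number of
#' rearrangement events drawn from `event_probs`. Designed for testing
#' ancestral-genome inference against a known ancestor.
#'
#' @param n_blocks,n_chromosomes ancestral layout.
#' @param tree rooted `phylo` with branch lengths, or a leaf count for a Yule
#'   tree of depth 1.
#' @param events_per_branch exact rearrangement count applied on every branch.
#' @param event_probs named sampling weights over inversion, fission, fusion,
#'   translocation.
#' @param seed integer.
#' @return list with `ancestor` and `genomes` ([MarkerGenome-class] objects),
#'   the `tree`, and the per-branch `events` list.
#' @examples
#' ms <- simulateMarkerClade(n_blocks = 10, tree = 4, events_per_branch = 1,
#'                           seed = 3)
#' ms$ancestor
#' @export
simulateMarkerClade <- function(n_blocks, n_chromosomes = 2, tree = 4,
                                events_per_branch = 2,
                                event_probs = c(inversion = 0.6,
                                                fission = 0.15, fusion = 0.15,
                                                translocation = 0.1),
                                seed = 1) {
  set.seed(seed)
  if (is.numeric(tree)) {
    tree <- ape::rphylo(tree, birth = 1, death = 0)
    tree$edge.length <- tree$edge.length / max(ape::node.depth.edgelength(tree))
    tree$tip.label <- sprintf("G%d", seq_along(tree$tip.label))
  }
  if (is.null(tree$node.label))
    tree$node.label <- sprintf("N%d", seq_len(tree$Nnode))
  cuts <- sort(sample_int(n_blocks - 1L, min(n_chromosomes - 1L, n_blocks - 1L)))
  bounds <- c(0L, cuts, n_blocks)
  chroms <- list()
  for (k in seq_len(length(bounds) - 1L))
    chroms[[sprintf("chr%d", k)]] <- seq.int(bounds[k] + 1L, bounds[k + 1L])
  anc <- chroms

  st_counter <- length(chroms)
  n_tip <- length(tree$tip.label)
  tree2 <- stats::reorder(tree, "cladewise")
  at_node <- list(); at_node[[n_tip + 1L]] <- chroms
  events <- list()
  genomes <- list()
  for (e in seq_len(nrow(tree2$edge))) {
    par <- tree2$edge[e, 1L]; child <- tree2$edge[e, 2L]
    branch <- node_label(tree, child)
    ch <- at_node[[par]]
    evs <- list()
    for (k in seq_len(events_per_branch)) {
      ev <- draw_marker_event(ch, event_probs, st_counter + 1L)
      if (is.null(ev)) break
      if (ev$type == "fission") st_counter <- st_counter + 1L
      ch <- marker_apply(ch, ev, st_counter)
      evs[[length(evs) + 1L]] <- ev
    }
    events[[branch]] <- evs
    at_node[[child]] <- ch
    if (child <= n_tip)
      genomes[[branch]] <- new("MarkerGenome", genome_id = branch,
                               chromosomes = ch)
  }
  list(ancestor = new("MarkerGenome", genome_id = "ancestor",
                      chromosomes = anc),
       genomes = genomes[tree$tip.label], tree = tree, events = events)
}
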