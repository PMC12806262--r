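## Ancestral genome inference under a genome-median adjacency model.
## Blocks are encoded as extremities (tail = 2b-1, head = 2b); a genome is a
## perfect set of adjacencies plus telomeres. The ancestor is the
## maximum-weight matching of extremities over adjacencies observed in the
## input genomes, decomposed into CARs.

ext_tail <- function(b) 2L * b - 1L
ext_head <- function(b) 2L * b
ext_block <- function(e) (e + 1L) %/% 2L

## left/right extremities of a signed block read along a chromosome
ext_left <- function(x) ifelse(x > 0L, ext_tail(abs(x)), ext_head(abs(x)))
ext_right <- function(x) ifelse(x > 0L, ext_head(abs(x)), ext_tail(abs(x)))

marker_blocks <- function(x) {
  chroms <- if (is(x, "MarkerGenome")) x@chromosomes else x@cars
  as.integer(sort(unique(abs(unlist(chroms, use.names = FALSE)))))
}

## internal adjacencies of a genome as a 2-column matrix (sorted pairs)
adjacency_pairs <- function(x) {
  chroms <- if (is(x, "MarkerGenome")) x@chromosomes else x@cars
  out <- matrix(integer(), 0L, 2L)
  for (v in chroms) {
    if (length(v) < 2L) next
    a <- ext_right(v[-length(v)])
    b <- ext_left(v[-1L])
    out <- rbind(out, cbind(pmin(a, b), pmax(a, b)))
  }
  out
}

adjacency_keys <- function(x) {
  p <- adjacency_pairs(x)
  if (!nrow(p)) return(character())
  paste(p[, 1L], p[, 2L], sep = "-")
}

#' Weighted adjacency graph over block extremities
#'
#' Collects every adjacency observed in at least one input genome, weighted
#' by its observation count (optionally weighted per genome).
#'
#' @param markers list of [MarkerGenome-class] objects sharing one block
#'   universe.
#' @param genome_weights optional numeric weights per genome (default 1
#'   each), e.g. inverse root-to-leaf branch lengths.
#' @return list with `edges` (e1, e2, weight), `blocks`, and the extremity
#'   telomere weights; input to [inferMedianGenome()].
#' @export
buildAdjacencyGraph <- function(markers, genome_weights = NULL) {
  if (!length(markers)) stopf("empty marker set")
  blocks <- marker_blocks(markers[[1L]])
  for (m in markers[-1L]) {
    if (!identical(marker_blocks(m), blocks))
      stopf("marker genomes have inconsistent block universes")
  }
  if (is.null(genome_weights)) genome_weights <- rep(1, length(markers))
  acc <- new.env(parent = emptyenv())
  for (i in seq_along(markers)) {
    keys <- adjacency_keys(markers[[i]])
    for (kk in keys) {
      acc[[kk]] <- (acc[[kk]] %||% 0) + genome_weights[i]
    }
  }
  keys <- sort(ls(acc))
  if (length(keys)) {
    sp <- do.call(rbind, strsplit(keys, "-", fixed = TRUE))
    edges <- data.frame(e1 = as.integer(sp[, 1L]), e2 = as.integer(sp[, 2L]),
                        weight = vapply(keys, function(kk) acc[[kk]], 0),
                        stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(e1 = integer(), e2 = integer(), weight = numeric())
  }
  rownames(edges) <- NULL
  list(edges = edges, blocks = blocks, n_genomes = length(markers),
       markers = markers)
}

## exact maximum-weight matching by branch and bound within connected
## components (candidate graphs are unions of <= n_genomes matchings, so
## components are small); deterministic exploration order
max_weight_matching <- function(edges) {
  if (!nrow(edges)) return(integer())
  edges <- edges[order(-edges$weight, edges$e1, edges$e2), , drop = FALSE]
  verts <- sort(unique(c(edges$e1, edges$e2)))
  comp <- setNames(seq_along(verts), verts)
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  for (r in seq_len(nrow(edges))) {
    a <- find(match(edges$e1[r], verts)); b <- find(match(edges$e2[r], verts))
    if (a != b) comp[max(a, b)] <- min(a, b)
  }
  roots <- vapply(seq_along(verts), find, 0L)
  chosen <- character()   # "e1-e2" keys of matched adjacencies
  for (rt in unique(roots)) {
    vs <- verts[roots == rt]
    es <- edges[edges$e1 %in% vs, , drop = FALSE]
    chosen <- c(chosen, match_component(vs, es))
  }
  chosen
}

## returns keys "e1-e2" of the matched adjacencies in one component
match_component <- function(vs, es) {
  best <- new.env(parent = emptyenv())
  best$w <- -1; best$sel <- character()
  n_e <- nrow(es)
  max_w_at <- vapply(vs, function(v)
    suppressWarnings(max(0, es$weight[es$e1 == v | es$e2 == v])), 0)
  names(max_w_at) <- vs
  recurse <- function(free, acc_w, sel) {
    ## bound: each free vertex contributes at most half its best edge twice
    if (acc_w + sum(max_w_at[as.character(free)]) / 2 < best$w) return()
    live <- es[es$e1 %in% free & es$e2 %in% free, , drop = FALSE]
    if (!nrow(live)) {
      if (acc_w > best$w) { best$w <- acc_w; best$sel <- sel }
      return()
    }
    v <- min(c(live$e1, live$e2))
    at_v <- which(live$e1 == v | live$e2 == v)
    for (r in at_v) {
      u <- if (live$e1[r] == v) live$e2[r] else live$e1[r]
      recurse(setdiff(free, c(v, u)), acc_w + live$weight[r],
              c(sel, paste(min(v, u), max(v, u), sep = "-")))
    }
    recurse(setdiff(free, v), acc_w, sel)  # leave v unmatched
  }
  recurse(vs, 0, character())
  best$sel
}

## decompose a selected adjacency set into canonical CARs; cycles are broken
## at their minimum-weight adjacency (wt = observation counts)
cars_from_selection <- function(sel, wt, blocks) {
  partner <- integer(2L * max(blocks))
  for (kk in sel) {
    e <- as.integer(strsplit(kk, "-", fixed = TRUE)[[1L]])
    partner[e[1L]] <- e[2L]; partner[e[2L]] <- e[1L]
  }
  used <- logical(2L * max(blocks))
  exts <- c(rbind(ext_tail(blocks), ext_head(blocks)))
  other_end <- function(e) if (e %% 2L == 1L) e + 1L else e - 1L

  walk <- function(start) {
    path <- integer(); e <- as.integer(start)
    repeat {
      b <- as.integer(ext_block(e))
      path <- c(path, if (e == ext_tail(b)) b else -b)
      used[c(e, other_end(e))] <<- TRUE
      nxt <- partner[other_end(e)]
      if (nxt == 0L || used[nxt]) break
      e <- nxt
    }
    path
  }

  cars <- list()
  for (e in exts) {                     # linear CARs start at free extremities
    if (used[e] || partner[e] != 0L) next
    cars[[length(cars) + 1L]] <- walk(e)
  }
  for (e in exts) {                     # leftovers lie on cycles
    if (used[e]) next
    cyc <- integer(); cur <- e
    repeat {
      cyc <- c(cyc, cur)
      nxt <- partner[other_end(cur)]
      if (nxt == cur || nxt == e || nxt == 0L) break
      cur <- nxt
    }
    adjs <- vapply(cyc, function(x) {
      p <- partner[other_end(x)]
      paste(min(other_end(x), p), max(other_end(x), p), sep = "-")
    }, "")
    wmin <- which.min(wt[adjs])
    cut <- as.integer(strsplit(adjs[wmin], "-", fixed = TRUE)[[1L]])
    partner[cut[1L]] <- 0L; partner[cut[2L]] <- 0L
    cars[[length(cars) + 1L]] <- walk(cut[1L])
  }
  cars <- lapply(cars, canonical_car)
  cars <- cars[order(vapply(cars, function(v) min(abs(v)), 0L))]
  names(cars) <- sprintf("CAR%d", seq_along(cars))
  cars
}

selection_to_ancestor <- function(sel, wt, blocks) {
  new("AncestorGenome", cars = cars_from_selection(sel, wt, blocks),
      blocks = blocks)
}

#' Infer the ancestral genome by the genome-median adjacency model
#'
#' Selects a matching of block extremities over the candidate adjacencies of
#' [buildAdjacencyGraph()] (each extremity used at most once). The initial
#' matching maximizes the net-benefit weight `2w - n` (an adjacency observed
#' in `w` of `n` genomes improves the total DCJ distance only when a
#' majority exhibits it); a deterministic local-improvement pass then adds,
#' removes or swaps single adjacencies while the exact total DCJ distance to
#' the input genomes decreases. The final matching is decomposed into linear
#' CARs, breaking circular components at their minimum-weight adjacency.
#'
#' On small instances (at most `exhaustive_max_edges` observed adjacencies)
#' every matching of the observed adjacencies is enumerated and scored by
#' the exact objective before refinement, which makes the heuristic exact
#' whenever an optimal median uses only observed adjacencies.
#'
#' @param graph result of [buildAdjacencyGraph()].
#' @param refine run the local-improvement pass (recommended).
#' @param exhaustive_max_edges enumeration threshold for small instances.
#' @return an [AncestorGenome-class].
#' @export
inferMedianGenome <- function(graph, refine = TRUE,
                              exhaustive_max_edges = 25L) {
  if (!length(graph$blocks)) stopf("empty adjacency graph")
  edges <- graph$edges
  wt <- setNames(edges$weight, paste(edges$e1, edges$e2, sep = "-"))
  if (!is.null(graph$markers) && nrow(edges) <= exhaustive_max_edges) {
    sel <- best_matching_exhaustive(edges, wt, graph)
  } else {
    net <- 2 * edges$weight - graph$n_genomes
    cand <- edges[net > 0, , drop = FALSE]
    cand$weight <- net[net > 0]
    sel <- max_weight_matching(cand)
    if (!is.null(graph$markers)) {
      ## the inputs themselves are candidate medians: start from whichever
      ## of {matching, input genome} has the smallest total distance, which
      ## also guarantees the median is never worse than any input
      marker_lists <- lapply(graph$markers, as_chrom_list)
      n_max <- max(graph$blocks)
      tot_of <- function(s)
        .dcj_total_cpp(lapply(unname(cars_from_selection(s, wt,
                                                         graph$blocks)),
                              as.integer), marker_lists, n_max)
      ## ties between equally good seeds resolve by the canonical selection
      ## string, so the result is independent of input genome order
      seeds <- c(list(sel), lapply(graph$markers, adjacency_keys))
      tots <- vapply(seeds, tot_of, 0L)
      canon <- vapply(seeds, function(s) paste(sort(s), collapse = ";"), "")
      sel <- seeds[[order(tots, canon)[1L]]]
    }
  }
  if (refine && !is.null(graph$markers))
    sel <- refine_selection(sel, edges, wt, graph)
  new("AncestorGenome", cars = cars_from_selection(sel, wt, graph$blocks),
      blocks = graph$blocks)
}

## enumerate every matching of the observed adjacencies (DFS, heavier edges
## first) and keep the first one attaining the minimum exact objective
best_matching_exhaustive <- function(edges, wt, graph, max_eval = 20000L) {
  ord <- order(-edges$weight, edges$e1, edges$e2)
  e1 <- edges$e1[ord]; e2 <- edges$e2[ord]
  keys <- paste(e1, e2, sep = "-")
  n_e <- length(keys)
  best <- new.env(parent = emptyenv())
  best$total <- Inf; best$sel <- character(); best$n_eval <- 0L
  marker_lists <- lapply(graph$markers, as_chrom_list)
  n_max <- max(graph$blocks)
  score <- function(sel) {
    best$n_eval <- best$n_eval + 1L
    tot <- .dcj_total_cpp(lapply(unname(cars_from_selection(sel, wt,
                                                            graph$blocks)),
                                 as.integer),
                          marker_lists, n_max)
    if (tot < best$total) { best$total <- tot; best$sel <- sel }
  }
  recurse <- function(r, used, sel) {
    if (best$n_eval >= max_eval) return()
    if (r > n_e) { score(sel); return() }
    if (!(e1[r] %in% used) && !(e2[r] %in% used))
      recurse(r + 1L, c(used, e1[r], e2[r]), c(sel, keys[r]))
    recurse(r + 1L, used, sel)
  }
  recurse(1L, integer(), character())
  best$sel
}

## greedy first-improvement search on the exact median objective; on small
## instances the candidate set is widened to every extremity pair and
## two-edge moves are tried, which escapes zero-gain plateaus (e.g. adding
## both adjacencies of a two-adjacency chromosome at once)
refine_selection <- function(sel, edges, wt, graph, max_sweeps = 20L,
                             small_blocks = 8L, pair_move_max = 60L) {
  if (length(graph$blocks) <= small_blocks) {
    cand <- edges[, c("e1", "e2", "weight")]
    exts <- sort(c(ext_tail(graph$blocks), ext_head(graph$blocks)))
    all_pairs <- t(combn(exts, 2L))
    all_pairs <- all_pairs[ext_block(all_pairs[, 1L]) !=
                           ext_block(all_pairs[, 2L]), , drop = FALSE]
    novel <- !(paste(all_pairs[, 1L], all_pairs[, 2L], sep = "-") %in%
               paste(cand$e1, cand$e2, sep = "-"))
    cand <- rbind(cand, data.frame(e1 = all_pairs[novel, 1L],
                                   e2 = all_pairs[novel, 2L], weight = 0))
  } else {
    cand <- edges[, c("e1", "e2", "weight")]
  }
  keys <- paste(cand$e1, cand$e2, sep = "-")
  wt2 <- wt
  missing <- setdiff(keys, names(wt2))
  if (length(missing)) wt2[missing] <- 0
  marker_lists <- lapply(graph$markers, as_chrom_list)
  n_max <- max(graph$blocks)
  total_of <- function(s)
    .dcj_total_cpp(lapply(unname(cars_from_selection(s, wt2, graph$blocks)),
                          as.integer),
                   marker_lists, n_max)
  without_conflicts <- function(s, ends) {
    if (!length(s)) return(s)
    sm <- do.call(rbind, strsplit(s, "-", fixed = TRUE))
    s[!(sm[, 1L] %in% ends | sm[, 2L] %in% ends)]
  }
  ord <- order(-cand$weight, cand$e1, cand$e2)
  best <- total_of(sel)
  for (sweep in seq_len(max_sweeps)) {
    improved <- FALSE
    for (r in ord) {
      k <- keys[r]
      if (k %in% sel) {
        cand_sel <- setdiff(sel, k)
      } else {
        ends <- c(cand$e1[r], cand$e2[r])
        cand_sel <- c(without_conflicts(sel, ends), k)
      }
      tot <- total_of(cand_sel)
      if (tot < best) {
        sel <- cand_sel; best <- tot; improved <- TRUE
      }
    }
    if (!improved && length(ord) <= pair_move_max) {
      for (r in ord) {
        for (s2 in ord) {
          if (s2 <= r) next
          ends <- c(cand$e1[r], cand$e2[r], cand$e2[s2], cand$e1[s2])
          if (anyDuplicated(ends)) next
          k1 <- keys[r]; k2 <- keys[s2]
          if (k1 %in% sel && k2 %in% sel) next
          cand_sel <- unique(c(without_conflicts(sel, ends), k1, k2))
          tot <- total_of(cand_sel)
          if (tot < best) {
            sel <- cand_sel; best <- tot; improved <- TRUE
            break
          }
        }
        if (improved) break
      }
    }
    if (!improved) break
  }
  sel
}

canonical_car <- function(v) {
  r <- -rev(v)
  if (abs(v[1L]) < abs(r[1L])) return(v)
  if (abs(v[1L]) > abs(r[1L])) return(r)
  if (identical(v, r)) return(v)
  if (v[1L] >= r[1L]) v else r
}

#' DCJ distance between two genomes on the same block universe
#'
#' The double-cut-and-join distance `N - (C + I/2)` where `N` is the block
#' count and `C`, `I` are the cycle and odd-path counts of the adjacency
#' graph between the two genomes (telomeres included as path ends).
#' Symmetric; zero iff the genomes are identical up to chromosome order and
#' orientation.
#'
#' @param a,b [MarkerGenome-class] or [AncestorGenome-class] objects.
#' @return non-negative integer distance.
#' @examples
#' g1 <- new("MarkerGenome", genome_id = "a",
#'           chromosomes = list(chr1 = c(1L, 2L, 3L)))
#' g2 <- new("MarkerGenome", genome_id = "b",
#'           chromosomes = list(chr1 = c(1L, -2L, 3L)))
#' dcjDistance(g1, g2)  # one inversion
#' @export
dcjDistance <- function(a, b) {
  ba <- marker_blocks(a); bb <- marker_blocks(b)
  if (!identical(ba, bb)) stopf("genomes have different block universes")
  N <- length(ba)
  if (N == 0L) return(0L)
  vert_map <- function(x) {
    chroms <- if (is(x, "MarkerGenome")) x@chromosomes else x@cars
    vid <- integer(2L * max(ba)); nv <- 0L
    size <- integer()
    for (v in chroms) {
      le <- ext_left(v); re <- ext_right(v)
      n <- length(v)
      ## telomeres
      for (e in c(le[1L], re[n])) {
        nv <- nv + 1L; vid[e] <- nv; size[nv] <- 1L
      }
      if (n >= 2L) {
        for (k in seq_len(n - 1L)) {
          nv <- nv + 1L
          vid[re[k]] <- nv; vid[le[k + 1L]] <- nv; size[nv] <- 2L
        }
      }
    }
    list(vid = vid, n = nv, size = size)
  }
  va <- vert_map(a); vb <- vert_map(b)
  exts <- c(rbind(ext_tail(ba), ext_head(ba)))
  ## bipartite graph: one edge per extremity
  parent <- seq_len(va$n + vb$n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (e in exts) {
    i <- va$vid[e]; j <- vb$vid[e] + va$n
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  }
  comp_of <- vapply(seq_len(va$n + vb$n), find, 0L)
  edge_comp <- vapply(exts, function(e) find(va$vid[e]), 0L)
  n_edges <- table(edge_comp)
  deg1 <- c(va$size, vb$size) == 1L
  deg1_by_comp <- tapply(deg1, comp_of, sum)
  cycles <- 0L; odd_paths <- 0L
  for (cc in names(n_edges)) {
    if (deg1_by_comp[[cc]] == 0L) cycles <- cycles + 1L
    else if (n_edges[[cc]] %% 2L == 1L) odd_paths <- odd_paths + 1L
  }
  as.integer(round(N - cycles - odd_paths / 2))
}

#' Rearrangement summary of an extant genome against the ancestor
#'
#' Chromosome-count-based fission/fusion estimates (a lower bound for
#' compound histories), a lower bound on inversions from block signs after
#' optimal CAR orientation, and the DCJ distance.
#'
#' @param ancestor an [AncestorGenome-class].
#' @param extant a [MarkerGenome-class] on the same block universe.
#' @return one-row data.frame (genome, dcj_distance, fissions, fusions,
#'   inversions_lower_bound).
#' @export
countFissionFusion <- function(ancestor, extant) {
  n_car <- length(ancestor@cars)
  n_chr <- length(extant@chromosomes)
  sign_ext <- integer(max(marker_blocks(extant)))
  for (v in extant@chromosomes) sign_ext[abs(v)] <- sign(v)
  inv_lb <- 0L
  for (v in ancestor@cars) {
    m <- sum(sign(v) != sign_ext[abs(v)])
    inv_lb <- inv_lb + min(m, length(v) - m)
  }
  data.frame(genome = extant@genome_id,
             dcj_distance = dcjDistance(ancestor, extant),
             fissions = max(0L, n_chr - n_car),
             fusions = max(0L, n_car - n_chr),
             inversions_lower_bound = inv_lb)
}

#' Fraction of a genome's adjacencies recovered by an inferred ancestor
#'
#' @param inferred an [AncestorGenome-class].
#' @param reference the true ancestor as a [MarkerGenome-class] (or another
#'   `AncestorGenome`).
#' @return fraction of the reference's internal adjacencies present in the
#'   inferred genome.
#' @export
adjacencyRecovery <- function(inferred, reference) {
  ref <- adjacency_keys(reference)
  if (!length(ref)) return(NA_real_)
  mean(ref %in% adjacency_keys(inferred))
}

#' Total DCJ distance from a candidate ancestor to a set of genomes
#' @param candidate `AncestorGenome` or `MarkerGenome`.
#' @param markers list of [MarkerGenome-class] objects.
#' @export
medianTotalDistance <- function(candidate, markers) {
  sum(vapply(markers, function(m) dcjDistance(candidate, m), 0L))
}
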