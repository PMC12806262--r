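## SV hotspot detection: windowed breakpoint counts against a per-chromosome
## uniform permutation null, Benjamini-Hochberg control across windows, and
## merging of significant windows into hotspot regions.

#' Detect SV hotspot regions by permutation testing
#'
#' Counts SV start breakpoints (one point per SV) in tiling (or sliding)
#' windows along each reference chromosome. The null preserves each
#' chromosome's SV count and redraws start positions uniformly; the
#' empirical p-value of a window is `(1 + #{perm >= obs}) / (1 + n_perm)`.
#' Windows significant after Benjamini-Hochberg adjustment (`q <= alpha`)
#' are merged into regions when overlapping or adjacent.
#'
#' @param svs SV table (from [callSvsFromAlignment()], possibly pooled over
#'   queries) with columns `ref_chrom` and `ref_start`.
#' @param ref_lengths named numeric: chromosome lengths in bp.
#' @param window_bp,step_bp window geometry (default 1 Mb tiling windows);
#'   a window wider than the chromosome degrades to one whole-chromosome
#'   window with a warning.
#' @param n_perm number of permutations (>= 100).
#' @param alpha FDR threshold on adjusted q.
#' @param seed RNG seed; output is deterministic given the seed.
#' @return data.frame of merged hotspot regions (ref_chrom, start, end,
#'   sv_count, empirical_p, bh_q), 0-based half-open, with the per-window
#'   table in `attr(,"windows")`.
#' @export
detectHotspots <- function(svs, ref_lengths, window_bp = 1e6,
                           step_bp = window_bp, n_perm = 1000, alpha = 0.05,
                           seed = 1) {
  stopifnot(n_perm >= 100, window_bp > 0, step_bp > 0)
  empty <- data.frame(ref_chrom = character(), start = numeric(),
                      end = numeric(), sv_count = integer(),
                      empirical_p = numeric(), bh_q = numeric())
  if (!nrow(svs)) {
    attr(empty, "windows") <- data.frame()
    return(empty)
  }
  set.seed(seed)
  wins <- list()
  for (cn in names(ref_lengths)) {
    L <- ref_lengths[[cn]]
    if (window_bp > L) {
      warnf("window (%g bp) wider than %s (%g bp): using one window",
            window_bp, cn, L)
      starts <- 0
    } else {
      starts <- seq(0, L - 1, by = step_bp)
      starts <- starts[starts < L]
    }
    wins[[cn]] <- data.frame(ref_chrom = cn, start = starts,
                             end = pmin(starts + window_bp, L))
  }
  wins <- do.call(rbind, wins)
  tiling <- step_bp == window_bp
  count_windows <- function(cn, pos) {
    w <- wins[wins$ref_chrom == cn, , drop = FALSE]
    if (tiling) {
      ## contiguous windows: direct binning
      idx <- pmin(floor(pos / window_bp) + 1L, nrow(w))
      tabulate(idx, nbins = nrow(w))
    } else {
      vapply(seq_len(nrow(w)),
             function(i) sum(pos >= w$start[i] & pos < w$end[i]), 0L)
    }
  }
  obs <- integer(nrow(wins))
  exceed <- integer(nrow(wins))
  for (cn in unique(wins$ref_chrom)) {
    sel <- wins$ref_chrom == cn
    pos <- svs$ref_start[svs$ref_chrom == cn]
    obs[sel] <- count_windows(cn, pos)
    m <- length(pos)
    L <- ref_lengths[[cn]]
    ex <- integer(sum(sel))
    for (b in seq_len(n_perm)) {
      perm <- count_windows(cn, floor(runif(m, 0, L)))
      ex <- ex + (perm >= obs[sel])
    }
    exceed[sel] <- ex
  }
  wins$sv_count <- obs
  wins$empirical_p <- (1 + exceed) / (1 + n_perm)
  wins$bh_q <- p.adjust(wins$empirical_p, method = "BH")
  called <- wins[wins$bh_q <= alpha & wins$sv_count > 0L, , drop = FALSE]
  if (!nrow(called)) {
    attr(empty, "windows") <- wins
    return(empty)
  }
  regions <- list()
  for (cn in unique(called$ref_chrom)) {
    cc <- called[called$ref_chrom == cn, , drop = FALSE]
    ir <- IRanges::reduce(IRanges::IRanges(start = cc$start + 1,
                                           end = cc$end), min.gapwidth = 1L)
    pos <- svs$ref_start[svs$ref_chrom == cn]
    for (k in seq_along(ir)) {
      s0 <- IRanges::start(ir)[k] - 1; e0 <- IRanges::end(ir)[k]
      member <- cc$start < e0 & cc$end > s0
      regions[[length(regions) + 1L]] <- data.frame(
        ref_chrom = cn, start = s0, end = e0,
        sv_count = sum(pos >= s0 & pos < e0),
        empirical_p = min(cc$empirical_p[member]),
        bh_q = min(cc$bh_q[member]), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, regions)
  out <- out[order(out$ref_chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "windows") <- wins
  out
}

#' Annotate hotspot regions with overlapping genes
#'
#' A gene is listed when its interval intersects the region under half-open
#' semantics: a gene starting exactly at the region end does not overlap.
#' Chromosome names present in the regions but absent from the annotation
#' are reported in `attr(,"skipped_contigs")`.
#'
#' @param regions hotspot table from [detectHotspots()].
#' @param annotation gene annotation: a data.frame (gene_id, chrom, start,
#'   end; 1-based inclusive as from [geneAnnotations()]) or a GFF3 file path.
#' @return `regions` with a `genes` character column (comma-separated ids).
#' @export
annotateRegions <- function(regions, annotation) {
  if (is.character(annotation) && length(annotation) == 1L)
    annotation <- readGff3Genes(annotation)
  stopifnot(all(c("gene_id", "chrom", "start", "end") %in% names(annotation)))
  skipped <- setdiff(unique(regions$ref_chrom), unique(annotation$chrom))
  genes <- character(nrow(regions))
  for (i in seq_len(nrow(regions))) {
    g <- annotation[annotation$chrom == regions$ref_chrom[i] &
                    annotation$start - 1L < regions$end[i] &
                    annotation$end > regions$start[i], , drop = FALSE]
    genes[i] <- paste(g$gene_id, collapse = ",")
  }
  regions$genes <- genes
  attr(regions, "skipped_contigs") <- skipped
  regions
}

## GFF3 gene features as the annotation data.frame used across the package
readGff3Genes <- function(path) {
  g <- rtracklayer::readGFF(path, filter = list(type = "gene"))
  data.frame(gene_id = as.character(g$ID), chrom = as.character(g$seqid),
             start = as.integer(g$start), end = as.integer(g$end),
             strand = as.character(g$strand), stringsAsFactors = FALSE)
}
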