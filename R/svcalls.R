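## Assembly-vs-reference SV calling from PAF alignments, following the
## six-class gap taxonomy (insertion, deletion, tandem and repeat
## expansion/contraction). Between consecutive anchors of a same-strand
## chain, the reference gap dr and query gap dq classify the event:
## non-unique flanks -> repeat_*, a negative gap -> tandem_*, otherwise
## insertion/deletion, with size |dq - dr|.

PAF_COLS <- c("qname", "qlen", "qstart", "qend", "strand",
              "tname", "tlen", "tstart", "tend", "nmatch", "alen", "mapq")

#' Read a minimal PAF alignment file
#'
#' Parses the 12 mandatory PAF columns (tags are ignored). Coordinates are
#' 0-based half-open as in the PAF specification.
#'
#' @param path PAF file.
#' @return data.frame with the 12 standard columns.
#' @export
readPaf <- function(path) {
  lines <- readLines(path)
  if (!length(lines))
    return(as.data.frame(setNames(rep(list(character()), 12L), PAF_COLS)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 12L)) stopf("PAF line with fewer than 12 fields")
  m <- do.call(rbind, lapply(parts, `[`, 1:12))
  df <- data.frame(m, stringsAsFactors = FALSE)
  names(df) <- PAF_COLS
  for (col in c("qlen", "qstart", "qend", "tlen", "tstart", "tend",
                "nmatch", "alen", "mapq"))
    df[[col]] <- as.integer(df[[col]])
  df
}

#' Write alignments as PAF
#' @param paf data.frame with the 12 standard columns.
#' @param path output file.
#' @export
writePaf <- function(paf, path) {
  write.table(paf[, PAF_COLS], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## anchor pieces of one segment in (ancestral, edited-copy) local coordinates
segment_pieces <- function(type, o, s, L) {
  if (is.na(type)) {
    return(data.frame(anc_s = 0L, anc_e = L, ed_s = 0L, ed_e = L))
  }
  switch(type,
    insertion = ,
    repeat_expansion = data.frame(
      anc_s = c(0L, o), anc_e = c(o, L),
      ed_s = c(0L, o + s), ed_e = c(o, L + s)),
    deletion = ,
    repeat_contraction = data.frame(
      anc_s = c(0L, o + s), anc_e = c(o, L),
      ed_s = c(0L, o), ed_e = c(o, L - s)),
    tandem_expansion = data.frame(
      anc_s = c(0L, o - s), anc_e = c(o, L),
      ed_s = c(0L, o), ed_e = c(o, L + s)),
    tandem_contraction = data.frame(
      anc_s = c(0L, o), anc_e = c(o, L),
      ed_s = c(0L, o - s), ed_e = c(o, L - s)),
    stopf("unknown SV type '%s'", type))
}

## absolute anchor coordinates for one shared segment carrying at most one
## SV (in either genome); shared by the alignment generator and the truth
## translator so expected call positions match the emitted geometry exactly
segment_anchors <- function(iq, ir, tq, tr, eq, er) {
  if (nrow(eq)) {
    pieces <- segment_pieces(eq$type[1L], eq$seg_offset[1L], eq$size[1L],
                             tr$len[ir])
    qs <- pieces$ed_s; qe <- pieces$ed_e
    rs <- pieces$anc_s; re <- pieces$anc_e
    sv_type <- eq$type[1L]
  } else if (nrow(er)) {
    ## ancestral length of the segment = query copy length (query clean)
    pieces <- segment_pieces(er$type[1L], er$seg_offset[1L], er$size[1L],
                             tq$len[iq])
    qs <- pieces$anc_s; qe <- pieces$anc_e
    rs <- pieces$ed_s; re <- pieces$ed_e
    sv_type <- er$type[1L]
  } else {
    qs <- 0L; qe <- tq$len[iq]; rs <- 0L; re <- tr$len[ir]
    sv_type <- NA_character_
  }
  oq <- tq$orient[iq]; orr <- tr$orient[ir]
  strand <- if (oq == orr) "+" else "-"
  qabs_s <- if (oq == 1L) tq$start[iq] + qs else tq$start[iq] + tq$len[iq] - qe
  qabs_e <- if (oq == 1L) tq$start[iq] + qe else tq$start[iq] + tq$len[iq] - qs
  rabs_s <- if (orr == 1L) tr$start[ir] + rs else tr$start[ir] + tr$len[ir] - re
  rabs_e <- if (orr == 1L) tr$start[ir] + re else tr$start[ir] + tr$len[ir] - rs
  list(coords = data.frame(qs = qabs_s, qe = qabs_e, rs = rabs_s,
                           re = rabs_e, strand = strand,
                           stringsAsFactors = FALSE),
       sv_type = sv_type)
}

## per-genome segment coordinate table (current coordinates)
segment_table <- function(genome) {
  rows <- lapply(names(genome$chroms), function(cn) {
    df <- genome$chroms[[cn]]
    len <- nchar(df$seq)
    end <- cumsum(len)
    data.frame(seg = df$seg, chrom = cn, start = end - len, end = end,
               len = len, orient = df$orient, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Exact alignment anchors between two simulated genomes, as PAF
#'
#' Uses the simulator's known homology: every segment shared by the two
#' genomes becomes one anchor, split around planted SVs so that the gap
#' signature of each SV class appears exactly as an assembly aligner would
#' report it (repeat-class events additionally emit a decoy multi-mapping
#' record that renders the flanking anchors non-unique). Segments carrying
#' an SV in both genomes are skipped.
#'
#' @param sim a [CladeSim-class].
#' @param query,reference leaf genome ids (reference may be `"ancestor"`).
#' @return PAF data.frame (query = `query`, target = `reference`).
#' @export
pafFromTruth <- function(sim, query, reference) {
  gq <- genome_object(sim, query)
  gr <- genome_object(sim, reference)
  tq <- segment_table(gq)
  tr <- segment_table(gr)
  sv_q <- if (identical(query, "ancestor")) truth(sim)@sv_events[0, ] else
    svTruthForGenome(truth(sim), query)
  sv_r <- if (identical(reference, "ancestor")) truth(sim)@sv_events[0, ] else
    svTruthForGenome(truth(sim), reference)
  shared <- intersect(tq$seg, tr$seg)
  recs <- list()
  decoy <- 0L
  for (seg in shared) {
    iq <- match(seg, tq$seg); ir <- match(seg, tr$seg)
    eq <- sv_q[sv_q$seg == seg, , drop = FALSE]
    er <- sv_r[sv_r$seg == seg, , drop = FALSE]
    if (nrow(eq) && nrow(er)) next            # ambiguous alignment: skip
    an <- segment_anchors(iq, ir, tq, tr, eq, er)
    for (k in seq_len(nrow(an$coords))) {
      recs[[length(recs) + 1L]] <- data.frame(
        qname = tq$chrom[iq], qstart = an$coords$qs[k],
        qend = an$coords$qe[k], strand = an$coords$strand[k],
        tname = tr$chrom[ir], tstart = an$coords$rs[k],
        tend = an$coords$re[k], stringsAsFactors = FALSE)
    }
    if (!is.na(an$sv_type) && grepl("^repeat_", an$sv_type)) {
      ## decoy record: the first flank's query interval maps elsewhere too
      decoy <- decoy + 1L
      recs[[length(recs) + 1L]] <- data.frame(
        qname = tq$chrom[iq], qstart = an$coords$qs[1L],
        qend = an$coords$qe[1L], strand = "+",
        tname = sprintf("decoy%d", decoy), tstart = 0L,
        tend = an$coords$qe[1L] - an$coords$qs[1L], stringsAsFactors = FALSE)
    }
  }
  if (!length(recs))
    return(as.data.frame(setNames(rep(list(integer()), 12L), PAF_COLS)))
  df <- do.call(rbind, recs)
  qlen <- setNames(vapply(gq$chroms, function(x) sum(nchar(x$seq)), 0),
                   names(gq$chroms))
  tlen <- setNames(vapply(gr$chroms, function(x) sum(nchar(x$seq)), 0),
                   names(gr$chroms))
  df$qlen <- as.integer(qlen[df$qname])
  df$tlen <- as.integer(tlen[df$tname])
  df$tlen[is.na(df$tlen)] <- df$tend[is.na(df$tlen)]   # decoy contigs
  df$nmatch <- df$tend - df$tstart
  df$alen <- pmax(df$tend - df$tstart, df$qend - df$qstart)
  df$mapq <- 60L
  df <- df[order(df$qname, df$tname, df$tstart), PAF_COLS]
  rownames(df) <- NULL
  df
}

## flag records whose query interval overlaps a record of another chain
## by > frac of the shorter interval
flag_unique <- function(paf, frac = 0.1) {
  n <- nrow(paf)
  uniq <- rep(TRUE, n)
  chain <- paste(paf$qname, paf$tname, paf$strand)
  for (qn in unique(paf$qname)) {
    idx <- which(paf$qname == qn)
    if (length(idx) < 2L) next
    ir <- IRanges::IRanges(start = paf$qstart[idx] + 1L, end = paf$qend[idx])
    hits <- IRanges::findOverlaps(ir, ir)
    a <- S4Vectors::queryHits(hits); b <- S4Vectors::subjectHits(hits)
    keep <- a < b & chain[idx[a]] != chain[idx[b]]
    a <- a[keep]; b <- b[keep]
    if (!length(a)) next
    ov <- IRanges::width(IRanges::pintersect(ir[a], ir[b]))
    shorter <- pmin(IRanges::width(ir[a]), IRanges::width(ir[b]))
    bad <- ov > frac * shorter
    uniq[idx[a[bad]]] <- FALSE
    uniq[idx[b[bad]]] <- FALSE
  }
  uniq
}

#' Call structural variants from assembly-vs-reference alignments
#'
#' Classifies the gap between each pair of consecutive same-strand anchors
#' on a (query chromosome, reference chromosome) chain by the reference gap
#' `dr` and query gap `dq`: a non-unique flanking anchor gives
#' `repeat_expansion`/`repeat_contraction` (by the sign of `dq - dr`), a
#' negative gap gives `tandem_expansion`/`tandem_contraction`, and otherwise
#' positive `dq - dr` is an insertion and negative a deletion. The size is
#' `|dq - dr|`, filtered to `[min_size, max_size]`. A record is non-unique
#' when its query interval overlaps a record of another chain by more than
#' 10%.
#'
#' @param paf PAF data.frame (see [readPaf()]); sorted internally with a
#'   warning if needed.
#' @param min_size,max_size size filter in bp.
#' @param ref_genome,query_genome labels carried into the output.
#' @return data.frame of SV records with 0-based half-open reference
#'   coordinates.
#' @export
callSvsFromAlignment <- function(paf, min_size = 50, max_size = 10000,
                                 ref_genome = NA_character_,
                                 query_genome = NA_character_) {
  empty <- data.frame(ref_genome = character(), query_genome = character(),
                      ref_chrom = character(), ref_start = integer(),
                      ref_end = integer(), type = character(),
                      size = integer(), query_chrom = character(),
                      query_start = integer(), query_end = integer())
  if (!nrow(paf)) {
    warnf("no usable alignment anchors; returning no SVs")
    return(empty)
  }
  chain0 <- paste(paf$qname, paf$tname, paf$strand)
  if (any(vapply(split(paf$tstart, chain0), is.unsorted, TRUE)))
    warnf("unsorted PAF: sorting by chain and reference start")
  ord <- order(paf$qname, paf$tname, paf$strand, paf$tstart)
  if (!identical(ord, seq_len(nrow(paf)))) paf <- paf[ord, , drop = FALSE]
  uniq <- flag_unique(paf)
  drop_decoy <- grepl("^decoy", paf$tname)
  keep <- which(!drop_decoy)
  calls <- list()
  chain <- paste(paf$qname, paf$tname, paf$strand)
  for (idx in split(keep, chain[keep])) {
    if (length(idx) < 2L) next
    for (k in seq_len(length(idx) - 1L)) {
      i <- idx[k]; j <- idx[k + 1L]
      dr <- paf$tstart[j] - paf$tend[i]
      if (paf$strand[i] == "+") {
        dq <- paf$qstart[j] - paf$qend[i]
        q_lo <- min(paf$qend[i], paf$qstart[j])
        q_hi <- max(paf$qend[i], paf$qstart[j])
      } else {
        dq <- paf$qstart[i] - paf$qend[j]
        q_lo <- min(paf$qend[j], paf$qstart[i])
        q_hi <- max(paf$qend[j], paf$qstart[i])
      }
      diffsz <- dq - dr
      size <- abs(diffsz)
      if (size < min_size || size > max_size) next
      if (!uniq[i] || !uniq[j]) {
        type <- if (diffsz > 0) "repeat_expansion" else "repeat_contraction"
      } else if (min(dr, dq) < 0) {
        type <- if (diffsz > 0) "tandem_expansion" else "tandem_contraction"
      } else {
        type <- if (diffsz > 0) "insertion" else "deletion"
      }
      calls[[length(calls) + 1L]] <- data.frame(
        ref_genome = ref_genome, query_genome = query_genome,
        ref_chrom = paf$tname[i],
        ref_start = min(paf$tend[i], paf$tstart[j]),
        ref_end = max(paf$tend[i], paf$tstart[j]),
        type = type, size = size, query_chrom = paf$qname[i],
        query_start = q_lo, query_end = q_hi, stringsAsFactors = FALSE)
    }
  }
  if (!length(calls)) return(empty)
  out <- do.call(rbind, calls)
  out <- out[order(out$ref_chrom, out$ref_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Expected SV calls for a simulated (reference, query) pair
#'
#' Translates the planted truth into the calls [callSvsFromAlignment()]
#' should produce on [pafFromTruth()] alignments: query-side events keep
#' their type; reference-side events appear mirrored (insertion and
#' deletion, expansion and contraction swap). Coordinates are on the
#' reference. Events in segments that are rearranged relative to the
#' reference orientation, or hit in both genomes, are omitted.
#'
#' Segments hit in both genomes yield no anchors inside the segment, so the
#' flanking gap exposes only the net length difference: when it falls within
#' the size filter it is expected as a plain insertion/deletion spanning the
#' segment.
#'
#' @inheritParams pafFromTruth
#' @param min_size,max_size the size filter the caller will apply (used for
#'   the net-difference expectation of doubly-hit segments).
#' @return data.frame (type, ref_chrom, ref_start, ref_end, size).
#' @export
truthSvTable <- function(sim, query, reference, min_size = 50,
                         max_size = 10000) {
  gr <- genome_object(sim, reference)
  gq <- genome_object(sim, query)
  tr <- segment_table(gr)
  tq <- segment_table(gq)
  sv_q <- if (identical(query, "ancestor")) truth(sim)@sv_events[0, ] else
    svTruthForGenome(truth(sim), query)
  sv_r <- if (identical(reference, "ancestor")) truth(sim)@sv_events[0, ] else
    svTruthForGenome(truth(sim), reference)
  both <- intersect(sv_q$seg, sv_r$seg)
  mirror <- c(insertion = "deletion", deletion = "insertion",
              tandem_expansion = "tandem_contraction",
              tandem_contraction = "tandem_expansion",
              repeat_expansion = "repeat_contraction",
              repeat_contraction = "repeat_expansion")
  rows <- list()
  ## expected call = gap between the two anchors of the segment, computed
  ## from the same geometry the alignment generator emits (any orientation);
  ## the called type follows the planted type, mirrored for reference-side
  ## events -- classification itself is never consulted here
  add_row <- function(seg, eq, er, from_ref) {
    ir <- match(seg, tr$seg); iq <- match(seg, tq$seg)
    if (is.na(ir) || is.na(iq)) return()
    an <- segment_anchors(iq, ir, tq, tr, eq, er)
    co <- an$coords[order(an$coords$rs), , drop = FALSE]
    if (nrow(co) != 2L) return()
    called <- if (from_ref) mirror[[an$sv_type]] else an$sv_type
    s <- if (from_ref) er$size[1L] else eq$size[1L]
    rows[[length(rows) + 1L]] <<- data.frame(
      type = called, ref_chrom = tr$chrom[ir],
      ref_start = min(co$re[1L], co$rs[2L]),
      ref_end = max(co$re[1L], co$rs[2L]), size = s,
      stringsAsFactors = FALSE)
  }
  none_q <- sv_q[0, , drop = FALSE]
  none_r <- sv_r[0, , drop = FALSE]
  for (r in seq_len(nrow(sv_q))) {
    if (sv_q$seg[r] %in% both) next
    add_row(sv_q$seg[r], sv_q[r, , drop = FALSE], none_r, FALSE)
  }
  for (r in seq_len(nrow(sv_r))) {
    if (sv_r$seg[r] %in% both) next
    add_row(sv_r$seg[r], none_q, sv_r[r, , drop = FALSE], TRUE)
  }
  ## doubly-hit segments: only the net length difference is visible
  gain <- c(insertion = 1L, tandem_expansion = 1L, repeat_expansion = 1L,
            deletion = -1L, tandem_contraction = -1L,
            repeat_contraction = -1L)
  for (seg in both) {
    ir <- match(seg, tr$seg); iq <- match(seg, tq$seg)
    if (is.na(ir) || is.na(iq)) next
    if (tr$orient[ir] != 1L || tq$orient[iq] != 1L) next
    eq <- sv_q[sv_q$seg == seg, ][1L, ]
    er <- sv_r[sv_r$seg == seg, ][1L, ]
    net <- gain[[eq$type]] * eq$size - gain[[er$type]] * er$size
    if (abs(net) < min_size || abs(net) > max_size) next
    rows[[length(rows) + 1L]] <- data.frame(
      type = if (net > 0) "insertion" else "deletion",
      ref_chrom = tr$chrom[ir], ref_start = tr$start[ir],
      ref_end = tr$end[ir], size = abs(net), stringsAsFactors = FALSE)
  }
  ## presence differences (gene gain/loss, novel spacers): an isolated
  ## segment missing from one genome, with flanks that stay adjacent in the
  ## other, is seen as a plain deletion/insertion of the segment
  adjacent_in <- function(tab, sa, sb) {
    ia <- match(sa, tab$seg); ib <- match(sb, tab$seg)
    !is.na(ia) && !is.na(ib) && ib == ia + 1L &&
      tab$chrom[ia] == tab$chrom[ib] &&
      tab$orient[ia] == 1L && tab$orient[ib] == 1L
  }
  for (ir in seq_len(nrow(tr))) {               # ref-only segments
    seg <- tr$seg[ir]
    if (seg %in% tq$seg || tr$orient[ir] != 1L) next
    s <- tr$len[ir]
    if (s < min_size || s > max_size) next
    if (ir == 1L || ir == nrow(tr)) next
    if (tr$chrom[ir - 1L] != tr$chrom[ir] ||
        tr$chrom[ir + 1L] != tr$chrom[ir]) next
    if (!adjacent_in(tq, tr$seg[ir - 1L], tr$seg[ir + 1L])) next
    rows[[length(rows) + 1L]] <- data.frame(
      type = "deletion", ref_chrom = tr$chrom[ir], ref_start = tr$start[ir],
      ref_end = tr$end[ir], size = s, stringsAsFactors = FALSE)
  }
  for (iq in seq_len(nrow(tq))) {               # query-only segments
    seg <- tq$seg[iq]
    if (seg %in% tr$seg || tq$orient[iq] != 1L) next
    s <- tq$len[iq]
    if (s < min_size || s > max_size) next
    if (iq == 1L || iq == nrow(tq)) next
    if (tq$chrom[iq - 1L] != tq$chrom[iq] ||
        tq$chrom[iq + 1L] != tq$chrom[iq]) next
    if (!adjacent_in(tr, tq$seg[iq - 1L], tq$seg[iq + 1L])) next
    ip <- match(tq$seg[iq - 1L], tr$seg)
    rows[[length(rows) + 1L]] <- data.frame(
      type = "insertion", ref_chrom = tr$chrom[ip], ref_start = tr$end[ip],
      ref_end = tr$end[ip], size = s, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(type = character(), ref_chrom = character(),
                      ref_start = integer(), ref_end = integer(),
                      size = integer()))
  out <- do.call(rbind, rows)
  out <- out[order(out$ref_chrom, out$ref_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call SVs for many queries against several references
#'
#' Runs [pafFromTruth()] + [callSvsFromAlignment()] for every
#' (reference, query) combination, skipping query = reference, and tabulates
#' counts by SV type.
#'
#' @param sim a [CladeSim-class].
#' @param references reference genome ids.
#' @param queries query genome ids (default: all leaves).
#' @param min_size,max_size size filter in bp.
#' @return list with `tables` (nested by reference then query) and `summary`
#'   (reference, query, type, n).
#' @export
multiReferenceCatalog <- function(sim, references, queries = genomeIds(sim),
                                  min_size = 50, max_size = 10000) {
  stopifnot(length(references) >= 1L)
  tables <- list()
  summ <- list()
  for (ref in references) {
    tables[[ref]] <- list()
    for (q in queries) {
      if (identical(q, ref)) {
        message("skipping query ", q, " against itself")
        next
      }
      paf <- pafFromTruth(sim, q, ref)
      svs <- callSvsFromAlignment(paf, min_size, max_size,
                                  ref_genome = ref, query_genome = q)
      tables[[ref]][[q]] <- svs
      counts <- table(factor(svs$type, levels = SV_TYPES))
      summ[[length(summ) + 1L]] <- data.frame(
        reference = ref, query = q, type = names(counts),
        n = as.integer(counts), stringsAsFactors = FALSE)
    }
  }
  list(tables = tables,
       summary = { s <- do.call(rbind, summ); rownames(s) <- NULL; s })
}
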