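## Promoter (or any pairwise) large-indel scanning by global affine-gap
## alignment, the generalized species-specific promoter deletion analysis.

IUPAC_CHARS <- "ACGTRYSWKMBDHVN"

check_iupac <- function(seqs) {
  pat <- sprintf("^[%s%s]*$", IUPAC_CHARS, tolower(IUPAC_CHARS))
  bad <- names(seqs)[!grepl(pat, as.character(seqs))]
  if (length(bad))
    stopf("non-IUPAC characters in sequence(s): %s",
          paste(bad, collapse = ", "))
}

#' Scan promoter sequences for large indels
#'
#' Aligns each query globally to the reference with affine gap penalties
#' chosen to favour one long gap over many short ones, then reports maximal
#' gap runs of at least `min_indel` bp: gaps in the query are deletions,
#' gaps in the reference insertions. Same-type gap runs separated by fewer
#' than `merge_within` aligned columns merge into one call (alignment
#' ambiguity around repeats). Offsets are 0-based positions on the
#' reference.
#'
#' @param reference a named `DNAStringSet` of length 1 (or a plain string).
#' @param queries a named `DNAStringSet`.
#' @param min_indel minimum reported indel length (bp, >= 1).
#' @param match,mismatch,gap_opening,gap_extension alignment scores (costs
#'   are positive numbers).
#' @param merge_within merge gap runs separated by fewer aligned columns.
#' @param flank flank width (columns) used for the flanking identity.
#' @return data.frame (reference, query, type, length, ref_offset,
#'   flank_identity).
#' @examples
#' ref <- Biostrings::DNAStringSet(c(p = paste(rep("ACGTT", 60), collapse = "")))
#' qry <- Biostrings::DNAStringSet(c(q = paste0(substr(ref[[1]], 1, 100),
#'                                              substr(ref[[1]], 201, 300))))
#' scanPromoterIndels(ref, qry, min_indel = 50)
#' @export
scanPromoterIndels <- function(reference, queries, min_indel = 50,
                               match = 2, mismatch = 3, gap_opening = 5,
                               gap_extension = 1, merge_within = 10,
                               flank = 50) {
  stopifnot(min_indel >= 1)
  if (is.character(reference))
    reference <- Biostrings::DNAStringSet(c(reference = reference))
  if (is.character(queries))
    queries <- Biostrings::DNAStringSet(queries)
  if (length(reference) != 1L) stopf("reference must be a single sequence")
  if (any(Biostrings::width(reference) == 0L) ||
      any(Biostrings::width(queries) == 0L))
    stopf("empty sequence in input")
  check_iupac(reference); check_iupac(queries)
  sub_mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = -mismatch, baseOnly = FALSE)
  out <- list()
  for (qn in names(queries)) {
    pa <- Biostrings::pairwiseAlignment(
      reference[[1L]], queries[[qn]], type = "global",
      substitutionMatrix = sub_mat, gapOpening = gap_opening,
      gapExtension = gap_extension)
    a <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1L]]
    b <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1L]]
    ## reference coordinate of each alignment column (0-based; gaps inherit
    ## the position of the next reference base)
    ref_pos <- cumsum(a != "-") - (a != "-")
    runs_of <- function(is_gap) {
      r <- rle(is_gap)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      data.frame(start = starts[r$values], end = ends[r$values],
                 len = r$lengths[r$values])
    }
    calls_for <- function(gaps, type) {
      if (!nrow(gaps)) return(NULL)
      ## merge same-type runs separated by < merge_within aligned columns
      merged <- gaps[1L, , drop = FALSE]
      if (nrow(gaps) > 1L) {
        for (k in 2:nrow(gaps)) {
          if (gaps$start[k] - merged$end[nrow(merged)] - 1L < merge_within) {
            merged$end[nrow(merged)] <- gaps$end[k]
            merged$len[nrow(merged)] <- merged$len[nrow(merged)] + gaps$len[k]
          } else {
            merged <- rbind(merged, gaps[k, , drop = FALSE])
          }
        }
      }
      merged <- merged[merged$len >= min_indel, , drop = FALSE]
      if (!nrow(merged)) return(NULL)
      fl_id <- vapply(seq_len(nrow(merged)), function(k) {
        cols <- c(seq.int(max(1L, merged$start[k] - flank),
                          merged$start[k] - 1L),
                  seq.int(merged$end[k] + 1L,
                          min(length(a), merged$end[k] + flank)))
        cols <- cols[cols >= 1L & cols <= length(a)]
        cols <- cols[a[cols] != "-" & b[cols] != "-"]
        if (!length(cols)) return(NA_real_)
        100 * mean(a[cols] == b[cols])
      }, 0)
      data.frame(reference = names(reference), query = qn, type = type,
                 length = merged$len, ref_offset = ref_pos[merged$start],
                 flank_identity = fl_id, stringsAsFactors = FALSE)
    }
    out[[length(out) + 1L]] <- calls_for(runs_of(b == "-"), "deletion")
    out[[length(out) + 1L]] <- calls_for(runs_of(a == "-"), "insertion")
  }
  out <- do.call(rbind, out)
  if (is.null(out))
    return(data.frame(reference = character(), query = character(),
                      type = character(), length = integer(),
                      ref_offset = integer(), flank_identity = numeric()))
  out <- out[order(out$query, out$ref_offset), , drop = FALSE]
  rownames(out) <- NULL
  out
}
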