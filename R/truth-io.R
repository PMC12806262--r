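## Plain-text serialization of TruthSet objects: one TSV per event class,
## the generating tree as JSON (edge list, full precision), and a JSON
## manifest with md5 checksums.

TRUTH_TABLES <- list(
  families = c(genome = "character", gene_id = "character",
               family_id = "character"),
  family_events = c(branch = "character", type = "character",
                    family = "character"),
  rearrangement_events = c(branch = "character", type = "character",
                           chrom = "character", chrom2 = "character",
                           gene_from = "integer", gene_to = "integer"),
  sv_events = c(branch = "character", type = "character", seg = "character",
                chrom = "character", start = "integer", end = "integer",
                size = "integer", seg_offset = "integer"),
  hotspot_intervals = c(chrom = "character", start = "numeric",
                        end = "numeric", multiplier = "numeric"),
  promoter_indels = c(genome = "character", family = "character",
                      length = "integer", offset = "integer")
)

tree_to_list <- function(tree) {
  if (is.null(tree)) return(NULL)
  list(tip_label = tree$tip.label, node_label = tree$node.label,
       Nnode = tree$Nnode,
       edge = as.data.frame(tree$edge), edge_length = tree$edge.length)
}

tree_from_list <- function(x) {
  if (is.null(x) || !length(x)) return(NULL)
  tr <- list(edge = as.matrix(x$edge), edge.length = as.numeric(x$edge_length),
             Nnode = as.integer(x$Nnode),
             tip.label = as.character(x$tip_label),
             node.label = as.character(x$node_label))
  dimnames(tr$edge) <- NULL
  class(tr) <- "phylo"
  attr(tr, "order") <- NULL
  tr
}

#' Write a truth set to disk as plain-text fixtures
#'
#' Emits one TSV per event class, the generating tree as JSON, and a
#' `manifest.json` with per-file md5 checksums. [readTruthSet()] round-trips
#' the object exactly.
#'
#' @param truth a [TruthSet-class].
#' @param out_dir output directory (created if needed).
#' @return invisibly, the manifest as a list.
#' @export
emitFixtures <- function(truth, out_dir) {
  stopifnot(is(truth, "TruthSet"))
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stopf("cannot create directory '%s'", out_dir)
  files <- character()
  for (tab in names(TRUTH_TABLES)) {
    f <- file.path(out_dir, paste0(tab, ".tsv"))
    write.table(slot(truth, tab), f, sep = "\t", quote = FALSE,
                row.names = FALSE)
    files <- c(files, f)
  }
  tf <- file.path(out_dir, "tree.json")
  jsonlite::write_json(tree_to_list(truth@tree), tf, auto_unbox = TRUE,
                       digits = NA, null = "null")
  files <- c(files, tf)
  manifest <- list(
    tables = lapply(setNames(nm = names(TRUTH_TABLES)), function(tab)
      list(file = paste0(tab, ".tsv"), rows = nrow(slot(truth, tab)))),
    tree = "tree.json",
    md5 = as.list(tools::md5sum(files))
  )
  names(manifest$md5) <- basename(files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Read a truth set written by [emitFixtures()]
#'
#' @param dir directory containing the fixture files.
#' @return a [TruthSet-class].
#' @export
readTruthSet <- function(dir) {
  slots <- list()
  for (tab in names(TRUTH_TABLES)) {
    f <- file.path(dir, paste0(tab, ".tsv"))
    if (!file.exists(f)) stopf("missing fixture file '%s'", f)
    cls <- TRUTH_TABLES[[tab]]
    df <- read.table(f, sep = "\t", header = TRUE, colClasses = unname(cls),
                     stringsAsFactors = FALSE)
    slots[[tab]] <- df
  }
  tree <- tree_from_list(jsonlite::read_json(file.path(dir, "tree.json"),
                                             simplifyVector = TRUE))
  new("TruthSet", families = slots$families,
      family_events = slots$family_events,
      rearrangement_events = slots$rearrangement_events,
      sv_events = slots$sv_events,
      hotspot_intervals = slots$hotspot_intervals,
      promoter_indels = slots$promoter_indels, tree = tree)
}
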