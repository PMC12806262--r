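## S4 classes for the central data objects.

setOldClass("phylo")

#' Simulation configuration for a synthetic clade
#'
#' Parameter object for [simulateClade()]. Defaults describe a small clade of
#' annotated genomes: a handful of chromosomes carrying fixed-length genes
#' separated by intergenic spacers, evolving along a rooted tree by gene
#' family gain/loss, chromosomal rearrangements, six classes of structural
#' variant, Jukes-Cantor substitutions and (optionally) promoter deletions.
#'
#' Gain/loss and substitution rates are per branch-length unit; rearrangement
#' and SV rates are expected event counts per branch. Realized counts are
#' Poisson draws recorded in the emitted [TruthSet].
#'
#' @slot n_genomes number of leaf genomes (used when `tree = "random"`).
#' @slot n_chromosomes,genes_per_chromosome ancestral genome layout.
#' @slot gene_length_bp,intergenic_bp segment lengths in bp.
#' @slot tree a rooted `phylo` with branch lengths, or `"random"` for a Yule
#'   tree with unit birth rate rescaled to `tree_depth`.
#' @slot tree_depth root-to-leaf depth used for random trees.
#' @slot rate_gene_gain,rate_gene_loss,rate_duplication events per
#'   branch-length unit.
#' @slot rate_inversion,rate_fission,rate_fusion,rate_translocation expected
#'   events per branch.
#' @slot sv_rates named numeric, expected events per branch for each of the
#'   six SV types.
#' @slot sv_size_range inclusive bp bounds for SV sizes (min at least 50,
#'   the SV caller's floor).
#' @slot sv_in_genes allow SVs to hit gene segments (default FALSE keeps the
#'   PAV and SV truths independent).
#' @slot hotspot_spec data.frame (chrom, start, end, multiplier) of ancestor
#'   intervals whose intergenic segments attract SVs `multiplier`-fold.
#' @slot substitution_rate expected substitutions per site per branch-length
#'   unit.
#' @slot promoter_deletion_spec empty list, or
#'   `list(genomes=, family=, length_bp=)` planting a species-specific
#'   promoter deletion (the foliar-nectary style case).
#' @slot promoter_bp promoter width upstream of the start codon.
#' @slot seed integer; fully determines the output.
#' @seealso [simConfig()], [simulateClade()]
#' @export
setClass("SimConfig", representation(
  n_genomes = "numeric", n_chromosomes = "numeric",
  genes_per_chromosome = "numeric", gene_length_bp = "numeric",
  intergenic_bp = "numeric", tree = "ANY", tree_depth = "numeric",
  rate_gene_gain = "numeric", rate_gene_loss = "numeric",
  rate_duplication = "numeric", rate_inversion = "numeric",
  rate_fission = "numeric", rate_fusion = "numeric",
  rate_translocation = "numeric", sv_rates = "numeric",
  sv_size_range = "numeric", sv_in_genes = "logical",
  hotspot_spec = "data.frame", substitution_rate = "numeric",
  promoter_deletion_spec = "list", promoter_bp = "numeric",
  seed = "numeric"
))

SV_TYPES <- c("insertion", "deletion", "tandem_expansion",
              "tandem_contraction", "repeat_expansion", "repeat_contraction")

setValidity("SimConfig", function(object) {
  msgs <- character()
  rates <- c(object@rate_gene_gain, object@rate_gene_loss,
             object@rate_duplication, object@rate_inversion,
             object@rate_fission, object@rate_fusion,
             object@rate_translocation, object@substitution_rate,
             object@sv_rates)
  if (any(rates < 0)) msgs <- c(msgs, "all rates must be >= 0")
  if (!setequal(names(object@sv_rates), SV_TYPES))
    msgs <- c(msgs, "sv_rates must be named with the six SV types")
  if (length(object@sv_size_range) != 2L ||
      object@sv_size_range[1] < 50 ||
      object@sv_size_range[2] < object@sv_size_range[1])
    msgs <- c(msgs, "sv_size_range must be [min >= 50, max >= min]")
  if (is.character(object@tree)) {
    if (!identical(object@tree, "random"))
      msgs <- c(msgs, "tree must be a rooted phylo object or \"random\"")
    if (object@n_genomes < 2) msgs <- c(msgs, "need at least 2 genomes")
  } else if (inherits(object@tree, "phylo")) {
    if (is.null(object@tree$edge.length))
      msgs <- c(msgs, "tree must carry branch lengths")
    if (length(object@tree$tip.label) < 2)
      msgs <- c(msgs, "tree must have >= 2 leaves")
    if (!ape::is.rooted(object@tree))
      msgs <- c(msgs, "tree must be rooted")
  } else msgs <- c(msgs, "tree must be a rooted phylo object or \"random\"")
  if (length(object@seed) != 1L || is.na(object@seed))
    msgs <- c(msgs, "seed must be a single integer")
  if (object@promoter_bp > object@intergenic_bp)
    msgs <- c(msgs, "promoter_bp cannot exceed intergenic_bp")
  if (length(msgs)) msgs else TRUE
})

#' Planted ground truth for a simulated clade
#'
#' Event-level record of everything [simulateClade()] planted, used as the
#' oracle by the test suite and by the pipeline's truth-comparison report.
#' Branch-level tables identify a branch by its child node label; events on an
#' internal branch apply to all descendant leaves (see [svTruthForGenome()]).
#'
#' @slot families data.frame (genome, gene_id, family_id): true family
#'   membership of every emitted gene.
#' @slot family_events per-branch gain/loss events.
#' @slot rearrangement_events per-branch typed rearrangements with gene-rank
#'   breakpoints.
#' @slot sv_events per-branch typed SVs with ancestor-coordinate intervals
#'   (0-based half-open).
#' @slot hotspot_intervals the planted clustered-SV regions.
#' @slot promoter_indels data.frame (genome, family, gene_id, length, offset).
#' @slot tree the generating tree (`phylo`, node-labelled).
#' @export
setClass("TruthSet", representation(
  families = "data.frame", family_events = "data.frame",
  rearrangement_events = "data.frame", sv_events = "data.frame",
  hotspot_intervals = "data.frame", promoter_indels = "data.frame",
  tree = "ANY"
))

#' A simulated clade of annotated genomes
#'
#' Result of [simulateClade()]: one assembled, annotated genome per tree leaf
#' plus the ancestral genome and the planted [TruthSet]. Genomes are stored
#' as per-chromosome segment tables (genes and intergenic spacers with their
#' ancestral identities), from which FASTA/GFF3 and CDS sets are derived.
#'
#' @slot config the [SimConfig] used.
#' @slot tree the realized `phylo` tree (leaf labels are genome ids).
#' @slot ancestor,genomes internal genome representations.
#' @slot truth the [TruthSet].
#' @export
setClass("CladeSim", representation(
  config = "SimConfig", tree = "ANY", ancestor = "list",
  genomes = "list", truth = "TruthSet"
))

#' Presence/absence variation matrix
#'
#' Binary gene-family-by-genome matrix with the family membership table it
#' was built from. Families are partitioned by occupancy into `core`
#' (present in all genomes), `specific` (exactly one) and `variable`
#' (in between); see [classifyOccupancy()].
#'
#' @slot presence integer matrix, families x genomes, values 0/1.
#' @slot members data.frame (family_id, genome, gene_id).
#' @export
setClass("PAVMatrix", representation(
  presence = "matrix", members = "data.frame"
))

setValidity("PAVMatrix", function(object) {
  m <- object@presence
  if (!all(m %in% c(0L, 1L))) return("presence matrix must be binary")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    return("presence matrix needs family and genome names")
  if (nrow(m) > 0L && any(rowSums(m) == 0L))
    return("zero-occupancy family row: every family must occur somewhere")
  TRUE
})

#' Signed block-order encoding of one genome
#'
#' Each chromosome is an ordered vector of signed shared-block (marker) ids;
#' the sign records orientation relative to the pivot genome's block
#' definition. Input encoding for ancestral genome inference.
#'
#' @slot genome_id character.
#' @slot chromosomes named list of signed integer vectors; each block id
#'   appears exactly once per genome.
#' @export
setClass("MarkerGenome", representation(
  genome_id = "character", chromosomes = "list"
))

setValidity("MarkerGenome", function(object) {
  ids <- abs(unlist(object@chromosomes, use.names = FALSE))
  if (anyDuplicated(ids)) return("block ids must be unique within a genome")
  if (length(ids) && any(ids == 0)) return("block ids must be non-zero")
  TRUE
})

#' Inferred ancestral genome as CARs
#'
#' Contiguous ancestral regions (CARs): ordered runs of signed block ids
#' produced by [inferMedianGenome()]. Linear only; every block of the shared
#' universe is used exactly once.
#'
#' @slot cars list of signed integer vectors.
#' @slot blocks the shared block-id universe.
#' @export
setClass("AncestorGenome", representation(
  cars = "list", blocks = "integer"
))

setValidity("AncestorGenome", function(object) {
  ids <- abs(unlist(object@cars, use.names = FALSE))
  if (anyDuplicated(ids)) return("each block id must be used exactly once")
  if (!setequal(ids, object@blocks)) return("CARs must cover the block universe")
  TRUE
})

#' Ultrametric, time-calibrated tree
#'
#' A rooted tree with node ages in absolute time units (Mya), obtained by
#' [calibrateAges()].
#'
#' @slot tree `phylo`, branch lengths in age units.
#' @slot ages numeric vector of node ages indexed by ape node number
#'   (leaves have age 0).
#' @slot calibration list(node=, age=) used for scaling.
#' @export
setClass("CalibratedTree", representation(
  tree = "ANY", ages = "numeric", calibration = "list"
))

## ---- accessors & show methods -------------------------------------------

#' @describeIn PAVMatrix-class the binary presence matrix.
#' @param x,object a `PAVMatrix`.
#' @export
presence <- function(x) {
  stopifnot(is(x, "PAVMatrix"))
  x@presence
}

#' @describeIn PAVMatrix-class family membership table.
#' @export
familyMembers <- function(x) {
  stopifnot(is(x, "PAVMatrix"))
  x@members
}

#' @describeIn PAVMatrix-class number of genomes carrying each family.
#' @export
occupancy <- function(x) rowSums(presence(x))

#' Genome identifiers of an object
#' @param x a `CladeSim`, `PAVMatrix` or `MarkerGenome` list.
#' @export
setGeneric("genomeIds", function(x) standardGeneric("genomeIds"))

#' @rdname genomeIds
#' @export
setMethod("genomeIds", "CladeSim", function(x) names(x@genomes))

#' @rdname genomeIds
#' @export
setMethod("genomeIds", "PAVMatrix", function(x) colnames(x@presence))

#' Planted truth of a simulation
#' @param x a `CladeSim`.
#' @export
truth <- function(x) {
  stopifnot(is(x, "CladeSim"))
  x@truth
}

#' @describeIn MarkerGenome-class chromosomes as signed block-id vectors.
#' @param x a `MarkerGenome`.
#' @export
markerChromosomes <- function(x) {
  stopifnot(is(x, "MarkerGenome"))
  x@chromosomes
}

#' @describeIn AncestorGenome-class the CAR list.
#' @param x an `AncestorGenome`.
#' @export
CARs <- function(x) {
  stopifnot(is(x, "AncestorGenome"))
  x@cars
}

#' @describeIn CalibratedTree-class node ages (Mya), indexed by node number.
#' @param x a `CalibratedTree`.
#' @export
nodeAges <- function(x) {
  stopifnot(is(x, "CalibratedTree"))
  x@ages
}

setMethod("show", "SimConfig", function(object) {
  tr <- if (is.character(object@tree)) "random (Yule)" else
    sprintf("fixed (%d leaves)", length(object@tree$tip.label))
  cat("SimConfig:", object@n_chromosomes, "chromosomes x",
      object@genes_per_chromosome, "genes; tree:", tr,
      "; seed", object@seed, "\n")
})

setMethod("show", "CladeSim", function(object) {
  cat("CladeSim with", length(object@genomes), "genomes:",
      paste(head(names(object@genomes), 8), collapse = ", "),
      if (length(object@genomes) > 8) "..." else "", "\n")
  cat("  planted events:", nrow(object@truth@family_events), "family,",
      nrow(object@truth@rearrangement_events), "rearrangement,",
      nrow(object@truth@sv_events), "SV,",
      nrow(object@truth@promoter_indels), "promoter indel\n")
})

setMethod("show", "PAVMatrix", function(object) {
  cat("PAVMatrix:", nrow(object@presence), "families x",
      ncol(object@presence), "genomes\n")
  if (nrow(object@presence)) {
    cl <- classifyOccupancy(object)
    cat("  core", cl["core"], "| variable", cl["variable"],
        "| specific", cl["specific"], "\n")
  }
})

setMethod("show", "MarkerGenome", function(object) {
  cat("MarkerGenome", object@genome_id, "-",
      length(object@chromosomes), "chromosomes,",
      length(unlist(object@chromosomes)), "blocks\n")
})

setMethod("show", "AncestorGenome", function(object) {
  cat("AncestorGenome:", length(object@cars), "CARs over",
      length(object@blocks), "blocks\n")
  for (i in seq_along(object@cars))
    cat("  CAR", i, ":", paste(object@cars[[i]], collapse = " "), "\n")
})

setMethod("show", "CalibratedTree", function(object) {
  cat("CalibratedTree:", length(object@tree$tip.label), "leaves; root age",
      signif(max(object@ages), 4), "- calibrated at node",
      object@calibration$node, "=", object@calibration$age, "\n")
})

setMethod("show", "TruthSet", function(object) {
  cat("TruthSet:", nrow(object@families), "genes,",
      nrow(object@family_events), "family events,",
      nrow(object@rearrangement_events), "rearrangements,",
      nrow(object@sv_events), "SVs,",
      nrow(object@promoter_indels), "promoter indels\n")
})
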