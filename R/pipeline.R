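## End-to-end pipeline: simulate -> families -> PAV -> synteny -> ancestor
## -> SVs -> hotspots -> tree -> promoter scan, with a machine-readable,
## deterministic report.

#' Demonstration configuration emulating a diploid cotton style clade
#'
#' Eight genomes on a fixed calibrated tree (in My): an outgroup splitting
#' at 10.13, a two-species "A-like" cultivated clade and a five-species
#' "D-like" wild clade separating at 5.45. Gene turnover, rearrangement and
#' SV rates are chosen to produce a core/variable/specific partition, SV
#' hotspot, and species-specific promoter deletion (444 bp, in two D-like
#' genomes) of the kind reported for real diploid cotton pan-genomes; see
#' the methods vignette for the reasoning behind each default.
#'
#' @param seed integer seed.
#' @return a [SimConfig-class].
#' @export
demoConfig <- function(seed = 1) {
  nwk <- paste0("(K1:10.13,((A1:1.5,A2:1.5):3.95,((D1:1,D2:1):1.5,",
                "(D3:1.4,(D4:0.8,D5:0.8):0.6):1.1):2.95):4.68);")
  tree <- ape::read.tree(text = nwk)
  simConfig(
    n_genomes = 8, n_chromosomes = 3, genes_per_chromosome = 100,
    gene_length_bp = 300, intergenic_bp = 2000, tree = tree,
    rate_gene_gain = 2.5, rate_gene_loss = 5,
    rate_inversion = 0.6, rate_fission = 0.15, rate_fusion = 0.15,
    rate_translocation = 0.2,
    sv_rates = c(insertion = 2, deletion = 2, tandem_expansion = 2,
                 tandem_contraction = 2, repeat_expansion = 2,
                 repeat_contraction = 2),
    sv_size_range = c(50, 600), substitution_rate = 0.0015,
    hotspot_spec = data.frame(chrom = "chr1", start = 40000, end = 100000,
                              multiplier = 12),
    promoter_deletion_spec = list(genomes = c("D4", "D5"),
                                  family = "F00050", length_bp = 444),
    promoter_bp = 1500, seed = seed)
}

## annotation + family rows for the ancestor genome (true families)
ancestor_family_rows <- function(sim) {
  g <- sim@ancestor
  rows <- list()
  for (cn in names(g$chroms)) {
    df <- g$chroms[[cn]]
    idx <- which(df$type == "gene")
    if (length(idx))
      rows[[cn]] <- data.frame(genome = "ancestor", gene_id = df$seg[idx],
                               family_id = df$family[idx])
  }
  do.call(rbind, rows)
}

## planted hotspot intervals translated into a reference genome's
## coordinates: the bounding span of the interval's spacer segments on the
## reference chromosome that retained most of them
hotspot_truth_in_ref <- function(sim, reference) {
  hspec <- truth(sim)@hotspot_intervals
  if (!nrow(hspec)) return(NULL)
  lay <- sim@ancestor$layout
  tr <- segment_table(genome_object(sim, reference))
  mid <- (lay$start + lay$end) / 2
  out <- list()
  for (h in seq_len(nrow(hspec))) {
    segs <- lay$seg[lay$chrom == hspec$chrom[h] & mid >= hspec$start[h] &
                    mid < hspec$end[h]]
    ti <- match(segs, tr$seg)
    ti <- ti[!is.na(ti)]
    if (!length(ti)) next
    sp <- split(ti, tr$chrom[ti])
    g <- sp[[which.max(lengths(sp))]]
    out[[length(out) + 1L]] <- data.frame(
      chrom = tr$chrom[g[1L]], start = min(tr$start[g]),
      end = max(tr$end[g]), stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out) else NULL
}

stage_checksum <- function(obj) {
  f <- tempfile()
  on.exit(unlink(f))
  jsonlite::write_json(obj, f, auto_unbox = TRUE, digits = 10,
                       force = TRUE, null = "null")
  unname(tools::md5sum(f))
}

interval_jaccard <- function(s1, e1, s2, e2) {
  inter <- max(0, min(e1, e2) - max(s1, s2))
  union <- (e1 - s1) + (e2 - s2) - inter
  if (union <= 0) return(0)
  inter / union
}

#' Match called SVs against expected calls
#'
#' Greedy one-to-one matching: a call matches a truth record of the same
#' type on the same reference chromosome when start breakpoints agree within
#' `tol` bp.
#'
#' @param calls table from [callSvsFromAlignment()].
#' @param truth_tab table from [truthSvTable()].
#' @param tol breakpoint tolerance in bp.
#' @return list with `recall`, `precision`, and counts.
#' @export
compareSvCalls <- function(calls, truth_tab, tol = 10) {
  if (!nrow(truth_tab))
    return(list(recall = NA_real_,
                precision = if (nrow(calls)) 0 else NA_real_,
                n_truth = 0L, n_calls = nrow(calls), n_matched = 0L))
  matched_call <- rep(FALSE, nrow(calls))
  matched_truth <- rep(FALSE, nrow(truth_tab))
  for (i in seq_len(nrow(truth_tab))) {
    cand <- which(!matched_call & calls$type == truth_tab$type[i] &
                  calls$ref_chrom == truth_tab$ref_chrom[i] &
                  abs(calls$ref_start - truth_tab$ref_start[i]) <= tol)
    if (length(cand)) {
      j <- cand[which.min(abs(calls$ref_start[cand] -
                              truth_tab$ref_start[i]))]
      matched_call[j] <- TRUE
      matched_truth[i] <- TRUE
    }
  }
  list(recall = mean(matched_truth),
       precision = if (nrow(calls)) mean(matched_call) else NA_real_,
       n_truth = nrow(truth_tab), n_calls = nrow(calls),
       n_matched = sum(matched_truth))
}

#' Run the full analysis pipeline on a simulated clade
#'
#' Simulates a clade from `config`, then runs gene family clustering, PAV
#' analysis, collinearity and marker construction against a pivot genome,
#' ancestral genome inference, SV calling against several references,
#' hotspot detection, phylogeny with age calibration, and the promoter
#' indel scan. Returns a deterministic, JSON-serializable report including
#' truth-comparison metrics; optionally writes all stage artifacts.
#'
#' @param config a [SimConfig-class] (see [demoConfig()]).
#' @param out_dir optional artifact directory.
#' @param references SV reference genome ids (default: three spread over
#'   the sorted genome ids).
#' @param pivot,outgroup pivot genome for marker construction and outgroup
#'   for rooting (default: the tree's first tip).
#' @param calibration list(tips=, age=); default calibrates the ingroup
#'   (non-outgroup) ancestor at its true age from the generating tree.
#' @param window_bp,step_bp,n_perm,alpha hotspot parameters (demo-scale
#'   windows by default).
#' @param min_size,max_size SV size filter.
#' @param min_anchors,max_gap collinearity chaining parameters.
#' @param n_orderings accumulation-curve orderings.
#' @param max_scs_families cap on single-copy families used for distances
#'   (kept moderate because each pair is globally aligned).
#' @param verbose log one line per stage.
#' @return the report as a nested list (see [validateReport()]).
#' @export
runPipeline <- function(config = demoConfig(), out_dir = NULL,
                        references = NULL, pivot = NULL, outgroup = NULL,
                        calibration = NULL, window_bp = 20000,
                        step_bp = window_bp, n_perm = 2000, alpha = 0.05,
                        min_size = 50, max_size = 10000, min_anchors = 5,
                        max_gap = 25, n_orderings = 50,
                        max_scs_families = 60, verbose = TRUE) {
  t_all <- Sys.time()
  log_stage <- function(name, t0) {
    if (verbose)
      message(sprintf("[panclade] %-10s %6.1fs", name,
                      as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }

  ## --- simulate ----------------------------------------------------------
  t0 <- Sys.time()
  sim <- simulateClade(config)
  ids <- genomeIds(sim)
  tru <- truth(sim)
  log_stage("simulate", t0)

  ## --- families + PAV ----------------------------------------------------
  t0 <- Sys.time()
  cds <- cdsSequences(sim)
  fam <- clusterGeneFamilies(cds)
  pav <- buildPavMatrix(fam, genomes = ids)
  counts <- classifyOccupancy(pav)
  acc <- accumulationCurves(pav, n_orderings = n_orderings,
                            seed = derive_seed(config@seed, 2))
  dendro <- clusterGenomesByPav(pav)
  tf <- tru@families
  rand <- randIndex(
    fam$family_id,
    tf$family_id[match(paste(fam$genome, fam$gene_id),
                       paste(tf$genome, tf$gene_id))])
  log_stage("pav", t0)

  ## --- synteny + markers -------------------------------------------------
  t0 <- Sys.time()
  if (is.null(pivot)) pivot <- sim@tree$tip.label[1L]
  if (is.null(outgroup)) outgroup <- sim@tree$tip.label[1L]
  ann <- lapply(setNames(nm = ids), function(g) geneAnnotations(sim, g))
  ## the true ancestor joins the comparison for evaluation only
  ann$ancestor <- geneAnnotations(sim, "ancestor")
  fam_eval <- rbind(tru@families[, c("family_id", "genome", "gene_id")],
                    ancestor_family_rows(sim)[, c("family_id", "genome",
                                                  "gene_id")])
  chained <- list()
  synteny_rows <- list()
  for (g in c(setdiff(ids, pivot), "ancestor")) {
    fams_for <- if (g == "ancestor") fam_eval else fam
    anch <- findAnchors(fams_for, ann, c(pivot, g))
    ch <- chainAnchors(anch, min_anchors = min_anchors, max_gap = max_gap)
    ch$blocks <- flagDisorderedBlocks(ch)
    chained[[g]] <- ch
    if (g != "ancestor")
      synteny_rows[[g]] <- data.frame(
        genome = g, n_anchors = sum(!is.na(ch$anchors$block_id)),
        n_blocks = nrow(ch$blocks),
        n_disordered = sum(ch$blocks$disordered))
  }
  synteny_tab <- do.call(rbind, synteny_rows)
  rownames(synteny_tab) <- NULL
  mk <- buildMarkerGenomes(chained, pivot)
  log_stage("synteny", t0)

  ## --- ancestor ----------------------------------------------------------
  t0 <- Sys.time()
  leaf_markers <- mk$markers[setdiff(names(mk$markers), "ancestor")]
  graph <- buildAdjacencyGraph(unname(leaf_markers))
  anc_genome <- inferMedianGenome(graph)
  rearr <- do.call(rbind, lapply(leaf_markers, function(m)
    countFissionFusion(anc_genome, m)))
  rownames(rearr) <- NULL
  anc_recovery <- adjacencyRecovery(anc_genome, mk$markers$ancestor)
  log_stage("ancestor", t0)

  ## --- SVs + hotspots ----------------------------------------------------
  t0 <- Sys.time()
  if (is.null(references)) {
    sids <- sort(ids)
    references <- unique(sids[round(seq(1, length(sids),
                                        length.out = min(3, length(sids))))])
  }
  cat_res <- multiReferenceCatalog(sim, references, queries = ids,
                                   min_size = min_size, max_size = max_size)
  ## truth comparison pooled over (reference, query) pairs
  n_match <- 0L; n_truth <- 0L; n_call <- 0L
  for (ref in references) {
    for (q in setdiff(ids, ref)) {
      cmp <- compareSvCalls(cat_res$tables[[ref]][[q]],
                            truthSvTable(sim, q, ref))
      n_match <- n_match + cmp$n_matched
      n_truth <- n_truth + cmp$n_truth
      n_call <- n_call + cmp$n_calls
    }
  }
  primary_ref <- references[1L]
  pooled <- do.call(rbind, cat_res$tables[[primary_ref]])
  ## non-redundant SV loci: an event shared by several queries (it happened
  ## on a deep branch, or on the reference's own lineage) is one locus
  pooled <- unique(pooled[, c("ref_chrom", "ref_start", "ref_end", "type",
                              "size")])
  ref_lengths <- vapply(genome_object(sim, primary_ref)$chroms,
                        function(df) sum(nchar(df$seq)), 0)
  hs <- detectHotspots(pooled, ref_lengths, window_bp = window_bp,
                       step_bp = step_bp, n_perm = n_perm, alpha = alpha,
                       seed = derive_seed(config@seed, 3))
  hs <- annotateRegions(hs, geneAnnotations(sim, primary_ref))
  hs_jacc <- NA_real_
  hs_truth <- hotspot_truth_in_ref(sim, primary_ref)
  if (!is.null(hs_truth) && nrow(hs_truth)) {
    hj <- numeric(0)
    for (h in seq_len(nrow(hs_truth))) {
      hi <- hs_truth[h, ]
      best <- 0
      for (r in seq_len(nrow(hs))) {
        if (hs$ref_chrom[r] != hi$chrom) next
        best <- max(best, interval_jaccard(hs$start[r], hs$end[r],
                                           hi$start, hi$end))
      }
      hj <- c(hj, best)
    }
    hs_jacc <- mean(hj)
  }
  log_stage("svcalls", t0)

  ## --- phylogeny ---------------------------------------------------------
  t0 <- Sys.time()
  scs <- selectSingleCopy(fam, cds)
  if (length(scs$families) > max_scs_families) {
    keep <- scs$families[seq_len(max_scs_families)]
    scs <- list(families = keep, seqs = scs$seqs[keep])
  }
  dm <- distanceMatrix(scs)
  phy <- njTree(dm, outgroup)
  if (is.null(calibration)) {
    true_h <- mean_path_heights(sim@tree)
    ing <- setdiff(ids, outgroup)
    cal_node <- ape::getMRCA(sim@tree, ing)
    calibration <- list(tips = ing, age = true_h[cal_node])
  }
  ct <- calibrateAges(phy, calibration$tips, calibration$age)
  root_age <- max(nodeAges(ct))
  rf <- ape::dist.topo(ape::unroot(phy), ape::unroot(sim@tree))
  log_stage("phylo", t0)

  ## --- promoter scan -----------------------------------------------------
  t0 <- Sys.time()
  prom <- NULL
  pds <- config@promoter_deletion_spec
  if (length(pds)) {
    proms <- promoterSequences(sim, pds$family)
    ref_gen <- sort(setdiff(names(proms), pds$genomes))[1L]
    prom <- scanPromoterIndels(proms[ref_gen],
                               proms[setdiff(names(proms), ref_gen)],
                               min_indel = 50)
  }
  log_stage("promoter", t0)

  report <- list(
    parameters = list(
      seed = config@seed, n_genomes = length(ids),
      n_chromosomes = config@n_chromosomes,
      genes_per_chromosome = config@genes_per_chromosome,
      substitution_rate = config@substitution_rate,
      pivot = pivot, outgroup = outgroup, references = references,
      min_size = min_size, max_size = max_size, window_bp = window_bp,
      n_perm = n_perm, alpha = alpha, min_anchors = min_anchors,
      max_gap = max_gap, n_orderings = n_orderings,
      calibration_age = calibration$age),
    pav = list(counts = as.list(counts), accumulation = acc,
               genome_tree = ape::write.tree(dendro)),
    synteny = list(per_genome = synteny_tab),
    ancestor = list(n_markers = length(anc_genome@blocks),
                    n_cars = length(anc_genome@cars),
                    cars = lapply(unname(CARs(anc_genome)), as.integer),
                    rearrangements = rearr),
    svs = list(summary = cat_res$summary,
               totals = stats::aggregate(n ~ reference + query,
                                         cat_res$summary, sum)),
    hotspots = list(n_regions = nrow(hs),
                    regions = hs[, c("ref_chrom", "start", "end", "sv_count",
                                     "empirical_p", "bh_q", "genes")]),
    phylo = list(tree = ape::write.tree(ct@tree),
                 n_single_copy = length(scs$families),
                 root_age = root_age,
                 calibration_age = calibration$age),
    promoter = list(calls = prom),
    truth_comparison = list(
      family_rand_index = rand,
      ancestor_adjacency_recovery = anc_recovery,
      sv_recall = if (n_truth) n_match / n_truth else NA_real_,
      sv_precision = if (n_call) n_match / n_call else NA_real_,
      hotspot_jaccard = hs_jacc,
      tree_rf_distance = as.numeric(rf))
  )
  report$checksums <- list(
    pav = stage_checksum(report$pav),
    synteny = stage_checksum(report$synteny),
    ancestor = stage_checksum(report$ancestor),
    svs = stage_checksum(report$svs),
    hotspots = stage_checksum(report$hotspots),
    phylo = stage_checksum(report$phylo),
    promoter = stage_checksum(report$promoter))

  if (!is.null(out_dir)) writeArtifacts(sim, report, pav, mk, anc_genome,
                                        cat_res, hs, ct, out_dir)
  if (verbose)
    message(sprintf("[panclade] total      %6.1fs",
                    as.numeric(difftime(Sys.time(), t_all, units = "secs"))))
  report
}

writeArtifacts <- function(sim, report, pav, mk, anc_genome, cat_res, hs,
                           ct, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write.table(presence(pav), file.path(out_dir, "pav_matrix.tsv"),
              sep = "\t", quote = FALSE, col.names = NA)
  for (ref in names(cat_res$tables)) {
    for (q in names(cat_res$tables[[ref]])) {
      write.table(cat_res$tables[[ref]][[q]],
                  file.path(out_dir, sprintf("svs_%s_vs_%s.tsv", q, ref)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  if (nrow(hs)) {
    bed <- hs[, c("ref_chrom", "start", "end")]
    write.table(bed, file.path(out_dir, "hotspots.bed"), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  write.table(hs, file.path(out_dir, "hotspots.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  con <- file(file.path(out_dir, "marker_genomes.txt"), "w")
  for (g in names(mk$markers)) {
    writeLines(paste0(">", g), con)
    for (v in markerChromosomes(mk$markers[[g]]))
      writeLines(paste(v, collapse = " "), con)
  }
  close(con)
  writeLines(vapply(CARs(anc_genome), paste, "", collapse = " "),
             file.path(out_dir, "ancestor_cars.txt"))
  ape::write.tree(ct@tree, file.path(out_dir, "tree_calibrated.nwk"))
  ages <- nodeAges(ct)
  write.table(data.frame(node = names(ages), age = unname(ages)),
              file.path(out_dir, "node_ages.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  emitFixtures(truth(sim), file.path(out_dir, "truth"))
  writeClade(sim, file.path(out_dir, "genomes"), include_ancestor = TRUE)
  writeReport(report, file.path(out_dir, "report.json"))
  invisible(out_dir)
}

#' Write a pipeline report as JSON
#' @param report list from [runPipeline()].
#' @param path output file.
#' @export
writeReport <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE, null = "null", force = TRUE)
  invisible(path)
}

#' Validate a pipeline report against the bundled schema
#'
#' Structural validation: every required field path exists and has the
#' expected JSON type, per `inst/extdata/report_schema.json`.
#'
#' @param report list from [runPipeline()] (or parsed from JSON).
#' @return TRUE invisibly; stops with the offending paths otherwise.
#' @export
validateReport <- function(report) {
  schema <- jsonlite::read_json(system.file("extdata",
                                            "report_schema.json",
                                            package = "panclade"))
  problems <- character()
  for (spec in schema$required) {
    path <- strsplit(spec$path, "/", fixed = TRUE)[[1L]]
    node <- report
    ok <- TRUE
    for (p in path) {
      if (!is.list(node) || is.null(node[[p]])) { ok <- FALSE; break }
      node <- node[[p]]
    }
    if (!ok) {
      problems <- c(problems, sprintf("missing: %s", spec$path))
      next
    }
    type_ok <- switch(spec$type,
      number = is.numeric(node),
      string = is.character(node),
      list = is.list(node) || is.data.frame(node),
      TRUE)
    if (!type_ok)
      problems <- c(problems,
                    sprintf("wrong type at %s (want %s)", spec$path,
                            spec$type))
  }
  if (length(problems))
    stopf("report schema violations:\n%s", paste(problems, collapse = "\n"))
  invisible(TRUE)
}
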