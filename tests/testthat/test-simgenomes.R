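test_that("zero-rate configs reproduce the ancestor byte for byte", {
  sim <- simulateClade(quiet_config(n_genomes = 3, seed = 11))
  anc <- as.character(assemblySeqs(sim, "ancestor"))
  for (g in genomeIds(sim)) {
    expect_identical(unname(as.character(assemblySeqs(sim, g))), unname(anc))
  }
  ## downstream PAV is all-core
  fam <- clusterGeneFamilies(cdsSequences(sim))
  counts <- classifyOccupancy(buildPavMatrix(fam, genomes = genomeIds(sim)))
  expect_equal(unname(counts["core"]), unname(counts["total"]))
  expect_equal(unname(counts["variable"]) + unname(counts["specific"]), 0L)
})

test_that("the seed fully determines the simulation", {
  cfg <- simConfig(n_genomes = 4, n_chromosomes = 2,
                   genes_per_chromosome = 15, sv_rates = sv_rates_all(1),
                   seed = 99)
  s1 <- simulateClade(cfg)
  s2 <- simulateClade(cfg)
  for (g in genomeIds(s1)) {
    expect_identical(as.character(assemblySeqs(s1, g)),
                     as.character(assemblySeqs(s2, g)))
  }
  expect_identical(truth(s1)@sv_events, truth(s2)@sv_events)
  expect_identical(truth(s1)@family_events, truth(s2)@family_events)
})

test_that("gene counts balance gains and losses along each root path", {
  cfg <- simConfig(n_genomes = 5, n_chromosomes = 2,
                   genes_per_chromosome = 25, rate_gene_gain = 3,
                   rate_gene_loss = 3, sv_rates = sv_rates_all(0),
                   substitution_rate = 0, seed = 7)
  sim <- simulateClade(cfg)
  tru <- truth(sim)
  n_anc <- 2 * 25
  for (g in genomeIds(sim)) {
    path <- panclade:::branch_path(tru@tree, g)
    ev <- tru@family_events[tru@family_events$branch %in% path, ]
    expected <- n_anc + sum(ev$type == "gain") - sum(ev$type == "loss")
    expect_equal(nrow(geneAnnotations(sim, g)), expected)
  }
})

test_that("realized SV counts per branch follow the configured Poisson law", {
  ## two-leaf clade, deletions only with mean 20 per branch; compare the
  ## realized mean against direct Poisson sampling at matched replication
  n_rep <- 200
  mean_target <- 20
  counts <- vapply(seq_len(n_rep), function(s) {
    cfg <- simConfig(n_genomes = 2, n_chromosomes = 1,
                     genes_per_chromosome = 100, tree_depth = 1,
                     rate_gene_gain = 0, rate_gene_loss = 0,
                     rate_inversion = 0, rate_fission = 0, rate_fusion = 0,
                     rate_translocation = 0,
                     sv_rates = c(deletion = mean_target),
                     sv_size_range = c(50, 100),
                     substitution_rate = 0, seed = 1000 + s)
    sim <- simulateClade(cfg)
    ev <- truth(sim)@sv_events
    sum(ev$branch == "G1")
  }, 0)
  set.seed(4242)
  oracle <- rpois(n_rep, mean_target)
  se <- sqrt(mean_target / n_rep)
  expect_lt(abs(mean(counts) - mean_target), 3 * se)
  expect_lt(abs(mean(counts) - mean(oracle)), 6 * se)
  ## chi-square goodness of fit against the Poisson law itself
  brk <- c(-Inf, 14, 17, 20, 23, 26, Inf)
  obs <- table(cut(counts, brk))
  pr <- diff(ppois(c(-Inf, 14, 17, 20, 23, 26, Inf), mean_target))
  gof <- suppressWarnings(chisq.test(as.vector(obs), p = pr))
  expect_gt(gof$p.value, 0.01)
})

test_that("an SV too large for any spacer raises a generation error", {
  cfg <- simConfig(n_genomes = 2, n_chromosomes = 1,
                   genes_per_chromosome = 4, intergenic_bp = 300,
                   promoter_bp = 200, rate_gene_gain = 0, rate_gene_loss = 0,
                   sv_rates = c(deletion = 5), sv_size_range = c(200, 250),
                   substitution_rate = 0, seed = 2)
  expect_error(simulateClade(cfg), "no segment can host")
})

test_that("invalid configurations are rejected", {
  expect_error(simConfig(sv_size_range = c(10, 100), seed = 1), "sv_size_range")
  expect_error(simConfig(rate_gene_gain = -1, seed = 1), "rates")
  expect_error(simConfig(tree = ape::rtree(1), seed = 1))
})

test_that("truth fixtures round-trip exactly through emit and read", {
  cfg <- simConfig(n_genomes = 3, n_chromosomes = 2,
                   genes_per_chromosome = 12, sv_rates = sv_rates_all(1),
                   rate_gene_gain = 1, rate_gene_loss = 0,
                   promoter_deletion_spec = list(genomes = "G2",
                                                 family = "F00010",
                                                 length_bp = 444),
                   seed = 21)
  sim <- simulateClade(cfg)
  dir <- withr::local_tempdir()
  manifest <- emitFixtures(truth(sim), dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  expect_true(jsonlite::validate(
    paste(readLines(file.path(dir, "manifest.json")), collapse = "\n")))
  back <- readTruthSet(dir)
  for (slot_name in c("families", "family_events", "rearrangement_events",
                      "sv_events", "hotspot_intervals", "promoter_indels")) {
    expect_equal(slot(back, slot_name), slot(truth(sim), slot_name))
  }
  expect_equal(back@tree$edge, truth(sim)@tree$edge)
  expect_equal(back@tree$tip.label, truth(sim)@tree$tip.label)
  expect_equal(back@tree$edge.length, truth(sim)@tree$edge.length)
  ## the planted 444-bp promoter deletion appears as exactly one truth row
  pi <- back@promoter_indels
  expect_equal(nrow(pi), 1L)
  expect_equal(pi$length, 444L)
  expect_equal(pi$genome, "G2")
})

test_that("an empty truth set emits valid zero-row fixtures", {
  empty <- new("TruthSet",
               families = data.frame(genome = character(),
                                     gene_id = character(),
                                     family_id = character()),
               family_events = data.frame(branch = character(),
                                          type = character(),
                                          family = character()),
               rearrangement_events = data.frame(
                 branch = character(), type = character(),
                 chrom = character(), chrom2 = character(),
                 gene_from = integer(), gene_to = integer()),
               sv_events = data.frame(branch = character(),
                                      type = character(), seg = character(),
                                      chrom = character(), start = integer(),
                                      end = integer(), size = integer(),
                                      seg_offset = integer()),
               hotspot_intervals = data.frame(chrom = character(),
                                              start = numeric(),
                                              end = numeric(),
                                              multiplier = numeric()),
               promoter_indels = data.frame(genome = character(),
                                            family = character(),
                                            length = integer(),
                                            offset = integer()),
               tree = NULL)
  dir <- withr::local_tempdir()
  emitFixtures(empty, dir)
  back <- readTruthSet(dir)
  expect_equal(nrow(back@families), 0L)
  expect_equal(nrow(back@sv_events), 0L)
})
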