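test_that("single-copy selection keeps exactly the universal families", {
  cds <- list(
    A = Biostrings::DNAStringSet(c(a1 = strrep("ACGT", 20),
                                   a2 = strrep("GGCA", 20),
                                   a3 = strrep("TTAC", 20))),
    B = Biostrings::DNAStringSet(c(b1 = strrep("ACGT", 20),
                                   b2 = strrep("GGCA", 20),
                                   b3 = strrep("GGCA", 20))))
  members <- data.frame(
    family_id = c("f1", "f1", "f2", "f2", "f2", "f3"),
    genome = c("A", "B", "A", "B", "B", "A"),
    gene_id = c("a1", "b1", "a2", "b2", "b3", "a3"))
  scs <- selectSingleCopy(members, cds)
  ## f2 is duplicated in B, f3 missing from B
  expect_equal(scs$families, "f1")
  expect_equal(names(scs$seqs$f1), c("A", "B"))
  expect_error(selectSingleCopy(members[5:6, ], cds), "single-copy")
})

test_that("zero-loss zero-duplication simulations keep all families single copy", {
  sim <- simulateClade(quiet_config(n_genomes = 4, genes_per_chromosome = 15,
                                    seed = 44))
  fam <- clusterGeneFamilies(cdsSequences(sim))
  scs <- selectSingleCopy(fam, cdsSequences(sim))
  expect_equal(length(scs$families), 15L)
})

test_that("Jukes-Cantor correction matches its closed form", {
  ## identical sequences: distance zero
  s <- strrep("ACGT", 50)
  scs <- list(families = "f1",
              seqs = list(f1 = Biostrings::DNAStringSet(c(A = s, B = s))))
  expect_equal(unname(distanceMatrix(scs)["A", "B"]), 0)
  ## p = 0.1 -> d = -0.75 log(1 - 0.4/3)
  x <- paste(rep("A", 200), collapse = "")
  y <- paste(c(rep("C", 20), rep("A", 180)), collapse = "")
  scs <- list(families = "f1",
              seqs = list(f1 = Biostrings::DNAStringSet(c(A = x, B = y))))
  expect_equal(unname(distanceMatrix(scs)["A", "B"]),
               -0.75 * log(1 - 0.4 / 3), tolerance = 1e-9)
  expect_equal(-0.75 * log(1 - 0.4 / 3), 0.1073256, tolerance = 1e-6)
  ## saturation hits the ceiling with a warning
  z <- paste(rep("G", 200), collapse = "")
  scs <- list(families = "f1",
              seqs = list(f1 = Biostrings::DNAStringSet(c(A = x, B = z))))
  expect_warning(d <- distanceMatrix(scs, ceiling = 5), "saturated")
  expect_equal(unname(d["A", "B"]), 5)
})

test_that("estimated distances recover twice the rate-depth product", {
  ## two-leaf clock tree of depth 0.5 at rate r: expected distance 2 * 0.5 r
  r <- 0.02
  tree <- ape::read.tree(text = "(G1:0.5,G2:0.5);")
  d_hat <- vapply(1:20, function(s) {
    cfg <- simConfig(n_genomes = 2, n_chromosomes = 1,
                     genes_per_chromosome = 30, tree = tree,
                     rate_gene_gain = 0, rate_gene_loss = 0,
                     rate_inversion = 0, rate_fission = 0, rate_fusion = 0,
                     rate_translocation = 0, sv_rates = sv_rates_all(0),
                     substitution_rate = r, seed = 500 + s)
    sim <- simulateClade(cfg)
    fam <- clusterGeneFamilies(cdsSequences(sim))
    scs <- selectSingleCopy(fam, cdsSequences(sim))
    unname(distanceMatrix(scs)["G1", "G2"])
  }, 0)
  sites <- 30 * 300
  se <- sd(d_hat) / sqrt(length(d_hat))
  expect_lt(abs(mean(d_hat) - 2 * 0.5 * r), 3 * se + 1e-4)
})

test_that("neighbor joining is exact on additive matrices", {
  set.seed(21)
  for (i in 1:12) {
    n <- sample(4:12, 1)
    tr <- ape::rtree(n, br = function(k) runif(k, 0.05, 1))
    dm <- ape::cophenetic.phylo(tr)
    out <- tr$tip.label[1]
    est <- njTree(dm, outgroup = out)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(est),
                                           ape::unroot(tr))), 0)
    ## recovered path lengths reproduce the generating matrix
    dm_est <- ape::cophenetic.phylo(est)[rownames(dm), colnames(dm)]
    expect_equal(dm_est, dm, tolerance = 1e-8)
  }
})

test_that("two-leaf trees split the distance at the root", {
  dm <- matrix(c(0, 0.3, 0.3, 0), 2, 2,
               dimnames = list(c("A", "B"), c("A", "B")))
  tr <- njTree(dm, "A")
  expect_equal(sort(tr$tip.label), c("A", "B"))
  expect_equal(unname(tr$edge.length), c(0.15, 0.15))
  expect_error(njTree(matrix(c(0, 1, 2, 0), 2, 2,
                             dimnames = list(c("A", "B"), c("A", "B"))), "A"),
               "symmetric")
})

test_that("calibrated trees are ultrametric with the requested node age", {
  set.seed(31)
  tr <- ape::rtree(8, br = function(k) runif(k, 0.1, 1))
  tr <- njTree(ape::cophenetic.phylo(tr), outgroup = tr$tip.label[1])
  ct <- calibrateAges(tr, calibration_node = length(tr$tip.label) + 1L,
                      calibration_age_mya = 10)
  expect_equal(max(nodeAges(ct)), 10)
  depths <- ape::node.depth.edgelength(ct@tree)
  leaf_depths <- depths[seq_along(ct@tree$tip.label)]
  expect_lt(diff(range(leaf_depths)) / max(leaf_depths), 1e-9)
  ## scaling invariance: calibrating a child node preserves depth ratios
  child <- ct@tree$edge[ct@tree$edge[, 1] == length(tr$tip.label) + 1L, 2]
  child <- child[child > length(tr$tip.label)][1]
  ct2 <- calibrateAges(tr, calibration_node = child,
                       calibration_age_mya = 3)
  a1 <- nodeAges(ct); a2 <- nodeAges(ct2)
  internal <- (length(tr$tip.label) + 1L):length(a1)
  ratio <- a1[internal] / a2[internal]
  expect_lt(diff(range(ratio)), 1e-9)
  expect_error(calibrateAges(tr, length(tr$tip.label) + 1L, -2), "positive")
  expect_error(calibrateAges(tr, 1L, 5), "internal")
})
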