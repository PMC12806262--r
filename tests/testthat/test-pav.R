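make_pav <- function(m, genomes = NULL, fams = NULL) {
  if (is.null(genomes)) genomes <- paste0("g", seq_len(ncol(m)))
  if (is.null(fams)) fams <- paste0("f", seq_len(nrow(m)))
  dimnames(m) <- list(fams, genomes)
  idx <- which(m == 1L, arr.ind = TRUE)
  members <- data.frame(family_id = fams[idx[, 1]],
                        genome = genomes[idx[, 2]],
                        gene_id = paste0("gene", seq_len(nrow(idx))))
  new("PAVMatrix", presence = m, members = members)
}

test_that("occupancy classification partitions families exactly", {
  all1 <- make_pav(matrix(1L, 5, 4))
  expect_equal(unname(classifyOccupancy(all1)),
               c(5L, 0L, 0L, 5L))
  ident <- make_pav(diag(1L, 4))
  expect_equal(unname(classifyOccupancy(ident)), c(0L, 0L, 4L, 4L))
  ## fuzz: partition property on random matrices
  set.seed(42)
  for (i in 1:25) {
    m <- matrix(rbinom(60, 1, 0.6), 12, 5)
    m[rowSums(m) == 0, sample.int(5, 1)] <- 1L
    cl <- classifyOccupancy(make_pav(m))
    expect_identical(unname(cl["core"] + cl["variable"] + cl["specific"]),
                     unname(cl["total"]))
  }
  ## the three class sizes printed for the real 22-genome pan-genome obey
  ## the same identity
  expect_identical(22384L + 34093L + 11330L, 67807L)
})

test_that("clustering groups identical genes and separates unrelated ones", {
  set.seed(1)
  x <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE),
             collapse = "")
  cds <- list(
    g1 = Biostrings::DNAStringSet(c(a1 = x)),
    g2 = Biostrings::DNAStringSet(c(b1 = x)),
    g3 = Biostrings::DNAStringSet(c(c1 = x)))
  fam <- clusterGeneFamilies(cds)
  expect_equal(length(unique(fam$family_id)), 1L)
  ## zero shared k-mers: two singleton families
  cds2 <- list(g1 = Biostrings::DNAStringSet(c(a = strrep("A", 60))),
               g2 = Biostrings::DNAStringSet(c(b = strrep("C", 60))))
  fam2 <- clusterGeneFamilies(cds2)
  expect_equal(length(unique(fam2$family_id)), 2L)
  ## duplicate gene ids in one genome are rejected
  cds3 <- list(g1 = Biostrings::DNAStringSet(c(a = x, a = x)))
  expect_error(clusterGeneFamilies(cds3), "duplicate gene id")
})

test_that("clustering recovers truth families exactly without substitutions", {
  sim <- simulateClade(quiet_config(n_genomes = 4, n_chromosomes = 2,
                                    genes_per_chromosome = 20, seed = 5))
  fam <- clusterGeneFamilies(cdsSequences(sim))
  expect_equal(randIndex(fam$family_id, truth_families_for(sim, fam)), 1)
})

test_that("sampled accumulation curves agree with exhaustive enumeration", {
  set.seed(8)
  m <- matrix(rbinom(40, 1, 0.5), 10, 4)
  m[rowSums(m) == 0, 1] <- 1L
  pav <- make_pav(m)
  curves <- accumulationCurves(pav, n_orderings = "all")
  ## independent brute-force enumeration over all 4! orderings
  perms <- as.matrix(expand.grid(rep(list(1:4), 4)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 4), ,
                 drop = FALSE]
  expect_equal(nrow(perms), 24L)
  pan <- core <- matrix(0, nrow(perms), 4)
  for (r in seq_len(nrow(perms))) {
    for (k in 1:4) {
      sub <- m[, perms[r, 1:k], drop = FALSE]
      pan[r, k] <- sum(rowSums(sub) > 0)
      core[r, k] <- sum(rowSums(sub) == k)
    }
  }
  expect_equal(curves$pan_mean, colMeans(pan))
  expect_equal(curves$core_mean, colMeans(core))
  expect_equal(curves$pan_sd, apply(pan, 2, sd))
  ## end points equal the direct classification
  cl <- classifyOccupancy(pav)
  expect_equal(curves$pan_mean[4], unname(cl["total"]))
  expect_equal(curves$core_mean[4], unname(cl["core"]))
})

test_that("accumulation is monotone for every sampled ordering", {
  set.seed(3)
  m <- matrix(rbinom(96, 1, 0.4), 16, 6)
  m[rowSums(m) == 0, 2] <- 1L
  curves <- accumulationCurves(make_pav(m), n_orderings = 40, seed = 9)
  expect_true(all(diff(curves$pan_mean) >= 0))
  expect_true(all(diff(curves$core_mean) <= 0))
  ## identical genomes: flat curves
  flat <- accumulationCurves(make_pav(matrix(1L, 7, 4)), n_orderings = 10,
                             seed = 1)
  expect_true(all(flat$pan_mean == 7) && all(flat$core_mean == 7))
})

test_that("PAV Jaccard distances match hand computation", {
  ## columns (1,1,0) vs (1,0,1): |intersection| = 1, |union| = 3
  m <- cbind(a = c(1L, 1L, 0L), b = c(1L, 0L, 1L))
  pav <- make_pav(m, genomes = c("a", "b"))
  d <- pavDistances(pav)
  expect_equal(d["a", "b"], 2 / 3)
  ## identical genomes at distance zero
  m2 <- cbind(a = c(1L, 0L, 1L), b = c(1L, 0L, 1L), c = c(0L, 1L, 1L))
  m2[2, 1] <- 1L  # avoid a zero row
  m2[2, 2] <- 1L
  d2 <- pavDistances(make_pav(m2, genomes = c("a", "b", "c")))
  expect_equal(d2["a", "b"], 0)
  tr <- clusterGenomesByPav(make_pav(m2, genomes = c("a", "b", "c")))
  expect_setequal(tr$tip.label, c("a", "b", "c"))
})

test_that("PAV dendrogram reflects the generating tree", {
  cfg <- simConfig(n_genomes = 6, n_chromosomes = 2,
                   genes_per_chromosome = 40, rate_gene_gain = 6,
                   rate_gene_loss = 6, sv_rates = sv_rates_all(0),
                   substitution_rate = 0.01, seed = 31)
  sim <- simulateClade(cfg)
  fam <- clusterGeneFamilies(cdsSequences(sim))
  pav <- buildPavMatrix(fam, genomes = genomeIds(sim))
  dendro <- clusterGenomesByPav(pav)
  coph <- as.matrix(cophenetic(dendro))
  pat <- ape::cophenetic.phylo(truth(sim)@tree)
  ids <- genomeIds(sim)
  rho <- cor(coph[ids, ids][lower.tri(coph[ids, ids])],
             pat[ids, ids][lower.tri(pat[ids, ids])], method = "spearman")
  expect_gt(rho, 0.8)
})

test_that("hypergeometric enrichment matches exact tail probabilities", {
  ann <- data.frame(gene = paste0("g", 1:5), term = "T1")
  bg <- paste0("g", 1:10)
  res <- enrichTerms(paste0("g", 1:4), ann, bg)
  ## all 4 drawn genes annotated: p = C(5,4) C(5,0) / C(10,4) = 5/210
  expect_equal(res$p[res$term == "T1"], 5 / 210, tolerance = 1e-12)
  ## a term annotating every background gene is never enriched
  ann2 <- rbind(ann, data.frame(gene = bg, term = "ALL"))
  res2 <- enrichTerms(paste0("g", 1:4), ann2, bg)
  expect_equal(res2$p[res2$term == "ALL"], 1)
  ## q values are monotone in the rank of p
  expect_true(all(diff(res2$q) >= 0))
  ## errors and degenerate cases
  expect_error(enrichTerms("absent", ann, bg), "absent from the background")
  expect_warning(res3 <- enrichTerms(character(), ann, bg), "empty")
  expect_equal(nrow(res3), 0L)
})
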