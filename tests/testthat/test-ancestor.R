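test_that("adjacency graphs count signed adjacencies correctly", {
  g1 <- mg("a", c(1, 2, 3))
  g2 <- mg("b", c(1, -2, 3))
  gr <- buildAdjacencyGraph(list(g1, g1, g1))
  expect_true(all(gr$edges$weight == 3))
  expect_equal(nrow(gr$edges), 2L)   # 1h-2t and 2h-3t
  gr2 <- buildAdjacencyGraph(list(g1, g2))
  ## extremities: tail(b)=2b-1, head(b)=2b
  keys <- paste(gr2$edges$e1, gr2$edges$e2, sep = "-")
  ## 1h-2t and 2h-3t from (1,2,3); 1h-2h and 2t-3t from (1,-2,3)
  expect_setequal(keys, c("2-3", "4-5", "2-4", "3-5"))
  expect_true(all(gr2$edges$weight == 1))
  expect_error(buildAdjacencyGraph(list()), "empty")
  expect_error(buildAdjacencyGraph(list(g1, mg("c", c(1, 2)))),
               "inconsistent")
})

test_that("unanimous genomes are their own median", {
  gs <- lapply(1:3, function(i) mg(paste0("g", i), c(1, 2, 3), c(4, 5)))
  anc <- inferMedianGenome(buildAdjacencyGraph(gs))
  expect_equal(length(CARs(anc)), 2L)
  expect_equal(unname(CARs(anc)), list(c(1L, 2L, 3L), c(4L, 5L)))
  expect_equal(medianTotalDistance(anc, gs), 0L)
})

test_that("DCJ distance matches hand-built cases and the metric axioms", {
  expect_equal(dcjDistance(mg("a", c(1, 2, 3)), mg("b", c(1, 2, 3))), 0L)
  expect_equal(dcjDistance(mg("a", c(1, 2, 3)), mg("b", c(1, -2, 3))), 1L)
  ## one fission
  expect_equal(dcjDistance(mg("a", c(1, 2), c(3, 4)),
                           mg("b", c(1, 2, 3, 4))), 1L)
  expect_error(dcjDistance(mg("a", c(1, 2)), mg("b", c(1, 2, 3))),
               "different block universes")
  set.seed(77)
  for (i in 1:30) {
    n <- sample(3:6, 1)
    a <- random_marker_genome(n, "a")
    b <- random_marker_genome(n, "b")
    c_ <- random_marker_genome(n, "c")
    dab <- dcjDistance(a, b)
    expect_equal(dab, dcjDistance(b, a))           # symmetry
    expect_equal(dcjDistance(a, a), 0L)            # identity
    expect_lte(dab, dcjDistance(a, c_) + dcjDistance(c_, b))  # triangle
  }
})

test_that("the median is never worse than any input genome", {
  set.seed(5)
  for (i in 1:10) {
    ms <- simulateMarkerClade(n_blocks = 30, n_chromosomes = 2, tree = 5,
                              events_per_branch = 2, seed = i)
    gs <- unname(ms$genomes)
    anc <- inferMedianGenome(buildAdjacencyGraph(gs))
    tot <- medianTotalDistance(anc, gs)
    for (g in gs) expect_lte(tot, medianTotalDistance(g, gs))
  }
})

test_that("the inferred CAR set is stable under input genome reordering", {
  ms <- simulateMarkerClade(n_blocks = 40, n_chromosomes = 3, tree = 6,
                            events_per_branch = 2, seed = 99)
  gs <- unname(ms$genomes)
  a1 <- inferMedianGenome(buildAdjacencyGraph(gs))
  a2 <- inferMedianGenome(buildAdjacencyGraph(rev(gs)))
  expect_equal(CARs(a1), CARs(a2))
})

test_that("fission and fusion counts follow chromosome arithmetic", {
  anc <- new("AncestorGenome", cars = list(CAR1 = c(1L, 2L, 3L, 4L)),
             blocks = 1:4)
  same <- mg("e0", c(1, 2, 3, 4))
  r0 <- countFissionFusion(anc, same)
  expect_equal(r0$dcj_distance, 0L)
  expect_equal(r0$fissions + r0$fusions + r0$inversions_lower_bound, 0L)
  split <- mg("e1", c(1, 2), c(3, 4))
  r1 <- countFissionFusion(anc, split)
  expect_equal(r1$fissions, 1L)
  expect_equal(r1$fusions, 0L)
  ## sign flips register as an inversion lower bound
  inv <- mg("e2", c(1, -2, 3, 4))
  expect_equal(countFissionFusion(anc, inv)$inversions_lower_bound, 1L)
  ## single-branch fission-only histories are counted exactly
  set.seed(2)
  for (i in 1:5) {
    ms <- simulateMarkerClade(n_blocks = 24, n_chromosomes = 2, tree = 2,
                              events_per_branch = 2,
                              event_probs = c(inversion = 0, fission = 1,
                                              fusion = 0,
                                              translocation = 0),
                              seed = i * 7)
    anc_mg <- ms$ancestor
    anc_obj <- new("AncestorGenome",
                   cars = unname(markerChromosomes(anc_mg)),
                   blocks = panclade:::marker_blocks(anc_mg))
    for (g in ms$genomes) {
      planted <- length(ms$events[[g@genome_id]])
      expect_equal(countFissionFusion(anc_obj, g)$fissions, planted)
    }
  }
})

test_that("marker clade simulation is deterministic and conservative", {
  m1 <- simulateMarkerClade(n_blocks = 20, tree = 4, events_per_branch = 2,
                            seed = 3)
  m2 <- simulateMarkerClade(n_blocks = 20, tree = 4, events_per_branch = 2,
                            seed = 3)
  expect_equal(lapply(m1$genomes, markerChromosomes),
               lapply(m2$genomes, markerChromosomes))
  for (g in m1$genomes) {
    expect_setequal(abs(unlist(markerChromosomes(g))), 1:20)
  }
})
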