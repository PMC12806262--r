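## constructed anchor tables: genome A rank i vs genome B rank according to
## a permutation
anchors_from_perm <- function(perm_b, chrom_b = "chr1") {
  n <- length(perm_b)
  data.frame(family_id = sprintf("F%03d", seq_len(n)),
             chrom_a = "chr1", rank_a = seq_len(n), strand_a = "+",
             chrom_b = chrom_b, rank_b = perm_b, strand_b = "+",
             stringsAsFactors = FALSE)
}

test_that("single-copy anchors are filtered and ordered", {
  fam <- data.frame(
    family_id = c("f1", "f1", "f2", "f2", "f2", "f3", "f3"),
    genome = c("A", "B", "A", "A", "B", "A", "B"),
    gene_id = c("a1", "b1", "a2", "a3", "b2", "a4", "b3"))
  ann <- list(
    A = data.frame(gene_id = c("a1", "a2", "a3", "a4"), chrom = "chr1",
                   start = c(10, 20, 30, 40), end = c(12, 22, 32, 42),
                   strand = "+"),
    B = data.frame(gene_id = c("b1", "b2", "b3"), chrom = "chr1",
                   start = c(5, 15, 25), end = c(6, 16, 26), strand = "+"))
  anc <- findAnchors(fam, ann, c("A", "B"))
  ## f2 has two copies in A and is excluded
  expect_setequal(anc$family_id, c("f1", "f3"))
  expect_equal(anc$rank_a, sort(anc$rank_a))
  expect_error(findAnchors(fam, ann, c("A", "missing")), "absent")
})

test_that("a perfectly collinear chromosome yields one forward block", {
  ch <- chainAnchors(anchors_from_perm(1:100), min_anchors = 5, max_gap = 25)
  expect_equal(nrow(ch$blocks), 1L)
  expect_equal(ch$blocks$orientation, "+")
  expect_equal(ch$blocks$n_anchors, 100L)
  expect_error(chainAnchors(anchors_from_perm(1:10), min_anchors = 1),
               "min_anchors")
})

test_that("a planted 20-gene inversion splits into +,-,+ blocks of 40/20/40", {
  ## max_gap must stay below half the inversion span, otherwise a forward
  ## chain can bridge the inversion through one anchor near its centre
  perm <- c(1:40, 60:41, 61:100)
  ch <- chainAnchors(anchors_from_perm(perm), min_anchors = 5, max_gap = 10)
  blocks <- ch$blocks[order(ch$blocks$start_a), ]
  expect_equal(nrow(blocks), 3L)
  expect_equal(blocks$orientation, c("+", "-", "+"))
  expect_equal(blocks$n_anchors, c(40L, 20L, 40L))
})

test_that("short scattered runs below min_anchors produce no blocks", {
  ## anchors alternate between two B chromosomes in runs of 3
  n <- 30
  anc <- anchors_from_perm(1:n)
  anc$chrom_b <- rep(c("chrB1", "chrB2"), each = 3, length.out = n)
  anc$rank_b <- unlist(lapply(split(seq_len(n), anc$chrom_b), seq_along))[
    order(unlist(split(seq_len(n), anc$chrom_b)))]
  ch <- chainAnchors(anc, min_anchors = 5, max_gap = 2)
  expect_equal(nrow(ch$blocks), 0L)
})

test_that("chaining is symmetric up to orientation", {
  ## three well-separated segments (rank-b offsets larger than max_gap) so
  ## boundary anchors cannot join two chains and the partition is unique
  perm <- c(50:41, 1:40, 90:51)
  a1 <- anchors_from_perm(perm)
  ## swap the roles of the two genomes
  a2 <- a1
  names(a2) <- c("family_id", "chrom_b", "rank_b", "strand_b", "chrom_a",
                 "rank_a", "strand_a")
  a2 <- a2[order(a2$rank_a), ]
  ch1 <- chainAnchors(a1, min_anchors = 5, max_gap = 10)
  ch2 <- chainAnchors(a2, min_anchors = 5, max_gap = 10)
  sets1 <- lapply(split(ch1$anchors$family_id[!is.na(ch1$anchors$block_id)],
                        ch1$anchors$block_id[!is.na(ch1$anchors$block_id)]),
                  sort)
  sets2 <- lapply(split(ch2$anchors$family_id[!is.na(ch2$anchors$block_id)],
                        ch2$anchors$block_id[!is.na(ch2$anchors$block_id)]),
                  sort)
  expect_setequal(unname(vapply(sets1, paste, "", collapse = ",")),
                  unname(vapply(sets2, paste, "", collapse = ",")))
})

test_that("disordered blocks are those off the dominant chromosome pairing", {
  ## 60 anchors on the 1:1 pairing, 6 translocated to another B chromosome
  anc <- anchors_from_perm(1:66)
  anc$chrom_b[31:36] <- "chrB2"
  anc$rank_b[31:36] <- 1:6
  anc$rank_b[37:66] <- 31:60
  ch <- chainAnchors(anc, min_anchors = 5, max_gap = 25)
  blocks <- flagDisorderedBlocks(ch)
  expect_equal(attr(blocks, "n_disordered"), 1L)
  expect_equal(blocks$chrom_b[blocks$disordered], "chrB2")
  ## all blocks on the dominant pairing: none disordered
  ch0 <- chainAnchors(anchors_from_perm(1:50), min_anchors = 5, max_gap = 25)
  expect_equal(attr(flagDisorderedBlocks(ch0), "n_disordered"), 0L)
})

test_that("zero-rearrangement clades give one block per chromosome and identical markers", {
  sim <- simulateClade(quiet_config(n_genomes = 3, n_chromosomes = 2,
                                    genes_per_chromosome = 25, seed = 13))
  fam <- clusterGeneFamilies(cdsSequences(sim))
  ann <- lapply(setNames(nm = genomeIds(sim)),
                function(g) geneAnnotations(sim, g))
  pivot <- "G1"
  chained <- list()
  for (g in setdiff(genomeIds(sim), pivot)) {
    ch <- chainAnchors(findAnchors(fam, ann, c(pivot, g)),
                       min_anchors = 5, max_gap = 25)
    expect_equal(nrow(ch$blocks), 2L)   # one block per chromosome
    expect_true(all(ch$blocks$orientation == "+"))
    expect_equal(attr(flagDisorderedBlocks(ch), "n_disordered"), 0L)
    chained[[g]] <- ch
  }
  mk <- buildMarkerGenomes(chained, pivot)
  ref <- markerChromosomes(mk$markers[[pivot]])
  for (g in names(mk$markers)) {
    expect_equal(unname(markerChromosomes(mk$markers[[g]])), unname(ref))
  }
})

test_that("a planted inversion flips one marker sign in place", {
  cfg <- quiet_config(n_genomes = 2, n_chromosomes = 1,
                      genes_per_chromosome = 60, seed = 17)
  sim <- simulateClade(cfg)
  ## invert genes 20..35 of G2 manually through the marker route:
  ## rebuild annotations with the inverted order
  fam <- clusterGeneFamilies(cdsSequences(sim))
  ann <- lapply(setNames(nm = genomeIds(sim)),
                function(g) geneAnnotations(sim, g))
  a2 <- ann$G2
  inv <- 20:35
  a2$start[inv] <- rev(a2$start[inv]); a2$end[inv] <- rev(a2$end[inv])
  ann$G2 <- a2
  ch <- chainAnchors(findAnchors(fam, ann, c("G1", "G2")),
                     min_anchors = 5, max_gap = 25)
  mk <- buildMarkerGenomes(list(G2 = ch), "G1")
  m1 <- unlist(markerChromosomes(mk$markers$G1))
  m2 <- unlist(markerChromosomes(mk$markers$G2))
  expect_equal(length(m1), length(m2))
  flipped <- which(m2 != m1)
  expect_equal(length(flipped), 1L)
  expect_equal(m2[flipped], -m1[flipped])
  expect_equal(abs(m2), abs(m1))  # order preserved
})
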