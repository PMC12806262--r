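uniform_svs <- function(n, L, chrom = "chr1") {
  data.frame(ref_chrom = rep(chrom, n), ref_start = floor(runif(n, 0, L)),
             ref_end = floor(runif(n, 0, L)),
             type = rep("deletion", n), size = rep(100L, n))
}

test_that("zero SVs give zero hotspots and degenerate windows warn", {
  empty <- uniform_svs(0, 1e6)
  hs <- detectHotspots(empty, c(chr1 = 1e6), n_perm = 100, seed = 1)
  expect_equal(nrow(hs), 0L)
  expect_warning(
    detectHotspots(uniform_svs(20, 5e5), c(chr1 = 5e5), window_bp = 1e6,
                   n_perm = 100, seed = 1),
    "wider than")
})

test_that("window empirical p agrees with the exact binomial scan", {
  ## one chromosome, uniform null: the count in a w/L window is
  ## Binomial(m, w/L); the permutation p must sit within Monte-Carlo error
  L <- 1e6; w <- 1e5; m <- 60
  set.seed(10)
  svs <- uniform_svs(m, L)
  hs <- detectHotspots(svs, c(chr1 = L), window_bp = w, n_perm = 2000,
                       alpha = 0.05, seed = 77)
  wins <- attr(hs, "windows")
  p_exact <- pbinom(wins$sv_count - 1, m, w / L, lower.tail = FALSE)
  se <- sqrt(p_exact * (1 - p_exact) / 2000) + 1 / 2000
  expect_true(all(abs(wins$empirical_p - p_exact) < 4 * se + 0.01))
})

test_that("false-positive window rate is controlled under the uniform null", {
  set.seed(55)
  frac <- vapply(1:30, function(s) {
    svs <- uniform_svs(80, 2e6)
    hs <- detectHotspots(svs, c(chr1 = 2e6), window_bp = 1e5,
                         n_perm = 400, alpha = 0.05, seed = s)
    wins <- attr(hs, "windows")
    mean(wins$bh_q <= 0.05)
  }, 0)
  expect_lte(mean(frac), 0.05)
})

test_that("a planted high-density region is recovered as one merged region", {
  set.seed(9)
  L <- 2e6
  hot <- c(9e5, 11e5)
  svs <- rbind(uniform_svs(100, L),
               data.frame(ref_chrom = "chr1",
                          ref_start = floor(runif(100, hot[1], hot[2])),
                          ref_end = 0L, type = "insertion", size = 60L))
  hs <- detectHotspots(svs, c(chr1 = L), window_bp = 1e5, n_perm = 500,
                       alpha = 0.05, seed = 3)
  expect_gte(nrow(hs), 1L)
  jac <- max(vapply(seq_len(nrow(hs)), function(r)
    panclade:::interval_jaccard(hs$start[r], hs$end[r], hot[1], hot[2]), 0))
  expect_gte(jac, 0.5)
})

test_that("hotspot detection is deterministic given the seed", {
  set.seed(2)
  svs <- uniform_svs(150, 1e6)
  h1 <- detectHotspots(svs, c(chr1 = 1e6), window_bp = 1e5, n_perm = 300,
                       seed = 5)
  h2 <- detectHotspots(svs, c(chr1 = 1e6), window_bp = 1e5, n_perm = 300,
                       seed = 5)
  expect_identical(attr(h1, "windows"), attr(h2, "windows"))
})

test_that("region annotation uses half-open gene intersection", {
  regions <- data.frame(ref_chrom = "chr1", start = 1000, end = 2000,
                        sv_count = 5L, empirical_p = 0.001, bh_q = 0.01)
  ann <- data.frame(
    gene_id = c("inside", "abutting", "overlap_left", "far", "other_chrom"),
    chrom = c("chr1", "chr1", "chr1", "chr1", "chrX"),
    start = c(1200, 2001, 900, 5000, 1200),   # 1-based inclusive
    end = c(1400, 2400, 1100, 5400, 1400))
  out <- annotateRegions(regions, ann)
  genes <- strsplit(out$genes, ",")[[1]]
  expect_setequal(genes, c("inside", "overlap_left"))
  ## a gene starting exactly at the region end (0-based) is excluded
  expect_false("abutting" %in% genes)
  expect_equal(attr(out, "skipped_contigs"), character(0))
  out2 <- annotateRegions(data.frame(ref_chrom = "chrZ", start = 0, end = 10),
                          ann)
  expect_equal(attr(out2, "skipped_contigs"), "chrZ")
})

test_that("GFF3 written by the simulator annotates regions consistently", {
  sim <- simulateClade(quiet_config(n_genomes = 2, genes_per_chromosome = 6,
                                    seed = 30))
  dir <- withr::local_tempdir()
  writeClade(sim, dir)
  ann_mem <- geneAnnotations(sim, "G1")
  regions <- data.frame(ref_chrom = "chr1", start = 0,
                        end = sum(ann_mem$end[2]) + 100)
  a1 <- annotateRegions(regions, ann_mem)
  a2 <- annotateRegions(regions, file.path(dir, "G1.gff3"))
  expect_equal(a1$genes, a2$genes)
})
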