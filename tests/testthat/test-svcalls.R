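## minimal hand-built PAF records
paf_row <- function(qs, qe, ts, te, strand = "+", qname = "q1",
                    tname = "t1", qlen = 100000L, tlen = 100000L) {
  data.frame(qname = qname, qlen = qlen, qstart = qs, qend = qe,
             strand = strand, tname = tname, tlen = tlen, tstart = ts,
             tend = te, nmatch = te - ts, alen = te - ts, mapq = 60L,
             stringsAsFactors = FALSE)
}

test_that("gap signatures classify into the six SV types", {
  ## dr = 0, dq = 500: insertion of 500
  paf <- rbind(paf_row(0, 1000, 0, 1000), paf_row(1500, 3000, 1000, 2500))
  sv <- callSvsFromAlignment(paf)
  expect_equal(sv$type, "insertion")
  expect_equal(sv$size, 500L)
  expect_equal(sv$ref_start, 1000L)
  ## dr = 500, dq = 0: deletion of 500
  paf <- rbind(paf_row(0, 1000, 0, 1000), paf_row(1000, 2500, 1500, 3000))
  sv <- callSvsFromAlignment(paf)
  expect_equal(sv$type, "deletion")
  expect_equal(sv$size, 500L)
  expect_equal(c(sv$ref_start, sv$ref_end), c(1000L, 1500L))
  ## dr = -300, dq = 0: tandem expansion
  paf <- rbind(paf_row(0, 1000, 0, 1000), paf_row(1000, 2500, 700, 2200))
  sv <- callSvsFromAlignment(paf)
  expect_equal(sv$type, "tandem_expansion")
  expect_equal(sv$size, 300L)
  ## dr = 0, dq = -300: tandem contraction
  paf <- rbind(paf_row(0, 1000, 0, 1000), paf_row(700, 2200, 1000, 2500))
  sv <- callSvsFromAlignment(paf)
  expect_equal(sv$type, "tandem_contraction")
  ## non-unique flank routes to the repeat classes
  paf <- rbind(paf_row(0, 1000, 0, 1000), paf_row(1500, 3000, 1000, 2500),
               paf_row(10, 990, 50000, 50980, tname = "t2"))
  sv <- callSvsFromAlignment(paf)
  sv <- sv[sv$ref_chrom == "t1", ]
  expect_equal(sv$type, "repeat_expansion")
  ## sizes outside the filter are dropped
  paf <- rbind(paf_row(0, 1000, 0, 1000), paf_row(1020, 3000, 1000, 2980))
  expect_equal(nrow(callSvsFromAlignment(paf, min_size = 50)), 0L)
})

test_that("classification is exhaustive and exclusive over gaps in range", {
  set.seed(11)
  for (i in 1:40) {
    dr <- sample(-400:600, 1); dq <- sample(-400:600, 1)
    if (abs(dq - dr) < 50 || abs(dq - dr) > 10000) next
    if (dr <= -1000 || dq <= -1000) next
    paf <- rbind(paf_row(0, 1000, 0, 1000),
                 paf_row(1000 + dq, 2500 + dq, 1000 + dr, 2500 + dr))
    sv <- callSvsFromAlignment(paf)
    expect_equal(nrow(sv), 1L)
    expect_true(sv$type %in% c("insertion", "deletion", "tandem_expansion",
                               "tandem_contraction"))
    expect_equal(sv$size, abs(dq - dr))
  }
})

test_that("empty and unsorted alignments are handled", {
  expect_warning(sv <- callSvsFromAlignment(paf_row(0, 10, 0, 10)[0, ]),
                 "no usable")
  expect_equal(nrow(sv), 0L)
  paf <- rbind(paf_row(1000, 2500, 1500, 3000), paf_row(0, 1000, 0, 1000))
  expect_warning(sv <- callSvsFromAlignment(paf), "unsorted")
  expect_equal(sv$type, "deletion")
})

test_that("PAF files round-trip through write and read", {
  paf <- rbind(paf_row(0, 1000, 0, 1000), paf_row(1500, 3000, 1000, 2500))
  f <- withr::local_tempfile()
  writePaf(paf, f)
  back <- readPaf(f)
  expect_equal(back, paf)
})

test_that("planted SVs are recovered with breakpoint accuracy", {
  cfg <- simConfig(n_genomes = 2, n_chromosomes = 2,
                   genes_per_chromosome = 60, rate_gene_gain = 0,
                   rate_gene_loss = 0, rate_inversion = 0, rate_fission = 0,
                   rate_fusion = 0, rate_translocation = 0,
                   sv_rates = sv_rates_all(5), substitution_rate = 0.01,
                   seed = 42)
  sim <- simulateClade(cfg)
  calls <- callSvsFromAlignment(pafFromTruth(sim, "G1", "G2"),
                                ref_genome = "G2", query_genome = "G1")
  tt <- truthSvTable(sim, "G1", "G2")
  cmp <- compareSvCalls(calls, tt, tol = 10)
  expect_gte(cmp$recall, 0.9)
  expect_gte(cmp$precision, 0.9)
})

test_that("insertions mirror deletions when genome roles swap", {
  cfg <- simConfig(n_genomes = 2, n_chromosomes = 1,
                   genes_per_chromosome = 80, rate_gene_gain = 0,
                   rate_gene_loss = 0, rate_inversion = 0, rate_fission = 0,
                   rate_fusion = 0, rate_translocation = 0,
                   sv_rates = c(insertion = 6, deletion = 6),
                   substitution_rate = 0, seed = 314)
  sim <- simulateClade(cfg)
  fwd <- callSvsFromAlignment(pafFromTruth(sim, "G1", "G2"))
  rev_ <- callSvsFromAlignment(pafFromTruth(sim, "G2", "G1"))
  expect_equal(sort(fwd$size[fwd$type == "insertion"]),
               sort(rev_$size[rev_$type == "deletion"]))
  expect_equal(sort(fwd$size[fwd$type == "deletion"]),
               sort(rev_$size[rev_$type == "insertion"]))
})

test_that("the multi-reference catalog skips self-comparisons", {
  cfg <- simConfig(n_genomes = 3, n_chromosomes = 1,
                   genes_per_chromosome = 30, sv_rates = sv_rates_all(2),
                   rate_gene_gain = 0, rate_gene_loss = 0, seed = 8)
  sim <- simulateClade(cfg)
  expect_message(cat_res <- multiReferenceCatalog(sim, references = "G1"),
                 "skipping")
  expect_null(cat_res$tables$G1$G1)
  expect_setequal(names(cat_res$tables$G1), c("G2", "G3"))
  expect_true(all(cat_res$summary$type %in% panclade:::SV_TYPES))
  ## identical genomes give zero SVs
  sim0 <- simulateClade(quiet_config(n_genomes = 2, seed = 4))
  cat0 <- multiReferenceCatalog(sim0, references = "G1")
  expect_equal(nrow(cat0$tables$G1$G2), 0L)
})
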