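## shared fixture builders for the test suite

sv_rates_all <- function(x) {
  setNames(rep(x, 6), c("insertion", "deletion", "tandem_expansion",
                        "tandem_contraction", "repeat_expansion",
                        "repeat_contraction"))
}

## a configuration with every stochastic process switched off
quiet_config <- function(n_genomes = 3, n_chromosomes = 1,
                         genes_per_chromosome = 10, seed = 1, ...) {
  simConfig(n_genomes = n_genomes, n_chromosomes = n_chromosomes,
            genes_per_chromosome = genes_per_chromosome,
            rate_gene_gain = 0, rate_gene_loss = 0, rate_inversion = 0,
            rate_fission = 0, rate_fusion = 0, rate_translocation = 0,
            sv_rates = sv_rates_all(0), substitution_rate = 0,
            seed = seed, ...)
}

mg <- function(id, ...) {
  chroms <- list(...)
  names(chroms) <- paste0("chr", seq_along(chroms))
  new("MarkerGenome", genome_id = id,
      chromosomes = lapply(chroms, as.integer))
}

## uniformly random multichromosomal signed genome on blocks 1..n
random_marker_genome <- function(n, id = "g") {
  v <- sample(n) * sample(c(-1L, 1L), n, replace = TRUE)
  cutpos <- which(sample(c(TRUE, FALSE), max(n - 1L, 0L), replace = TRUE))
  bounds <- c(0L, cutpos, n)
  chroms <- list()
  for (k in seq_len(length(bounds) - 1L)) {
    if (bounds[k + 1L] > bounds[k])
      chroms[[length(chroms) + 1L]] <- as.integer(v[(bounds[k] + 1L):
                                                    bounds[k + 1L]])
  }
  names(chroms) <- paste0("c", seq_along(chroms))
  new("MarkerGenome", genome_id = id, chromosomes = chroms)
}

## family membership of a simulation matched to the clustering output order
truth_families_for <- function(sim, fam) {
  tf <- truth(sim)@families
  tf$family_id[match(paste(fam$genome, fam$gene_id),
                     paste(tf$genome, tf$gene_id))]
}
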