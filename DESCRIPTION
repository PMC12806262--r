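Package: panclade
Title: Pan-Genome, Synteny, Ancestral-Genome and Structural-Variant Analysis
    for Clades of Annotated Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for desk-scale comparative genomics of a clade of related
    genome assemblies, modelled on diploid plant super pan-genome studies.
    Includes a clade simulator that evolves an annotated ancestral genome
    along a phylogeny while recording every planted event (gene family gain
    and loss, chromosomal rearrangements, six classes of structural variant,
    promoter deletions) as a machine-readable truth set; k-mer based gene
    family clustering and presence/absence (PAV) analysis with core, variable
    and specific partitions, accumulation curves, PAV-based genome clustering
    and term enrichment; collinearity block chaining and signed marker-genome
    encoding; ancestral genome reconstruction under a genome-median adjacency
    model with DCJ distances and fission/fusion accounting; assembly-alignment
    structural variant calling with hotspot detection by permutation testing;
    neighbor-joining phylogenies from Jukes-Cantor distances with divergence
    time calibration; and promoter indel scanning. Exhaustive search oracles
    (breadth-first DCJ sorting, brute-force genome medians) are included for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    ape,
    Biostrings,
    S4Vectors,
    IRanges,
    rtracklayer,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
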