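---
title: "panclade: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{panclade: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

panclade is a desk-scale toolkit for comparative genomics of a clade of
annotated genome assemblies, of the kind used in diploid plant super
pan-genome studies: pan-genome presence/absence analysis, collinearity and
ancestral genome reconstruction, structural variant (SV) calling with
hotspot detection, phylogeny and divergence-time estimation, and promoter
indel scanning. Because the real inputs of such studies are tens of
gigabases of assemblies, every analysis here is paired with a clade
*simulator* that generates small annotated genomes with planted, fully
recorded evolutionary events, so that each stage can be validated against
ground truth. This vignette explains the models, the defaults and the
design decisions; it states no empirical result beyond what the package's
tests and acceptance script themselves compute.

## The clade simulator

`simulateClade()` evolves an ancestral genome along a rooted tree. The
ancestor is deliberately simple: `n_chromosomes` chromosomes, each an
alternation of fixed-length random genes (default 300 bp, one gene family
each) and intergenic spacers (default 2,000 bp). On each branch, in order:

* **Gene loss** and **gene gain** at rates per branch-length unit. A gain
  creates a brand-new single-member family rather than duplicating an
  existing gene, so genome-specific genes arise exactly as the
  frequency-one class of a pan-genome occupancy spectrum; duplication is a
  separate rate, default 0.
* **Chromosomal rearrangements** (inversion, fission, fusion,
  translocation) at per-branch rates, applied at gene-unit boundaries.
  Inversions reverse-complement the affected sequence and flip strands.
* **Structural variants** of six classes (insertion, deletion, tandem
  expansion/contraction, repeat expansion/contraction) at per-branch rates,
  with sizes uniform in `sv_size_range` (minimum 50 bp, the calling
  floor). SVs are placed in ancestral intergenic spacers, at most one per
  spacer per root-to-leaf lineage, so that every event has unambiguous
  ancestor coordinates. A `hotspot_spec` multiplies the placement weight of
  spacers inside chosen intervals, planting clustered-SV regions.
* **Substitutions** under Jukes-Cantor: Poisson(rate × branch length ×
  length) hits per segment, each replacing a site by a uniformly chosen
  different base (multiple hits allowed). This matches the correction used
  downstream.

Species-specific **promoter deletions** are applied at the leaves: a chosen
family's strand-aware upstream spacer loses a block of stated length inside
its promoter window (default 1,500 bp). The target family is immune to
loss, and rearrangement breakpoints are redrawn when they would fall on
the target gene or its flanking spacers: the promoter analysis presumes a
conserved syntenic context for the scanned gene across species (as holds
for the real nectary-gene case), and without this guard an inversion on
one lineage can swap which ancestral spacer sits upstream, leaving the
compared promoters with no homology at all. All realized (not expected) events are recorded in a
`TruthSet`, which `emitFixtures()`/`readTruthSet()` round-trip exactly
through plain-text tables.

What the simulator does *not* emulate: transposable elements and other
repeats (hence sequence-level alignment ambiguity), intron structure,
unequal gene lengths, gene conversion, polyploidy, and assembly error.
Passing tests therefore demonstrate correctness of the analysis logic on
clean signals, not robustness to every artifact of real assemblies.

### Alignments from truth

For SV calling the simulator emits PAF alignment anchors directly from its
known homology (`pafFromTruth()`): each shared segment is one anchor, split
around planted SVs so that the gap signature of each SV class appears
exactly as an assembly aligner would report it. Repeat-class events emit an
additional decoy record overlapping a flank's query interval, reproducing
the multi-mapping evidence that distinguishes repeat from tandem events.
This keeps tests free of an external aligner; real PAF files from, e.g.,
minimap2 can be supplied to `callSvsFromAlignment()` unchanged.

## Gene families and PAV

`clusterGeneFamilies()` links two genes when their nucleotide 8-mer sets
have Jaccard similarity at least 0.5, and takes single-linkage connected
components. The threshold and k are exposed; the defaults separate random
sequences (expected similarity near 0) from orthologs at the few-percent
divergence the simulator produces. Real pan-genome pipelines cluster
proteins with dedicated tools; this nucleotide clustering plays that role
at desk scale. Candidate pairs are pre-screened by shared 16-mers sampled
every 8 bp — two sequences below ~20% divergence share many such seeds, so
the screen does not affect results in the intended regime, while unrelated
pairs almost never pay for an exact Jaccard computation.

Occupancy classes are strict: `core` = present in all n genomes,
`specific` = exactly one, `variable` = in between; the three counts always
partition the total (the same arithmetic identity the published cotton
partition obeys). Accumulation curves sample genome orderings uniformly
(default 100, seeded) or enumerate all orderings when n! is small. Genome
clustering uses average linkage on the Jaccard distance between PAV
columns, with columns pre-sorted by genome id so ties resolve
deterministically. Term enrichment is the field-default one-sided
hypergeometric test with Benjamini-Hochberg FDR; term assignments are user
input.

## Collinearity and marker genomes

Anchors are gene families single-copy in both genomes of a pair,
coordinatized by gene rank along chromosomes — rearrangement inference
operates on order, which the simulator controls exactly, so ranks rather
than base pairs are the natural unit. Chaining extracts, per chromosome
pair, the longest strictly monotone anchor run (increasing on A;
increasing or decreasing on B, fixing orientation) with rank gaps at most
`max_gap` on both sides, greedily and repeatedly until no chain of
`min_anchors` remains (defaults 25 and 5, MCScanX-like). Note that a
forward chain can bridge an inversion through a single anchor near its
centre when `max_gap` exceeds half the inversion span; tests therefore use
gaps below that bound when they assert exact block structure.

A block is **disordered** when its chromosome pair differs from the
dominant pairing (the B-chromosome receiving most anchors for that
A-chromosome, ties to the lexicographically smaller id). This is the most
literal operational reading of blocks "disordered on different
corresponding genomes"; since the published count for the real A-genome
pair depends on unstated parameters, it is treated as motivation, not as a
target.

`buildMarkerGenomes()` cuts the pivot genome's rank axis at all block
boundaries observed against any genome, keeps the atomic segments covered
in *every* genome (the universal marker set), and encodes each genome as
ordered lists of signed marker ids per chromosome. The pivot defaults to
the tree's first leaf (the outgroup in the demonstration configuration).

## Ancestral genome inference

Blocks are encoded as head/tail extremities; a genome is a matching of
extremities (adjacencies) plus telomeres. `buildAdjacencyGraph()` counts
every adjacency observed across the input genomes.
`inferMedianGenome()` seeks the genome minimizing the total DCJ distance
to the inputs (the genome median problem):

* the initial matching maximizes the net-benefit weight `2w − n` over
  observed adjacencies — an adjacency carried by `w` of `n` genomes helps
  the median only when a majority exhibits it, so raw observation counts
  would systematically over-join chromosomes;
* on small instances (≤ 25 observed adjacencies) all matchings of observed
  adjacencies are enumerated and scored by the exact objective;
* on larger instances, the input genomes themselves are also evaluated as
  candidate medians and the best of {matching, inputs} seeds the search
  (ties broken canonically), which guarantees the median is never worse
  than any input genome;
* a deterministic local-improvement pass then adds, removes or swaps
  adjacencies (on small instances including novel, unobserved ones and
  two-edge moves, which escape zero-gain plateaus) while the exact total
  DCJ distance decreases.

The matching decomposes into linear CARs; circular components are
linearized by deleting their minimum-weight adjacency, as cotton
chromosomes are linear. The DCJ distance itself is the closed form
`d = N − (C + I/2)` on the adjacency graph of two genomes (cycles `C`, odd
paths `I`, telomeres as path ends); the package also ships two exhaustive
oracles — breadth-first search over DCJ operations (`dcjDistanceBfs()`,
allowing circular intermediates) and brute-force enumeration of all linear
arrangements (`medianBruteForce()`) — as independent validation routes.

Fission/fusion counts against an extant genome use the chromosome-count
difference, a deliberate lower bound for compound histories; the inversion
lower bound counts sign disagreements after optimal CAR orientation.

## SV calling and hotspots

Between consecutive same-strand anchors of a (query chromosome, reference
chromosome) chain, the reference gap `dr` and query gap `dq` classify the
event, following the six-class gap taxonomy whose names match the
published SV categories: a non-unique flanking anchor (query interval
overlapping a record of *another* chain by > 10%) routes to the repeat
classes; otherwise a negative gap means a tandem event; otherwise the sign
of `dq − dr` separates insertion from deletion. The size is `|dq − dr|`,
filtered to [50 bp, 10 kb] by default. Overlap with the immediate chain
partner is excluded from the uniqueness rule because that overlap *is* the
tandem signature. Segments carrying SVs in both genomes align ambiguously
and contribute only their net length difference, which the truth
translator (`truthSvTable()`) models explicitly, as it does the mirroring
of reference-side events (insertion ↔ deletion, expansion ↔ contraction)
and the plain indels left by gene gain and loss.

`detectHotspots()` counts SV start breakpoints (one point per SV, avoiding
double-counting of large events) in tiling windows, compares each window
against a per-chromosome uniform permutation null preserving SV counts
(`p = (1 + #{perm ≥ obs}) / (1 + n_perm)`), adjusts across windows by
Benjamini-Hochberg, and merges adjacent significant windows. Window size
defaults to 1 Mb — the field convention for plant SV hotspots — with
20 kb used at demonstration scale; `n_perm` defaults to 1,000, and must
comfortably exceed the window count divided by alpha for the BH-adjusted
floor `(1/(1+n_perm)) × #windows` to remain below alpha. The pipeline
deduplicates pooled calls to non-redundant loci first: an event on a deep
branch (or on the reference's own lineage) is otherwise counted once per
query, which both inflates reference-specific regions and dilutes planted
signal.

## Phylogeny and divergence times

Families single-copy in every genome are aligned pairwise per genome pair
(global alignment, match +1, mismatch −1, linear gap −2; equal-length
pairs, which the simulator always produces, take a positional fast path
since the optimal alignment is gapless at these divergences). Per-family
p-distances combine as a site-weighted mean — exactly the p-distance of
the concatenated alignment — before the Jukes-Cantor correction
`d = −(3/4)·log(1 − 4p/3)`; saturated pairs (p ≥ 0.75) receive a
configurable ceiling with a warning.

The tree is neighbor-joining with negative branches clamped to zero,
rooted on the outgroup edge at the point that equalizes mean root-to-leaf
depth on both sides (clock-consistent rooting; a naive midpoint split
biases the root age upward). The published analysis used a
maximum-likelihood tree; distance NJ was chosen here because topology and
calibrated ages are the tested properties and an ML search engine is out
of proportion for this artifact — this divergence is documented in the
README. `calibrateAges()` assigns each internal node the mean root-to-leaf
path length through it, scales ages so the calibration node has the stated
age, and enforces parent-older-than-child, yielding an ultrametric
chronogram by construction.

## Promoter indel scanning

`scanPromoterIndels()` aligns each query to the reference globally with
affine gaps (match +2, mismatch −3, open −5, extend −1) — a scheme that
prefers one long gap over scattered short ones, matching the biological
question of a single large promoter deletion. Maximal gap runs of at least
`min_indel` bp (default 50) are reported with exact length and 0-based
reference offset; same-type runs separated by fewer than 10 aligned
columns merge, absorbing alignment ambiguity around repeats. Gaps in the
query are deletions, gaps in the reference insertions, so swapping the two
sequences mirrors the calls. Note that when a promoter window of fixed
width is extracted upstream of a gene that lost sequence, the window
shifts to include extra upstream sequence; the scan then reports the
planted deletion plus a compensating insertion at offset ~0, which is a
property of fixed-width extraction, not of the aligner.

## The demonstration configuration

`demoConfig()` fixes the study conditions used by the pipeline tests and
the acceptance script: eight genomes on a calibrated tree (time in My)
with an outgroup splitting at 10.13, a two-species cultivated-like clade
and a five-species wild-like clade separating at 5.45 — the published
divergence structure of the diploid cotton system this package emulates.
Three chromosomes of 100 genes give 300 ancestral families; gain/loss
rates of 2.5 and 5 events per My yield a core/variable/specific balance of
the kind real plant pan-genomes show (roughly 40% core). The
substitution rate, 0.0015 per site per My, is an *effective* rate chosen
so that nucleotide k-mer clustering remains reliable at the 10 My clade
depth; real cotton pipelines cluster proteins, which tolerate far higher
nucleotide divergence. Each SV class occurs at 2 events per branch with
sizes 50–600 bp; one 60 kb interval on chr1 attracts SVs twelve-fold.
The interval is deliberately wide: a spacer hosts at most one SV per
lineage, so a narrow interval saturates and its realized density contrast
collapses regardless of the multiplier. A 444 bp promoter deletion is
planted in two wild-clade genomes, mirroring the foliar-nectary promoter
case. The pipeline calibrates the ingroup ancestor at its true age and
reports the estimated root age, so recovering ~10.13 My is a computation,
not an input. When truth-comparison metrics are computed, planted hotspot
intervals are translated into the reference genome's coordinates through
the segment layout (the reference's own rearrangements would otherwise
shift them), and the inferred median is compared with the true root's
marker encoding — note that the genome median legitimately differs from
the root whenever a rearrangement falls on the stem or outgroup lineage,
so adjacency recovery below 1 is expected behaviour, not error, at demo
scale.

Problem sizes throughout the test suite (e.g. 200 blocks for ancestor
recovery, 200 random pairs for the DCJ oracle, 50 seeds for hotspot
calibration, up to 60 single-copy families for distance matrices) were
chosen as the smallest scales at which the statistical properties under
test are stable.

## Pipeline and determinism

`runPipeline()` runs all stages in dependency order on one configuration
and returns a JSON-serializable report that lists every stage's parameters
and, for simulated inputs, truth-comparison metrics (family Rand index,
ancestral adjacency recovery against the true ancestor's marker encoding,
SV recall/precision, hotspot interval Jaccard, Robinson-Foulds distance).
All randomness derives from the configuration seed, the report carries no
timestamps, and stage checksums are md5 digests of the serialized stage
outputs, so identical configurations produce byte-identical reports. A
content-addressed cache was considered and rejected: at desk scale a full
run takes well under a minute, and cache state would be the only source of
irreproducibility. Real-assembly inputs are supported at the module level
(FASTA/GFF3 readers, `readPaf()`); the orchestrator itself is
simulation-first, since its role here is verifiable end-to-end analysis.

## Known limitations

* Family clustering is nucleotide-based and single-linkage; at divergences
  beyond ~20% it will fragment families (by design of the regime).
* The genome median is NP-hard; outside the exhaustively-enumerated small
  regime the matching-plus-refinement heuristic carries no optimality
  guarantee, though it is validated against planted ancestors.
* Fission/fusion counts are lower bounds under compound rearrangements.
* The SV truth translator omits events in segments inverted relative to
  the reference and compound presence changes at chain breaks; measured
  precision on rearrangement-heavy simulations is accordingly
  conservative.
* Divergence times inherit every caveat of distance-based clock methods;
  no rate heterogeneity model is fitted.
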