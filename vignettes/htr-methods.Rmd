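---
title: "Methods: detecting highly transcribed regions and cross-species expression divergence"
author: "htrtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting highly transcribed regions and cross-species expression divergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

htrtools re-implements, as a tested pipeline over synthetic data with
planted ground truth, the analysis style of total-RNA short-read surveys of
primate brain transcriptomes: unstranded 36-nt single-end reads mapped to a
reference genome, annotated against a fixed seven-category partition,
scanned for highly transcribed regions (HTR), and compared across human,
chimpanzee and rhesus macaque through a common-dispersion negative binomial
(NB) exact test, expression-divergence trees and permutation nulls.

The package is organised as an analysis workflow: `analysis/01_simulate.R`
through `analysis/07_coding_potential.R` are thin narrative drivers over
the package functions, writing their tables under `results/`. Every
computation lives in the package itself so the test suite and
`scripts/acceptance.R` exercise the same code paths.

# Coordinates and containers

Intervals are held in `GRanges` (1-based, closed), the standard container
of the Bioconductor ecosystem; BED input/output converts its 0-based
half-open convention at the boundary (via rtracklayer), and GTF is 1-based
inclusive natively. Length, overlap and complement semantics are identical
under either convention; only the boundary arithmetic differs, and the
round-trip tests pin it down. Strand is recorded but ignored by all
counting operations: the library preparation modelled here loses strand
information.

Three-species alignments are colinear gapless blocks (indels occur only
between blocks); each block lists one equal-length span per species.
Projection maps a base to the same offset within its block, returns the
span covering all aligned bases, flags partial projections, and is exactly
invertible for intervals inside one block — the property the tests enforce
on 1,000 random cases. This is a deliberate simplification of chained
whole-genome alignments: it preserves the two semantics downstream stages
need (which regions are alignable; coordinate transfer) without modelling
within-block indels.

# Read annotation

Each read takes the highest-precedence category it overlaps by at least
one nucleotide: exon > intronic repeat > intron > intergenic repeat >
mitochondrial > ncRNA > intergenic. Junction-flagged reads are exonic
unconditionally. rRNA-overlapping reads are excluded before any category
logic, mirroring the exclusion of the dominant rRNA fraction from the
analysis. Because the categories partition the genome, a read can never
tie between two tracks at the same level; the hierarchy alone decides.
Multi-mapped reads, where included, are represented by a flag and a
location count; counting uses a single placement.

The composition summary reports per-category proportions either per read
or per covered nucleotide (union of read footprints, each base labelled by
the same hierarchy), always next to the genome's own category fractions.

# The HTR caller

Reads sorted along a contig are chained greedily: the chain breaks when the
gap to the next read — measured end-to-start, i.e. the number of uncovered
bases between reads, with a running maximum of ends so contained reads
cannot break a chain — exceeds `maxspacing` (default 150 nt; a gap of
exactly 150 still chains). Chains with at least `minhits` reads (default
10) become HTR, with boundaries at the 5'-most read start and 3'-most read
end. A start-to-start spacing variant is available as a config switch.
Single-linkage chaining with a running maximum is equivalent to connected
components of the pairwise "gap ≤ maxspacing" relation, which is exactly
how the independent test oracle computes it.

igHTR are HTR lying entirely within the non-repeat intergenic category
track and overlapping no annotated transcript (genes, ncRNA — the
transcript-exclusion track). Cross-sample unification single-links HTR
overlapping by ≥ 1 nt and takes 5'-most/3'-most boundaries, recounting
reads per sample within the unified span. igHTR clusters are maximal
groups of ≥ 2 igHTR sharing one intergenic (between-gene) region; an
optional gap cap is provided but off by default, since within-cluster
spacings in the data this models resemble intron lengths. Nearest-gene
assignment reports distance and the 3'/5' side by gene strand, with a
10-kb proximity window.

# Resampling machinery

All permutation nulls draw length-matched random regions: the exact length
multiset of the observed set, placed uniformly at positions where the
region fits inside the background (minus any exclusion), mutually
non-overlapping, by rejection resampling of colliding members. Empirical
p-values use the add-one rule (1 + #{null ≥ observed}) / (1 + B), so the
smallest attainable p is 1/(B+1); B defaults to 1000.

The overlap test counts query regions touching ≥ 1 feature (optionally
extending features first, e.g. 1 kb for short structural-RNA predictions).
The connection test counts pairs joined by two *distinct* blocks of one
spliced EST — consecutive igHTR of a cluster, or a gene's 3'-terminal exon
and a downstream igHTR within the proximity window. Conservation
comparisons resample, from each comparison class, the same number of bases
as the focal class holds (1,000 times, percentile 95% intervals); the
focal class itself is reported as its plain mean. The enrichment statistic
is the hypergeometric upper tail per category plus a min-p permutation
over random same-size foregrounds for a family-wise global p. Category
excess uses the exact one-sided binomial tail.

One property worth stating: an exact permutation test on a coarse discrete
statistic is conservative — with few query regions the overlap count takes
few values and P(p < 0.05) sits visibly below 5%. The calibration check
therefore uses enough regions and feature coverage that the statistic is
rich; this is a property of exact discrete tests, not of the
implementation.

# Species-specific expression

Gene expression is the count of uniquely mapped exonic reads (junction
reads excluded, since exon boundaries need not match across genomes when
counts are transferred through the alignment), normalised by exonic
length; genes detected in ≥ 2 of the 4 samples are kept. Libraries are
equalised by subsampling to the smallest library rather than by scaling
inside the test, keeping the conditional test exact.

The common dispersion φ is estimated from the two same-species replicates
by maximising the summed conditional likelihood of each row's split given
its total: for equal-mean, equal-library NB counts the split is
Dirichlet-multinomial with both shape parameters 1/φ, reducing to
Binomial(s, ½) at φ = 0. The search is a log-scale grid refined by
`optimize`, with an explicit boundary check at φ = 0. The exact test sums
the probabilities of all splits as or less probable than the observed one
(the "small-p" two-sided rule; a doubled-one-tail variant is exposed).
Agreement with edgeR's `estimateCommonDisp`/`exactTest` at equal library
sizes is pinned in the tests as an independent cross-check, while the
implementation itself is this package's own.

P-values are BH-adjusted within each pairwise comparison (a pooled option
exists; the source design is ambiguous on this point). A row is called
specific to species S only when both comparisons involving S are
significant (q < 0.05) and the out-group comparison is not, in *both*
replicate-defined sample triples G1 and G2. Two consequences the tests
document: the calling is stringent — with φ = 0.1 a 4-fold change lies
only ~2.7 null standard deviations out, so per-row power is low, matching
the small species-specific fractions such studies report — and exact
conditional p-values are sub-uniform at small totals (discreteness), so
the uniformity check runs at row totals of several hundred reads where the
continuous reference applies.

Equal-read genomic windows tile the alignment-covered genome into runs of
exactly N = 50 reads summed over the three species (human = both
replicates), boundaries snapping to member reads, remainder dropped; each
window is then tested exactly like a gene, and the excess of intergenic
windows among species-specific ones is the binomial test above.

# Expression divergence

Rates are quantile-normalised across samples (limma's implementation; with
ties, tied entries receive the average of their would-be quantile values,
so exact identical-sorted-columns holds on tie-free data). Distances are
Euclidean, Manhattan or 1 − Spearman's ρ (average ranks on ties),
optionally after Z-transforming each gene to mean 0, sd 1 across samples
to remove expression-level influence. UPGMA (average-linkage `hclust`
behind the package surface, labels ordered lexicographically first so ties
merge deterministically) yields an ultrametric tree; node support is the
fraction of 1,000 gene-bootstrap trees containing each clade of the
observed rooted tree.

# CSF coding potential

The CSF matrix holds log2 odds of reference→aligned codon-pair frequencies
under a coding versus a noncoding training process, Laplace-smoothed with
pseudocount 1; codon pairs containing gaps or ambiguity are skipped.
Scanning slides a 90-nt (30-codon) window, codon-stepped, over three
offsets of the forward alignment and three of the reverse complement of
both sequences; the locus score is the max over all windows and frames.
The six-frame maximum is exactly strand-symmetric by construction, an
invariant the tests assert identically.

Real two-species genomic alignments are out of scope, so training and
held-out loci come from the package's own codon-pair simulator — two fully
explicit processes (synonymous-biased: keep the codon with p = 0.55,
third-position variant with p = 0.35, uniform otherwise; neutral: each
base independently kept with p = 0.75) whose joint pair probabilities are
available in closed form (`codon_pair_probs`), giving an analytic oracle
for the trained matrix. Scores from these synthetic processes live on
their own scale, so the classification cutoff is chosen on training score
distributions (Youden-optimal, `choose_csf_cutoff`) exactly as the
original cutoff was chosen from known coding/noncoding score
distributions; the default cutoff of 2 is kept as the documented value for
the original human–mouse matrix scale. At 1e5 training codons the
well-populated (identity) matrix entries match the analytic log-odds to
better than 0.1 bits on average; rare entries are pseudocount-dominated at
any realistic training size, which is the expected behaviour of Laplace
smoothing, not an error.

# The synthetic-data generator

`simulation_config()` defaults define the study conditions: a 10-Mb
genome (16-kb mitochondrial contig), 100 genes with log-normal exon
(~250 nt) and intron (~1.5 kb) lengths, 30 ncRNA loci, 4 rRNA loci, five
repeat families on an age gradient with mappability falling toward young
families and the youngest planted at 3× activity, 50 planted intergenic
transcription units in clusters of 3 (unit ~800 nt, intron-like spacing
~1.5 kb, 25% of clusters anchored 1–3 kb downstream of a gene's 3' end),
four samples (two human replicates, chimpanzee, macaque) of 1.5 M reads
with 37% rRNA, 5% multi-mapped and 2% junction-flagged exonic reads,
per-unit NB counts with common dispersion φ = 0.1 shared across samples
through per-gene expression factors, graded genome-wide expression
divergence (per-gene mean-one log-normal species factors, sdlog 0.3 for
the nearer and 0.6 for the farther species, so replicates resemble each
other more than species do and divergence grows with distance), 5% of
genes and 20% of planted units species-specific at 4-fold, ESTs covering 48% of planted units plus
cluster bridges and gene-3' links, alignment blocks covering 90% of the
genome with per-species coordinate drift, and a conservation track
elevated exon > planted igHTR > background.

Two modelling choices deserve emphasis. First, read densities, not
composition shares, drive HTR behaviour: a 10-Mb genome cannot match a
3-Gb genome in both at once, and chaining depends on density against
`maxspacing`. The defaults therefore keep the intergenic background at a
realistic per-nt density (2e-5 reads/nt) and put planted units far above
the minhits/maxspacing regime (~0.1 reads/nt), at the cost of a
smaller-than-real intergenic share of reads; a 500-nt feature-free buffer
around planted clusters keeps their boundaries recoverable rather than
merging into adjacent repeat reads. Second, the generator emits *exactly*
`library_size` reads: per-unit NB counts are drawn first (a per-unit Gamma
multiplier times Poisson, so unit totals are exactly NB), then the total
is adjusted by uniform thinning or weight-proportional top-up; this
preserves the moment structure the tests check to within their tolerances.
Unique reads from repeat elements accrue in proportion to uniquely
mappable positions, which is what makes activity per mappable nt the
correct normaliser.

What the generator does not emulate: sequence content (no FASTA; the CSF
codon simulator is the one exception), mapping errors and mismatch
structure, strand-specific artefacts, within-species biological
replication noise beyond the shared NB dispersion (the source design had
no intra-species variance estimate either; replicate noise is a free
parameter), within-block alignment indels, and GC or mappability gradients
outside repeats. Passing tests therefore demonstrate the statistical
machinery on data satisfying the model's assumptions, not robustness to
real-data artefacts upstream of mapping.

# Problem sizes and reproducibility

The test suite runs the full pipeline at the default 10-Mb / 1.5-M-read
configuration for reproducibility checks, the planted-recovery check at a
1-M-read library, permutation calibration on 500 small datasets at
B = 200, NB checks on 10,000-row matrices, and 100 replicate simulations
for repeat-elevation detection at a 2-Mb configuration — sizes chosen so
each check has the statistical resolution its assertion needs. All
randomness flows from explicit seeds; two pipeline runs at one seed write
byte-identical outputs, which the suite asserts by file hash.

# Known limitations

The igHTR definition inherits the annotation's completeness: anything
absent from the transcript-exclusion track can surface as igHTR. The
caller's boundaries are read-supported, so they shrink inside true units
by roughly one mean read gap at each end. The NB test shares one
dispersion across all loci and species — exactly the modelled design, but
an acknowledged simplification. The gene-3' connection window reuses the
10-kb proximity default; the EvoFold-style 1-kb feature extension is a
caller option rather than a second code path. The block-projection model
cannot express inversions or duplications.
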