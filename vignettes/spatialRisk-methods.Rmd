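---
title: "Models and methods behind spatialRisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind spatialRisk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`spatialRisk` implements a cross-disorder analysis of two GWAS risk
architectures in a 3D chromatin-domain model of the nucleus. This vignette
documents the models, their assumptions, the tunable parameters, the
numerical choices, and what the synthetic-data generator does and does not
emulate.

## The data model

Chromatin domains (TAD-scale, ~0.1–3 Mb) are the analysis unit. A diploid
bead model (`BeadModel`) places one bead per domain copy (haplotypes "A"
and "B") at an (x, y, z) coordinate in *model units*, confined to a
spherical nucleus of radius `nucleusRadius` (default 3.0) centred at the
origin. We never convert model units to nanometres: all distance statements
are relative within one model. Contact matrices (`ContactMap`) are sparse
upper-triangle triplets over a genome-wide bin table, typed `raw`
(integral counts) or `normalized`; the binomial caller refuses normalized
input and the interactome extractor refuses raw input, because the
expected-count model is a counting model while interactome scores are
balanced frequencies. Internally all intervals are 1-based closed GRanges;
every text format (BED, gtrack, HiC-Pro abs.bed, BEDPE, WashU) is 0-based
half-open and converted only at the I/O boundary.

## Shared domains and linear-genome baselines

A domain is *shared* when it contains at least one trait-A index SNP
(half-open containment) and overlaps at least one trait-B risk locus by at
least 1 bp. A locus spanning several domains counts for each of them —
bedtools-intersect semantics, which keeps the annotation a plain interval
join. Haploid counting collapses the two haplotype copies; diploid counting
returns bead ids and drops beads absent from the supplied model, mirroring
domains discarded from an embedding run.

Linear-genome baselines quantify how little the two architectures overlap
in sequence: the number of loci containing a SNP, the fraction of loci
whose nearest same-chromosome SNP is more than a threshold (default 1 Mb)
away, and consecutive-neighbour distances within each risk set.
Consecutive distances use midpoints for interval loci and positions for
SNPs; we chose consecutive (not all-pairs) neighbours because the
statistic is meant to describe typical spacing between independent signals,
and midpoints because boundary conventions otherwise dominate for wide
loci. Loci on SNP-free chromosomes get infinite distance and count toward
the beyond-threshold fraction; this is deliberate — absence of any nearby
SNP is the strongest form of separation.

The shuffle test for the shared count reassigns every SNP and every locus
to a uniformly random domain (per-trait totals preserved) and recounts
shared domains. Permutation p-values throughout the package use the
add-one convention p = (1 + k)/(1 + N), which can never return 0 and whose
floor 1/(N + 1) states the resolution of the test honestly. The two-sided
version doubles the smaller tail, capped at 1. Note that with dense risk
sets the uniform null can *exceed* the observed sharing — structured risk
placement constrains colocalization as often as it creates it — so the
two-sided test is the right default.

## Euclidean hot spots

Pairwise straight-line distances δ between shared-risk beads are clustered
agglomeratively (complete linkage by default, the default of the heatmap
clustering tool commonly used for this purpose; average linkage by flag).
The tree is cut at `k` clusters; clusters smaller than `min_size`
(default 3, the smallest cluster size we consider interpretable) are
discarded. No principled cut rule exists for this kind of data, so
`k = "auto"` maximizes the mean silhouette width over k in
[2, min(15, n/3)] — reproducible and documented — and an explicit `k`
override is always available. Clustering is invariant to bead input order
and to rigid motions of the model because it sees only the distance
matrix. The degenerate all-coincident case returns a single cluster rather
than erroring, since downstream significance handles it naturally.

Significance of a hot spot of size m is assessed against draws of m beads
without replacement from the shared-domain pool: the headline empirical p
is the add-one rank of the observed mean intra-cluster distance among the
null means. A one-sided Wilcoxon rank-sum p comparing the hot spot's
distance set against the pooled null distances is reported alongside, with
a Shapiro normality check of the observed distances recorded (the
non-normality of bead distances is the rationale for a rank test); we
treat the rank-sum p as descriptive, not primary, because pooled distances
from overlapping draws are dependent and the rank-sum test is
anticonservative under that dependence. The empirical p on the mean is the
quantity our calibration tests hold to uniformity under the null.

One honest caveat: when hot spots are first *detected* by clustering and
then *tested* on the same coordinates, selection inflates significance —
the tightest clusters of even a uniform cloud test as tight. The package
reports this p as the original analysis defines it, and our calibration
tests therefore draw the tested set independently of any clustering. For
inference about a specific detected hot spot, replicate-stability (mean
pairwise adjusted Rand index across independent embedding runs, plus
best-match Jaccard) is the more trustworthy signal, and both are provided.

Cross-model projection maps each hot-spot domain to every overlapping bead
of a target cell type's model, per haplotype, and recomputes distances
restricted to inter-chromosomal pairs. The restriction avoids counting
short distances between beads that merely tile the same genomic
neighbourhood — different cell types split domains differently, so
same-chromosome distances would measure segmentation granularity, not
spatial organization.

## Binomial contact calling

For a raw intra-chromosomal matrix, the expected count at bin separation d
is E(d) = (Σ counts at separation d) / (number of bin pairs at separation
d), counting absent pairs as zero — the complete pair census, because an
unobserved pair is an observation of zero, not missing data. The diagonal
is excluded. The probability that the bin-of-interest i contacts partner j
is p_ij = E(d_ij) / Σ_k E(d_ik) over all intra-chromosomal partners k
(sums to 1 by construction; an all-zero profile is a no-signal error, not
a silent zero). The p-value is the upper binomial tail
P(X ≥ o_ij), X ~ Binomial(n_i, p_ij), with n_i the *chromosome-wide* total
observed count of bin i, while the tested (and BH-adjusted) family is the
±1 Mb window around i. That asymmetry — chromosome-wide tries, windowed
family — is implemented exactly as specified by the two defining
sentences of the method; a `tries = "window"` flag and a global-BH option
exist for sensitivity analysis. E(d) is computed per chromosome (a pooled
option is a one-line change away but per-chromosome is the default since
decay profiles differ between chromosomes). Tail probabilities come from
`pbinom(..., lower.tail = FALSE)`, which works in log space internally; we
verified exact agreement (1e-12 relative) with explicit `dbinom` tail
summation on exhaustive small cases.

## Cross-disorder interactome

At the interactome resolution (40 kb default), a contact qualifies when
one anchor bin overlaps a trait-A SNP and the other overlaps a trait-B
locus. Reciprocal orientations are the same unordered pair and are counted
once; bins carrying both traits may anchor either side, and a contact
between two such dual bins is flagged "both" rather than double-counted.
Contacts are classified intra/trans-chromosomal; intra contacts are
within-domain when both anchors' (largest-overlap) domains coincide. A
contact belongs to a hot spot when both anchor domains are members.
Zero-frequency pairs are never emitted. Feature annotation counts a
feature once per contact if it overlaps either anchor, and per-hot-spot
totals deduplicate features across contacts (clamped accumulation).

## eQTL permutation enrichment

The randomization unit is the *bin*, not the eQTL: each permutation draws
|target| bins without replacement from the background universe and
recomputes the overlap of unique significant eQTL coordinates
(FDR < 1e-8, strict) with the drawn bins. Ties count toward the null
("≥ observed"), keeping the test conservative. Per-bin overlap counts are
precomputed once so 10,000 permutations are subset sums. Whether the
original permutations preserved per-chromosome bin composition is not
knowable from the method's description; both modes are implemented and
unconstrained resampling is the default. The multi-tissue scan runs the
same test per catalog with derived seeds and flags p < 0.05;
unique-coordinate deduplication across catalogs is available. LD clumping
itself is out of scope (it requires genotype LD); `clumpedInputFilter()`
consumes an externally produced assignment table and keeps one lead per
gene-by-clump.

## The synthetic-data generator

The generator's defaults are the study conditions the package is designed
around: ~1.25 Mb domains on a 150 Mb three-chromosome toy genome (matching
the ~1.3 Mb average domain size of the reference segmentation), nucleus
radius 3.0 model units, 289 trait-A SNPs and 139 trait-B loci (typical
GWAS summary sizes for the two-trait comparison), power-law contact decay
with exponent 1, Poisson counts with base mean `sequencing_depth`
(interpreted as the expected count at one-bin separation), and a trans
background at 0.001 of the cis base mean — far sparser than cis, as in
real Hi-C. Trans pairs share one Poisson mean, so they are drawn without
enumeration: the number of non-zero trans pairs is
Binomial(N_trans, 1 − e^(−μ)), placed uniformly among distinct trans
pairs, with zero-truncated Poisson values — exactly the law of independent
Poisson draws. Planted structure (hot-spot bead clusters drawn uniformly
within `spread` of a center, loop pairs with multiplied means, a
controlled fraction of domains carrying both risk types, eQTL placement
weight multiplied by a fold inside target bins) is recorded in a manifest
so every downstream stage has ground truth to test against. The planted
shared count is `ceiling(shared_fraction × n_haploid_domains)`, capped at
`min(n_snps, n_loci)`; remaining SNPs and loci go to disjoint domain pools
so no sharing arises by accident. A single master seed deterministically
derives per-stage substreams (all below 2^31), making identical configs
byte-identical end to end.

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: LD structure among SNPs (risk loci are
independent intervals, not haplotype blocks), ligation-junction and
coverage biases of real Hi-C (counts are clean Poisson around the decay
law; real counts are overdispersed — a negative-binomial option is a
natural config extension), chromosome territories or compartments in the
bead coordinates (non-planted beads are uniform in the ball), and the
Monte-Carlo embedding itself (coordinates are consumed or synthesized,
never optimized from contacts).

## Problem sizes and defaults in the shipped pipeline

`pipelineConfig()` runs the full chain on 120 haploid domains (150 Mb at
40 kb matrix resolution), 120 SNPs / 60 loci with shared fraction 0.10,
500 hot-spot null samples, 500 shuffle permutations and 1000 eQTL
permutations, finishing in well under a minute on one CPU — sizes chosen
so an end-to-end run is an interactive operation while every statistic
retains its behaviour at scale (the operations are vectorized and handle
full-genome inputs; 10,000-permutation defaults are used when calling the
stage functions directly). In the pipeline, the synthetic eQTL catalog is
generated with its planted enrichment in the interactome anchor bins that
the run itself discovered, so the final permutation test has a known
signal to find; with `eqtl_enrichment_fold = 1` the same path serves as a
null calibration.

## Numerical and edge-case conventions

Empirical p-values are add-one and two-sided by tail doubling capped at 1.
Binomial tails never underflow to zero at moderate sizes (log-space
computation). Scores in text formats are written with 6 significant
digits, and bp coordinates as plain integers, so write–read–write cycles
are byte-identical. Degenerate inputs favour defined results over errors
when a convention is defensible: empty SNP sets give zero shared domains;
an empty eQTL catalog gives overlap 0 and p = 1; fewer than two risk
elements per chromosome give an empty separation statistic; a hot spot
equal to its pool gives p = 1 with a warning; zero-variance correlation
inputs return NA with a note. Hard errors are reserved for contract
violations: normalized matrices in the caller, raw in the extractor,
windows smaller than a bin, observed counts above tries, backgrounds
smaller than targets, malformed format lines (reported with line
numbers).
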