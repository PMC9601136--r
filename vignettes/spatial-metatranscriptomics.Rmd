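---
title: "Methods: multi-site metagenome merging and spatially aware metatranscriptome analysis"
author: "SpatialMetaTx"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Methods: multi-site metagenome merging and spatially aware metatranscriptome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The analysis problem

Shotgun metagenome and metatranscriptome samples collected at several sites
along an ordered organ axis — here modelled on the gut chain cecum →
transverse colon → feces in two or more individuals — pose two coupled
problems.  First, per-site assemblies fragment each genome differently, so
the "same gene" has no common coordinate system across sites; merging the
per-site scaffolds into one common reference fixes that and improves
contiguity, because fragments from different sites complement one another.
Second, a large fraction of genes carries no KO/COG annotation; their
function can be predicted from *spatial covariation*: genes serving the
same metabolic process tend to share the shape of their expression profile
over the site chain, and a bivariate spatial association statistic (Lee's
L) quantifies exactly that — correlation of two profiles combined with
their smoothness over a site-adjacency graph.

`SpatialMetaTx` implements the full pipeline: scaffold merging, gene
catalogue construction, read mapping and counting, whole-community (TPM)
and per-cell expression, L-statistic covariation with ROC-calibrated
thresholds and label transfer, and assembly grading — plus a synthetic
community generator with complete truth tables so every stage can be
validated end to end.

# Scaffold merging

`mergeSites()` folds per-site scaffold sets into one reference, largest
set first (the largest assembly is the best backbone; input order is
otherwise irrelevant on unambiguous overlaps, which the tests check by
permutation).  Each fold calls `mergePair()`:

* **Overlap detection** (`findScaffoldOverlaps()`): shared 21-mers seed
  diagonals per scaffold pair and orientation; the best diagonal is
  extended gaplessly to the maximal implied overlap and verified by
  mismatch counting.  A candidate is kept when the aligned length is at
  least `mL` (default 1000 bp — short contigs below 1000 bp are discarded
  on input) and identity is at least `c` percent (default 95).  `hco`
  (default 100 bp) caps the inner overhang a join may leave unaligned.
  The three knobs deliberately mirror the roles of the merge length
  cutoff, alignment confidence and overlap confidence of long-read
  scaffold mergers, but their semantics here are exactly as defined above
  (identity is a percent, the overhang a length); the external tools'
  unit-less confidence scores do not translate.
* **Greedy merging**: candidates are accepted in sorted order (alignment
  length, then identity, then ids), each scaffold end used at most once,
  union-find forbidding cycles, so the accepted joins form paths that are
  spliced deterministically.  Reference-set bases win inside accepted
  overlaps: the accumulating assembly is treated as the reference.
* **Containment**: a query scaffold aligned over ≥ 90% of its length at
  identity ≥ `c` inside a reference scaffold is dropped (recorded, not
  silently); a final sweep removes scaffolds contained in the merged
  output itself, which arise when a small backbone fragment is swallowed
  by a longer spliced scaffold.
* **Provenance**: every merged scaffold carries an exact tiling of source
  (site, scaffold, interval, orientation) segments, so every base is
  traceable to exactly one input base; the class validity check enforces
  the tiling.  Scaffolds are reported in a canonical orientation (majority
  of provenance bases forward).
* Runs of ≥ 10 `N` split scaffolds before overlap detection, so
  scaffolding gaps cannot seed anchors.

Since the seeding is gapless, overlaps with small indels are found only if
one diagonal still dominates; this is adequate for the substitution-only
error model of the simulator and is stated as a limitation for real data.

# Gene catalogue

`callOrfs()` is a deliberate stand-in for a statistical gene finder: all
maximal ORFs (ATG to stop, six frames) of ≥ 300 nt, same-strand overlaps
resolved longest-first.  External gene models are accepted as GFF3
everywhere features are consumed.  `matchGenesAcross()` measures
gene-identity retention across assemblies: genes of the per-site
catalogues are matched greedily at ≤ 3 edits (Levenshtein — the band
subsumes the pure-substitution reading; candidates are pruned by length
difference), connected components touching every site count as "common to
all sites", and a common gene is retained when any member matches the
merged catalogue at ≤ 3 edits.  Unknown proteins are clustered greedily by
length-sorted centroids at ≥ 90% identity over ≥ 85% of the shorter
sequence (the coverage default echoes the annotation alignment coverage
customary for such catalogues); known genes are grouped by COG label, with
multi-label genes in every matching cluster (flagged).

# Quantification

`mapReads()` is a gapless seed-and-verify short-read mapper (five seed
offsets per mate, both orientations, unique-best placement within a 5%
mismatch budget, ambiguous best → unmapped; properly paired = same
scaffold, opposite strands, fragment ≤ 2000 bp).  External SAM is accepted
interchangeably.  `countReads()` reimplements union-mode pair counting: a
pair counts for gene *g* iff the union of genes overlapped by either mate
is exactly {*g*}; counting is strand-agnostic because the ORF stand-in
does not guarantee strand fidelity.

Two expression layers:

* **Whole community**: TPM.  With counts $c_g$ and lengths $l_g$ (kb),
  $\mathrm{tpm}_g = 10^6 (c_g/l_g) / \sum_h (c_h/l_h)$; the column sum is
  $10^6$ by construction (tested to $10^{-6}$ relative).
* **Per cell**: $(c_g/l_g) / (d_g + \mathrm{pseudodepth})$, where $d_g$ is
  the mean per-base DNA depth of the gene.  Both numerator and denominator
  scale with species abundance, so the ratio estimates expression per
  bacterium, independent of abundance — the property that distinguishes
  the two layers, asserted on a constructed fixture where one species is
  scaled 10×.  Genes with zero DNA depth are masked (NA), not zero: the
  per-bacterium rate is undefined there.  The exact published form of this
  normalisation is not public; this realisation preserves its stated
  contract (mRNA counts normalised by DNA coverage) and the cancellation
  property.

KO-level differential calls use log2 differences with a scale-adaptive
pseudocount (half the smallest positive value of the layer) and the
2-fold-same-direction-in-every-individual rule.

# Spatial covariation

The sample grid is the ordered (individual, site) pairs; with two
individuals and three sites each profile is a 6-vector.  The weight matrix
V (`buildWeights()`) is block-diagonal across individuals, with chain
adjacency over the ordered sites, self-inclusion on, rows standardised to
sum to 1.  The published construction of V is not available; this is the
minimal structure consistent with "spatial relevance between multiple
intestinal sites", and the package treats it as a design choice.

Lee's L (`leeL()`) is

$$ L(x,y) = \frac{n}{\sum_i (\sum_j v_{ij})^2}\;
   \frac{\sum_i \big(\sum_j v_{ij}(x_j-\bar x)\big)
                \big(\sum_j v_{ij}(y_j-\bar y)\big)}
        {\lVert x-\bar x\rVert\,\lVert y-\bar y\rVert}. $$

With $V=I$ it equals the Pearson correlation (an oracle test), it is
symmetric and invariant to positive affine maps of either argument, and a
literal triple-loop implementation agrees to $10^{-12}$.

Cluster profiles are sums of member-gene expression, log2(1+x) transformed
(differential analysis operates in log2 space; configurable off).
`benchmarkKnown()` scores all pairs of reaction-labelled known clusters
(positive = shared reaction; unlabelled clusters are excluded, not treated
as negatives), sweeps the ROC over all distinct L values, integrates AUC
by trapezoid (equal to the tie-corrected pair-counting estimator — an
oracle test), and selects the threshold θ as the smallest L with empirical
FPR ≤ 0.05.  The reference operating point θ = 0.885 known from gut
metatranscriptome work can be forced via
`pipelineConfig(covariation = list(L_threshold_override = 0.885))`, but
the package always calibrates by default, because θ is a property of the
data at hand.  `transferFunctions()` links every (unknown, known) pair
with L ≥ θ and assigns the union of linked labels;
`enrichFunctions()` tests per-category enrichment with a two-sided Fisher
exact test, Benjamini–Hochberg adjusted, at adjusted p < 0.01.

# The synthetic community generator

The generator is first-class, tested code.  Its defaults define the study
conditions used throughout the tests:

* **Genomes** (`simulateGenomes()`): i.i.d. background at GC 0.5 with
  non-overlapping planted ORFs (ATG, no internal in-frame stop, stop; 300
  to 1500 nt; density 1/4000 bp — about one gene per 4 kb, a deliberately
  sparse caricature of a prokaryote so that union counting stays
  unambiguous).  Demo communities use 6 genomes of 30 kb (reconstruction
  checks use 100 kb genomes, about 600 kb of total sequence); these sizes
  keep whole-pipeline runs in seconds while every scaffold still spans
  many fragments.
* **Abundance**: per species, a lognormal individual baseline times a
  smooth site gradient — species composition changes along the gut axis.
* **Expression** (`assignExpression()`): every gene follows a latent
  spatial profile; the two members of a designed covariant pair share one
  profile and a reaction label.  A latent profile is a random direction in
  the spatially smooth subspace of the sample grid — a per-individual
  linear gradient over the site chain plus a between-individual offset
  contrast — with a fixed energy split (30% offset) and a lognormal
  amplitude around `effectSize`.  The fixed split is intentional: Lee's L
  couples correlation with smoothing, so profiles whose spatial-frequency
  composition varies wildly would make L depend on composition rather than
  on the shared shape; the covariance is induced via shared latents rather
  than copied values so pair members differ in magnitude while sharing
  shape — matching what the L statistic detects.  Expression is
  `exp(base + latent + N(0, noiseSd))`.  At `effectSize = 0` the design
  collapses to exchangeable noise, which is the calibration null.
* **Unknown genes**: 30% of genes are stripped of KO/COG labels (echoing
  the roughly quarter of gut genes absent from COG); their reaction truth
  moves to a hidden column used only for scoring label transfer.
* **Fragmentation** (`fragmentPerSite()`): each site receives a complete
  tiling of every genome with breakpoints staggered between sites by
  2–3 kb (≥ `mL`), nominal fragment length 9 kb, nothing below the
  1000 bp contig floor.  Within a site adjacent fragments share no
  overlap, so single-site assemblies cannot be merged further — only
  cross-site merging can reconstruct the genome, which mirrors the
  situation the merging method exists for.
* **Reads** (`simulateReads()`): paired 150 nt reads, insert 400 ± 40 bp,
  uniform within genomes (DNA, rate ∝ abundance) or gene bodies (mRNA,
  rate ∝ abundance × expression × gene length, like a fragmented
  transcript library), i.i.d. substitution errors, constant Q40
  qualities, exact rounded budgets, full truth tables.

What the generator does **not** emulate — and therefore what green tests
do not show about real data: indels and structural variation, strain
mixtures, rRNA carry-over, coverage biases (GC, position), shared k-mer
content between species, operonic gene structure, and quality-score
variation.

# Numerical and procedural choices

* All randomised stages take explicit seeds and restore the caller's RNG
  state; equal seeds give byte-identical outputs.
* Greedy procedures (merge joins, ORF overlap resolution, gene matching,
  protein clustering) operate on globally sorted candidate lists with
  full tie-breaks, so results are independent of input order.
* ROC threshold selection takes the smallest L whose empirical FPR meets
  the target; with no qualifying finite threshold, θ sits just above the
  maximum score (sensitivity 0) rather than failing.
* Degenerate inputs: constant expression profiles are excluded from the
  L analysis (logged), zero-depth genes are masked in the per-cell layer,
  all-zero TPM columns are flagged, an empty benchmark truth set is an
  error rather than a silent AUC.
* The chimera index is length-weighted at scaffold granularity
  (configurable to count-weighted); the composite performance metric is
  this package's own composite, `N50_broken × (1 − CI) × (TAL / assembly
  bp)` — monotone in contiguity, accuracy and completeness, but **not**
  numerically identical to any published composite score; the published
  definitions of both are not available in detail.

# Known limitations

Numeric agreement with published headline values (AUC 0.830/0.729,
θ = 0.885, mapping rates, nonchimeric rates) is out of reach by design:
those derive from hundreds of gigabases of real sequencing data and from
supplementary definitions that are not public.  The package instead
reproduces the *properties* those numbers witness — merged contiguity
dominating per-site assemblies, merged mapping rates at least matching
per-site rates, FPR-controlled covariation with high recovery under
strong designed effects and null calibration at zero effect, and accuracy
metrics that move correctly under chimera injection — each verified
against independent oracles in the test suite and recomputed from scratch
by `scripts/acceptance.R`.
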