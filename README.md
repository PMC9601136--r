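# SpatialMetaTx

Integrated metagenome + metatranscriptome analysis for microbial
communities sampled at several sites along an ordered organ axis (for
example the gut chain cecum → transverse colon → feces) in multiple
individuals.  The package is aimed at microbiome researchers who have
per-site assembly scaffolds plus paired-end DNA and mRNA reads and want
one common reference, comparable expression values across sites, and
function predictions for unannotated genes.

## What it computes

1. **Common reference reconstruction** — per-site scaffold sets are merged
   by end-anchored overlaps (minimum alignment length `mL` = 1000 bp,
   identity `c` ≥ 95 %, inner overhang ≤ `hco` = 100 bp), greedily with
   deterministic tie-breaks; contained scaffolds are dropped and every
   merged base carries provenance back to one input base
   (`mergeSites()`).
2. **Expression quantification** — reads are mapped (gapless
   seed-and-verify stand-in mapper; external SAM accepted), counted per
   gene in HTSeq-style union mode, and normalised two ways
   (`computeTpm()`, `computePerCell()`):

   * whole community: `tpm_g = 1e6 (c_g/l_g) / Σ_h (c_h/l_h)`
   * per cell: `(c_g/l_g) / d_g`, the mRNA rate divided by the gene's
     mean DNA depth `d_g`, which cancels species abundance and estimates
     expression per bacterium.
3. **Function prediction by spatial covariation** — cluster expression
   profiles over the (individual × site) grid are compared with Lee's
   bivariate spatial association statistic

   `L(x,y) = [n / Σ_i(Σ_j v_ij)²] · Σ_i (Σ_j v_ij x̃_j)(Σ_j v_ij ỹ_j) / (‖x̃‖‖ỹ‖)`

   over a row-standardised site-adjacency matrix V (block-diagonal per
   individual).  A threshold calibrated on annotated (COG) clusters to
   FPR < 0.05 via ROC (`benchmarkKnown()`) links unannotated clusters to
   annotated ones and transfers labels (`transferFunctions()`), with
   Fisher/Benjamini-Hochberg enrichment (`enrichFunctions()`).
4. **Assembly grading** — generalized N-statistics N10..N100, chimera
   index, nonchimeric rate, MAL/TAL and a composite performance metric
   (`evaluateAssembly()`), plus mapping-rate comparison between
   references (`mappingRate()`).
5. **Synthetic communities** — `simulateGenomes()`,
   `assignExpression()`, `fragmentPerSite()` and `simulateReads()`
   generate multi-site, multi-individual data with designed covariant
   gene pairs and complete truth tables; everything is a pure function of
   (parameters, seed).

See the methods vignette
(`vignettes/spatial-metatranscriptomics.Rmd`) for the models, parameter
meanings and design decisions.

## Worked example

```r
library(SpatialMetaTx)
report <- runDemo(seed = 0, rnaDepth = 0.5)
printDemoReport(report)
```

which prints (seed 0):

```
Demo (seed 0)
  exact reconstruction of all genomes: TRUE
  merged N-curve dominates all site curves: TRUE
  TPM conservation: max |sum - 1e6| = 1.16e-10
  Spearman(TPM, truth community expression) = 0.999
  covariation AUC = 0.624, theta = 0.397 (FPR 0.046)
  designed unknown-known pairs recovered: 2 / 6
  RNA mapping rate: merged 100.0% vs sites 100.0%, 100.0%, 100.0%
  nonchimeric rate 100.0%, CI 0.000, CPM 30000
```

Reading this: the three per-site scaffold sets of six 30 kb genomes were
merged back into exactly the six genomes (so the merged N-statistic curve
dominates every per-site curve and the nonchimeric rate is 100 %); TPM
columns sum to 10⁶; TPM ranks track the truth (abundance × expression)
almost perfectly; the covariation benchmark on annotated clusters reaches
AUC ≈ 0.62 under the demo's moderate effect size, and the calibrated
threshold keeps the empirical FPR below the 0.05 target.  Recovery of
designed unknown–known pairs at this moderate effect size is weak — the
whole-community layer confounds expression with the abundance gradients —
which is exactly the regime the calibration study probes at profile scale
(see below).  Individual stages are available as ordinary functions
(`mergeSites()`, `mapReads()`, `benchmarkKnown()`, ...), and a staged
file-based runner with checksummed resume is `runPipeline()`; a thin
command-line wrapper lives in `inst/scripts/spatialmetatx.R`.

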