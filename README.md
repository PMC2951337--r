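# lumisig

Gene-signature derivation and projection for luminal breast cancer
expression studies.

## The problem

A recurring workflow in breast-cancer transcriptomics starts from a small
RNAi knockdown experiment in a luminal cell line and asks what the
perturbed transcription factor does in tumors: which genes respond to the
knockdown, whether that response signature is "active" in particular tumor
subtypes or mammary cell lineages, how it relates to the luminal/ER+ gene
cluster, and whether the gene's expression stratifies patient survival.
`lumisig` implements that chain as reusable, tested components for
computational biologists who want the statistics without a GUI package:

- **prep** — two-channel lowess normalization
  (M = log2(Cy5/Cy3) against A = ½·log2(Cy5·Cy3)), intensity/presence
  gene filtering (≥ 10 units in both channels, present in ≥ 70% of
  samples), probe-to-gene collapse, TSV round-tripping;
- **SAM engine** (written from scratch) — the two-class unpaired
  relative-difference statistic d = (x̄₂ − x̄₁)/(s + s₀), fudge-factor
  tuning by the CV-of-window-MAD criterion, an exact enumerated or seeded
  sampled permutation null, asymmetric delta cutpoints against the
  expected order statistics d̄, and median-false-positive FDR calibration;
- **activity** — signatures weighted by SAM statistics projected onto any
  expression matrix as an inner product, compared across groups by ANOVA;
- **modules** — average-linkage correlation dendrograms over genes with a
  node-correlation threshold module around a seed gene (e.g. the 0.65
  cluster around ESR1), and exclusive overlap decomposition of a module
  against named signatures;
- **cohort statistics** — rank-split expression halves, Kaplan–Meier
  curves, log-rank tests, t/ANOVA group association, 2×2 chi-square, and
  growth-curve doubling times;
- **synthetic data** — seeded generators for every input shape (knockdown
  series, subtype-structured tumor cohort with exponential survival,
  sorted mammary-lineage panel, biased two-channel spot tables), each
  emitting its ground truth so recovery is testable end to end.

Everything is S4 (the expression container extends
`SummarizedExperiment`), deterministic for a fixed seed, and free of any
network dependency.

## Worked example

Derive a signature from a simulated 6-vs-5 knockdown, project it onto a
lineage panel, and stratify survival in a simulated tumor cohort:

```r
library(lumisig)

kd  <- simulateKnockdown(nGenes = 1000, deFraction = 0.1, effectSize = 2,
                         sigma = 0.5, seed = 1)
res <- runSam(kd$expression, kd$labels, seed = 1)
res
#> SamResult: 1000 genes
#>   s0 = 0.4022; 462 enumerated permutations

sig <- deriveSignature(res, fdrThreshold = 0.05)
sig
#> GeneSignature 'signature': 100 genes (51 positive, 49 negative); FDR < 0.05
mean(kd$trueDe %in% geneIds(sig))
#> [1] 0.96

lin <- simulateLineages(sig, plantedPopulation = "ML", seed = 1)
act <- projectSignature(sig, lin$expression)
cmp <- compareActivity(act, lin$populations)
cmp$summary
#>   group n        q1    median        q3      mean
#> 1  MaSC 5 -61.76597 -54.85481 -50.96352 -55.71808
#> 2    LP 5 -54.86128 -49.27615 -40.54799 -49.57798
#> 3    ML 5 228.43877 229.97106 241.19637 233.59270
#> 4    St 5 -57.74850 -44.31915 -42.17838 -52.52242
cmp$pValue
#> [1] 2.28e-16

co <- simulateCohort(logHazardRatio = -0.5, seed = 1)
survivalByExpression(co$expression, co$clinical, co$markerGene)$logrank
#> $statistic 13.1   $df 1   $pValue 0.000296
```

Reading the output: the permutation null was fully enumerated (all 462
label assignments of a 5-vs-6 design), the 5%-FDR signature recovered 96%
of the planted genes, its projected activity is maximal in the planted
mature-luminal (ML) population with ANOVA p ≈ 2e-16, and in the cohort —
where high marker expression was simulated protective — the rank-split
halves separate by log-rank chi-square 13.1 (p ≈ 3e-4).

`runPipeline()` chains the stages from one config and writes
provenance-stamped artifacts; see the methods vignette
(`vignettes/lumisig-methods.Rmd`) for the model details, parameter
defaults, and design choices. `reproduceGSE21371()` re-analyzes the real
deposited knockdown series when a user has downloaded it, reporting
derived counts side by side with the published ones; it skips cleanly
otherwise.

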