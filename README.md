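# metaboSL

Synthetic-lethal (SL) interaction prediction for cancer cell lines from
constraint-based metabolic models and somatic mutation data.

Two genes form a synthetic-lethal pair when losing either alone is
tolerated but losing both kills the cell — a prime source of targeted
therapy candidates (mutated driver gene = the tumour's existing hit,
SL partner = the drug target). `metaboSL` predicts such pairs by asking
whether the *simulated* growth cost of knocking out a gene differs between
cell lines that do and do not carry damaging mutations in a driver gene.

## What the package computes

1. **Context-specific models.** From a generic genome-scale metabolic
   model (SBML L3+FBC or JSON) and per-cell-line expression profiles,
   an iMAT-style mixed-integer extraction keeps highly-expressed
   reactions active (flux ≥ ε) and silences lowly-expressed ones, with a
   grid search over (LB, UB) expression thresholds that returns the first
   pair yielding a growing model. Flux balance analysis is the LP

       maximize cᵀx  subject to  Sx = 0,  l ≤ x ≤ u

   over the stoichiometric matrix S.
2. **KO-score matrix.** Per cell line, the L1-minimal (taxicab) flux
   vector at the FBA optimum is mapped through the gene–protein–reaction
   rules to a KO-gene list; each listed gene is knocked out (closing the
   reactions its loss disables) and scored by the growth ratio
   KO/wild-type ∈ [0, 1]. Genes outside the list default to 1.
3. **Mutation-stratified scan.** For every (driver, KO gene) pair —
   drivers being metabolic genes with damaging mutations in ≥ 2 lines —
   a two-sided pooled-variance t-test compares KO scores between mutated
   and wild-type lines. Pairs whose mutated-group mean exceeds 0.95 are
   filtered (p = 1); tiny uniform noise (10⁻¹² – 10⁻¹¹) guards against
   zero-variance groups; Benjamini–Hochberg FDR is applied across the
   scan.
4. **Screen validation.** The same stratified test runs on measured
   dependency matrices (CRISPR gene effect, shRNA ATARiS, drug-response
   log-fold-change), and the overlap of significant pairs is scored with
   an upper-tail hypergeometric test P(X ≥ overlap).
5. **Enrichment.** Per driver, partners ranked by |t| feed a preranked
   weighted-KS gene-set enrichment with a permutation null, and process
   frequencies are counted across drivers.

A naive exhaustive double-deletion baseline
(`exhaustiveDoubleDeletionSL`, growth-ratio cutoff 0.01) is included for
comparison with purely deterministic SL prediction.

## Worked example

```r
library(metaboSL)

## deterministic toy dataset: driver g2's backup pathway is silenced in
## mutated lines, making partner g1 essential only there
ds  <- generatePlantedSLDataset(list(seed = 7))
tab <- scanFixtureDataset(ds, seed = 7)
tab
#> SLResultTable: 4 (driver, KO gene) pairs, 1 significant
#>  driver ko_gene             t             p          fdr mean_mut mean_wt ...
#>      g2      g1 -893309918196 2.803424e-205 1.12137e-204        0       1
#>      g2      g2             0  1.000000e+00  1.00000e+00        1       1
#>      ...
```

The (g2, g1) pair is recovered with mutated-group mean 0 (lethal
knockout) against wild-type mean 1; the enormous |t| reflects the
separated constant groups plus the anti-degeneracy noise. The remaining
pairs have mutated-group means above 0.95 and are filtered to p = 1.

Screen-style validation on published contingency counts:

```r
cc <- ContingencyCounts(nMethod = 6462, nScreen = 2929,
                        overlap = 140, universe = 159030)
hypergeometricEnrichment(cc)$p
#> [1] 0.0287
```

A configured end-to-end run (`runPipeline`, or the CLI at
`inst/scripts/slscan-cli.R`) writes per-stage CSVs plus a JSON manifest
and skips up-to-date stages on rerun.

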