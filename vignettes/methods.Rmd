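---
title: "Methods: constraint-based synthetic-lethality scanning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: constraint-based synthetic-lethality scanning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaboSL)
```

## The model

A metabolic network is summarised by its stoichiometric matrix $S$
(metabolites × reactions), flux bounds $l \le v \le u$ and an objective
vector $c$ singling out the biomass reaction. Flux balance analysis
(FBA) assumes a pseudo-steady state, $Sv = 0$, and takes the maximal
attainable biomass flux $c^\top v$ as a proxy for growth capacity.
Gene–protein–reaction (GPR) rules — boolean expressions with AND for
enzyme complexes and OR for isozymes — connect genotype to the network:
a gene knockout closes (bounds to zero) exactly the reactions whose rule
evaluates false. The knockout score of gene $g$ in a cell line is the
ratio of post-knockout to wild-type biomass optimum, clipped to
$[0, 1]$.

The synthetic-lethality logic is statistical rather than enumerative:
cell lines are stratified by the damaging-mutation status of a *driver*
gene (damaging in at least `min_mutated_lines = 2` lines), and for each
candidate partner the knockout scores of the two strata are compared
with a two-sample t-test. A pair is called when knocking the partner out
is systematically more lethal in driver-mutated lines.

## Per-cell-line model construction

Expression profiles (log2 TPM) are mapped to reactions through the GPR
rules with the COBRA convention AND → min, OR → max. Genes absent from a
profile are ignored inside a rule; a reaction none of whose genes are
profiled (or with no rule) is *unmapped* and classified "moderate", so
the extraction neither rewards nor penalises it. Classification uses two
thresholds: value ≥ UB → high, ≤ LB → low (ties inclusive on both
sides; the inputs are continuous, so the convention is immaterial in
practice but fixed for determinism).

The iMAT-style extraction maximises

$$\#\{\text{high reactions with } |v| \ge \varepsilon\} +
  \#\{\text{low reactions with } v = 0\}$$

subject to $Sv = 0$ and the bounds, with binary indicators entering
through big-M constraints. The context model keeps the core reactions
(by default the biomass reaction plus all exchanges) and every reaction
carrying flux $|v| > 10^{-6}$ at the MILP optimum; orphan metabolites
are pruned. Because dropped reactions carry zero flux, the restricted
optimum stays feasible, so an extracted model always admits FBA.

Threshold pairs come from a grid searched in a fixed order; the first
pair whose extracted model grows (objective $> 10^{-6}$) wins. When the
caller provides no grid, quantile pairs of the profile are used in the
order (q25, q75), (q25, q90), (q10, q75), (q10, q90), (q50, q75) — a
declared convention: the appropriate grid is data-dependent, and "first
suitable" is only well-defined once an order is fixed. For data whose
expression is engineered around known levels (the bundled toy scenarios,
two levels at 1 and 9), an absolute grid such as LB = 2 / UB = 5 is the
right choice and is what the synthetic datasets carry; quantiles of a
two-level expression distribution with only a handful of genes land
inside one of the levels and classify by jitter instead of by signal.

Model QC reports blocked reactions (zero flux in every feasible
solution, by per-reaction flux maximisation/minimisation), the biomass
value, and structural checks. Functionality tasks ("produce metabolite T
from inputs I") close all exchanges, open imports for the task inputs,
add a demand for the target and require demand flux ≥
`epsilon_task = 1e-4`. Construction success is benchmarked against 100
random reaction subsets of the generic model at the same size; random
models always retain the exchanges and the biomass reaction — without
them essentially every random subset fails every task and the
99%-quantile criterion degenerates.

## The scan

For each cell line the KO-gene list is derived parsimoniously: solve
FBA, then minimise the taxicab norm $\sum_i |v_i|$ with the objective
pinned to the FBA optimum (within $10^{-6}\max(1, |v^\ast|)$ — exact
equality pins are numerically brittle), and collect the genes of
reactions with $|v| > 10^{-6}$. Genes outside the list score 1 by
definition (their knockout cannot affect the parsimonious solution's
route).

Per (driver, KO gene) pair:

* pairs whose mutated-group mean exceeds `filter_mean = 0.95` are
  filtered without testing and assigned p = 1 — the knockout is
  essentially inert where the driver is mutated;
* otherwise uniform noise on $[10^{-12}, 10^{-11}]$ is added to every
  observation (simulated ratios are piecewise constant; whole groups at
  exactly 1 or 0 would give zero-variance t-tests), and a **two-sided
  pooled-variance (Student) t-test** compares the strata. Pooled and
  two-sided are declared conventions; the sign of t is mean(mutated) −
  mean(wild), so lethality concentrated in mutated lines gives t < 0.
  The noise is drawn from a generator seeded per (scan seed, driver, KO
  gene), so a pair's result is independent of scan iteration order;
* Benjamini–Hochberg adjustment runs across all tested pairs of one
  scan, filtered pairs included at p = 1 (they are genuine members of
  the tested family); pairs with fewer than two lines in either stratum
  are skipped and excluded from the family, since a one-observation
  t-test is undefined;
* pairs are significant at FDR ≤ `alpha = 0.05`.

Experimental screens (CRISPR gene effect, shRNA ATARiS, drug
log-fold-change) run through the same stratified test without the
filter and without noise — measured data carry natural variance — with
missing values dropped pairwise. Concordance between a scan and a
screen is counted over the pairs tested in both, and enrichment of the
overlap uses the inclusive upper tail $P(X \ge \text{overlap})$ of the
hypergeometric distribution; the inclusive tail is the convention that
reproduces the published per-cancer enrichment values recomputed in
`scripts/acceptance.R`.

## Enrichment of SL partners

Per driver, tested partners are ranked by descending |t| (ties: larger
raw score, then lexicographic id), with the driver itself appended at
the mean partner t. Gene-set enrichment is the preranked weighted-KS
statistic (weight |score|, exponent 1): hits advance the running sum
proportionally to |score|, misses retreat uniformly, the enrichment
score is the extreme deviation. Only a gene-label permutation null is
available from a ranked list, so p is the fraction of `n_perm = 1000`
seeded label permutations with $|ES_{perm}| \ge |ES|$; sets overlapping
the list in fewer than 2 genes, or covering it entirely, are skipped.
Frequencies of nominally significant sets are counted across drivers
(a BH option exists but is off by default — frequency counting is
descriptive).

## Numerical choices

* LP/MILP: the package's own dense two-phase simplex with Bland's rule
  — deterministic pivoting, so repeated runs yield identical flux
  vectors — under a depth-first zero-gap branch-and-bound for the iMAT
  binaries (most-fractional branching, 1-branch first). Problems here
  are small and dense; the solver is validated against vertex
  enumeration on random networks in the test suite.
* Zero-flux threshold $10^{-6}$ everywhere a support is taken
  (feasibility tolerance ~$10^{-9}$, three orders of margin).
* Negative objective values from solver noise clip to 0 before ratio
  formation; knockout models reported infeasible score 0.
* iMAT activation $\varepsilon = 0.1$ flux units; integrality tolerance
  $10^{-6}$; optimality gap 0.
* Pipeline CSVs print floats in 6-significant-digit scientific
  notation, making reruns byte-identical.
* All seeded randomness derives sub-seeds from a 31-base polynomial
  string hash of (master seed, label) modulo $2^{31} - 1$, so results
  are independent of iteration order and stable across platforms that
  share R's Mersenne-Twister.

## What the synthetic data do and do not show

`generatePlantedSLDataset` emulates the *statistical shape* the scan
assumes, on a 5-reaction parallel-route network: mutated lines carry a
damaging MAF record for the driver and silence its backup pathway at
the expression level, so the partner becomes essential exactly there;
wild lines express everything highly; ±0.1 jitter (too small to cross
the LB = 2 / UB = 5 thresholds) exercises the numerics.
`generateNullDataset` draws mutation labels Bernoulli(0.5) per gene,
independent of expression; expression still varies (the backup-route
gene is lowly expressed in a random half of the lines) so knockout
scores have genuine variance carrying no SL signal. The trunk-route
gene stays high so every line's construction succeeds — the calibration
study measures the scan, not construction failures.

Passing the recovery and calibration suites therefore shows the
pipeline composes correctly and controls false positives under its own
assumptions. It does not show robustness to what real data add:
genome-scale models with thousands of coupled reactions and alternate
optima, bimodal and batch-affected expression, mutation spectra with
passenger damage, or dependency screens with off-target structure.

Problem sizes in the bundled studies: 100 planted replicates and 20
null replicates at 20 cell lines on the toy network, 50 random
≤10-reaction networks for solver validation, exhaustive indicator
enumeration on ≤12-reaction toys, and hypergeometric brute-force checks
at universes ≤ 500.

## Known limitations

* Only metabolic genes can be drivers or partners; regulatory and
  signalling lethality is invisible to the model.
* The extraction solves a MILP whose alternate optima are broken by a
  deterministic search order, not by biology; a different but equally
  optimal context model can be defensible.
* The L1-support KO-gene list deliberately restricts simulation to the
  parsimonious route; genes whose knockout only matters off that route
  default to score 1.
* The built-in dense simplex targets small networks; genome-scale
  models (thousands of reactions) want a sparse revised simplex or an
  external solver behind the same interfaces.
* Hypergeometric enrichment treats pairs as exchangeable; correlated
  pairs (shared drivers, shared pathways) make the p-values optimistic.
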