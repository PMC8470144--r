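---
title: "Methods: consensus feature selection for two-group metabolomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus feature selection for two-group metabolomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(consensusmet)
```

## Scope and model of the data

`consensusmet` analyses steady-state, two-group relative-abundance panels:
a samples × metabolites matrix with a control and a treated group of at
least two (typically six) replicates each. The package treats abundances
as log-normal around a metabolite-specific baseline, with three nuisance
processes layered on top: a per-sample multiplicative scaling (cell
counts), missing readings that concentrate at low intensity, and
independent biological noise on the log scale. Zeros are measured values;
only absent readings are "missing", and they are never imputed — a
metabolite with any missing reading is removed before analysis.

## Preprocessing

`preprocess_panel()` applies, in order: optional cell-count division;
the strict completeness filter (`filter_complete()`, reporting the
retention fraction); control-mean normalization (`normalize_to_control()`,
after which every control-group column mean is exactly 1); fold change on
that un-logged scale (`fold_change()`, so FC < 1 reads as
down-regulation); log transform; Pareto scaling.

Choices worth stating:

* **Log base 10.** Only "log-transformed" is specified by convention in
  this field; the base is irrelevant to the t, VIP and MDA statistics
  (monotone linear on the log scale) but is pinned for reproducibility to
  the MetaboAnalyst convention.
* **Control-group mean** (not median) as the normalization reference; a
  median option would be a one-line change but the mean matches the
  definition of fold change used downstream.
* **Univariate models run on the log matrix; multivariate models on the
  Pareto-scaled matrix** (`test_on` switches this). Pareto scaling
  reweights features for the projection methods but only rescales each
  feature for the t-test, so this mirrors the common tooling default.
* Pareto scaling of a constant column would divide by zero; such columns
  are centred, left unscaled, and flagged with a warning.

## The four feature-selection models

**t-test.** Pooled-variance two-sided two-sample t per metabolite
(Welch available), BH adjustment across retained metabolites, significant
at q < 0.05. Constant metabolites get t = 0, p = 1 with a warning rather
than an error, since a single flat feature should not abort a panel.

**SAM.** `d_i = (mean difference) / (s_i + s0)` with `s_i` the pooled
standard error and `s0` chosen by the percentile search that minimises
the coefficient of variation of `mad(d)` across `s`-quantile windows.
The permutation null enumerates all distinct balanced label splits when
they fit the budget (462 for six vs six; sampling without replacement
otherwise). Calling is delta-band based: ranks where the observed order
statistic departs from the permutation-expected one by more than delta,
beyond the first crossing. A called metabolite's per-feature q can
therefore marginally exceed the target FDR — this is inherent to band
calling and is reported transparently in the consensus table.

The FDR attached to a delta is `pi0 ×` (mean permutation false count) `/`
(number called), with `pi0` from the quartile rule. Two design points
deserve emphasis, both driven by measurement rather than convention:

* *Mean, not median, false counts.* With a few hundred features and a few
  hundred permutations, the median count beyond the cutoffs is exactly 0
  whenever fewer than half the permutations put any value there, so a
  median-based curve collapses to 0 at the extreme tail and a smallest-
  delta search latches onto those dips: on effect-free 12 × 200 panels it
  made at least one false call in ~45% of simulations. The mean keeps the
  fractional information (it can never be 0 while anything is called,
  since the observed labelling is one of the enumerated splits).
* *Two counting schemes, take the worse.* Counts beyond the observed
  cutoffs are the classic estimator but are selection-biased exactly
  where the delta search looks; counts beyond cutoffs recomputed within
  each permutation by the same cut rule are self-calibrating under label
  exchangeability. The working FDR is the maximum of the two, and the
  delta search walks the suffix maximum of that curve, which makes
  target → delta monotone. Measured on 200 effect-free panels this brings
  the probability of any false call at target 0.05 down to ≈ 0.045
  without costing sensitivity (planted effects at FC 3 are still fully
  recovered).

**PLS-DA.** PLS1 NIPALS against the centred class code (control −1,
treated +1), five components by default, deflating X per component. VIP
uses the Y-variance-weighted squared weights; the mean squared VIP is 1
by construction and is asserted after every fit. The gate "VIP > 1.0
across all five components" is read as the five-component cumulative VIP
(per-component VIPs are reported alongside, and the consensus table
prints the component-1 VIP, the convention of published tables). The
permutation test (default 2000 repeats) uses the between/within
separation of component-1 scores, refit under each relabelling so that
the overfitting of a 12 × 200 projection is priced into the null;
relabellings identical to the observed one (or its swap) are redrawn
because the `(1 + exceed)/(1 + B)` rule already accounts for the observed
configuration — the p-value floor is exactly `1/(B+1)`. LOOCV reports
both Q² = 1 − PRESS/TSS on the class code and hold-out classification
accuracy, since "predictive power" in the field is sometimes one and
sometimes the other.

**Random forest.** 500 CART trees on bootstrap resamples, √p candidate
features per split, grown to purity (the `randomForest` implementation).
Importance is the raw out-of-bag mean decrease in accuracy, unscaled by
its standard error — the magnitudes (10⁻⁴–10⁻²) of published MDA columns
match raw per-tree averages, not the studentised score. The gate is the
strict MDA > 0; a constant feature has MDA exactly 0 and is excluded.
One permutation per tree per feature (the classic estimator) is used.

## Consensus

`build_consensus()` requires the four models to share one metabolite
universe and intersects their calls; all comparisons are strict
inequalities. The overlap report emits per-method totals and the full
sixteen-cell membership lattice. Removing a gate can only grow the
consensus; the consensus is by construction a subset of every method's
list, and its sensitivity is bounded by the weakest model — both
properties are asserted in the test suite rather than assumed.

## Pathway stage

Pathways are compound sets plus a directed compound graph (JSON schema;
KGML ingestion via `read_kgml()`). Name matching is case- and
punctuation-insensitive against IDs and synonyms, and unmatched names are
returned, never dropped silently.

* **Percent affected** = `100 · hits / size`, 1 d.p. By default `size` is
  the pathway's library size regardless of how many members were
  measured, matching the denominators of published tables; a
  measured-only denominator is available (`size_from = "measured"`).
* **Global Test** is the Goeman score statistic on the pathway's measured
  member columns with a label-permutation p-value (`(1+exceed)/(1+B)`),
  chosen over the asymptotic distribution because n = 6 per group is far
  from asymptotia. For a single-member pathway it reduces to the
  permutation test of the squared mean difference for that metabolite,
  which the tests exploit as an independent oracle.
* **Impact** is the fraction of out-degree centrality (normalized to sum
  to 1 over the pathway) carried by the hit compounds; an edgeless
  pathway falls back to uniform importance. Published impact values from
  dated KEGG topologies are not reproducible without that topology, so
  impact is validated on hand-checkable fixtures (a three-compound chain
  with hits at the head has impact 0.5).
* Filters: `full` mode keeps FDR < 0.05 AND impact > 0.25 AND percent
  affected > 20 (all strict); `fdr` mode keeps FDR < 0.05; the unfiltered
  table is always retained.
* **Super-pathway heatmap matrix**: per super-pathway class and
  condition, the mean |log2 FC| over measured member metabolites (the
  aggregation statistic is pluggable), ordered by Ward (`ward.D2`)
  clustering on Euclidean distance.

## Synthetic data generator

`sim_config()` defaults describe the design the package targets: 296
metabolites, 6 replicates per group, baseline natural-log means uniform
on [log 10³, log 10⁷] (relative LC-MS/MS intensities span several
decades), within-group log-SD 0.2, 10% of metabolites differential with
fold changes in [1.25, 4] and random direction, cell-count CV 0.1, and
abundance-biased missingness at an overall per-cell rate of 0.04. The
biased mode masks cells with probability logistic in log abundance
(slope 1.5 per log unit), with the intercept calibrated by root-finding
so the realized overall rate matches the configured one; at 12 samples
this leaves roughly 78–83% of metabolites fully observed, the retention
range reported for panels of this design. None of the variance defaults
are published values; they were chosen once as plausible for this assay
class and are not tuned.

What the generator does **not** emulate: correlated metabolite blocks,
batch or injection-order drift, heteroscedastic peak-integration error,
isotope interference. Passing tests on this generator therefore
demonstrate correctness of the statistical machinery under a clean
log-normal world, not robustness to every real-data pathology.

## Numerical and degenerate-input choices

* Permutation p-values are never 0 (`+1` smoothing); permutation budgets
  below 50 (SAM) warn and below 100 (PLS-DA) error.
* The SAM delta grid steps by 0.01 from 0 to the largest band departure;
  delta ≤ 0 is the degenerate zero-width band where everything is called
  and the FDR estimate equals pi0.
* NIPALS stops early at rank exhaustion (zero-norm weight or score) and
  warns when asked for more components than the data support.
* An empty call set reports SAM FDR 0; an all-constant matrix, an
  all-missing panel, a zero control mean, and a hit outside its pathway
  are errors that name the offending metabolites.
* Simulation, SAM label sampling, forest bootstraps and permutation tests
  are all seeded; identical configs give identical output, which the
  pipeline test asserts byte-for-byte on the written tables.

## Problem sizes used by the checks

The distributional checks run at the sizes the package documents as its
reference conditions: 500 effect-free panels of 12 × 200 for the null
false-discovery proportions of BH and SAM, and 100 seeds of 20 planted
effects at FC 3 among 200 metabolites for consensus recovery (median
recovery and per-method empirical FDR). `scripts/acceptance.R` recomputes
all of them from scratch with a caller-supplied seed.

## Known limitations

* No imputation, by design: low-abundance information is discarded with
  the incomplete metabolites, and the completeness filter can be harsh
  when missingness is heavy.
* SAM's delta-band calling and permutation FDR are estimates, not
  guarantees; with n = 6 per group the permutation space (462 balanced
  splits) bounds how fine the tail can be resolved.
* The random-forest stage inherits `randomForest`'s determinism-per-seed
  but not bit-stability across library versions.
* Pathway impact depends entirely on the supplied topology; with real
  KEGG data, results will vary with the library's version and species.
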