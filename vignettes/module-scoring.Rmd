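---
title: "Injury-module activation scoring: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Injury-module activation scoring: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toxmod)
```

## The model

`toxmod` quantifies the activation of curated gene-set *injury modules* from
control/treatment expression data collected under a grid of (platform, dose,
time) conditions — the typical layout of a toxicogenomic exposure study with
an in vivo arm and an in vitro (cell culture) arm.

**Fold change.** All statistics operate on log2-transformed expression. The
per-gene log2 fold change of a condition is the difference between the mean
log2 expression of the treated cohort and that of its matched control cohort
(the control cohort of the same platform and exposure time). This
mean-difference definition is unbiased for the true log2 shift whenever the
within-cohort noise is additive on the log scale, which is exactly what the
bundled generator simulates.

**Differential expression.** Per-gene significance comes from a two-sided
Welch unequal-variance t-test on the log2 values. This is a deliberate,
declared substitution for quantifier-specific variance models
(bootstrap-based transcript-abundance pipelines): the only downstream use of
the per-gene p-values is the FDR cut, and the test sits behind a single
function (`de_test()`) so it can be swapped without touching anything else.
Genes with zero variance in both cohorts and equal means receive p = 1; a
nonzero mean difference with zero variance receives p = 0. Benjamini–Hochberg
adjustment (`bh_adjust()`, delegating to `stats::p.adjust`) yields q-values,
and a gene is a DEG when **q ≤ 0.1** (inclusive; ties at the boundary are
counted in).

**Module scores.** A module matched to the profile (case-insensitive
identifier intersection) is scored two ways:

- `aafc_score()` — the *aggregated absolute fold change*: the mean of
  |log2 FC| over the matched genes. Direction-blind; it measures how much the
  module's genes move. The mean (rather than the sum) is used so scores are
  comparable across module sizes; because every null subset has exactly the
  module's size, mean and sum differ by a constant factor and give identical
  z-scores.
- `afc_score()` — the *aggregate fold change*: the mean of signed log2 FC.
  Its sign carries net direction (positive = net upregulation), which is what
  directional pathway readouts need. For any input |AFC| ≤ AAFC.

**Permutation null and activation.** The null distribution of a module score
is generated by drawing `n_resamples` (default 10,000) gene subsets of
exactly the matched size, without replacement, from the profile's measured
genes, and scoring each subset with the same statistic. The activation score
is `z = (score − null mean) / null sd`, and a module is called **activated
when z > 2**. An empirical p-value accompanies z: for AAFC the upper tail
(only excess magnitude is interesting), for AFC two-sided around the null
mean (up- and downregulation are both meaningful). Monte-Carlo p-values use
the standard (r + 1)/(N + 1) correction so p is never exactly 0, and ties
count toward the tail (conservative).

## Tunable parameters

| parameter | default | units / meaning |
|---|---|---|
| `q_threshold` | 0.1 | FDR level for DEG calls (inclusive) |
| `activation_threshold` / `z_threshold` | 2.0 | null sds above the mean for an activation call |
| `n_resamples` | 10,000 | permutation draws per (module, condition) cell; ≥ 100 enforced |
| `pseudocount` | 1.0 | added before log2 when transforming raw abundances |
| `statistic` | `"aafc"` | `"aafc"` (magnitude) or `"afc"` (directional) |
| `exhaustive_limit` | 200,000 | subset-count ceiling below which the null is enumerated exactly |
| `seed` | — | single top-level seed; every cell derives its own child stream |

The 0.1/2.0/10,000 triple reflects common practice for this family of
gene-set activation analyses; all three are plain arguments.

## Numerical choices

- **Exhaustive small-instance oracle.** When `choose(m, k)` ≤ 200,000 (and
  `mode = "auto"`), `permutation_null()` enumerates every subset instead of
  sampling. The exhaustive null is the entire subset population, so its sd
  uses the population denominator n; Monte-Carlo draws estimate that sd with
  the usual n − 1. Exhaustive tails are exact fractions (no +1 correction).
- **Degenerate nulls.** A constant profile, or a module spanning the whole
  universe, gives null sd = 0; z and p are reported as `NA` with a warning
  and `activated = FALSE` — never a division by zero.
- **Reproducibility.** `module_activation()` derives a deterministic child
  seed per (module, condition) from the top-level seed via a string hash, so
  the table's cells do not depend on evaluation order and two runs with the
  same seed are bit-identical. All generator randomness is likewise seeded,
  and library code restores the caller's RNG state.
- **Identifiers.** Gene identifiers are opaque, case-folded strings; no
  ortholog mapping is attempted (cross-species comparisons operate on
  module-score vectors, not genes).
- **Missing data.** Genes with fewer than two usable values in either cohort
  are dropped per condition, with a warning and a count — no imputation.
- **PCA.** `pca_embed()` centers columns, does not scale, and fixes signs by
  making each component's largest-magnitude loading positive. Fold-change
  PCAs take the conditions as items and the common genes as features.
- **Silhouette.** `cluster_separation_check()` quantifies the visual
  "clusters separate" claim as the mean silhouette over the first two PCs;
  singleton groups take silhouette 0 by convention and raise a flag.
- **ORA.** `ora_test()` is the plain upper-tail hypergeometric test. Some
  web enrichment tools apply an EASE-style correction (subtracting 1 from
  the hit count), so their printed p-values will differ slightly; the plain
  test is the textbook choice and exactly matches tail enumeration.

## What the synthetic generator emulates — and what it does not

`simulate_experiment()` reproduces the *design* of a two-platform exposure
study: 2 platforms × 2 doses × 2 exposure times, small cohorts (n = 3 per
cohort by default, configurable), a ~10⁴-gene universe, and a minority of
genes perturbed with dose- and time-dependent effect sizes concentrated in
designated modules. Gene baselines are Gaussian on the log2 scale
(mean 6, sd 2); within-cohort noise is i.i.d. Gaussian (sd 0.5 log2 units);
planted shifts are deterministic per gene
(`effect_log2 × dose multiplier × time multiplier`), so the simulation truth
is exact and the expected fold change of a planted gene equals its planted
shift. Dose multipliers default to 1 (low) and 1.5 (high), time multipliers
likewise 1 and 1.5 — encoding the qualitative dose- and time-escalation seen
in such studies. A fraction `direction_mix` (default 0.8) of each planted
module's genes move up, the rest down, reflecting the predominance of
upregulation among top responding genes. An optional negative-binomial count
mode (`noise_model = "negbin"`) adds mean–variance coupling.

The generator does **not** emulate: library-size or composition effects,
gene–gene correlation beyond the planted modules, heavy-tailed or
outlier-prone noise, transcript-level uncertainty, batch structure, or any
dose–response saturation. Tests passing on synthetic data therefore
demonstrate the statistical machinery (calibration, recovery, monotonicity,
determinism) under the stated noise model — they do not certify performance
on real sequencing data, where variance estimation is harder and nulls are
not exchangeable.

## Design choices where the design was open

- **AAFC aggregation = mean.** Sum and mean give identical z (the null
  matches the module size exactly); the mean keeps scores comparable across
  module sizes in reports.
- **Null = gene subsets without replacement**, redrawn independently per
  module and per condition: the most literal reading of "randomly selected
  fold-change values", and it preserves the finite-universe structure.
- **AFC significance two-sided, AAFC upper-tailed** (see above).
- **DEG threshold inclusive (q ≤ 0.1).** The boundary only matters at exact
  ties; inclusivity is recorded here once and applied everywhere.
- **Common-gene core = strict all-set intersection.** Intersecting the union
  of per-platform sets instead would be laxer; the strict core is what the
  downstream ranking and PCA consume, and it is idempotent and
  order-independent.
- **Controls are per (platform, time).** Treated cohorts at both doses share
  the control cohort of their platform/time stratum, as exposure studies
  normally do.
- **CLI as a thin wrapper.** `exec/toxmod` parses flags and calls the same
  exported functions; `run_pipeline()` is the tested programmatic surface and
  writes a JSON manifest (config echo, input/output checksums, warnings) so a
  run can be reproduced bit-for-bit.

## Problem sizes used by the test and acceptance suites

Simulated checks use universes of 2,000–5,000 genes (5,000 for calibration
checks, 2,000 for the 100-replicate recovery study, 3,000 with six planted
50-gene modules for the dose-monotonicity study), chosen as the smallest
sizes at which the binomial/CLT bands in those checks are meaningful. The
dose-response simulations plant `effect_log2 = 2` — the same planted-effect
size as the recovery study; at n = 3 and noise 0.5 this sits at moderate
power for the low dose and high power for the high dose, so DEG counts and
module z-scores order by dose in nearly every replicate.

## Known limitations

- The Welch test at n = 3 per cohort has few degrees of freedom; its
  p-values are calibrated under Gaussian noise (the KS check) but will be
  anti-conservative under heavy tails.
- Module scores share one profile, so scores of overlapping modules are
  correlated; the per-module nulls do not model that correlation.
- `afc`/`aafc` z-scores are comparable across conditions only insofar as the
  profiles' fold-change scales are; no cross-condition standardization is
  applied.
- No ortholog mapping: cross-species comparisons require score vectors over
  a shared module vocabulary.
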