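---
title: "Methods: per-layer marker quantification and prognostic statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: per-layer marker quantification and prognostic statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(layerquant)
```

# Overview

`layerquant` implements the quantitative backbone of a 3-D tissue-imaging
prognosis workflow for a secreted protease-inhibitor marker (elafin/PI3) in
esophageal squamous cell carcinoma, organised in five analysis stages plus a
synthetic-data module that makes every stage testable without external data:

1. **Stack quantification** — a 3-channel confocal z-stack (marker, cell
   membrane, nuclei) is reduced to a per-layer *relative marker intensity*:
   the count of marker-positive pixels divided by the count of
   membrane-positive pixels in the same layer.
2. **Paired layer statistics** — two subjects' layer profiles are compared
   with an exact paired sign-flip permutation test on dichotomized,
   clustered layer scores.
3. **Survival cutpoint scan** — a continuous expression biomarker is
   dichotomized at the cutoff maximising Youden's index, with
   covariate-adjusted Cox model fits and Kaplan–Meier/log-rank comparisons.
4. **Paired score comparison** — tumour vs normal ordinal
   immunohistochemistry scores, paired and unpaired.
5. **Concordance filter** — genes moving in opposite directions across an
   overexpression and a knockdown contrast.

# The relative-intensity statistic

Acquisition geometry follows the source protocol: square fields of
512 pixels spanning 317.95 µm (so `pixel_size = 317.95/512` µm) and a z-step
of 0.7 µm. A stack of $n$ layers therefore spans $0.7n$ µm; 199 layers are
139.3 µm of tissue.

Per layer $z$ and channel $c$, preprocessing is (i) background subtraction
(per-layer percentile, default the 20th, or a constant) with clamping at
zero, and (ii) an optional per-layer 2-D median filter (default window
3×3; window 1 disables it). Pixels are counted as positive when strictly
above a per-channel threshold (default 0 after preprocessing), and

$$ r_z = \frac{\#\{\text{marker pixels}\}_z}{\#\{\text{membrane pixels}\}_z}. $$

Layers with no membrane-positive pixels have no defined ratio; they are
flagged and excluded from selection and clustering rather than treated as
zeros. Layer selection keeps the longest contiguous run with $r_z$ strictly
above the weak-signal cutoff 0.01, reproducing the reported single
contiguous ranges (e.g. layers 13–60 → 48 layers → 33.6 µm); an option
returns all supra-cutoff layers instead. Whether counting should use the
raw or the fully preprocessed image is not specified by the source
procedure; this package counts on the fully preprocessed image.

The sum z-projection adds intensities across layers per channel and is
integer-exact, so the total projected intensity equals the total stack
intensity — a conservation law the tests assert literally.

# The exact paired sign-flip permutation test

The defined layers of each subject are partitioned in z-order into $K = 20$
contiguous clusters of near-equal size (the first $N \bmod K$ clusters get
one extra layer; 200 layers give 20 clusters of 10). Each layer is
dichotomized at 0.05 and the cluster score is the *proportion* of
supra-cutoff layers in the cluster, kept as an exact count/size pair. The
proportion convention is the only score definition under which the
fractional observed mean differences reported for the two tissue pairs
(0.160, 0.195) are attainable with $K = 20$.

With paired scores $a_i, b_i$ and differences $d_i = a_i - b_i$, the test
enumerates all $2^K$ sign vectors $s \in \{\pm 1\}^K$ (swapping the two
subjects within a cluster negates that cluster's difference) and computes
$T_s = \tfrac1K \sum_i s_i d_i$. For exact tie detection every $d_i$ is
scaled by the least common multiple of all cluster sizes, making each $T_s$
an integer multiple of a common unit; floating-point equality never decides
a tie. For $K = 20$ this is exactly 1,048,576 reallocations; enumeration is
refused above $K = 24$ in favour of the Monte-Carlo variant, which samples
sign vectors uniformly, pools the observed statistic, and reports a
binomial standard error.

**Tie convention.** The observed statistic's tie block, starting at
ascending rank $r$ with $t$ members, is assigned the midpoint of its tied
ranks, $r + (t-1)/2$, and the upper-tail p-value is

$$ p = 1 - \frac{r + (t-1)/2}{2^K}. $$

This is the standard midrank and the form implemented everywhere in the
package. It is the unique convention that simultaneously (a) keeps
$p \in [0, 1)$ for every configuration (a "plus half the tie count"
variant goes negative when the observed value is the unique maximum),
(b) satisfies the exact anti-symmetry identity
$p(a,b) + p(b,a) = 1 - 2^{-K}$, and (c) gives the all-tied degenerate case
$p = 1/2 - 2^{-(K+1)}$. With the reported tie-block ranks of the two tissue
pairs it reproduces the published p-values at their printed precision:

```{r worked}
round(midpoint_tie_pvalue(983041, 65536, 2^20), 2)
round(midpoint_tie_pvalue(1015809, 32768, 2^20), 3)
```

The test is reported upper-tailed (the direction of the worked examples)
with a two-sided companion (twice the smaller tail, capped at 1), since the
source analysis declares two-sided testing without printing a two-sided
formula; neither intent is guessed, both numbers are returned.

Under exchangeable nulls the midrank p-value is essentially calibrated; the
test suite measures the rejection rate at the 0.05 level over 2,500
simulated null series and asserts it stays below 0.06.

# Survival cutpoint scan

Candidate cutoffs are midpoints between consecutive sorted unique
expression values; cutoffs leaving either group under 10% of the cohort are
inadmissible. For each admissible cutoff, Youden's index
$J = \text{sensitivity} + \text{specificity} - 1$ is computed with the
dichotomized expression as classifier and **vital status at last
follow-up** as the binary outcome — the most literal reading of the source
procedure, which does not define sensitivity for a censored outcome. A
censoring-aware variant (status at a fixed horizon, subjects censored
earlier excluded) is available via `outcome = "horizon"`. The
covariate-adjusted Cox model (`survival::coxph`, Efron ties, adjusting age,
sex, smoking, alcohol) supplies the group log hazard ratio and Wald p-value;
non-converged fits are flagged and excluded from selection. The selected
cutoff maximises $J$, ties broken towards the smaller cutoff.

A caution the package documents rather than hides: the p-value at the
*selected* cutoff inherits the optimism of maximum selection and is
anti-conservative under the null. One test measures this directly (null
tables, rejection rate at the selected cutoff well above the nominal 5%).

# What the generators emulate

All generators are deterministic functions of their seed.

* `simulate_stack()` builds tumour nests as random spheres (radius 6
  voxels, filling ~25% of the volume by default) and draws the marker
  either as random-walk filaments dilated to ~2 voxels and restricted to
  the stroma ("stromal-web", the interweaved fibrous phenotype) or as
  Bernoulli voxels inside nests ("nest-confined"). The membrane channel
  covers the whole field, matching a lipophilic membrane dye; nuclei are
  sparse spots. Intensities are 150 grey levels plus optional Gaussian
  noise, clamped at zero and rounded (16-bit range). Ground truth is the
  *realised* mask, so noise-free quantification must match it exactly —
  and the tests assert identity, not approximation. Not emulated:
  point-spread functions, optical-clearing physics, photorealism.
* `simulate_layer_profiles()` draws each layer's ratio so the probability
  of lying at/above the dichotomization cutoff is exactly the requested
  fraction — the quantity the permutation test responds to.
* `simulate_survival_table()` draws expression from a two-component
  mixture ±4 units around the planted cutoff (sd 2.5), rounded to integer
  units as expression is typically reported. The separation is a
  deliberate identifiability choice: a planted hazard step is only
  recoverable as a *specific* cutpoint when the data do not pack subjects
  arbitrarily close to it on both sides. Survival is exponential with the
  hazard multiplied by `hazard_ratio` above the cutoff and log-linear
  covariate effects (age ~ N(58, 8) centred in the linear predictor;
  binary sex/smoking/alcohol with prevalences 0.8/0.6/0.6; default log
  hazards 0.02/0.2/0.3/0.2 — modest, realistic epidemiological effect
  sizes). Censoring is an independent exponential whose single global rate
  is solved so the expected censored fraction equals `censor_rate`; a
  per-subject censoring rate proportional to the subject's own hazard
  would make the event indicator independent of the biomarker group and is
  exactly the wrong null to build in.
* `simulate_de_tables()` plants an exact number of concordant genes
  (strictly above threshold in the "up" contrast and strictly below the
  negated threshold in the "down" contrast); every other gene violates at
  least one condition.

Passing tests on these generators show the pipeline recovers what it is
pointed at under known, favourable conditions; they do not certify
performance on real tissue, where background structure, optical artefacts
and non-exponential hazards all intrude.

# Numerical choices and degenerate inputs

* Exact integer arithmetic for permutation ties (LCM scaling); sums stay
  far below the 2^53 double-integer limit for any realistic cluster sizes.
* Zero-membrane layers: flagged undefined, dropped before clustering,
  cluster sizes rebalanced on the remaining layers.
* Zero-variance paired scores: reported as `p = 1` with a `zero_variance`
  flag instead of failing, so degenerate synthetic inputs cannot crash a
  pipeline run.
* Empty layer selection (nothing above cutoff): returned as an explicit
  empty selection with zero thickness, not an error.
* Cutoff-scan ties in $J$: smaller cutoff wins, making selection
  deterministic.
* The strict `>`/`<` reading of the fold-change threshold is the default;
  `strict = FALSE` switches to `>=`/`<=`.
* Reported layer ranges are 1-based inclusive; thickness is
  `count x z_step`. One published selection row (64 layers printed as
  45.5 µm, which implies 65) is inconsistent with the other three rows
  under any single convention and is documented here as an inconsistency
  rather than emulated.

# Problem sizes used by the test-suite experiments

The suite's simulation studies use: 2,500 null series for permutation
calibration; 100 seeds of 32×32×200 stacks (three per seed) for the
pattern-separation study; 100 seeds of n = 400 cohorts for cutpoint
recovery. These sizes give Monte-Carlo standard errors comfortably inside
the asserted margins while keeping a full test run in a few minutes.
Noise-free stacks in the recovery tests are quantified with preprocessing
disabled (no background, window 1): the synthetic stacks have no background
to remove, and exact mask recovery is the property under test. The median
filter and percentile background subtraction are validated separately
against brute-force per-pixel oracles.

# Known limitations

* The filament generator controls marker density only approximately (it
  stops adding filaments once the target voxel count is reached); ground
  truth uses the realised mask, so downstream exactness is unaffected.
* The Youden outcome ignores censoring by default (the literal reading);
  use the horizon variant when follow-up is short relative to the hazard.
* The permutation test treats clusters as exchangeable units and models no
  spatial autocorrelation between neighbouring clusters.
* `run_pipeline()` is a synthetic-data demonstration harness; point the
  stage functions at real profile/survival CSVs for actual analyses.
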