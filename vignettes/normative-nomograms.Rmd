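---
title: "Model-free normative nomograms for hippocampal volume: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-free normative nomograms for hippocampal volume: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Hippocampal volume measured on structural MRI is a widely used marker of
neurodegeneration, but a single measurement is uninterpretable without an
age- and sex-matched reference distribution. `hippnorm` builds such
references — nomograms of quantile curves over age — from participant-level
tables of image-derived phenotypes (IDPs: scalar volumes in mm³ produced by
an automated segmentation pipeline), and provides the companion analyses:
confound correction, trajectory-inflection detection, sex-difference
testing, and a percentile lookup that ranks an individual against the
reference population.

Everything is deliberately model-free where the science is uncertain: the
age trend is estimated by sliding windows rather than a parametric curve,
because imposing linearity (or any fixed functional form) is precisely what
the trajectory analyses are designed to interrogate.

## Pipeline and models

### Outlier exclusion

Volumes are screened per region with a median-absolute-deviation distance,
`|x − median| / MAD`, and excluded above a cutoff of 5. Two conventions are
fixed and documented rather than argued:

* the MAD is **unscaled** (no 1.4826 Gaussian-consistency factor); the
  cutoff was historically chosen by inspection against this raw-MAD
  convention, so changing the scaling would silently change the cutoff.
  `mad_filter(scale_factor = 1.4826)` restores the consistent estimator.
* masking is **per region**, so different regions may retain different row
  sets — left and right hippocampus legitimately lose different outliers.

A zero MAD (over half the values identical) leaves everything included,
with a warning, since the distance is then undefined.

### Confound regression

Nuisance effects are removed by subtracting fitted ordinary-least-squares
slopes, `corrected = v − Σ_c b_c (x_c − ref_c)`, never by forming ratios:
regional volumes do not all scale proportionately with head size, so a
ratio correction distorts small structures. Available confounds:

* `scan_date` — linear scanner drift (hardware ageing biases volume
  estimates over a multi-year acquisition window);
* `head_scaling` — the volumetric scaling of the native head image to
  standard space, inversely related to head size. Its reference value
  defaults to 1.29874, the population constant of the published correction
  table, so that correction is neutral exactly there;
* `age` — used only for analyses (e.g. lifestyle covariates) that must not
  be confounded by the age trend; never for the nomograms themselves,
  whose whole point is the age dependence.

Other confounds default their reference to the sample mean, which makes the
correction mean-preserving. By construction the corrected volumes are
orthogonal to every fitted confound (|r| < 1e−10 on the fitting set), and
applying a model at all-reference inputs is the identity.

### Sliding-window quantile curves

Observations are sorted by age; each window holds a fixed **fraction**
(default 0.10) of participants and advances by **step** sorted observations
(default 1, i.e. maximal overlap — the step is a free choice since only the
overlap and width are scientifically constrained). Within each window the
nine levels 2.5, 5, 10, 25, 50, 75, 90, 95, 97.5 are computed as type-7
quantiles (linear interpolation between order statistics — the convention
must be pinned because the reference analysis does not state one). The
x-coordinate of a window is the **median age of its members**; in an
age-peaked cohort the extreme windows must reach across sparse tails, so
the plotted age span contracts at both ends — an emergent property, not a
hard-coded cut.

Curves are then smoothed with a Gaussian moving average of SD 20 **window
steps** (kernel truncated at ±3 SD, weights renormalised where the support
is clipped at the boundaries; no padding). Because all curves on a grid
share the same positive weights, smoothing preserves the pointwise ordering
of the quantile levels: curves never cross, before or after smoothing.
`kernel_sd = 0` and `kernel_sd = 10` variants reproduce the usual
robustness checks.

Two conventions worth knowing:

* window means and medians are exactly invariant under duplicating every
  observation; the other interpolated quantile levels are only
  asymptotically so (a property of type-7 interpolation, not of the
  windowing);
* flat (tied) curves report their peak at the youngest window, with a
  relative 1e−9 near-tie band so floating-point jitter cannot move a tie.

The age-adjusted percentile table removes the age trend by subtracting the
(raw, unsmoothed) window-mean curve interpolated at each participant's age
and adding the residual back onto the grand mean; interpolating against the
smoothed curve is available as a switch. Ages outside the window grid use
the nearest edge value and are flagged.

### Ratio trajectories and the permutation peak test

A region's ratio to the rest of grey matter, `V / (GM − V)`, rises while
the region declines more slowly than the remaining grey matter and falls
once its decline accelerates past it; the age of the smoothed ratio curve's
maximum marks that transition. The sex difference in peak age is tested by
permutation: sex labels are shuffled **within 1-year age bins** (so each
permuted group keeps the exact age composition of the original), both
curves and their peaks are fully recomputed per permutation — including the
windowing and smoothing, the conservative choice — and the two-sided
p-value is `(1 + #{|null| ≥ |obs|}) / (n_perm + 1)`. The add-one form
avoids p = 0 at finite n; the raw proportion is available with
`add_one = FALSE`. Across regions, p-values are Benjamini–Hochberg
adjusted. For exchangeability, the deconfounding inside the test is fitted
on the pooled cohort rather than per sex.

Numerical slopes of any windowed curve use central differences on the
median-age grid (one-sided at the ends, duplicate grid ages collapsed by
averaging), with an optional participant-level bootstrap for pointwise
percentile bands; the window of most negative slope is the trajectory's
inflection.

### Joinpoint regression

Mean deconfounded volume per 1-year age bin is modelled as continuous
piecewise-linear (hinge basis `1, x, (x − τ_j)+`). Joinpoints live on the
bin grid and are found by exhaustive search under the standard spacing
rules: no joinpoint within two data points of either end, at least two
data points between joinpoints, and at most one joinpoint per seven data
points (capped at 4). The number of joinpoints is chosen sequentially:
k vs k+1 is tested on the RSS ratio, with the null built by permuting the
k-model's residuals and refitting **both** models by full grid search per
permutation (the residual-permutation scheme; n_perm defaults to 999). The
ladder tests each step at `alpha / k_max` — a Bonferroni convention over
the selection sequence, mirroring the standard software default rather
than any claim of the reference analysis.

Conditional on the selected joinpoint positions, each slope change Δm gets
an OLS standard error, a t statistic on `n_bins − 2(k+1)` degrees of
freedom, and a two-sided p. Joinpoint age intervals are inverted from an
F-comparison: a candidate bin is inside the interval when its constrained
fit is not rejected against the grid optimum; for a noise-free break the
interval collapses to the true bin. Bins are unweighted by default (the
reference analysis does not mention weighting); `weighted = TRUE` weights
by bin counts.

The permutation refits are accelerated by precomputing thin-QR projectors
for every admissible placement, so each permutation costs one small matrix
product per model order; results are identical to naive refitting.

### Percentile lookup

Quantile curves are interpolated linearly between the two age-grid columns
flanking the query age (`age_method = "nearest"` switches to the
nearest-window alternative); the percentile is then linear in volume
between the flanking level curves. Below the 2.5th or above the 97.5th
curve the lookup reports `"<2.5"` / `">97.5"` instead of extrapolating into
tails the nomogram never estimated — a clinical-safety choice. Ages outside
the smoothed grid clamp to the nearest column and the answer is flagged
`extrapolated`. Volumes may be entered in cm³ (`unit = "cm3"`); head-size
correction can be applied on the fly from the nomogram's own fitted slope,
and requesting it against a nomogram that was not head-size corrected is an
error, never silent.

`self_percentile_audit()` checks calibration: held-out members of the same
population should receive percentiles uniform on (2.5, 97.5) outside the
censored tails, which is tested by Kolmogorov–Smirnov. One subtlety: with
only the nine display levels, linear interpolation between adjacent curves
carries ~1.5 percentile points of granularity, which a KS test at n ≈ 5000
will flag even when the pipeline is perfectly calibrated. Calibration
checks therefore audit against a finely graduated chart
(`levels = seq(2.5, 97.5, by = 2.5)`); the 9-level chart is a display
resolution, not a calibration property.

## The synthetic cohort generator

UK-scale population imaging data are access-controlled, so the package
ships a generator that emulates their statistical structure and makes every
stage testable end to end. Per region and sex,

```
volume = baseline + age effect + head-scaling effect + drift
         + covariate shifts + noise,
```

with all systematic terms mean-centred within sex. Two calibration choices
anchor the generator to published summary statistics:

* `baseline` is the sex-specific cohort mean and `sd` the marginal SD
  (defaults: female average hippocampus 3765.18 ± 366.75 mm³, male
  3972.97 ± 431.03 mm³, total grey matter 594,250 ± 48,028 /
  641,307 ± 51,379 mm³, 10,463 / 9,330 participants). The Gaussian noise
  SD is set to `sqrt(sd² − var(systematic part))`, so the marginal SD
  matches the target by construction;
* standardized covariate effects (hypertension, smoking, education on the
  Hedges' g scale; BMI on the Pearson r scale) are scaled by the residual
  SD after confound correction, because that is the scale on which such
  effects are reported.

Age trajectories are continuous hinges: slope `pre_slope` before
`change_age`, plus `slope_change` after. Defaults place the female
bilateral hippocampal hinge at 64.5 years with Δm = −32.44 mm³/yr and the
male hinge at 63.5 with Δm = −26.45, and give total grey matter an earlier,
larger hinge per sex. The unprinted pre-slopes were chosen once so that the
rest-of-grey-matter relative decline lies between the hippocampal pre- and
post-hinge relative declines — this makes the hippocampus-to-rest-of-GM
ratio peak at the hinge age, reproducing the qualitative geometry of the
reference trajectories. Ages follow a triangular density on 45–80 peaking
at 64 (fewer participants at the age limits; the true empirical density is
not public, so this is a stand-in, not a claim). Head scaling is
Normal(1.29874, 0.1) with a small sex offset (males have larger heads,
hence lower scaling); its per-hemisphere regression slopes default to the
published −1340.89 / −1532.24 (hippocampus) and −354,545.84 (total grey
matter). Scanner drift is a *relative* volume change per scan-date day
(dimensionless; a single absolute mm³/day slope cannot fit structures four
orders of magnitude apart). A configurable fraction of rows (default 0.7%)
is displaced by ±8 SD, symmetrically so the median stays unbiased. All
randomness flows from one master seed through per-column streams, so
generation is bit-reproducible and adding a column never perturbs the
others.

What the generator does **not** emulate — and hence what passing tests do
not establish about real data: spatial correlation between neighbouring
regions beyond the left/right construction, non-Gaussian volume
distributions, age-varying variance, scanner software version changes,
site effects, longitudinal repeat scans, and any relationship between the
covariates themselves (BMI, smoking, hypertension are drawn
independently).

## Problem sizes and numerical choices

The test-suite simulations use scaled-down designs chosen to balance
statistical resolution against runtime: joinpoint recovery and null
calibration use 100 replicates of 35-bin series with Monte Carlo selection
at 99 permutations; permutation-test calibration uses 200 replicates of
700-per-sex cohorts at 199 permutations; the power check uses one
20,000-participant cohort under low-noise generator conditions (the
4-year peak separation is not resolvable at full Table-scale noise, where
peak localisation noise alone spans ±4–5 years). The bootstrap coverage
check runs 20 replicates at B = 40. Exact worked examples (effect sizes
from published group summaries) are asserted at the printed precision.

Degenerate inputs are handled explicitly: zero MAD (warn, keep), zero
kernel SD (identity), constant curves (tie to youngest window), empty
bins (dropped with a warning), missing confound values (flagged rows, not
dropped), perfect fits in model selection (stop the ladder), and zero
variance in effect sizes (g = 0 for equal means, error otherwise).

## Known limitations

* The sliding-window estimator is a description, not a generative model:
  it cannot extrapolate beyond the observed age span, and its effective
  age resolution degrades where the cohort is sparse.
* Joinpoint selection tends to find a joinpoint even under a smooth
  nonlinear transition; a selected k = 1 should be read as "a slope change
  around this age describes the trend well", not as evidence of a sharp
  break.
* The permutation peak test's power depends strongly on the curvature of
  the ratio curve near its peak; flat peaks give honest but wide nulls.
* Percentiles outside (2.5, 97.5) are censored by design; users needing
  extreme tails must rebuild nomograms with wider level sets.
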