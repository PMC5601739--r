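---
title: "Serum peptidome diagnostic panels: models, methods and design choices"
author: "pepdiag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Serum peptidome diagnostic panels: models, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepdiag)
```

## The problem

Low-molecular-weight serum peptides (the peptidome, roughly <= 10 kDa)
carry proteolytic fingerprints of disease. A standard discovery design for
a blood-based cancer classifier profiles sera by MALDI-TOF mass
spectrometry in two independent case-control cohorts: peaks are detected
and aligned across samples in a discovery cohort, candidate peaks are
screened univariately, a multivariate binary logistic panel is built by
stepwise selection, and the frozen panel is then applied, coefficients
unchanged, to an external validation cohort. `pepdiag` implements this
whole chain, together with a synthetic-cohort generator so that every
stage can be exercised and tested without instrument data.

This vignette records the models behind each stage, the tunable
parameters and their defaults, and the design decisions taken where the
conventional workflow leaves room.

## Spectral preprocessing

A raw spectrum is a pair of series $(m/z_i, y_i)$ on an acquisition grid
(default 1,000-10,000 Th). The chain runs in a fixed, logged order:

1. **Crop** to the acquisition range.
2. **Smooth**: centered moving average, default 5 points. Windows shrink
   at the spectrum edges rather than reflecting data, so no values are
   invented at the boundaries; the operator is linear.
3. **Baseline**: local maxima that are prominent above 3x the local
   robust noise (median absolute deviation, scaled) are "dominant"; the
   minimum between consecutive dominant maxima becomes a baseline anchor;
   windows (default 100 Th) without a dominant maximum contribute their
   minimum. Anchors are linearly interpolated, constant-extrapolated at
   the ends, and the baseline is subtracted with clamping at zero.
4. **Noise**: per half-overlapping 100 Th window, the robust scale
   $1.4826 \times \mathrm{MAD}$, interpolated to every grid point. The
   MAD is used because peaks contaminate any local window and a standard
   deviation would track them.
5. **TIC normalization**: every intensity is divided by the spectrum's
   total intensity, making intensities sum to one (idempotent). The
   local noise series is divided by the same factor, so signal-to-noise
   is unchanged by normalization.
6. **Peak detection**: strict local maxima (plateaus resolved to their
   leftmost point) with apex S/N at or above the cut-off (default 5.0,
   boundary included). The reported m/z is the intensity-weighted
   centroid over the contiguous region above half the apex.

Ordering detection after normalization is the conventional
serum-profiling choice; because S/N is invariant under the global
division, the order affects only the scale on which peak intensities are
reported (normalized scale here, recorded in the processing log).

## Alignment, peak matrix, presence filter

Peak lists are aligned by single-linkage gap clustering of the pooled
sorted centroids: a cluster breaks when the gap to the next peak exceeds
`tol_rel` (default 0.001, i.e. 0.1%) times the running cluster mean.
This respects a pairwise maximum-shift tolerance without imposing fixed
bin edges. Each sample contributes at most one member per cluster (the
most intense), the reference m/z is the member mean, and the
samples-by-peaks matrix encodes absent peaks as intensity 0 rather than
missing — group averages then reflect zero-filled absences and the
logistic stage needs no imputation. Reference peaks present in at least
50% of samples (boundary included) survive the presence filter.

## Univariate screening

For each reference peak the two groups are compared with a
Shapiro-Wilk-gated test: Student's pooled-variance $t$ if **both**
groups pass normality at $\alpha = 0.05$ (the stricter both-groups
reading), otherwise the Mann-Whitney U-test. The Mann-Whitney
implementation counts exceeding pairs with half credit for ties; for
$n_1 + n_2 \le 12$ the two-tailed P-value is exact from the full
permutation distribution (twice the smaller tail, capped at 1), and
otherwise a tie-corrected normal approximation without continuity
correction is used. Per-peak discrimination is summarized by the
rank-based ROC AUC, which satisfies the exact identity
$\mathrm{AUC} = U / (n_1 n_2)$, with a Hanley-McNeil 95% interval.
Screening keeps peaks with $P < 0.05$ without multiple-testing
adjustment, matching the conventional candidate-selection practice in
this literature; a Benjamini-Hochberg option exists but is off by
default. Demographic comparisons use the same pooled $t$ (which also
accepts summary statistics) and the uncorrected Pearson chi-square for
2x2 tables.

## The stepwise logistic panel

`fit_panel()` is the package's central fitting function. The logistic
likelihood is maximized by iteratively reweighted least squares on
internally standardized columns (coefficients are returned on the
original scale), declaring convergence when the largest score component
falls below $10^{-8}$, and raising an explicit error when a
standardized coefficient diverges past 20 — the practical signature of
perfect separation. Selection is forward by likelihood-ratio test
(enter when the smallest candidate P is below `p_enter`, default 0.05;
ties broken by ascending m/z) with backward Wald elimination after each
entry (remove while the worst included P exceeds `p_remove`, default
0.10, refitting after each removal). This LRT-in/Wald-out combination
approximates the stepwise behaviour of mainstream commercial statistics
packages, whose defaults these thresholds mirror. The procedure is
deterministic and a visited-set guard rules out cycling.

Reporting follows the standard epidemiological shape:
$\mathrm{OR} = e^{\beta}$ with Wald interval
$e^{\beta \pm 1.96\,\mathrm{se}}$. Classification uses a probability
cutoff of 0.5, the common default when no cutoff is stated. Sensitivity
and specificity carry Wald binomial intervals
$\hat p \pm 1.96\sqrt{\hat p(1-\hat p)/n}$, clipped to $[0,1]$.
External validation never refits: panel peaks are matched to the
validation matrix by nearest reference m/z within 0.1% relative
tolerance, unmatched peaks contribute zero intensity (with a warning),
and the panel ROC AUC is computed on the validation probabilities.

Intensity units in serum profiling are arbitrary, and published
coefficient magnitudes imply that features are often rescaled before
regression in ways reports do not state; `fit_panel(scale = )` exposes
that rescaling explicitly rather than guessing one.

## The synthetic cohort generator

`generate_cohort()` draws each spectrum as

$$ y(m) = g \left[ \sum_{j \in \text{present}} h_j
  e^{-(m - c_j(1+\delta))^2 / 2\sigma_j^2}
  + A e^{-(m - m_{\min})/\tau} + \varepsilon(m) \right]_+ $$

with per-peak Bernoulli presence, log-normal apex heights $h_j$
parameterized by a class mean and coefficient of variation, Gaussian
point noise $\varepsilon$ (sd 10 by default), an exponentially decaying
baseline ($A = 200$, $\tau = 1500$ Th), a per-spectrum log-normal TIC
factor $g$ (cv 0.15, typical spot-to-spot variability), and one uniform
relative calibration shift $\delta$ per spectrum, bounded by 0.001 —
the same 0.1% the alignment stage tolerates. The default planted signal
is ten discriminative peaks at the published discovery-cohort m/z
positions, directions and group mean intensities; their log-normal
spread is not a free dial but is calibrated per peak so that the
two-class ROC AUC implied by the log-normal model,
$\Phi(|\ln r| / \sqrt{2}\sigma_{\log})$ for mean ratio $r$, equals the
published per-peak discovery AUC (0.623-0.980). An earlier uniform-cv
draft overstated every peak's discrimination and produced nearly
separated fits unlike the study regime; matching the printed AUCs
reproduces both the univariate screen's behaviour and a stepwise
regression with healthy Wald statistics. Twelve shared-mean nuisance
peaks (present in most spectra, no class signal) and 202 low-presence
background peaks (15% presence) fill out the funnel that the presence
filter is meant to cut. Peak width defaults to
$\sigma_j = 5\times10^{-4} \, c_j$, a resolving-power-like scaling, on
a 1 Th grid.

The generator is deterministic given its configuration (the seed is
part of the configuration and the global RNG stream is left
untouched). What it does **not** emulate: isotopic envelopes, detector
saturation, replicate spot acquisition, chemical noise correlations, or
batch effects. Passing tests on these cohorts therefore demonstrate
the correctness and statistical calibration of the pipeline, not
clinical performance on real sera.

`simulate_panel_matrix()` serves a different purpose: studying the
stepwise selector itself. It plants a *true linear logistic law* —
disease status drawn as
$\mathrm{Bernoulli}(\mathrm{logit}^{-1}(\beta_0 + \sum_j \beta_j x_j))$
with nonzero $\beta_j$ only on the five published panel m/z values
(sign = published tendency, magnitude one standard deviation of the
feature per unit of linear predictor) — and five redundant peaks that
are noisy multiples of informative ones, hence marginally
discriminative but conditionally independent of the outcome. Exact
case/control quotas come from retrospective sampling, which preserves
the logistic form up to the intercept. Class-conditional log-normal
draws were deliberately *not* used here: under them a linear-in-intensity
logistic model is misspecified, and a noisy copy of a peak genuinely
improves the fitted likelihood, so no selector should be expected to
discard it. With the planted-law design, a correct stepwise run keeps
the five informative peaks and drops the redundant ones, which is
exactly what the tests assert.

## Numerical and degenerate-input choices

- Smoothing requires an odd window; window 1 is the identity.
- An all-zero spectrum cannot be TIC-normalized (error); an
  all-constant spectrum has noise level 0 (warning) and positive peaks
  then have infinite S/N.
- A baseline window wider than the spectrum span degrades to a flat
  global-minimum baseline with a warning.
- Detected apexes closer than two grid steps are merged, keeping the
  higher (a resolution floor).
- Zero pooled variance in the $t$ test gives P = 1 for equal means.
- A 2x2 table with an empty group (row) is an error; an empty category
  (column) carries no association information and returns P = 1.
- Stepwise with no admissible candidate returns the intercept-only
  panel with a warning rather than failing.

## Problem sizes

The shipped tests run the full spectral pipeline at 50 + 50 discovery
and 45 + 45 validation spectra with a reduced background-peak count,
and the selection study at 100 + 100; the acceptance script runs the
pipeline at the study's own sizes (100/100 discovery, 91/91
validation, full 224-peak structure) and completes in well under a
minute. These sizes are the package's chosen compromise between test
depth and turnaround.

## Known limitations

- The preprocessing chain is one canonical ordering of steps that
  real vendor software interleaves in partially undocumented ways;
  the processing log makes the ordering explicit rather than claiming
  to reproduce any particular product.
- Wald intervals for proportions are reported because they reproduce
  the conventional published form; they are known to undercover near
  0 and 1.
- The stepwise procedure inherits the usual caveats of significance-
  driven selection (optimism of in-sample performance, instability of
  the selected set under resampling); external validation with frozen
  coefficients is the guard the workflow itself provides.

## A worked example

```{r example, eval = FALSE}
cfg <- cohort_config(n_cases = 100, n_controls = 100, seed = 1)
discovery <- generate_cohort(cfg, "discovery")
run <- run_discovery(discovery)
print(run)

validation <- generate_cohort(
  cohort_config(n_cases = 91, n_controls = 91, seed = 1001), "validation")
perf <- run_validation(run$panel, validation)
print(perf)
```
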