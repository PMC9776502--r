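---
title: "Methods: perfect matrices of Lagrange differences for cardiac interval screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: perfect matrices of Lagrange differences for cardiac interval screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmold)
```

## The problem

Atrial fibrillation frequently runs silent: subjects have unremarkable
resting ECGs while their beat-to-beat dynamics already carry the
signature of the arrhythmia. Rather than thresholding any single interval,
`pmold` quantifies how three interval series of the same heart — JT
(repolarization), QRS (depolarization) and RR (beat period) — relate to
each other *as a coupled system*, beat by beat.

## The matrix model

Write x, y, z for the three beat-wise series (default binding x = JT,
y = QRS, z = RR) and let δ be a lag in beats. At each center beat n the
third-order perfect matrix of Lagrange differences is

$$
\begin{pmatrix}
x_n & y_{n+\delta}-x_{n+\delta} & z_{n+\delta}-x_{n+\delta}\\
y_{n-\delta}-x_{n-\delta} & y_n & z_{n+\delta}-y_{n+\delta}\\
z_{n-\delta}-x_{n-\delta} & z_{n-\delta}-y_{n-\delta} & z_n
\end{pmatrix},
$$

and the second-order matrix keeps $x_n, y_n$ on the diagonal with the
forward difference $x_{n+\delta}-y_{n+\delta}$ above and the backward
difference $x_{n-\delta}-y_{n-\delta}$ below. Both layouts are *perfect*:
all elements distinct, zeroth-order differences exactly on the diagonal,
first-order differences everywhere else, time offsets summing to zero,
and each variable symbol used equally often among the differences (in the
third-order layout each of x, y, z appears four times across the six
difference elements). `validate_perfect_structure()` checks the five
conditions mechanically:

```{r}
validate_perfect_structure(symbolic_structure(3))
```

Six of the nine entries of the 3×3 matrix are differences (against two of
four in the 2×2), which is why the third-order architecture is the more
sensitive probe of inter-interval dynamics — a claim the package exposes
directly through `sensitivity_report()`, which compares the variance of
the mapped signal for the three pairs against the triple.

### Mapping and smoothing

Each matrix is collapsed to a scalar by a mapping F. The default is the
**Frobenius norm**; the spectral norm, the modulus of the dominant
eigenvalue and (for 2×2) the discriminant of the characteristic
polynomial are selectable. Which norm underlies the mapping is a genuine
design choice: with intervals in seconds, the Frobenius norm yields
relationship values on the 0.7–1.5 scale of the per-subject statistics
this method is used with, and it is smooth, cheap and basis-independent,
so it is the default.

The mapped sequence is then smoothed twice with centered moving averages:
an *internal* pass of radius 2 samples and an *external* pass of radius
10 samples (both configurable, both recorded in all metadata). Windows
shrink symmetrically at the sequence ends (radius `min(r, i-1, n-i)`), so
the output keeps the input length, constants pass through unchanged, and
no value leaves the range of the input. The specific radii are a package
default, not a published constant; every report carries the radii used.

### Per-subject statistics

For the smoothed sequence the package reports variance σ², mean, median
x̃ and standard deviation σₓ (sample, n−1, by default), the one-sigma band
x̃ ± σₓ — deliberately centered on the median, which is robust against the
skewed excursions the band is meant to isolate — and the signed excursion
area

$$
A = \Delta t\Big[\sum_{s_i > \text{up}} (s_i - \text{up})
  + \sum_{s_i < \text{low}} (s_i - \text{low})\Big],
$$

so below-band excursions contribute negatively. Δt defaults to one beat;
passing the mean beat spacing (minutes) instead puts A on the physical
time axis. The lag δ defaults to 1 beat — the shortest lag resolves the
fastest beat-to-beat dynamics and imposes the weakest series-length
requirement (N ≥ 2δ + 1); all outputs record the δ used.

## The cohort baseline and the classifier

Per-subject variances of the smoothed relationship are the classification
feature. For each cohort (healthy, unhealthy) `fit_cohort()` estimates a
Gaussian: arithmetic mean μ, sample standard deviation σ, a t-interval
for μ and a chi-square interval for σ at 95%, plus an Anderson–Darling
composite-normality test at the 5% level. The sample (n−1) estimator is
fixed as the default because the classifier's two reference candidates
reproduce their published two-decimal indicator values (0.07, 0.54) under
it, and not under the population estimator.

The Anderson–Darling test is implemented in the package (statistic with
the D'Agostino small-sample correction, standard piecewise p-value
approximation) because the reference unhealthy cohort has n = 7 and the
common CRAN implementation declines samples that small; the test suite
pins the in-package implementation to `nortest::ad.test` exactly
(statistic and p-value) wherever both are defined.

The **variation interval** spans both fits: left = μ_h − σ_h,
right = μ_uh + σ_uh. A candidate variance C maps to

- C ≤ left → IND = 0 (condition 1),
- C ≥ right → IND = 1 (condition 2),
- otherwise IND = (C − left)/(right − left) (condition 3),

clipped to [0, 1], with the condition code reporting which branch fired
so clipping loses no information. An alternative anchoring of the linear
form — inner anchors μ_uh − σ_uh and μ_h + σ_h, i.e. the cohort roles
transposed — circulates alongside this method; it is inconsistent with
the interval boundaries above and does not reproduce the reference
candidates (it yields ≈ 0.53 where 0.07 is expected), so it is available
only behind `indicator(..., formula = "transposed")` and never used by
default.

```{r}
iv <- reference_baseline()
c(left = iv$left, right = iv$right)
round(indicator(0.0018, iv)$ind, 2)
round(indicator(0.0040, iv)$ind, 2)
```

The semi-gauge colors are thresholds on IND: green for IND ≤ 1/3, red
for IND ≥ 1, yellow between. The numeric thresholds are a package choice
(no published quantification exists); the defaults place the two
reference candidates on green (0.07) and yellow (0.54) and reserve red
for candidates at or beyond the right boundary. Both thresholds are
configurable, and `gauge_report()` serializes the dial as data (needle
fraction = IND) rather than graphics.

## The synthetic cohort generator

No public interval recordings accompany the reference cohorts, so the
generator emulates the *statistical* contrast the classifier exploits:

- **RR**: stationary AR(1), `rr[i] = m + φ(rr[i-1] - m) + e`, with
  innovation sd `rr_sd * sqrt(1 - φ²)` so `rr_sd` is the marginal sd.
  Healthy defaults: m = 0.90 s, sd = 0.035 s, φ = 0.8 (autocorrelated,
  low variance — respiratory sinus arrhythmia scale). AF-like defaults:
  m = 0.85 s, sd = 0.12 s, φ = 0.1 (irregularly irregular).
- **JT**: `0.02 + 0.30·√RR + N(0, σ)` — a Bazett-style square-root
  rate-dependence of repolarization; coefficients are configuration
  values, not physiological claims.
- **QRS**: independent Gaussian (0.09 ± 0.005 s healthy), since QRS
  duration does not track the beat period.

Cohorts derive one deterministic seed per subject from the cohort seed
and jitter the rate parameters multiplicatively (rr_mean ×U(0.93, 1.07),
rr_sd ×U(0.80, 1.25), qrs_mean ×U(0.95, 1.05)). All intervals are clipped
at a 0.02 s physiological floor with clip events counted (zero at the
defaults). Default recording length is 2000 beats (≈ half an hour).

What the generator does *not* model: f-waves or any waveform morphology,
ectopic beats, artifacts, non-stationary drift, or true JT/QRS
pathophysiology. Passing tests therefore demonstrate that the pipeline
separates autocorrelated low-variance dynamics from irregular
high-variance dynamics — the defining RR signature of AF — not clinical
performance on real ECGs.

## Numerical choices and degenerate inputs

- Beat indexing is 1-based at the interface; the valid center window for
  lag δ is the closed range [δ + 1, N − δ].
- Constant series are legal everywhere: the matrix degenerates to its
  diagonal, the relationship sequence is constant (`c√3` for diagonal
  constant c), variance and excursion area are exactly zero.
- A cohort of identical variances yields σ = 0: the fit is flagged
  `degenerate`, the normality test is reported as rejected, and a
  variation interval whose boundaries invert (left ≥ right) is flagged
  invalid with a warning — classification against it errors rather than
  producing a silent nonsense indicator.
- The indicator is continuous at both interval boundaries and
  non-decreasing in C; it is invariant under common affine rescaling of
  (C, left, right).
- JSON round-trips preserve doubles to ≈ 1 ulp (the serializer's
  shortest-representation rounding), which is the tolerance the
  round-trip tests assert.

## Problem sizes in the test suite

The suite regenerates everything programmatically: matrix oracles on
1000 random matrices; end-to-end cohort separation with 20 healthy + 20
AF-like subjects of 500 beats (baseline fitted on half, indicator
evaluated on the held-out half); the four-ordering combination study on
8 + 7 subjects of 200 beats (60 summary rows); estimator recovery on 200
replicates of n = 1000 normal draws and Anderson–Darling calibration on
500 replicates of n = 50. These sizes keep single-subject computations
well under a second while leaving the statistical assertions
well-powered.

## Limitations

- The method consumes *annotated* intervals; detecting and delineating
  J, T, Q, R, S points from raw ECG waveforms is out of scope.
- The packaged reference baseline derives from 15 subjects; its variation
  interval is correspondingly wide, and the Gaussian model rests on an
  Anderson–Darling non-rejection at n = 8 and 7, which is weak evidence.
- The lag δ, the choice of norm and the smoothing radii all modulate the
  absolute variance scale; baselines and candidates must be computed
  under the same configuration (the metadata fingerprint in every output
  exists to enforce this).
- IND is a position within an interval, not a calibrated probability;
  color thresholds are advisory defaults for a screening aid, not
  diagnostic cutoffs.
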