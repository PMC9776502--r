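# pmold

Decision support for early atrial-fibrillation (AF) screening from
beat-wise cardiac intervals, built on **perfect matrices of Lagrange
differences**.

AF is often asymptomatic ("silent AF"), yet its hallmark — irregularly
irregular RR intervals, together with altered repolarization (JT) and
depolarization (QRS) dynamics — is present in routine ECG annotations.
`pmold` quantifies the *algebraic relationship* between the three interval
series of one subject and turns it into a screening indicator:

1. **Matrix trajectory.** At each beat *n* the three series
   x = JT, y = QRS, z = RR are embedded in a 3×3 (or 2×2) *perfect matrix
   of Lagrange differences* with lag δ: zeroth-order differences (raw
   values xₙ, yₙ, zₙ) on the diagonal, first-order differences such as
   yₙ₊δ − xₙ₊δ and zₙ₋δ − yₙ₋δ off the diagonal. The layout satisfies five
   structural conditions: all elements distinct, zeroth-order on the
   diagonal, first-order elsewhere, total time lag zero, and balanced
   variable symbols (each of x, y, z appears 4 times among the six
   differences).
2. **Scalar mapping + smoothing.** Each matrix is mapped to a scalar by a
   matrix norm (Frobenius by default), and the mapped sequence is smoothed
   by two centered moving averages (internal radius 2, external radius 10
   samples).
3. **Per-subject statistics.** The smoothed sequence is summarized by its
   variance σ², mean, median x̃ and standard deviation σₓ, the one-sigma
   band x̃ ± σₓ, and the signed area A of excursions outside the band.
4. **Cohort baseline + classifier.** Per-subject variances of a healthy
   and an unhealthy cohort are fitted with Gaussians (Anderson–Darling
   normality check, 95% CIs). The *variation interval*
   [μ_h − σ_h, μ_uh + σ_uh] spans both fits; a new candidate's variance C
   maps to the indicator IND = (C − left)/(right − left), clipped to
   [0, 1], and to a green/yellow/red semi-gauge.

A seeded synthetic generator (stationary AR(1) RR dynamics, √RR-coupled
JT, independent QRS) produces healthy and AF-like cohorts so the whole
pipeline is testable without clinical data.

## Worked example

```r
library(pmold)

iv <- reference_baseline()   # packaged cohort variances: 8 healthy, 7 AF
iv
#> <variation_interval> [0.0014692, 0.0061242]

classify(0.0018, iv)
#> <classification_result> C=0.0018  IND=0.07  condition 3  -> GREEN
#>   variation interval [0.0014692, 0.0061242]

classify(0.0040, iv)
#> <classification_result> C=0.004  IND=0.54  condition 3  -> YELLOW
#>   variation interval [0.0014692, 0.0061242]
```

The first candidate sits near the healthy boundary of the variation
interval: its AF likelihood is 0.07 and the gauge points to green. The
second candidate's variance of 0.0040 would pass for healthy on its own
(the healthy cohort contains that exact value), but its position inside
the variation interval yields an AF likelihood of 0.54 — the gauge points
to yellow, flagging possible silent AF.

End to end from an interval file:

```r
s <- read_intervals("subject.csv")     # columns rr, jt, qrs in seconds
classify_subject(s, iv)                # matrices -> norm -> smooth -> C -> IND
```

Or from a shell:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","pmold.R",package="pmold"))')" \
    classify --value 0.0018 --out gauge.json
#> C = 0.0018 -> IND = 0.07 (condition 3), gauge: GREEN
```

The CLI also exposes `simulate`, `relationship`, `summarize`,
`sensitivity`, `combinations` and `baseline` subcommands.

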