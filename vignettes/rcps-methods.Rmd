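---
title: "Measuring regional cerebral protein synthesis from autoradiograms: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring regional cerebral protein synthesis from autoradiograms: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rcpskit)
```

# The measurement and its model

The L-[1-¹⁴C]leucine method measures the rate at which brain tissue
incorporates leucine into protein, *in vivo* and simultaneously for every
region visible on a film autoradiogram. Three measurements enter the
computation:

1. **The arterial input history.** After an intravenous tracer bolus, timed
   arterial samples give the labelled leucine activity `C*p(t)` (nCi/mL) and
   the total plasma leucine `Cp` (nmol/mL). Their ratio is the plasma
   specific activity (nCi/nmol), and its time integral over the experiment
   is the amount of labelling "opportunity" the tissue received.
2. **Terminal tissue labelling.** At `T` (60 min) the brain is sectioned and
   exposed to film alongside calibrated ¹⁴C standards; the optical density
   over a region, mapped through the standards curve, gives `P*ᵢ(T)`, the
   labelled-protein concentration (nCi/g).
3. **The precursor correction λ.** Only a fraction λᵢ of the tissue
   precursor pool comes from plasma; the remainder is unlabelled leucine
   recycled from tissue proteolysis. Ignoring λ would underestimate rates.

The operational equation combines them:

$$R_i = \frac{P^*_i(T)}{\lambda_i \int_0^T C^*_p(t)/C_p \, dt}$$

`compute_rcps()` is this arithmetic; `rcps_fit()` applies it across a cohort
and carries provenance (per-subject integrals, λ, T) into every output.

**Assumptions.** The tracer amount is small enough not to perturb leucine
metabolism; labelled protein does not degrade appreciably within the hour;
formalin fixation removes free (unincorporated) tracer, so the film signal
is attributed entirely to protein-bound ¹⁴C (an optional free-fraction
subtraction parameter exists, default 0, to expose this assumption); and λ
is constant per region over the experiment.

# Tunable parameters

| Parameter | Units | Default | Why |
|---|---|---|---|
| `lambda` | fraction | 0.6 | Placeholder in a plausible range for this preparation; the true value must be measured separately per strain/condition and supplied by the user. Every report echoes the λ used, and rates scale exactly as 1/λ (`tests` assert this), so results are correctable post hoc. |
| `T` | min | 60 | Terminal time of the experiment. |
| `cp_mode` | — | `per_sample` | The ratio is formed sample-by-sample (general; reduces to the pooled form when Cp is constant). `constant` divides by the mean sampled Cp — the convention when Cp is treated as a single pooled value. |
| sampling schedule | min | 0.25–60, 10 draws | Dense early draws cover the bolus peak; the number and spacing of draws is a convention of practice, not a published fact. |
| `extrapolation_policy` | — | `linear_flagged` | ODs outside the standards span are linearly continued and *flagged*; flagged regions are excluded from statistics by default (configurable), emulating the unequal per-region n of film-quality-limited studies. |
| Bonferroni `m` | count | number of regions | The full family size; may exceed the number of testable regions. |
| t-test flavor | — | Welch | The safer default when group variances differ; a pooled-variance switch exists. |

# What the simulator emulates (and what it does not)

`cohort_spec()` + `simulate_cohort()` forward-simulate every input the
pipeline consumes, so the whole chain can be checked against known truth:

* **Input function** — a biexponential bolus
  `C*p(t) = A(e^{-βt} - e^{-αt})` (default α = 1.0/min, β = 0.05/min,
  A = 2000 nCi/mL). No published plasma curve exists for this study; the
  biexponential is the standard smooth description of an IV bolus and has a
  closed-form peak, which the tests exploit. A gamma-variate alternative
  exercises shape-robustness. Plasma leucine defaults to 137 nmol/mL (the
  measured wild-type arterial value) and may drift linearly.
* **Biological variation** — per-subject, per-region true rates are the
  regional wild-type means times a genotype multiplier `(1 − effect)` times
  a unit-mean lognormal with CV 0.15 (the published power analysis assumed
  8–17% CV across regions; 15% sits at its conservative end). Lognormal
  keeps rates positive.
* **Measurement noise** — multiplicative lognormal (CV 0.05) independently
  on each plasma activity and concentration reading; additive Gaussian OD
  noise (sd 0.01) on every film pixel. One master seed; each noise stream
  draws from a deterministically derived child seed, so bundles regenerate
  bit-identically.
* **Film and standards** — a Hill-type saturating characteristic
  `OD = OD_max·a/(a + K)` with OD_max = 2 and K = 4000 nCi/g, so the
  calibration fit is exercised on a genuinely nonlinear response while the
  working range (0–5000 nCi/g) stays below ~56% of saturation, as an
  appropriately exposed film would. The default standards set has 14 graded
  steps spaced approximately uniformly in OD (commercial ¹⁴C microscale
  strips carry a similar number); with 8 coarse steps a piecewise-linear
  curve cannot invert a saturating film to 1%, which drove both choices.
* **Geometry** — regions are rectangular patches and the standards strip is
  a reserved margin. There is **no anatomical realism**: no atlas shapes, no
  registration error, no partial-volume mixing at region borders, no film
  grain structure (noise is i.i.d. Gaussian, real film grain is correlated),
  and no section-to-section variability. Passing recovery tests therefore
  validates the *computation* — calibration, integration, the operational
  equation, statistics — not the image-registration and ROI-drawing steps of
  a real workflow, which remain the user's responsibility.

## Default group structure

Defaults mirror the study conditions: 23 regions with wild-type means from
the published table, per-region decreases equal to the printed percent
differences (30–60%), and n = 8 vs 5.

# Numerical choices

* **Integration** is the trapezoidal rule on the measured ratio points — no
  functional form is fitted to the input function, because none is
  published. The curve is anchored at (0, 0) when the first draw is after
  injection (physically forced: no tracer pre-injection). If sampling stops
  before `T`, the last ratio is carried flat (conservative and bounded,
  rather than extrapolated); a warning fires if coverage is below 90% of
  `T`. On the default 10-draw schedule the trapezoid is within ~1.4% of
  adaptive quadrature across realistic bolus shapes; at 0.25-min sampling
  the error drops below 0.04%, which is the "dense" setting the zero-noise
  recovery tests use.
* **Calibration** is a monotone piecewise-linear interpolant through the
  averaged standards — exactly invertible at knots, no polynomial overshoot.
  A zero-activity standard is required and folds film fog into the curve, so
  there is no separate background-subtraction step. ¹⁴C decay over a 42-day
  exposure is ignored (half-life 5730 years; correction < 10⁻⁴).
* **ROI statistic** is the arithmetic mean OD converted *after* averaging
  (classical densitometry); convert-before-average is available for
  sensitivity checks. SDs use the n−1 denominator.
* **TIFF encoding**: OD is stored as `round(OD·scale)` in 16-bit grayscale,
  scale 10000 by default, reduced automatically when the brightest OD would
  overflow (identity-film phantoms encode activities in the thousands); the
  scale actually used is always in the sidecar JSON and readers honour it.
* **Rounding of percent differences** is to the nearest integer with ties
  away from zero — the convention that reproduces 22 of 23 printed rows of
  the reference table. The remaining row (ventral hippocampus, printed −41
  vs −40 from the printed means) was evidently computed from unrounded
  means; the package documents rather than guesses it.
* **Degenerate inputs**: zero-variance groups in post hoc tests return
  t = 0, p = 1 when means agree (rather than erroring), empty ROIs and
  missing labels are hard errors, and an integral ≤ 0 (no tracer) is
  rejected.

# Statistics

The rCPS design is a split-plot: genotype between subjects, region within.
`mixed_anova()` fits `value ~ genotype*region + Error(subject)`, testing
genotype against between-subject variation and region/interaction against
the within-subject residual, with no sphericity correction by default
(matching the uncorrected degrees of freedom reported in this literature; a
Greenhouse–Geisser option would be a natural extension). Western tables use
`factorial_anova()` (genotype × treatment between, band/site within),
reported with the highest-order interaction first. Post hoc per-region
Welch t tests use `p_adj = min(1, m·p_raw)` with an explicit family size m.

**Missing data.** Real studies lose regions to film quality, giving unequal
per-region n while still reporting a single ANOVA. The exact handling used
originally is not recoverable (the published interaction degrees of freedom
cannot arise from 23 complete regions), so the package declares its own
policy instead of guessing: post hoc tests are per-region complete-case;
the mixed ANOVA keeps regions observed in ≥ `min_n` (default 3) subjects
per genotype and then subjects complete on the retained regions, and the
policy applied is recorded on the result. The published F statistics are
therefore *not* reproduction targets; the printed percent differences are.

The test suite cross-checks all F values against an independently coded
cell-means sums-of-squares oracle on balanced designs (agreement to 1e-8),
and checks the family-wise error of the Bonferroni family at α = 0.05 over
1000 null cohorts.

# Problem sizes used in validation

Validation workloads are sized to characterize the estimator precisely
while remaining quick to run: zero-noise recovery uses the full 23-region,
8-vs-5 study at 0.25-min plasma sampling (one cohort, file-to-file); noisy
recovery uses 200 replicate cohorts at the default noise levels; the
integration contract uses 20 random bolus shapes with rise 0.7–1.5/min and
decay 0.02–0.05/min (terminal specific activity ≥ 5% of peak at 60 min, peak
within ~5 min — the band where late 45/60-min draws still carry signal);
calibration inversion is probed at 50 random interior ODs; the null
family-wise error uses 1000 cohorts.

# Known limitations

* λ is a configuration input, never estimated from data; a wrong λ scales
  all rates by a common factor (percent differences are immune).
* No compartmental modelling of the input function or of tissue free-leucine
  kinetics beyond the λ constant; no whole-blood/plasma partition
  correction.
* The phantom's geometric regions make ROI measurement trivially exact;
  real atlas-referenced ROI placement error is out of scope.
* Only Bonferroni multiplicity control; only two-group comparisons in the
  post hoc layer.
* The mixed ANOVA is a fixed-effects split-plot, not a random-slope mixed
  model; with severe imbalance its complete-case policy discards data that
  a likelihood-based mixed model would use.
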