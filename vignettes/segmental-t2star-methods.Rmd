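---
title: "Segmental myocardial T2* analysis: models, correction map, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmental myocardial T2* analysis: models, correction map, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segt2star)
```

## The problem

Myocardial T2* mapping is the reference method for non-invasive cardiac iron
quantification: iron shortens the effective transverse relaxation time T2*
(ms), equivalently raises the relaxation rate R2* = 1000/T2* (Hz). Clinical
practice usually reports one global value — the mean over the 16 segments of
the AHA left-ventricular model — but iron deposits heterogeneously, and a
segmental reading detects regional overload earlier. The obstacle is that in
perfectly healthy myocardium the segmental T2* values are *not* uniform:
susceptibility and geometric artifacts (pulmonary veins, diaphragm,
heart–lung interface, cardiac veins) depress T2* in reproducible,
location-specific ways. A segmental technique therefore needs a per-segment
*correction-factor map* estimated from a healthy cohort on the same sequence
and analysis software.

This package implements that analysis chain end to end, together with a
synthetic-data module that emulates the kind of healthy cohort from which
such maps are estimated, so that every stage can be exercised and tested without
scanner data.

## Signal model and relaxometry

Each pixel of a multi-echo gradient-echo (MEGE) acquisition decays
mono-exponentially,

$$S(TE) = S_0 \exp(-TE / T2^*),$$

sampled at the echo times of the protocol. The default
`echo_protocol()` is the clinical black-blood MEGE protocol: 10 echoes,
first at 2.02 ms, spacing 2.26 ms, last at 22.36 ms.

`fit_monoexponential()` offers two estimators:

* **log-linear** (default): OLS of $\log S$ on $TE$. Transparent, fast, and
  exact on noiseless data; it is also vectorized in closed form across all
  pixels of a map (`fit_t2star_map()`).
* **nonlinear**: Levenberg–Marquardt least squares on the signal scale,
  initialized from the log-linear fit. Preferable at low SNR because the
  log transform re-weights noise.

Numerical choices: the fit is unweighted (a squared-signal weighting is a
well-known alternative but the unweighted fit is the transparent baseline);
the noise-floor truncation rule (`truncation = "noise_floor"`) drops
trailing echoes with signal below $2\sigma$, but is **off** by default —
with healthy-range T2* (> 20 ms) all ten echoes of the default protocol stay
well above any realistic noise floor. Degenerate inputs (non-decaying
signal, fewer than three positive echoes) yield `valid = FALSE` and an `NA`
estimate rather than an error, so single bad pixels do not abort a map.

Segmental values are the **arithmetic mean of the per-pixel T2*** inside the
segment ROI (`segment_mean_t2star()`), not a fit of the mean signal; the
global value is the unweighted arithmetic mean of the 16 segmental T2*
values in the ms domain (`global_t2star()`). Averaging domains matter:
because 1000/x is convex, the mean of reciprocals exceeds the reciprocal of
the mean (Jensen), which is why a cohort's native global T2* (~34 ms for the
built-in normative distribution) is noticeably larger than the reciprocal of
its mean R2*. Summaries and comparisons of cohorts are made in whichever
domain the published reference used (R2* for the correction map and the
cohort comparison; T2* for normative tables).

## The AHA model and segment masks

`build_segment_masks()` partitions an idealized short-axis annulus into the
standard AHA sectors: 6 × 60° on the basal and mid slices, 4 × 90° on the
apical slice, numbered counterclockwise from the anterior right-ventricular
insertion (anterior at the top of the image, RV on the left, mathematical
angle convention). Segment 17 (the true apex) is excluded throughout: the
three-slice 16-segment model is the convention for T2* reporting. The
annulus is eroded *radially* by the contour offset (default 2 mm on each
side) before sectoring, mirroring the practice of drawing ROIs offset from
both contours to avoid epicardial fat and the blood pool. Apical sector
boundaries are rotated −15° relative to the segment-1 origin so the four
sector centres align with the anterior/septal/inferior/lateral directions.

The masks are idealized circular sectors on three identical slices; manual
ROIs on real anatomy cannot be replicated programmatically, and no long-axis
taper is modelled.

## The correction-factor map

The mid-ventricular septum (segments 8 and 9) is conventionally protected
from susceptibility artifacts and anchors the map. For subject $j$ let
$R2^*_{kj}$ be the rate in segment $k$ and $R2^*_{ms,j}$ the mean of the
subject's segments 8 and 9. The factor for segment $k$ is the averaged
deviation

$$\Delta R2^*_k = \frac{1}{N}\sum_{j=1}^N \left(R2^*_{kj} - R2^*_{ms,j}\right),$$

which by linearity equals the difference between the cohort's segmental mean
and its mid-septal mean — both computations are implemented and must agree
to 1e−12 (a test asserts this). The choice of "mean of segments 8 and 9" as
the reference is the only definition under which the published factor table
is internally consistent with its own published segmental means (e.g.
36.3 − (28.5 + 27.5)/2 = 8.3 ≈ the printed 8.31), so the package fixes it.

Applying the map (`apply_correction()`) subtracts each factor **in the R2*
domain** and reconverts:

$$T2^{*,corr}_k = \frac{1000}{1000/T2^*_k - \Delta R2^*_k}.$$

A positive factor (artifact-depressed segment) raises the corrected T2*;
corrected values are strictly increasing in the factor. If a subtraction
would drive R2* non-positive the segment is flagged uncorrectable and set to
`NA` (counted and warned) — it cannot be silently clamped without biasing
cohort statistics. Correction is applied per subject per segment; two
closure properties pin the arithmetic down: applying a cohort's own map
equalizes all 16 corrected segmental means at the cohort mid-septal mean,
and on an independent cohort from the same population the spread (max−min)
of corrected segmental means is strictly smaller than the native spread.

Comparison against a published cohort for which only per-segment
`(n, mean, SD)` summaries exist uses a pooled-variance (Student) two-sample
t-test from summary statistics with $df = n_1 + n_2 - 2$ and Bonferroni
multiplier 16 (`compare_cohorts_segmental()`). Pooled variance, not Welch,
is used deliberately: it is the definition under which the published
comparison p-values (0.0031, 0.0002, …) are reproduced exactly; Welch is
not. Corrected p-values are capped at 1.

## Statistics: gates, ICC form, multivariable model

All normality gating uses Shapiro–Wilk at α = 0.05, the customary choice at
cohort sizes ≤ 50: paired comparisons choose paired t vs Wilcoxon signed
rank (`paired_difference_test()`), group comparisons choose Student t
(pooled) vs Mann–Whitney (`group_compare()`), correlations choose Pearson
(both variables normal) vs Spearman (`correlate()`). Because the gate itself
has a 5% false-rejection rate, truly normal data are routed to the
parametric test about 95% of the time, not always — the tests assert the
predominant route, and that the combined procedure's type-I error stays
near nominal.

Bland–Altman limits (`bland_altman()`) use the fixed 1.96 multiplier rather
than a t quantile — the conventional large-sample definition, and the one
consistent with published limit tables (e.g. a global inter-study SD of
0.88 ms giving limits ±1.73 ms). ICC (`icc_agreement()`) is fixed to the
two-way random, absolute-agreement, single-measures form, ICC(2,1): for
test–retest data absolute agreement is the conservative choice because a
systematic session offset counts as disagreement. Published reliability
values from other (unstated) ICC forms are not comparable and are not
targeted. Classification bands: > 0.75 excellent, 0.60–0.74 good,
0.40–0.59 fair, < 0.40 poor.

The "ANCOVA-style" covariate analysis (`multivariable_model()`) is an
ordinary linear model of T2* on age, sex and wall thickness, without
interactions — with only the predictor list specified by convention, the
additive OLS model is the transparent reading. Wall thickness exists only
for the mid-ventricular segments 7–12, so segmental models are restricted
to those segments (each with its own thickness) and Bonferroni-corrected
across the responses fitted in the call.

## The synthetic cohort: what it emulates and what it does not

`generate_segmental_cohort()` emulates the design of the normative study
population: 50 subjects, exactly sex-balanced, equal counts in five age
decades (20–69), with ages uniform within decade and sex alternating within
each decade so balance is exact by construction, not in expectation.
Per-subject segmental R2* values are drawn **independently per segment**
from normal distributions whose means and SDs default to the built-in
normative segmental table (`segment_distribution()`), then converted to T2*.

Two deliberate modelling choices:

* **Truncation.** Draws are truncated symmetrically at μ ± 3σ (and to
  positive values). An untruncated (or merely positivity-truncated) normal
  places mass arbitrarily close to R2* = 0, and the reciprocal 1000/R2*
  then has *no finite mean*: cohort averages of corrected T2* become
  dominated by rare near-zero draws instead of converging. Symmetric ±3σ
  truncation keeps the target mean exact, shrinks the SD by only 1.3%, and
  bounds every derived statistic. This is the standard simulation guard
  against non-physiological extremes, stated here because it is load-bearing.
* **Independence.** No inter-segment covariance is imposed (none is
  published); independent draws reproduce the published segmental and
  global means, which is what the map estimation consumes. A consequence
  worth knowing: the *between-subject* SD of the simulated native global
  T2* (≈ 1.7 ms at these parameters) is smaller than a real cohort's
  (several ms), because real segments co-vary within subject. Cohort
  *means* are therefore faithful; global-SD-sensitive quantities are not,
  and are not targeted.

The optional age effect is an additive subject-level shift of all segmental
T2* values, linear in age and centred on the design's mid-age;
`calibrate_age_slope()` converts a requested population age–T2* correlation
(e.g. the weak negative correlation reported in healthy adults, r ≈ −0.29)
into the slope, using exact truncated-normal reciprocal moments for the
global-T2* variance. The default is no age effect. Wall thickness is drawn
with the male–female contrast typical of healthy adults (≈ 1.6–1.8 mm,
SD ≈ 1.1 mm); no thickness→T2* effect is simulated.

`generate_multiecho_phantom()` renders the signal model directly: an
annular "myocardium" whose pixels decay with their segment's T2*, a black
blood pool and background at zero mean signal, and Gaussian or Rician noise
(Rician — the magnitude of a complex Gaussian — is the default, being the
physical model for magnitude MRI). It contains no cardiac anatomy, motion,
k-space effects or susceptibility physics: segmental fluctuation is a
*population-level* property imposed through the cohort spec, not modelled
from field maps. Passing phantom tests therefore demonstrates the fitting
and masking machinery, not robustness to real-world artifacts.

## Problem sizes and tolerances used in the test suite

Cohort-level recovery runs at n = 5000 subjects, where the standard error
of the simulated global means is ≈ 0.01–0.03 ms and the published means are
recovered within ±0.5 ms; distributional fidelity is checked at 3 standard
errors. Monte-Carlo fit-bias checks use 1000 replicates; gate-behaviour
checks use 200–500 seeds; the phantom noise check uses σ = S0/50 with
several hundred pixels per segment and a 5% tolerance frozen from a
10-seed pilot. Second-order delta-method arithmetic,
$E[1000/X] \approx (1000/\mu)(1 + \sigma^2/\mu^2)$, explains why the
simulated corrected means sit slightly above the naive reciprocal of the
corrected mean rates — and exact truncated-normal integration (used in
`calibrate_age_slope()`) confirms the simulated values to ~0.1 ms.

## Known limitations

* Masks are idealized sectors; no contour detection on real images.
* The generator matches published segmental means/SDs but not the
  between-subject global SD (see independence note above), and no attempt
  is made to match it.
* Published reproducibility ICCs and segment-level agreement limits depend
  on raw repeat-scan images that are not reconstructible from summaries;
  the machinery is validated by internal-consistency properties instead.
* Only the mono-exponential model is fitted: no bi-exponential or
  offset-term variants, no fat–water separation, no motion correction.
* Corrected values assume the map's acquisition setup (sequence, scanner,
  software) matches the data's; maps are not transferable across setups,
  which is precisely why the map-estimation machinery is exposed.
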