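# segt2star

Segmental myocardial T2* relaxometry with mid-septal artifact correction.

## What problem this solves

Myocardial T2* cardiac MRI is the reference technique for non-invasive
cardiac iron quantification: tissue iron shortens T2* (ms), i.e. raises the
relaxation rate R2* = 1000/T2* (Hz). Reading T2* **per AHA segment** instead
of as a single global mean detects regional iron overload earlier — but
healthy myocardium itself shows reproducible, location-specific T2*
depressions from susceptibility and geometric artifacts (diaphragm,
pulmonary veins, heart–lung interface). A segmental technique therefore
needs a per-segment **correction-factor map** estimated from a healthy
cohort acquired with the same sequence, scanner and analysis software.

`segt2star` is for imaging scientists and cardiac-MR methodologists who want
to estimate, validate and apply such maps. It implements:

* mono-exponential multi-echo decay fitting, per sample or per pixel
  (`fit_monoexponential()`, `fit_t2star_map()`), with the standard 10-echo
  black-blood MEGE protocol (TE 2.02–22.36 ms, spacing 2.26 ms) as default;
* the AHA 16-segment model on three short-axis slices: sector masks on an
  eroded annulus (`build_segment_masks()`) and bull's-eye reporting
  (`bullseye_table()`, `bullseye_plot()`);
* the segmental correction map: for subject *j* and segment *k*,

  $$\Delta R2^*_k = \frac{1}{N}\sum_{j=1}^{N}\left(R2^*_{kj} - R2^*_{ms,j}\right),$$

  with the mid-septal reference \(R2^*_{ms,j}\) = mean of segments 8 and 9
  (`estimate_correction_factors()`); application subtracts the factor in the
  R2* domain and reconverts, \(T2^{*,corr} = 1000/(1000/T2^* - \Delta R2^*_k)\)
  (`apply_correction()`);
* cohort statistics: pooled-variance t-tests against published summary
  tables with Bonferroni correction (`compare_cohorts_segmental()`),
  normative tables stratified by age decade / sex / slice
  (`normative_summary()`), normality-gated correlation and group tests, and
  an OLS covariate model on age, sex and wall thickness
  (`multivariable_model()`);
* reproducibility statistics: normality-gated paired tests, Bland–Altman
  95% limits of agreement, and ICC(2,1) (`agreement_analysis()`);
* a synthetic-data module: sex- and age-balanced segmental cohorts drawn
  from the built-in normative segmental R2* distribution
  (`generate_segmental_cohort()`) and multi-echo annular phantoms with
  Rician or Gaussian noise, written as NIfTI
  (`generate_multiecho_phantom()`, `write_phantom_nifti()`).

Two published reference tables ship with the package:
`reference_segmental_r2star("cvi42")` (a 50-subject normative black-blood
MEGE cohort) and `"hippo"` (the 22-subject cohort behind the HIPPO MIOT
segmental software), plus both cohorts' correction-factor maps
(`reference_correction_factors()`).

## Worked example

```r
library(segt2star)

# a healthy, sex- and age-balanced cohort of 50 subjects
cohort <- generate_segmental_cohort(cohort_design(n_subjects = 50), seed = 7)

# estimate the mid-septum-referenced correction map from it
estimate_correction_factors(cohort)
#> Segmental R2* correction map (estimated; N = 50; reference: mean of AHA segments 8 and 9 (mid septum))
#>  segment            aha_name delta_r2star
#>        1      basal anterior      1.64203
#>        2  basal anteroseptal      0.87567
#>        3  basal inferoseptal     -0.04871
#>        4      basal inferior      7.87580
#>        5 basal inferolateral      7.80691
#>        ...
#>       16      apical lateral      8.57450
```

The large factors (segments 4, 5, 11, 16 — inferior/inferolateral wall and
apical lateral wall) are the artifact-prone regions; septal factors are near
zero, which is why the septum anchors the map.

```r
# which segments differ from the published HIPPO reference population?
cmp <- compare_cohorts_segmental(reference_segmental_r2star("cvi42"),
                                 reference_segmental_r2star("hippo"))
cmp[cmp$significant_corrected, c("segment", "aha_name", "p", "p_corrected")]
#>    segment            aha_name            p p_corrected
#> 5        5 basal inferolateral 0.0030566321 0.048906114
#> 6        6 basal anterolateral 0.0021743544 0.034789670
#> 7        7        mid anterior 0.0002238540 0.003581665
#> 11      11   mid inferolateral 0.0001523211 0.002437137
#> 16      16      apical lateral 0.0009763720 0.015621952
```

Five segments survive Bonferroni correction (eight before correction):
segmental normative values do not transfer between sequences, scanners and
software, so each setup needs its own map.

```r
# correct an independent cohort with the published map and summarize
held_out <- generate_segmental_cohort(cohort_design(n_subjects = 50), seed = 8)
corrected <- apply_correction(held_out, reference_correction_factors("cvi42"))
normative_summary(corrected, "slice")
#>   stratum  n mean_t2star sd_t2star
#> 1   basal 50    37.73993  3.782378
#> 2     mid 50    38.15701  4.956194
#> 3  apical 50    37.88224  4.614280

# reproducibility of a simulated repeat scan
repeat_scan <- simulate_repeat_measurement(held_out, noise_sd = 0.6, seed = 9)
agreement_analysis(global_t2star(held_out), global_t2star(repeat_scan))
#> inter_study agreement (n = 50): diff -0.01 +/- 0.15 ms, p = 0.710 (paired_t)
#>   Bland-Altman limits [-0.31, 0.29]; ICC = 0.997 (excellent)
```

After correction the three slice means agree closely (the map removes the
segmental artifact structure), the corrected global mean rises from
34.51 ms to 37.93 ms in this cohort, and the simulated repeat scan shows no
bias with excellent single-measure reliability.

A thin command-line front end mirrors these steps
(`inst/cli/segt2star simulate|correct|analyze`); see the script header for
usage. The methods vignette
(`vignettes/segmental-t2star-methods.Rmd`) documents the models, the
statistical gates and every deliberate design choice.

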