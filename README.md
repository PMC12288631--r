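# mrsquant

Quantification of single-voxel, metabolite-cycled ¹H-MR spectra at 3 T —
from raw single-shot transients to cohort-level group statistics — with a
synthetic-data generator that makes every stage testable against known
ground truth.

## The problem

In-vivo MR spectroscopy studies of the motor system (primary motor cortex,
lumbar spinal cord enlargement) compare metabolite levels — total
N-acetylaspartate (tNAA, neuronal marker), total choline (tCho, membrane
turnover), myo-inositol (mI, glial marker) — between patients and healthy
controls, usually as ratios to total creatine (tCr) and, where a water
reference exists, as absolute millimolar concentrations. Getting from raw
acquisitions to those numbers requires a long chain: per-shot water
fitting, motion-compensation outlier rejection, phase/frequency/eddy
correction, metabolite-cycling combination, HSVD residual-water removal,
linear-combination model fitting with a macromolecular background (MMBG),
Cramér–Rao lower bounds, two-compartment water referencing, quality gating,
and Welch-test group comparison. `mrsquant` implements that chain as
composable, pipe-friendly functions returning tibbles.

At its core sits the water-referenced quantification

```
M = S_M / S_H2O · 1/(1 − exp(−TR/T1)) · 1/exp(−TE/(1.5·T2))
    · (f_GM·d_GM + f_WM·d_WM) · [H2O]_molar
```

(the 1.5 factor accounts for slower apparent T2 under semi-LASER
refocusing), a 19-component linear-combination model (18 parametric
metabolite multiplets + a Voigt-line MMBG comb: 5 Hz spacing, 14 Hz
Lorentz, 7.8/0.7 Hz Gauss width for brain/cord), CRLBs from the Fisher
information, and cohort QC that drops whole spectra when more than half of
the analyzed metabolites exceed 1.5× (brain) or 2.0× (cord) their median
cohort CRLB, or the Gauss linewidth exceeds 7.5/10 Hz.

## Worked example

Simulate a small two-group brain cohort, quantify every subject end to end,
and compare groups:

```r
library(mrsquant)
set.seed(1)

acq <- acquisition_config("brain", n_points = 1024, n_shots_per_run = 16)
truth <- ground_truth(
  noise_sd = 20, mmbg_scale = 1, water_noise_sd = 0.002,
  corrupt_shot_indices = c(5, 17, 28)
)
design <- cohort_design("brain", n_hc = 8, n_sci = 8)
cohort <- simulate_cohort(design, seed = 42, acq = acq, truth_template = truth)

res <- quantify_cohort(cohort)
dplyr::select(res$table, subject_id, group, tnaa_tcr, tcr, qc_kept)
#> # A tibble: 16 × 5
#>   subject_id group tnaa_tcr   tcr qc_kept
#>   <chr>      <chr>    <dbl> <dbl> <lgl>
#> 1 S001       HC        1.85  6.94 TRUE
#> 2 S002       HC        1.88  8.08 TRUE
#> 3 S003       HC        2.07  8.28 TRUE
#> 4 S004       HC        1.88  7.71 TRUE
#> 5 S005       HC        2.19  7.42 TRUE
#> 6 S006       HC        2.36  8.30 TRUE
#> # ℹ 10 more rows

stats <- run_analysis(dplyr::filter(res$table, qc_kept),
                      contrasts = c("tnaa_tcr", "tcho_tcr", "mi_tcr", "tcr"))
dplyr::select(stats$contrasts, outcome, mean_a, mean_b, t, df, p, pct_diff)
#> # A tibble: 4 × 7
#>   outcome  mean_a mean_b      t    df      p pct_diff
#>   <chr>     <dbl>  <dbl>  <dbl> <dbl>  <dbl>    <dbl>
#> 1 tnaa_tcr  1.97   1.71   2.39   9.38 0.0395    -13
#> 2 tcho_tcr  0.219  0.237 -0.723 10.6  0.486       8.2
#> 3 mi_tcr    0.856  0.841  0.277 12.7  0.786      -1.8
#> 4 tcr       7.66   7.73  -0.223 13.1  0.827       1
```

Each row of `res$table` is one subject's quantification (metabolite/tCr
ratios, absolute tCr in mM, fitted Gauss linewidth, QC decision). The
contrast table gives per-outcome Welch tests: group means, the t statistic
with Welch–Satterthwaite degrees of freedom, the p-value and the percent
difference of the patient group relative to controls. In this small draw
the simulated tNAA/tCr deficit comes out at −13% (design −8.8%; eight
subjects per group leave substantial sampling spread), tCr itself shows no
group difference, as designed, and all 16 spectra pass QC.

The reporting convention for group differences is

```r
percent_difference(1.94, 1.77)
#> [1] -8.8
```

Other entry points: `simulate_subject()` / `preprocess_subject()` /
`fit_lcm()` / `fit_water_decay()` / `absolute_concentration()` for
stage-by-stage work; `tidy()`, `glance()`, `autoplot()` and
`plot_cohort()` for inspection; `write_transients()` / `read_transients()`
for the JSON + CSV interchange format. The methods vignette
(`vignettes/mrs-quantification.Rmd`) documents the models, defaults and
known limitations.

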