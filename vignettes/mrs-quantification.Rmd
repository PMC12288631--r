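---
title: "Metabolite quantification for metabolite-cycled 1H-MRS: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabolite quantification for metabolite-cycled 1H-MRS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`mrsquant` implements a complete analysis chain for single-voxel proton MR
spectroscopy (1H-MRS) acquired with metabolite cycling at 3 T, of the kind
used to compare metabolite levels between patient and control cohorts in the
motor cortex and the lumbar spinal cord enlargement. Because deposited raw
data for such studies are rare, the package pairs every processing stage
with a synthetic-data generator that produces acquisitions with known ground
truth, so each stage is testable end to end. This vignette documents the
models, the tunable parameters, the numerical choices, and what the
synthetic tests do and do not establish about real data.

## The signal model

A *shot* (transient) is one complex free-induction decay of `n_points`
samples at dwell time `1/spectral_width`. Spectra are obtained by a unitary
DFT (`fid_to_spec()`), which preserves energy so noise levels carry over
unchanged between domains. Frequencies are offsets from the carrier placed
on water at 4.68 ppm; the spectrometer frequency defaults to 123.25 MHz
(3 T). The ppm axis of a spectrum is `water_ppm + f/f0`.

Each resonance is a Voigt line: a Lorentzian decay `exp(-pi * L * t)` times
a Gaussian decay `exp(-(pi * G * t)^2 / (4 log 2))`, with `L` and `G` the
FWHM in Hz. Metabolites are parametric multiplets — lists of chemical-shift
positions with proton-weighted relative intensities — stored in a versioned
JSON basis file (`load_basis()`) covering 18 metabolites (aspartate through
taurine). This is a deliberate simplification: a density-matrix simulation
would reproduce J-coupling evolution with TE, which parametric multiplets do
not. The basis suffices to exercise fitting, uncertainty and cohort
machinery; it does not claim spectral accuracy for strongly coupled spin
systems such as glutamate at arbitrary TE.

## What the generator emulates

`simulate_subject()` produces, per subject:

* `n_runs x n_shots_per_run` transients (defaults: 2 x 128 for the brain
  protocol at TR 2500 ms / TE 35 ms, 2 x 256 for the cord at TR 2000 ms /
  TE 41 ms). The unsuppressed water resonance is present in every shot;
  the metabolite + macromolecular signal flips sign with the cycling state
  (ideal inversion). Metabolite amplitudes carry the T1 saturation and
  stretched-T2 decay at the protocol's TR/TE, using the same relaxation
  table the quantification later inverts.
* shot-to-shot frequency/phase drift (linear or random walk), uniform-range
  corruption of designated "motion" shots (amplitude factor 0.5–0.9,
  frequency jumps 15–40 Hz, linewidth broadening 2–4 x), and additive
  complex white noise.
* an 8-echo unsuppressed water series (TEs 35|41, 50, 75, 100, 140, 200,
  400, 1000 ms at TR 6000 ms) following the biexponential two-compartment
  decay, with *fractional* per-echo noise: each echo amplitude is in
  practice an estimate of an enormous water resonance, so its precision is
  a roughly constant fraction of its value rather than a constant absolute
  level.

The macromolecular background (MMBG) ground truth follows the same model the
field fits it with — a comb of Voigt lines at 5 Hz spacing with 14 Hz
Lorentz width and a region-specific Gauss width (7.8 Hz brain, 0.7 Hz cord)
— with an amplitude profile tracing broad humps at literature MM positions
(0.9–3.2 ppm). What a cohort analysis must recover is the unknown amplitude
profile.

Not emulated: pulse-sequence physics, B0/B1 maps, eddy-current distortions,
imperfect inversion (available as a cycling-efficiency option in concept but
off by default: cycling is ideal sign alternation), physiological noise
structure (respiratory/cardiac), and J-evolution. Passing tests therefore
demonstrate correctness of the processing and inference chain under a
well-specified signal model, not robustness to every artifact of in-vivo
data.

Cohorts (`simulate_cohort()`) draw per-subject tCr and the tNAA/tCr,
tCho/tCr and mI/tCr ratios from Gaussian group distributions; the default
design (`cohort_design()`) uses healthy-control and spinal-cord-injury
group means and SDs typical of published motor-system cohorts (brain
tNAA/tCr 1.94 ± 0.21 vs 1.77 ± 0.14; cord 2.48 ± 0.76 vs 1.81 ± 0.80; tCr
7.74 mM in the control brain). Per-subject seeds derive deterministically
from the master seed, so any subject regenerates in isolation.

## Shot-level processing

`fit_water_shot()` fits one Lorentzian water line (amplitude, frequency,
zero-order phase, linewidth) to the leading 512 time-domain points of each
shot by Levenberg–Marquardt, with uncertainties from the Gauss–Newton
covariance at the solution. Non-convergence is flagged with infinite
uncertainties, never an exception.

`reject_shots()` implements motion compensation: a shot is excluded when
(a) the relative uncertainty of its water amplitude or linewidth *exceeds*
5% (strict inequality — a shot at exactly 5.0% is kept), or (b) any of its
water frequency, amplitude or linewidth deviates from the ensemble median by
more than `mad_k` (default 3) robust standard deviations (1.4826 x MAD),
OR-combined across the three features. The MAD statistic was an open design
choice; median/MAD with k = 3 is the conventional robust default and `mad_k`
is exposed.

`correct_and_combine()` demodulates each kept shot by its water model phase
(zero-order plus linear term) — this single operation performs the
frequency, phase and eddy-current corrections, since any eddy-current phase
is part of the water phase trajectory. An optional Klose-style subtraction
of the residual smoothed water phase (`klose = TRUE`) is available for data
with genuine time-varying eddy phases; it is off by default because the
generator injects none, and because subtracting a measured phase estimate
perturbs the metabolite signal at the level of the metabolite-to-water
ratio, spoiling the otherwise exact water cancellation of clean cycling
pairs. Shots are corrected *before* pairing; cycling pairs are then
half-differenced (metabolite) and half-summed (water), pairs whose partner
was rejected are dropped with a warning rather than re-paired across
neighbours, and all pairs of both runs are averaged.

`remove_residual_water()` is an HSVD implementation: Hankel matrix of the
leading 512 points, truncated SVD (model order 16 by default), component
frequencies and dampings from the eigenvalues of the signal-subspace shift
operator, complex amplitudes by least squares over the full signal, and
subtraction of the components inside the water band (default 4.68 ± 0.4
ppm). Amplitudes are fitted jointly over all components: an in-band-only
fit was evaluated and rejected because the in-band exponentials absorb
out-of-band signal tails and over-subtract. Growing components (|pole| > 1)
are projected onto the unit circle to keep the long Vandermonde basis
bounded. If nothing falls in the band, the input is returned bit-identical.

## Linear-combination fitting

`fit_lcm()` models the windowed complex spectrum (default 0.5–4.2 ppm) as a
non-negative linear combination of the 18 basis metabolites plus the MMBG
(fixed shape, free scale), under four shared nonlinear parameters: common
Gaussian linewidth, common extra Lorentzian width, global frequency shift,
and zero-order phase. All columns, including the MMBG, share the subject's
extra Voigt decay — shim-driven broadening acts on macromolecular lines just
as on metabolites. Amplitudes are profiled out by non-negative least squares
at every step of the outer Levenberg–Marquardt iteration (variable
projection), which makes the fit deterministic given its starting values
(gauss 3 Hz, lorentz 0.5 Hz, zero shift and phase — the preprocessing has
already aligned the spectrum to water). Whether Lorentz widths should be
shared or per-metabolite was left open by convention; shared is the default
here as the more parsimonious choice at desk scale.

The noise SD is estimated from the real part of the signal-free 10.5–12 ppm
region (falling back to the top decile of the axis if absent). The residual
RMS in signal-free portions of the window agrees with this estimate to
within 15% in the test suite.

**CRLBs.** `compute_crlb()` builds the Fisher information from the numeric
model Jacobian over *all* parameters (amplitudes and the shared nonlinear
terms) and the estimated complex noise variance; the bound for a parameter
is the square root of the corresponding diagonal of the inverse information.
The inverse is computed by SVD so that the noise scaling is exact at any
level; directions with negligible curvature (relative singular value below
1e-12) are unidentifiable and propagate an infinite bound to parameters
loading on them, and structurally absent components (all-zero sensitivity)
get an infinite bound silently. Bounds are reported per metabolite
individually; sums such as tNAA = NAA + NAAG, tCr = Cr + PCr and
tCho = GPC + PCho get no individual bound, because Cr/PCr and GPC/PCho are
nearly collinear at 3 T and their individual bounds are large and strongly
anti-correlated. For uncertainty of the sums, `amplitude_covariance()`
returns the full amplitude covariance (Moore–Penrose inverse of the
information), from which `var(sum) = 1' Cov 1` propagates correctly. No
soft constraint couples Cr/PCr or GPC/PCho — the collinearity is handled
through reporting of sums, not through priors.

**MMBG estimation.** `estimate_mmbg()` averages at least two control
spectra and jointly fits the metabolite basis plus every individual comb
line (non-negative amplitudes, shared nonlinear parameters). Two details
matter. First, a second-difference roughness penalty on the comb amplitudes
(weight `smoothness`, default 0.5 relative to the comb column scale) keeps
the broad-by-nature background from sharpening into metabolite peaks during
the joint fit. Second, an alternating refinement re-fits the metabolite
block against the comb-subtracted data and the comb against the
metabolite-subtracted residual for five iterations, sharpening the
separation. The resulting line-amplitude profile is then fixed; subject
fits only scale it.

## Water referencing and absolute quantification

`fit_water_decay()` fits `S(TE) = S_par exp(-TE/T2_par) + S_CSF
exp(-TE/T2_CSF)` to the magnitude echo amplitudes. The biexponential is
degenerate when the truth is effectively single-compartment — notably in
the cord, where CSF-selective inversion nulls the CSF signal and the
generator models this simply as `f_CSF = 0` — so the function performs
explicit model selection: a second compartment is accepted only when its T2
is distinct (ratio > 1.2), its amplitude non-negligible (> 0.1% of the
total) and the fit improvement real (> 1% of the single-compartment RSS);
otherwise the single-compartment solution is returned with `s_csf = 0`.
If the optimum violates `T2_par < T2_CSF` the compartments are relabelled.
Magnitude (not complex) fitting is used throughout.

`absolute_concentration()` implements

$$
M = \frac{S_M}{S_{H_2O}}
  \cdot \frac{1}{1 - e^{-TR/T_1}}
  \cdot \frac{1}{e^{-TE/(1.5\,T_2)}}
  \cdot (f_{GM}\,d_{GM} + f_{WM}\,d_{WM})
  \cdot [H_2O]_{molar}
$$

with the 1.5 stretch factor accounting for the slower apparent T2
relaxation under adiabatic (semi-LASER) refocusing. `f_GM + f_WM = 1` with
CSF excluded (regional defaults 0.38/0.62 brain, 0.36/0.64 cord); water
contents default to `d_GM = 0.78`, `d_WM = 0.65`; `[H2O]_molar` defaults to
55,500 mM (pure-water molarity) and is configurable, as is the metabolite
T1/T2 table shipped with the basis — literature-style values, config rather
than claims. `S_H2O` is the parenchymal TE = 0 amplitude divided by the two
protons of water; metabolite proton counts are inside the basis intensities,
so fitted amplitudes are already on a per-molecule scale. TE = 0 is allowed
as the correction-free limit. Ratios are computed on relaxation-corrected
amplitudes (`calibrate_ratios()` with TR/TE), so they compare
concentrations, not raw signals; mM values are `ratio x tCr_mM`, and the
same calibration factor converts amplitude CRLBs to mM.

## Quality gating and cohort statistics

`gate_spectra()` excludes whole spectra, never single metabolites: per
analyzed metabolite (default NAA, NAAG, Cr, PCr, GPC, PCho, mI) the cutoff
is `crlb_multiplier` times the cohort median of its absolute (mM) CRLB —
1.5x in the brain, 2.0x in the cord — and a subject falls when strictly
more than half of the analyzed metabolites exceed their cutoffs, or when
its common Gaussian linewidth exceeds 7.5 Hz (brain) / 10 Hz (cord). Ties
at exactly half are kept. The cohort median is pooled over all subjects and
computed once (no iterative re-medianing); working on absolute mM CRLBs
makes the decisions invariant to any common unit rescaling.

`welch_test()`, `percent_difference()` (100 x (SCI − HC)/HC, one decimal),
`correlate()` (Pearson, or Spearman with midrank ties) and `run_analysis()`
produce the cohort report: Welch contrasts for tNAA/tCr, tCho/tCr, mI/tCr,
tCr and the cord cross-sectional areas where present, plus a
Pearson+Spearman association battery against clinical scores, lesion
metrics and time since injury in the patient group. Tests are two-sided by
default (directional alternatives are available and labelled in the output)
and no multiplicity correction is applied by default, matching common
practice in exploratory cohort reports; a Benjamini–Hochberg option exists.

## Problem sizes and numerical choices

The test suite and the acceptance script run scaled-down acquisitions —
1024 complex points and 16-shot runs instead of 2048/128 — at a per-shot
noise level (`noise_sd = 20` in generator units) that yields averaged
spectra with NAA SNR near 70, comfortably inside the range of good in-vivo
brain data and above the SNR ≥ 15 regime the recovery checks assume. The
end-to-end cohort check uses 50 subjects per group; the CRLB validation 500
Monte-Carlo replicates; the motion-compensation check the full 256-shot
protocol with 26 corrupted shots; the Welch calibration 5000 null
replicates. These sizes are the package's choice of desk-scale conditions.

Numerical details worth knowing:

* Degenerate inputs error early with specific messages (odd shot counts,
  non-power-of-two lengths, volume fractions not summing to one, all shots
  rejected, all-equal echo times, zero tCr amplitude).
* The MAD-based outlier rule treats a zero MAD with nonzero deviation as an
  infinite z-score (exclusion) and a zero deviation as z = 0 (kept), so
  ideal noiseless ensembles never self-exclude.
* Tie-break in rejection reasons: uncertainty and outlier flags are
  recorded jointly ("uncertainty+outlier") when both fire.
* `percent_difference()` rounds to one decimal for reporting (configurable).

## Known limitations

* tCr concentration estimates carry a small cohort-level systematic
  (~1–2% at the default conditions) that originates in the estimated MMBG
  profile's interplay with the creatine region and in the curvature of the
  Gauss/Lorentz lineshape ridge. It shrinks with SNR but is not captured by
  the propagated per-subject uncertainty, so nominal-95% coverage of design
  tCr varies by cohort realization (roughly 83–95% across seeds at the
  default conditions). Ratios to tCr largely cancel this effect (bias well
  under 1%).
* The parametric basis does not evolve J-coupling with TE; conclusions
  about coupled spin systems transfer to real data only qualitatively.
* Metabolite cycling is ideal; inversion-efficiency losses and subtraction
  artifacts from real cycling pulses are not modelled.
* The two-compartment water model assumes pure biexponential decay;
  exchange and multi-compartment T2 spectra are out of scope.
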