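## Shared fixtures: a scaled-down acquisition (fewer shots, 1024 points)
## whose averaged SNR matches realistic in-vivo spectra, so every stage is
## exercised at desk scale.

quick_acq <- function(region = "brain", n_shots_per_run = 16L, ...) {
  acquisition_config(region,
    n_points = 1024, n_shots_per_run = n_shots_per_run, ...
  )
}

quick_truth <- function(noise_sd = 20, mmbg_scale = 1,
                        water_noise_sd = 0.002, ...) {
  ground_truth(
    noise_sd = noise_sd, mmbg_scale = mmbg_scale,
    water_noise_sd = water_noise_sd, ...
  )
}

## pure-noise truth: no metabolites, no MMBG, no water
noise_only_truth <- function(noise_sd) {
  conc <- default_concentrations("brain") * 0
  ground_truth(
    concentrations = conc, mmbg_scale = 0, noise_sd = noise_sd,
    H2O_molar = 0
  )
}

## water-only truth: no metabolites, no MMBG
water_only_truth <- function(...) {
  ground_truth(
    concentrations = default_concentrations("brain") * 0,
    mmbg_scale = 0, ...
  )
}

## single-line spectrum from a one-metabolite basis, optional complex noise
naa_basis <- function() basis_subset(load_basis(), "naa")

line_spectrum <- function(amp = 10, noise_sd = 0, seed = NULL,
                          n = 1024, sw = 4000, lorentz = 1, gauss = 3,
                          basis = naa_basis()) {
  t <- (seq_len(n) - 1) / sw
  fid <- amp * mrsquant:::basis_fids(basis, n, sw)[, 1] *
    mrsquant:::voigt_decay(t, lorentz, gauss)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    fid <- fid + complex(
      real = stats::rnorm(n, 0, noise_sd),
      imaginary = stats::rnorm(n, 0, noise_sd)
    )
  }
  new_spectrum(fid_to_spec(fid), sw, 123.25)
}

## water fit table constructed directly (for rejection-rule tests)
make_fits <- function(n, frequency = 0, amplitude = 100, linewidth = 6,
                      amp_rel_unc = 0.01, lw_rel_unc = 0.01) {
  tibble::tibble(
    shot_index = seq_len(n),
    amplitude = rep_len(amplitude, n),
    amp_rel_unc = rep_len(amp_rel_unc, n),
    frequency = rep_len(frequency, n),
    freq_unc = 0.01,
    phase_deg = 0,
    linewidth = rep_len(linewidth, n),
    lw_rel_unc = rep_len(lw_rel_unc, n),
    converged = TRUE
  )
}
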