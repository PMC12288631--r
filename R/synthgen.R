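#' Acquisition configuration for a metabolite-cycled single-voxel protocol
#'
#' Defaults follow the 3 T study protocols: brain semi-LASER at TR 2500 ms /
#' TE 35 ms with two runs of 128 shots; lumbar cord at TR 2000 ms / TE 41 ms
#' with two runs of 256 shots.  Spectral width and number of points are
#' simulator choices (4000 Hz, 2048 complex points), configurable.
#'
#' @param region `"brain"` or `"cord"`.
#' @param spectrometer_frequency Spectrometer frequency in MHz (3 T proton).
#' @param spectral_width Spectral width in Hz.
#' @param n_points Number of complex points per shot; power of two, >= 512.
#' @param TR,TE Repetition and echo time of the metabolite acquisition, ms.
#' @param n_shots_per_run Shots per run (even, cycling pairs).
#' @param n_runs Number of runs.
#' @param water_ppm Carrier position in ppm.
#' @param water_te_list Echo times of the unsuppressed water series, ms.
#' @param water_TR TR of the water series, ms.
#' @return A list of class `mrs_acq`.
#' @export
acquisition_config <- function(region = c("brain", "cord"),
                               spectrometer_frequency = 123.25,
                               spectral_width = 4000,
                               n_points = 2048,
                               TR = NULL, TE = NULL,
                               n_shots_per_run = NULL, n_runs = 2,
                               water_ppm = 4.68,
                               water_te_list = NULL,
                               water_TR = 6000) {
  region <- match.arg(region)
  if (is.null(TR)) TR <- if (region == "brain") 2500 else 2000
  if (is.null(TE)) TE <- if (region == "brain") 35 else 41
  if (is.null(n_shots_per_run)) {
    n_shots_per_run <- if (region == "brain") 128L else 256L
  }
  if (is.null(water_te_list)) {
    first_te <- if (region == "brain") 35 else 41
    water_te_list <- c(first_te, 1000, 50, 400, 200, 75, 100, 140)
  }
  if (n_points < 512 || bitwAnd(n_points, n_points - 1L) != 0) {
    stop("n_points must be >= 512 and a power of two", call. = FALSE)
  }
  if (spectral_width <= 0) stop("spectral_width must be positive", call. = FALSE)
  if (n_shots_per_run %% 2 != 0) {
    stop("n_shots_per_run must be even (cycling pairs)", call. = FALSE)
  }
  structure(
    list(
      region = region, spectrometer_frequency = spectrometer_frequency,
      spectral_width = spectral_width, n_points = as.integer(n_points),
      TR = TR, TE = TE, n_shots_per_run = as.integer(n_shots_per_run),
      n_runs = as.integer(n_runs), water_ppm = water_ppm,
      water_te_list = water_te_list, water_TR = water_TR
    ),
    class = "mrs_acq"
  )
}

#' Default ground-truth metabolite concentrations (mM)
#'
#' Healthy-control style concentrations; brain defaults give
#' tCr = Cr + PCr = 7.74 mM and tNAA/tCr close to 1.94, cord defaults give
#' tCr = 4.02 mM and tNAA/tCr close to 2.48.
#'
#' @param region `"brain"` or `"cord"`.
#' @return Named numeric vector of concentrations in mM.
#' @export
default_concentrations <- function(region = c("brain", "cord")) {
  region <- match.arg(region)
  if (region == "brain") {
    c(
      asp = 2.0, cr = 4.00, gaba = 1.3, glc = 1.2, glu = 8.5, gln = 2.5,
      gsh = 1.8, gly = 0.8, gpc = 0.95, lac = 0.7, mi = 6.73, naa = 13.2,
      naag = 1.82, pcr = 3.74, pcho = 0.75, pe = 1.5, scyllo = 0.3, tau = 1.4
    )
  } else {
    c(
      asp = 1.5, cr = 2.08, gaba = 0.8, glc = 0.8, glu = 5.0, gln = 1.8,
      gsh = 1.2, gly = 0.5, gpc = 1.70, lac = 0.6, mi = 7.80, naa = 8.77,
      naag = 1.20, pcr = 1.94, pcho = 1.00, pe = 1.2, scyllo = 0.2, tau = 1.1
    )
  }
}

#' Ground truth for one simulated subject
#'
#' Collects every quantity the simulator needs and the downstream pipeline
#' estimates: metabolite concentrations, macromolecular background scale,
#' lineshape, phase/frequency offsets, per-shot drift, motion-corrupted shot
#' indices, noise level, tissue volume fractions and water relaxation.
#'
#' @param concentrations Named mM vector over the basis metabolites.
#' @param mmbg_scale Macromolecular background scale (1 = default amplitude).
#' @param gauss_lw Shared Gaussian linewidth (FWHM, Hz) from shim quality.
#' @param lorentz_lw Extra Lorentzian broadening common to all lines (Hz).
#' @param water_lorentz_lw Water line Lorentz FWHM in Hz.
#' @param zero_order_phase Zero-order phase in degrees.
#' @param frequency_offset Global frequency offset in Hz.
#' @param noise_sd Per-point SD of each of the real and imaginary noise parts.
#' @param drift Drift model: list with `type` (`"linear"` or `"random_walk"`),
#'   `freq_hz_per_shot`, `phase_deg_per_shot`.
#' @param corrupt_shot_indices Integer indices (1-based, over all shots of all
#'   runs) of motion-corrupted shots.
#' @param corruption Ranges for the corruption model: multiplicative amplitude
#'   factor, additive |frequency jump| (Hz), linewidth broadening factor, each
#'   drawn uniformly (frequency jump with random sign).
#' @param f_GM,f_WM,f_CSF Voxel volume fractions, summing to 1.
#' @param water_T2_parenchyma,water_T2_CSF Water T2 per compartment, ms.
#' @param water_noise_sd Fractional (relative) noise SD per water echo
#'   amplitude: each echo is an estimate of a very large water resonance, so
#'   its precision is approximately a constant fraction of its value.
#' @param H2O_molar Molar water concentration, mM.
#' @param d_GM,d_WM Relative water content of grey and white matter.
#' @return A list of class `mrs_truth`.
#' @export
ground_truth <- function(concentrations = default_concentrations("brain"),
                         mmbg_scale = 1,
                         gauss_lw = 3.4, lorentz_lw = 2,
                         water_lorentz_lw = 6,
                         zero_order_phase = 0, frequency_offset = 0,
                         noise_sd = 0,
                         drift = list(
                           type = "linear",
                           freq_hz_per_shot = 0, phase_deg_per_shot = 0
                         ),
                         corrupt_shot_indices = integer(0),
                         corruption = list(
                           amp_factor = c(0.5, 0.9),
                           freq_jump_hz = c(15, 40),
                           lw_factor = c(2, 4)
                         ),
                         f_GM = 0.361, f_WM = 0.589, f_CSF = 0.05,
                         water_T2_parenchyma = 70, water_T2_CSF = 500,
                         water_noise_sd = 0,
                         H2O_molar = 55500, d_GM = 0.78, d_WM = 0.65) {
  if (any(concentrations < 0)) stop("concentrations must be >= 0", call. = FALSE)
  if (abs(f_GM + f_WM + f_CSF - 1) > 1e-9) {
    stop("f_GM + f_WM + f_CSF must equal 1", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(
    list(
      concentrations = concentrations, mmbg_scale = mmbg_scale,
      gauss_lw = gauss_lw, lorentz_lw = lorentz_lw,
      water_lorentz_lw = water_lorentz_lw,
      zero_order_phase = zero_order_phase,
      frequency_offset = frequency_offset,
      noise_sd = noise_sd, drift = drift,
      corrupt_shot_indices = as.integer(corrupt_shot_indices),
      corruption = corruption,
      f_GM = f_GM, f_WM = f_WM, f_CSF = f_CSF,
      water_T2_parenchyma = water_T2_parenchyma,
      water_T2_CSF = water_T2_CSF,
      water_noise_sd = water_noise_sd,
      H2O_molar = H2O_molar, d_GM = d_GM, d_WM = d_WM
    ),
    class = "mrs_truth"
  )
}

## Relaxation attenuation applied to metabolite signals at acquisition:
## T1 saturation at TR and T2 decay at TE with the semi-LASER 1.5x stretch.
## The same factors are inverted by the quantification equation.
relax_attenuation <- function(basis, TR, TE, t2_stretch = 1.5) {
  a <- (1 - exp(-TR / basis$meta$t1_ms)) *
    exp(-TE / (t2_stretch * basis$meta$t2_ms))
  stats::setNames(a, basis$meta$metabolite)
}

## Water amplitude at TE = 0 for the parenchymal compartment, in the same
## per-molecule signal units as metabolite amplitudes: 2 protons per water
## molecule times the tissue water content at the CSF-excluded GM/WM
## fractions.  Metabolite and water signal both arise from the parenchymal
## sub-volume, so that volume cancels and does not appear here.
water_amp_parenchyma <- function(truth) {
  fsum <- truth$f_GM + truth$f_WM
  if (fsum <= 0) {
    return(0)
  }
  tissue_factor <- (truth$f_GM * truth$d_GM + truth$f_WM * truth$d_WM) / fsum
  2 * truth$H2O_molar * tissue_factor
}

## CSF water relative to the parenchymal sub-volume (water content 1)
water_amp_csf <- function(truth) {
  fsum <- truth$f_GM + truth$f_WM
  if (fsum <= 0) {
    return(0)
  }
  2 * truth$H2O_molar * truth$f_CSF / fsum
}

#' Simulate one subject's metabolite-cycled acquisition and water echo series
#'
#' Generates `n_runs * n_shots_per_run` complex transients.  Each shot holds
#' the unsuppressed water resonance plus the metabolite and macromolecular
#' signal whose sign alternates with the metabolite-cycling state; metabolite
#' amplitudes carry the T1/T2 attenuation at the protocol's TR/TE.  Shot-to-
#' shot frequency/phase drift, uniform-range corruption of flagged "motion"
#' shots, and additive complex white noise complete the model.  The
#' unsuppressed water echo series follows the biexponential two-compartment
#' decay over the protocol's TE list.
#'
#' @param truth A [ground_truth()] object.
#' @param acq An [acquisition_config()] object.
#' @param seed Integer seed; the result is fully reproducible given the seed.
#' @param basis An [load_basis()] object.
#' @return A list with `transients` (class `mrs_transients`: list of shots
#'   with samples, cycling state, run and shot index, plus the config) and
#'   `water_series` (class `mrs_water_series`: TE list, magnitude amplitudes,
#'   TR).
#' @export
simulate_subject <- function(truth, acq, seed, basis = load_basis()) {
  stopifnot(inherits(truth, "mrs_truth"), inherits(acq, "mrs_acq"))
  n_total <- acq$n_runs * acq$n_shots_per_run
  if (length(truth$corrupt_shot_indices) &&
    (min(truth$corrupt_shot_indices) < 1 ||
      max(truth$corrupt_shot_indices) > n_total)) {
    stop("corrupt_shot_indices outside the valid shot range", call. = FALSE)
  }
  t <- time_axis(acq$n_points, acq$spectral_width)

  ## noise-free building blocks
  att <- relax_attenuation(basis, acq$TR, acq$TE)
  bmat <- basis_fids(basis, acq$n_points, acq$spectral_width)
  conc <- truth$concentrations[colnames(bmat)]
  met_fid0 <- as.vector(bmat %*% (conc * att[colnames(bmat)])) +
    mmbg_truth_fid(basis, acq$n_points, acq$spectral_width, truth$mmbg_scale,
      region = acq$region
    )
  gdecay <- voigt_decay(t, truth$lorentz_lw, truth$gauss_lw)
  met_fid0 <- met_fid0 * gdecay

  w_amp <- water_amp_parenchyma(truth) *
    exp(-acq$TE / truth$water_T2_parenchyma) +
    water_amp_csf(truth) * exp(-acq$TE / truth$water_T2_CSF)
  water_decay <- voigt_decay(t, truth$water_lorentz_lw, truth$gauss_lw)

  set.seed(derive_seed(seed, 1L))
  drift <- truth$drift
  shots <- vector("list", n_total)
  global_idx <- 0L
  freq_rw <- 0
  phase_rw <- 0
  for (run in seq_len(acq$n_runs)) {
    for (k in seq_len(acq$n_shots_per_run)) {
      global_idx <- global_idx + 1L
      cyc <- if (k %% 2 == 1) 1L else -1L
      if (identical(drift$type, "random_walk")) {
        freq_rw <- freq_rw + stats::rnorm(1, 0, drift$freq_hz_per_shot)
        phase_rw <- phase_rw + stats::rnorm(1, 0, drift$phase_deg_per_shot)
        df <- freq_rw
        dp <- phase_rw
      } else {
        df <- drift$freq_hz_per_shot * (global_idx - 1L)
        dp <- drift$phase_deg_per_shot * (global_idx - 1L)
      }
      f_shot <- truth$frequency_offset + df
      ph_shot <- deg2rad(truth$zero_order_phase + dp)

      amp_factor <- 1
      lw_factor <- 1
      if (global_idx %in% truth$corrupt_shot_indices) {
        cr <- truth$corruption
        amp_factor <- stats::runif(1, cr$amp_factor[1], cr$amp_factor[2])
        f_shot <- f_shot + sample(c(-1, 1), 1) *
          stats::runif(1, cr$freq_jump_hz[1], cr$freq_jump_hz[2])
        lw_factor <- stats::runif(1, cr$lw_factor[1], cr$lw_factor[2])
      }
      extra_decay <- if (lw_factor > 1) {
        voigt_decay(t, (lw_factor - 1) * truth$water_lorentz_lw, 0)
      } else {
        1
      }

      fid <- (w_amp * water_decay + cyc * met_fid0) * amp_factor *
        extra_decay * exp(1i * (2 * pi * f_shot * t + ph_shot))
      if (truth$noise_sd > 0) {
        fid <- fid + complex(
          real = stats::rnorm(acq$n_points, 0, truth$noise_sd),
          imaginary = stats::rnorm(acq$n_points, 0, truth$noise_sd)
        )
      }
      shots[[global_idx]] <- list(
        samples = fid, cycling_state = cyc,
        run_index = run, shot_index = global_idx
      )
    }
  }

  ## unsuppressed water echo series (magnitude amplitudes)
  set.seed(derive_seed(seed, 2L))
  s_par <- water_amp_parenchyma(truth)
  s_csf <- water_amp_csf(truth)
  amp <- s_par * exp(-acq$water_te_list / truth$water_T2_parenchyma) +
    s_csf * exp(-acq$water_te_list / truth$water_T2_CSF)
  if (truth$water_noise_sd > 0) {
    amp <- abs(amp * (1 + stats::rnorm(length(amp), 0, truth$water_noise_sd)))
  }
  list(
    transients = structure(
      list(shots = shots, acq = acq),
      class = "mrs_transients"
    ),
    water_series = structure(
      list(te_list = acq$water_te_list, amplitudes = amp, TR = acq$water_TR),
      class = "mrs_water_series"
    )
  )
}

#' @export
print.mrs_transients <- function(x, ...) {
  cat("<mrs_transients> ", length(x$shots), " shots (",
    x$acq$n_runs, " runs x ", x$acq$n_shots_per_run, "), ",
    x$acq$n_points, " points, region ", x$acq$region, "\n",
    sep = ""
  )
  invisible(x)
}

#' @export
print.mrs_water_series <- function(x, ...) {
  cat("<mrs_water_series> TEs:", paste(x$te_list, collapse = ", "), "ms\n")
  invisible(x)
}

#' Cohort design for the group-level simulator
#'
#' Defaults mirror the study's printed group summaries: healthy controls (HC)
#' and spinal-cord-injury patients (SCI) with region-specific mean tCr and
#' metabolite/tCr ratios.  Between-subject SDs are the printed cohort SDs.
#'
#' @param region `"brain"` or `"cord"`.
#' @param n_hc,n_sci Group sizes.
#' @param means,sds Optional named lists overriding per-group design means and
#'   between-subject SDs for `tcr` (mM), `tnaa_ratio`, `tcho_ratio`,
#'   `mi_ratio`; each a list with elements `HC` and `SCI` of named vectors.
#' @return A tibble with one row per group, class `mrs_cohort_design`.
#' @export
cohort_design <- function(region = c("brain", "cord"),
                          n_hc = 18, n_sci = 15,
                          means = NULL, sds = NULL) {
  region <- match.arg(region)
  d <- if (region == "brain") {
    tibble::tibble(
      group = c("HC", "SCI"), n = c(n_hc, n_sci),
      tcr = c(7.74, 7.88), tcr_sd = c(0.67, 0.76),
      tnaa_ratio = c(1.94, 1.77), tnaa_sd = c(0.21, 0.14),
      tcho_ratio = c(0.22, 0.23), tcho_sd = c(0.05, 0.03),
      mi_ratio = c(0.87, 0.86), mi_sd = c(0.10, 0.13)
    )
  } else {
    tibble::tibble(
      group = c("HC", "SCI"), n = c(n_hc, n_sci),
      tcr = c(4.02, 4.75), tcr_sd = c(1.33, 1.66),
      tnaa_ratio = c(2.48, 1.81), tnaa_sd = c(0.76, 0.80),
      tcho_ratio = c(0.67, 0.60), tcho_sd = c(0.43, 0.34),
      mi_ratio = c(1.94, 2.31), mi_sd = c(0.61, 0.52)
    )
  }
  if (!is.null(means)) {
    for (g in names(means)) {
      for (v in names(means[[g]])) d[d$group == g, v] <- means[[g]][[v]]
    }
  }
  if (!is.null(sds)) {
    for (g in names(sds)) {
      for (v in names(sds[[g]])) {
        d[d$group == g, paste0(sub("_ratio", "", v), "_sd")] <- sds[[g]][[v]]
      }
    }
  }
  if (any(d$n < 0) || any(d[grep("_sd$", names(d))] < 0)) {
    stop("group sizes and SDs must be non-negative", call. = FALSE)
  }
  d$region <- region
  class(d) <- c("mrs_cohort_design", class(d))
  d
}

#' Simulate a cohort of subjects from a group design
#'
#' Per-subject ground truths are drawn from the group distributions (tCr and
#' the three target ratios Gaussian around the design means, truncated at
#' zero); remaining metabolites keep the regional defaults scaled to the
#' subject's tCr.  Per-subject seeds derive deterministically from the master
#' seed, so any subject can be regenerated in isolation.
#'
#' @param design A [cohort_design()] tibble.
#' @param seed Master integer seed.
#' @param acq Acquisition configuration (defaults to the design's region).
#' @param truth_template A [ground_truth()] whose non-concentration fields
#'   (noise, drift, corruption, tissue fractions...) apply to every subject.
#' @param basis Basis set.
#' @param simulate If `FALSE`, only draw ground truths (fast; no transients).
#' @return A tibble with one row per subject: `subject_id`, `group`,
#'   `region`, `seed`, design draws (`tcr`, `tnaa_ratio`, ...), and — when
#'   `simulate = TRUE` — list-columns `truth`, `transients`, `water_series`.
#' @export
simulate_cohort <- function(design, seed,
                            acq = acquisition_config(design$region[1]),
                            truth_template = ground_truth(),
                            basis = load_basis(),
                            simulate = TRUE) {
  stopifnot(inherits(design, "mrs_cohort_design"))
  region <- design$region[1]
  rows <- list()
  sid <- 0L
  for (g in seq_len(nrow(design))) {
    dg <- design[g, ]
    set.seed(derive_seed(seed, 100L + g))
    for (i in seq_len(dg$n)) {
      sid <- sid + 1L
      draw <- function(mean, sd) max(mean + stats::rnorm(1, 0, sd), 1e-3)
      rows[[sid]] <- tibble::tibble(
        subject_id = sprintf("S%03d", sid),
        group = dg$group, region = region,
        seed = derive_seed(seed, 1000L + sid),
        tcr = draw(dg$tcr, dg$tcr_sd),
        tnaa_ratio = draw(dg$tnaa_ratio, dg$tnaa_sd),
        tcho_ratio = draw(dg$tcho_ratio, dg$tcho_sd),
        mi_ratio = draw(dg$mi_ratio, dg$mi_sd)
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  out$truth <- purrr::pmap(
    out[c("tcr", "tnaa_ratio", "tcho_ratio", "mi_ratio")],
    function(tcr, tnaa_ratio, tcho_ratio, mi_ratio) {
      subject_truth(truth_template, region, tcr, tnaa_ratio, tcho_ratio,
        mi_ratio,
        basis = basis
      )
    }
  )
  if (simulate) {
    sims <- purrr::map2(
      out$truth, out$seed,
      function(tr, sd) simulate_subject(tr, acq, sd, basis = basis)
    )
    out$transients <- purrr::map(sims, "transients")
    out$water_series <- purrr::map(sims, "water_series")
  }
  out
}

## Build a subject ground truth realising given tCr and ratios, keeping the
## regional default concentration pattern for everything else (scaled to tCr).
subject_truth <- function(template, region, tcr, tnaa_ratio, tcho_ratio,
                          mi_ratio, basis = load_basis()) {
  conc <- default_concentrations(region)
  scale_tcr <- tcr / (conc["cr"] + conc["pcr"])
  conc <- conc * scale_tcr
  ## impose target ratios, preserving the NAA:NAAG and GPC:PCho splits
  tnaa <- tnaa_ratio * tcr
  r <- conc["naa"] / (conc["naa"] + conc["naag"])
  conc["naa"] <- tnaa * r
  conc["naag"] <- tnaa * (1 - r)
  tcho <- tcho_ratio * tcr
  r <- conc["gpc"] / (conc["gpc"] + conc["pcho"])
  conc["gpc"] <- tcho * r
  conc["pcho"] <- tcho * (1 - r)
  conc["mi"] <- mi_ratio * tcr
  tr <- template
  tr$concentrations <- conc
  tr
}
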