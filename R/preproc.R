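#' Construct a spectrum object
#'
#' A spectrum is a complex frequency-domain vector plus the metadata needed to
#' interpret it (spectral width, spectrometer frequency, carrier position) and
#' a provenance record of how many shots went into it.
#'
#' @param values Complex frequency-domain samples, frequencies increasing.
#' @param spectral_width Spectral width in Hz.
#' @param frequency_mhz Spectrometer frequency in MHz.
#' @param water_ppm Carrier position in ppm.
#' @param provenance List, e.g. `n_shots_kept`, `n_shots_excluded`, `runs`.
#' @return An object of class `mrs_spectrum`.
#' @export
new_spectrum <- function(values, spectral_width, frequency_mhz,
                         water_ppm = 4.68, provenance = list()) {
  structure(
    list(
      values = values, spectral_width = spectral_width,
      frequency_mhz = frequency_mhz, water_ppm = water_ppm,
      provenance = provenance
    ),
    class = "mrs_spectrum"
  )
}

#' @export
print.mrs_spectrum <- function(x, ...) {
  cat("<mrs_spectrum> ", length(x$values), " points, sw ", x$spectral_width,
    " Hz @ ", x$frequency_mhz, " MHz\n",
    sep = ""
  )
  invisible(x)
}

#' ppm axis of a spectrum
#' @param spectrum An `mrs_spectrum`.
#' @return Numeric ppm vector (strictly increasing).
#' @export
spectrum_ppm <- function(spectrum) {
  ppm_axis(
    length(spectrum$values), spectrum$spectral_width,
    spectrum$frequency_mhz, spectrum$water_ppm
  )
}

## residual for the single-Voigt water model, stacked (Re, Im)
water_model_resid <- function(par, samples, t) {
  model <- par[["amp"]] * exp(1i * par[["phase"]]) *
    exp(1i * 2 * pi * par[["freq"]] * t) *
    voigt_decay(t, abs(par[["lw"]]), 0)
  d <- samples - model
  c(Re(d), Im(d))
}

num_jacobian <- function(fn, par, eps = 1e-6) {
  f0 <- fn(par)
  J <- matrix(0, nrow = length(f0), ncol = length(par))
  for (j in seq_along(par)) {
    h <- eps * max(abs(par[j]), 1)
    pj <- par
    pj[j] <- pj[j] + h
    J[, j] <- (fn(pj) - f0) / h
  }
  J
}

#' Fit the water resonance of one single shot
#'
#' Nonlinear least squares of one Lorentzian water line (amplitude, frequency,
#' zero-order phase, linewidth) to the leading portion of the time-domain
#' shot, where the unsuppressed water dominates everything else by orders of
#' magnitude.  Relative uncertainties come from the local curvature of the
#' objective (Gauss-Newton covariance).
#'
#' @param transient A single shot (list with `samples`, `shot_index`).
#' @param acq The acquisition configuration.
#' @param n_fit_points Number of leading time-domain points used in the fit.
#' @return A one-row tibble (class retained): `shot_index`, `amplitude`,
#'   `amp_rel_unc`, `frequency`, `freq_unc`, `phase_deg`, `linewidth`,
#'   `lw_rel_unc`, `converged`.  Non-convergence is flagged with infinite
#'   uncertainties, never an error.
#' @export
fit_water_shot <- function(transient, acq, n_fit_points = 512) {
  n <- min(n_fit_points, acq$n_points)
  s <- transient$samples[seq_len(n)]
  t <- time_axis(acq$n_points, acq$spectral_width)[seq_len(n)]

  ## starting values: peak of the truncated spectrum, first-point magnitude
  ## and phase, log-magnitude decay slope
  sp <- fid_to_spec(s)
  f <- freq_axis(n, acq$spectral_width)
  f0 <- f[which.max(abs(sp))]
  mag <- abs(s)
  half <- max(2L, n %/% 2L)
  slope <- (log(mag[half] + 1e-300) - log(mag[1] + 1e-300)) / (t[half] - t[1])
  lw0 <- max(-slope / pi, 0.5)
  start <- c(
    amp = mag[1], freq = f0, phase = Arg(s[1]) - 2 * pi * f0 * t[1], lw = lw0
  )

  failed <- tibble::tibble(
    shot_index = transient$shot_index, amplitude = NA_real_,
    amp_rel_unc = Inf, frequency = NA_real_, freq_unc = Inf,
    phase_deg = NA_real_, linewidth = NA_real_, lw_rel_unc = Inf,
    converged = FALSE
  )
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = start, fn = water_model_resid, samples = s, t = t,
      control = minpack.lm::nls.lm.control(maxiter = 60)
    ),
    error = function(e) NULL
  )
  if (is.null(fit) || !fit$info %in% 1:4) {
    return(failed)
  }
  par <- fit$par
  par[["lw"]] <- abs(par[["lw"]])
  m <- 2L * n
  sigma2 <- fit$deviance / max(m - length(par), 1)
  J <- num_jacobian(function(p) water_model_resid(p, s, t), unlist(par))
  cov <- tryCatch(sigma2 * solve(crossprod(J)), error = function(e) NULL)
  sds <- if (is.null(cov)) rep(Inf, 4) else sqrt(pmax(diag(cov), 0))
  tibble::tibble(
    shot_index = transient$shot_index,
    amplitude = par[["amp"]],
    amp_rel_unc = sds[1] / abs(par[["amp"]]),
    frequency = par[["freq"]],
    freq_unc = sds[2],
    phase_deg = rad2deg(par[["phase"]]),
    linewidth = par[["lw"]],
    lw_rel_unc = sds[4] / par[["lw"]],
    converged = TRUE
  )
}

#' Fit the water line of every shot in a transient set
#' @param transients An `mrs_transients` object.
#' @param n_fit_points Passed to [fit_water_shot()].
#' @return A tibble with one row per shot.
#' @export
fit_water_shots <- function(transients, n_fit_points = 512) {
  purrr::map_dfr(
    transients$shots, fit_water_shot,
    acq = transients$acq, n_fit_points = n_fit_points
  )
}

#' Motion-compensation shot rejection
#'
#' A shot is excluded if (a) the relative fitting uncertainty of its water
#' amplitude or linewidth exceeds 5% (strict inequality), or (b) any of its
#' water frequency, amplitude or linewidth deviates from the robust centre of
#' the shot ensemble (median) by more than `mad_k` robust SDs (1.4826 x MAD).
#' Reasons are recorded per shot.
#'
#' @param fits Tibble from [fit_water_shots()]; at least 4 rows.
#' @param max_rel_uncertainty Uncertainty threshold (default 0.05).
#' @param mad_k Robust z-score threshold (default 3).
#' @return List with `kept` and `excluded` (shot indices) and `report`, a
#'   per-shot tibble (`shot_index`, features, `kept`, `reason`).
#' @export
reject_shots <- function(fits, max_rel_uncertainty = 0.05, mad_k = 3) {
  if (nrow(fits) < 4) stop("need at least 4 shot fits", call. = FALSE)
  robust_z <- function(x) {
    med <- stats::median(x, na.rm = TRUE)
    dev <- abs(x - med)
    s <- 1.4826 * stats::median(dev, na.rm = TRUE)
    ifelse(dev == 0, 0, dev / s) # s == 0 with dev > 0 => Inf => outlier
  }
  z_f <- robust_z(fits$frequency)
  z_a <- robust_z(fits$amplitude)
  z_l <- robust_z(fits$linewidth)
  bad_unc <- !fits$converged |
    fits$amp_rel_unc > max_rel_uncertainty |
    fits$lw_rel_unc > max_rel_uncertainty
  bad_out <- z_f > mad_k | z_a > mad_k | z_l > mad_k
  bad_out[is.na(bad_out)] <- TRUE

  reason <- character(nrow(fits))
  reason[bad_out] <- "outlier"
  reason[bad_unc] <- "uncertainty"
  reason[bad_unc & bad_out] <- "uncertainty+outlier"
  excluded <- bad_unc | bad_out

  if (all(excluded)) {
    dom <- names(sort(table(reason[excluded]), decreasing = TRUE))[1]
    stop("all shots excluded (dominant reason: ", dom, ")", call. = FALSE)
  }
  report <- dplyr::mutate(fits,
    z_frequency = z_f, z_amplitude = z_a, z_linewidth = z_l,
    kept = !excluded, reason = dplyr::if_else(excluded, reason, "")
  )
  list(
    kept = fits$shot_index[!excluded],
    excluded = fits$shot_index[excluded],
    report = report
  )
}

#' Correct kept shots and combine them by the metabolite-cycling scheme
#'
#' Each kept shot is frequency-shifted and zero-order-phased to its own water
#' fit; this demodulation by the water model phase (zero-order plus linear
#' term) also serves as the eddy-current correction.  With `klose = TRUE` the
#' residual time-dependent phase of the smoothed water signal is additionally
#' subtracted.  Cycling pairs are then combined — half-difference giving the
#' metabolite spectrum, half-sum the water spectrum — and all pairs of all
#' runs are averaged.  Shots whose cycling partner was rejected are dropped
#' with a warning.
#'
#' @param transients An `mrs_transients` object.
#' @param fits Per-shot water fits aligned with the transients.
#' @param kept Shot indices to keep (from [reject_shots()]).
#' @param klose Subtract residual smoothed water phase (default `FALSE`).
#' @return List with `metabolite` and `water`, both `mrs_spectrum` objects.
#' @export
correct_and_combine <- function(transients, fits, kept, klose = FALSE) {
  if (length(kept) == 0) stop("no shots kept", call. = FALSE)
  acq <- transients$acq
  t <- time_axis(acq$n_points, acq$spectral_width)
  shots <- transients$shots[order(purrr::map_int(transients$shots, "shot_index"))]
  idx <- purrr::map_int(shots, "shot_index")
  fitrow <- match(idx, fits$shot_index)

  corrected <- vector("list", length(shots))
  for (i in seq_along(shots)) {
    if (!idx[i] %in% kept) next
    fr <- fits[fitrow[i], ]
    phase <- 2 * pi * fr$frequency * t + deg2rad(fr$phase_deg)
    s <- shots[[i]]$samples * exp(-1i * phase)
    if (klose) {
      k <- rep(1 / 33, 33)
      wr <- as.numeric(stats::filter(Re(s), k, sides = 2))
      wi <- as.numeric(stats::filter(Im(s), k, sides = 2))
      na <- is.na(wr)
      w <- complex(real = wr, imaginary = wi)
      w[na] <- s[na]
      s <- s * exp(-1i * unwrap_phase(Arg(w)))
    }
    corrected[[i]] <- s
  }

  met_sum <- complex(length.out = acq$n_points)
  wat_sum <- complex(length.out = acq$n_points)
  n_pairs <- 0L
  n_orphans <- 0L
  for (i in seq(1, length(shots) - 1, by = 2)) {
    a <- corrected[[i]]
    b <- corrected[[i + 1]]
    if (is.null(a) || is.null(b)) {
      if (xor(is.null(a), is.null(b))) n_orphans <- n_orphans + 1L
      next
    }
    ca <- shots[[i]]$cycling_state
    cb <- shots[[i + 1]]$cycling_state
    met_sum <- met_sum + (ca * a + cb * b) / 2
    wat_sum <- wat_sum + (a + b) / 2
    n_pairs <- n_pairs + 1L
  }
  if (n_pairs == 0) stop("no complete cycling pairs after rejection", call. = FALSE)
  if (n_orphans > 0) {
    warning(n_orphans, " orphaned cycling shot(s) dropped", call. = FALSE)
  }
  prov <- list(
    n_shots_kept = 2L * n_pairs,
    n_shots_excluded = length(shots) - 2L * n_pairs,
    runs = sort(unique(purrr::map_int(shots, "run_index")))
  )
  mk <- function(fid) {
    new_spectrum(fid_to_spec(fid / n_pairs),
      spectral_width = acq$spectral_width,
      frequency_mhz = acq$spectrometer_frequency,
      water_ppm = acq$water_ppm, provenance = prov
    )
  }
  list(metabolite = mk(met_sum), water = mk(wat_sum))
}

#' Full shot-level preprocessing chain
#'
#' Water fits, motion rejection, correction, cycling combination and residual
#' water removal in one call.
#'
#' @param transients An `mrs_transients` object.
#' @param max_rel_uncertainty,mad_k Rejection thresholds ([reject_shots()]).
#' @param water_band_ppm Residual-water removal band ([remove_residual_water()]).
#' @param model_order HSVD model order.
#' @param klose Passed to [correct_and_combine()].
#' @return List with `metabolite` (water-removed), `water`, and `qc` (the
#'   per-shot report tibble).
#' @export
preprocess_subject <- function(transients, max_rel_uncertainty = 0.05,
                               mad_k = 3, water_band_ppm = c(4.28, 5.08),
                               model_order = 16, klose = FALSE) {
  fits <- fit_water_shots(transients)
  rej <- reject_shots(fits,
    max_rel_uncertainty = max_rel_uncertainty, mad_k = mad_k
  )
  spectra <- correct_and_combine(transients, fits, rej$kept, klose = klose)
  met <- remove_residual_water(spectra$metabolite,
    water_band_ppm = water_band_ppm, model_order = model_order
  )
  list(metabolite = met, water = spectra$water, qc = rej$report)
}
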