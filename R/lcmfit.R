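#' Voigt-line macromolecular background model
#'
#' The macromolecular background (MMBG) is a comb of equally spaced Voigt
#' lines — 5 Hz spacing, 14 Hz Lorentz width, and a region-specific Gauss
#' width of 7.8 Hz in the brain and 0.7 Hz in the spinal cord.  The line
#' amplitude profile is fixed once estimated from a cohort average of healthy
#' controls ([estimate_mmbg()]); only an overall scale stays free during
#' subject fits.
#'
#' @param region `"brain"` or `"cord"`.
#' @param window_ppm ppm interval the comb spans.
#' @param spacing_hz Line spacing in Hz (default 5).
#' @param lorentz_fwhm Lorentz width in Hz (default 14).
#' @param gauss_fwhm Gauss width in Hz; region default if `NULL`.
#' @param frequency_mhz,water_ppm Axis calibration.
#' @param amplitudes Fixed line amplitudes (default zero until estimated).
#' @return A list of class `mrs_mmbg`.
#' @export
mmbg_model <- function(region = c("brain", "cord"),
                       window_ppm = c(0.5, 4.2),
                       spacing_hz = 5, lorentz_fwhm = 14,
                       gauss_fwhm = NULL,
                       frequency_mhz = 123.25, water_ppm = 4.68,
                       amplitudes = NULL) {
  region <- match.arg(region)
  if (is.null(gauss_fwhm)) gauss_fwhm <- if (region == "brain") 7.8 else 0.7
  stopifnot(spacing_hz > 0, lorentz_fwhm > 0, gauss_fwhm > 0)
  hz <- sort(ppm_to_hz(window_ppm, frequency_mhz, water_ppm))
  freq_hz <- seq(hz[1], hz[2], by = spacing_hz)
  if (is.null(amplitudes)) amplitudes <- rep(0, length(freq_hz))
  stopifnot(length(amplitudes) == length(freq_hz), all(amplitudes >= 0))
  structure(
    list(
      region = region, freq_hz = freq_hz, spacing_hz = spacing_hz,
      lorentz_fwhm = lorentz_fwhm, gauss_fwhm = gauss_fwhm,
      amplitudes = amplitudes, frequency_mhz = frequency_mhz,
      water_ppm = water_ppm, window_ppm = window_ppm
    ),
    class = "mrs_mmbg"
  )
}

#' @export
print.mrs_mmbg <- function(x, ...) {
  cat("<mrs_mmbg> ", x$region, ": ", length(x$freq_hz), " Voigt lines, ",
    x$spacing_hz, " Hz spacing, ", x$lorentz_fwhm, "/", x$gauss_fwhm,
    " Hz Lorentz/Gauss\n",
    sep = ""
  )
  invisible(x)
}

## unit-scale MMBG FID at the model's fixed line amplitudes
mmbg_fid <- function(mmbg, n_points, spectral_width) {
  if (all(mmbg$amplitudes == 0)) {
    return(complex(length.out = n_points))
  }
  t <- time_axis(n_points, spectral_width)
  lines <- data.frame(
    freq_hz = mmbg$freq_hz, amp = mmbg$amplitudes,
    lorentz_fwhm = mmbg$lorentz_fwhm
  )
  lines_fid(t, lines, gauss_fwhm = mmbg$gauss_fwhm)
}

## FID matrix of the individual comb lines (for MMBG estimation)
mmbg_comb_fids <- function(mmbg, n_points, spectral_width) {
  t <- time_axis(n_points, spectral_width)
  out <- matrix(0i, nrow = n_points, ncol = length(mmbg$freq_hz))
  for (j in seq_along(mmbg$freq_hz)) {
    out[, j] <- lines_fid(
      t,
      data.frame(
        freq_hz = mmbg$freq_hz[j], amp = 1, lorentz_fwhm = mmbg$lorentz_fwhm
      ),
      gauss_fwhm = mmbg$gauss_fwhm
    )
  }
  out
}

## stacked real/imag design vector for the fit window
stack_ri <- function(x) c(Re(x), Im(x))

window_index <- function(spectrum, window_ppm) {
  ppm <- spectrum_ppm(spectrum)
  which(ppm >= window_ppm[1] & ppm <= window_ppm[2])
}

#' Estimate the spectral noise SD
#'
#' SD of the real part in a signal-free ppm region (default 10.5-12 ppm,
#' falling back to the top decile of the axis when the region is absent).
#'
#' @param spectrum An `mrs_spectrum`.
#' @param region ppm interval assumed signal-free.
#' @return Noise SD per spectral point (real/imaginary channel).
#' @export
estimate_noise_sd <- function(spectrum, region = c(10.5, 12)) {
  ppm <- spectrum_ppm(spectrum)
  idx <- which(ppm >= region[1] & ppm <= region[2])
  if (length(idx) < 16) idx <- which(ppm >= stats::quantile(ppm, 0.9))
  stats::sd(Re(spectrum$values[idx]))
}

## Shared machinery: windowed design matrix for given nonlinear parameters.
## All columns — metabolites and MMBG — share the subject's extra Voigt
## decay, global shift and zero-order phase: shim-driven broadening acts on
## the macromolecular lines just as on the metabolites.
lcm_design <- function(theta, prep) {
  decay <- voigt_decay(prep$t, abs(theta[["lorentz"]]), abs(theta[["gauss"]])) *
    exp(1i * (2 * pi * theta[["shift"]] * prep$t + theta[["phase"]]))
  cols <- cbind(prep$bfids, prep$mcols) * decay
  sp <- stats::mvfft(cols)
  sp <- sp[c((nrow(sp) %/% 2 + 1):nrow(sp), 1:(nrow(sp) %/% 2)), , drop = FALSE] /
    sqrt(nrow(sp))
  w <- sp[prep$idx, , drop = FALSE]
  rbind(Re(w), Im(w))
}

lcm_prep <- function(spectrum, basis, mmbg, window_ppm, comb = FALSE) {
  n <- length(spectrum$values)
  sw <- spectrum$spectral_width
  mcols <- if (comb) {
    mmbg_comb_fids(mmbg, n, sw)
  } else {
    matrix(mmbg_fid(mmbg, n, sw), ncol = 1)
  }
  list(
    t = time_axis(n, sw),
    bfids = basis_fids(basis, n, sw),
    mcols = mcols,
    idx = window_index(spectrum, window_ppm),
    names = c(
      metabolite_names(basis),
      if (comb) paste0("mmbg_", seq_len(ncol(mcols))) else "mmbg"
    )
  )
}

lcm_solve <- function(theta, prep, b, penalty = NULL) {
  A <- lcm_design(theta, prep)
  A_fit <- A
  b_fit <- b
  if (!is.null(penalty)) {
    A_fit <- rbind(A, penalty)
    b_fit <- c(b, numeric(nrow(penalty)))
  }
  drop <- which(colSums(abs(A_fit)) == 0) # e.g. zero MMBG column before estimation
  if (length(drop)) {
    x <- numeric(ncol(A))
    fit <- pracma::lsqnonneg(A_fit[, -drop, drop = FALSE], b_fit)
    x[-drop] <- fit$x
  } else {
    x <- pracma::lsqnonneg(A_fit, b_fit)$x
  }
  list(x = x, resid = b - A %*% x, A = A)
}

#' Linear-combination model fit of an averaged metabolite spectrum
#'
#' Fits the spectrum over the ppm window as a non-negative linear combination
#' of the 18 parametric metabolite basis spectra plus the fixed-shape MMBG
#' (free overall scale), with four shared nonlinear parameters: common Gauss
#' linewidth, common extra Lorentz width, global frequency shift, and
#' zero-order phase.  Amplitudes are profiled out by non-negative least
#' squares at each step of the nonlinear optimisation (variable projection),
#' which makes the fit deterministic given its starting values.
#'
#' @param spectrum A preprocessed `mrs_spectrum` (water removed).
#' @param basis An [load_basis()] basis set.
#' @param mmbg An [mmbg_model()] (typically from [estimate_mmbg()]).
#' @param window_ppm Fit window in ppm (default 0.5-4.2).
#' @param start Starting values for `c(gauss, lorentz, shift, phase)`.
#' @param noise_region ppm interval for the noise estimate.
#' @return An object of class `mrs_lcm_fit`: `amplitudes` (named, institution
#'   units; last element `mmbg` is the background scale), `crlb` (same units),
#'   `gauss_lw`, `lorentz_lw`, `shift_hz`, `phase_deg`, `residual`,
#'   `noise_sd`, `converged`, and the model context needed by
#'   [compute_crlb()].  Non-convergence is flagged with infinite CRLBs.
#' @export
fit_lcm <- function(spectrum, basis, mmbg, window_ppm = c(0.5, 4.2),
                    start = c(gauss = 3, lorentz = 0.5, shift = 0, phase = 0),
                    noise_region = c(10.5, 12)) {
  stopifnot(inherits(spectrum, "mrs_spectrum"), inherits(mmbg, "mrs_mmbg"))
  prep <- lcm_prep(spectrum, basis, mmbg, window_ppm)
  b <- stack_ri(spectrum$values[prep$idx])
  noise_sd <- estimate_noise_sd(spectrum, noise_region)

  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = start,
      fn = function(theta) as.vector(lcm_solve(theta, prep, b)$resid),
      lower = c(0, 0, -30, -pi / 2), upper = c(25, 25, 30, pi / 2),
      control = minpack.lm::nls.lm.control(maxiter = 100, ptol = 1e-10)
    ),
    error = function(e) NULL
  )
  converged <- !is.null(fit) && fit$info %in% 1:4
  theta <- if (converged) fit$par else start
  sol <- lcm_solve(theta, prep, b)
  amps <- stats::setNames(as.vector(sol$x), prep$names)

  out <- structure(
    list(
      amplitudes = amps,
      gauss_lw = theta[["gauss"]], lorentz_lw = theta[["lorentz"]],
      shift_hz = theta[["shift"]], phase_deg = rad2deg(theta[["phase"]]),
      residual = as.vector(sol$resid), noise_sd = noise_sd,
      window_ppm = window_ppm, converged = converged,
      basis = basis, mmbg = mmbg,
      spectrum_meta = list(
        n = length(spectrum$values), spectral_width = spectrum$spectral_width,
        frequency_mhz = spectrum$frequency_mhz, water_ppm = spectrum$water_ppm
      ),
      theta = theta, prep = prep, b = b
    ),
    class = "mrs_lcm_fit"
  )
  out$crlb <- compute_crlb(out)
  out
}

#' @export
print.mrs_lcm_fit <- function(x, ...) {
  cat("<mrs_lcm_fit> ", sum(x$amplitudes > 0), " nonzero amplitudes, Gauss lw ",
    round(x$gauss_lw, 2), " Hz, converged: ", x$converged, "\n",
    sep = ""
  )
  invisible(x)
}

#' Cramer-Rao lower bounds of a linear-combination fit
#'
#' Builds the Fisher information from the model Jacobian at the solution —
#' over all amplitudes and the shared nonlinear parameters — and the
#' estimated complex noise variance; the CRLB of a parameter is the square
#' root of the corresponding diagonal element of the inverse information.
#' Bounds are reported per metabolite individually; no bounds for sums are
#' produced.  A singular information matrix yields infinite CRLBs.
#'
#' @param result An `mrs_lcm_fit`.
#' @param noise_sd Noise SD; defaults to the estimate stored in `result`.
#' @return Named vector of amplitude CRLBs (same units as the amplitudes).
#' @export
compute_crlb <- function(result, noise_sd = NULL) {
  stopifnot(inherits(result, "mrs_lcm_fit"))
  if (is.null(noise_sd)) noise_sd <- result$noise_sd
  if (!result$converged || !is.finite(noise_sd) || noise_sd < 0) {
    return(stats::setNames(
      rep(Inf, length(result$amplitudes)), names(result$amplitudes)
    ))
  }
  p_amp <- length(result$amplitudes)
  J <- lcm_model_jacobian(result)
  ## structurally absent components (all-zero sensitivity, e.g. an MMBG with
  ## zero line amplitudes) carry no information: infinite bound, silently
  live <- colSums(abs(J)) > 0
  crlb_all <- rep(Inf, ncol(J))
  if (any(live)) {
    ## invert J'J by SVD so the sigma scaling stays exact at any noise
    ## level; directions with negligible curvature are unidentifiable and
    ## propagate an infinite bound to the parameters loading on them
    G <- crossprod(J[, live, drop = FALSE])
    sv <- svd(G)
    ok <- sv$d > 1e-12 * sv$d[1]
    if (!all(ok)) {
      warning("near-singular Fisher information for some parameters",
        call. = FALSE
      )
    }
    dinv <- vapply(seq_len(nrow(G)), function(i) {
      v <- sv$v[i, ]
      if (any(!ok & abs(v) > 1e-6)) {
        return(Inf)
      }
      sum(v[ok]^2 / sv$d[ok])
    }, numeric(1))
    crlb_all[live] <- noise_sd * sqrt(dinv)
  }
  stats::setNames(crlb_all[seq_len(p_amp)], names(result$amplitudes))
}

## full model Jacobian at the solution: columns are all amplitudes followed
## by the four shared nonlinear parameters
lcm_model_jacobian <- function(result) {
  prep <- result$prep
  amps <- result$amplitudes
  theta <- result$theta
  p_amp <- length(amps)
  model_fn <- function(par) {
    a <- par[seq_len(p_amp)]
    th <- par[(p_amp + 1):length(par)]
    names(th) <- c("gauss", "lorentz", "shift", "phase")
    as.vector(lcm_design(th, prep) %*% a)
  }
  num_jacobian(model_fn, c(amps, theta))
}

#' Covariance of the fitted amplitudes
#'
#' Moore-Penrose inverse of the Fisher information, restricted to the
#' amplitude block.  Unlike the individual CRLBs this carries the
#' cross-metabolite correlations, so uncertainties of derived sums
#' (tNAA, tCr, tCho) propagate correctly:
#' `var(sum) = 1' Cov 1` over the summed rows.
#'
#' @param result An `mrs_lcm_fit`.
#' @param noise_sd Noise SD; defaults to the fit's estimate.
#' @return A named covariance matrix over the amplitude parameters.
#' @export
amplitude_covariance <- function(result, noise_sd = NULL) {
  stopifnot(inherits(result, "mrs_lcm_fit"))
  if (is.null(noise_sd)) noise_sd <- result$noise_sd
  p_amp <- length(result$amplitudes)
  nm <- names(result$amplitudes)
  if (!result$converged || !is.finite(noise_sd) || noise_sd < 0) {
    m <- matrix(Inf, p_amp, p_amp, dimnames = list(nm, nm))
    return(m)
  }
  J <- lcm_model_jacobian(result)
  live <- colSums(abs(J)) > 0
  G <- crossprod(J[, live, drop = FALSE])
  sv <- svd(G)
  ok <- sv$d > 1e-12 * sv$d[1]
  Ginv <- sv$v[, ok, drop = FALSE] %*%
    (t(sv$v[, ok, drop = FALSE]) / sv$d[ok])
  cov_all <- matrix(Inf, length(live), length(live))
  cov_all[live, live] <- noise_sd^2 * Ginv
  out <- cov_all[seq_len(p_amp), seq_len(p_amp), drop = FALSE]
  dimnames(out) <- list(nm, nm)
  out
}

#' Estimate the MMBG line-amplitude profile from healthy-control spectra
#'
#' Averages at least two control spectra and jointly fits the metabolite
#' basis plus every individual Voigt comb line (non-negative amplitudes,
#' shared nonlinear parameters).  The resulting line amplitudes become the
#' fixed MMBG shape used in subject fits, where only an overall scale is
#' free.
#'
#' @param spectra List of at least two control `mrs_spectrum` objects.
#' @param basis Basis set.
#' @param region `"brain"` or `"cord"` — sets the region's Gauss width.
#' @param window_ppm Fit window.
#' @param smoothness Weight of a second-difference roughness penalty on the
#'   comb line amplitudes, relative to the design-column scale.  The
#'   macromolecular background is broad by nature; the penalty keeps the
#'   comb from sharpening into metabolite peaks during the joint fit.
#' @return An [mmbg_model()] with estimated `amplitudes`.
#' @export
estimate_mmbg <- function(spectra, basis, region = c("brain", "cord"),
                          window_ppm = c(0.5, 4.2), smoothness = 0.5) {
  region <- match.arg(region)
  if (!is.list(spectra) || length(spectra) < 2) {
    stop("MMBG estimation needs at least 2 control spectra", call. = FALSE)
  }
  avg <- spectra[[1]]
  vals <- purrr::reduce(purrr::map(spectra, "values"), `+`) / length(spectra)
  avg$values <- vals

  mmbg0 <- mmbg_model(
    region = region, window_ppm = window_ppm,
    frequency_mhz = avg$frequency_mhz, water_ppm = avg$water_ppm
  )
  prep <- lcm_prep(avg, basis, mmbg0, window_ppm, comb = TRUE)
  b <- stack_ri(avg$values[prep$idx])

  ## roughness penalty rows: lambda * second difference over comb amplitudes
  n_met <- length(metabolite_names(basis))
  n_comb <- length(mmbg0$freq_hz)
  penalty <- NULL
  if (smoothness > 0 && n_comb >= 3) {
    A0 <- lcm_design(c(gauss = 3, lorentz = 0.5, shift = 0, phase = 0), prep)
    col_scale <- mean(sqrt(colSums(
      A0[, n_met + seq_len(n_comb), drop = FALSE]^2
    )))
    D <- matrix(0, nrow = n_comb - 2, ncol = n_met + n_comb)
    for (i in seq_len(n_comb - 2)) {
      D[i, n_met + i + 0:2] <- c(1, -2, 1)
    }
    penalty <- smoothness * col_scale * D
  }

  start <- c(gauss = 3, lorentz = 0.5, shift = 0, phase = 0)
  fit <- minpack.lm::nls.lm(
    par = start,
    fn = function(theta) as.vector(lcm_solve(theta, prep, b, penalty)$resid),
    lower = c(0, 0, -30, -pi / 2), upper = c(25, 25, 30, pi / 2),
    control = minpack.lm::nls.lm.control(maxiter = 60, ptol = 1e-9)
  )
  sol <- lcm_solve(fit$par, prep, b, penalty)
  x <- as.vector(sol$x)

  ## alternating refinement: the one-shot penalised split trades metabolite
  ## against background shape; re-fitting each block against the other's
  ## residual sharpens the separation (narrow peaks vs broad comb are close
  ## to orthogonal, so this converges quickly)
  A <- lcm_design(fit$par, prep)
  A_met <- A[, seq_len(n_met), drop = FALSE]
  A_comb <- A[, n_met + seq_len(n_comb), drop = FALSE]
  light <- if (is.null(penalty)) NULL else {
    penalty[, n_met + seq_len(n_comb), drop = FALSE] / 4
  }
  for (it in seq_len(5)) {
    met_part <- A_comb %*% x[n_met + seq_len(n_comb)]
    x_met <- pracma::lsqnonneg(A_met, as.vector(b - met_part))$x
    comb_target <- as.vector(b - A_met %*% x_met)
    if (is.null(light)) {
      x_comb <- pracma::lsqnonneg(A_comb, comb_target)$x
    } else {
      x_comb <- pracma::lsqnonneg(
        rbind(A_comb, light), c(comb_target, numeric(nrow(light)))
      )$x
    }
    x <- c(x_met, x_comb)
  }
  mmbg0$amplitudes <- x[(n_met + 1):length(x)]
  mmbg0
}
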