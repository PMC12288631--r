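#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a linear-combination fit
#'
#' @param x An `mrs_lcm_fit`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate` (amplitude) and `crlb`.
#' @export
tidy.mrs_lcm_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$amplitudes),
    estimate = unname(x$amplitudes),
    crlb = unname(x$crlb[names(x$amplitudes)])
  )
}

#' One-row summary of a linear-combination fit
#'
#' @param x An `mrs_lcm_fit`.
#' @param ... Unused.
#' @return Tibble with the shared nonlinear parameters, residual RMS, noise
#'   SD and convergence flag.
#' @export
glance.mrs_lcm_fit <- function(x, ...) {
  tibble::tibble(
    gauss_lw = x$gauss_lw, lorentz_lw = x$lorentz_lw,
    shift_hz = x$shift_hz, phase_deg = x$phase_deg,
    residual_rms = sqrt(mean(x$residual^2)),
    noise_sd = x$noise_sd, converged = x$converged
  )
}

#' Tidy a water echo series
#'
#' @param x An `mrs_water_series`.
#' @param ... Unused.
#' @return Tibble with `te` (ms) and `amplitude`.
#' @export
tidy.mrs_water_series <- function(x, ...) {
  tibble::tibble(te = x$te_list, amplitude = x$amplitudes)
}

#' Tidy a spectrum into a ppm-indexed tibble
#'
#' @param x An `mrs_spectrum`.
#' @param ... Unused.
#' @return Tibble with `ppm`, `real`, `imaginary`, `magnitude`.
#' @export
tidy.mrs_spectrum <- function(x, ...) {
  tibble::tibble(
    ppm = spectrum_ppm(x),
    real = Re(x$values), imaginary = Im(x$values),
    magnitude = abs(x$values)
  )
}
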