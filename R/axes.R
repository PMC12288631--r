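#' @keywords internal
#' @importFrom rlang .data
"_PACKAGE"

## FFT conventions used throughout the package.
##
## A transient (FID) is a complex vector sampled at dwell time 1/spectral_width.
## Its spectrum is the unitary DFT, shifted so that frequency runs from
## -sw/2 to +sw/2 - sw/n in increasing order.  The 1/sqrt(n) scaling makes the
## transform energy-preserving (Parseval), so noise levels are directly
## comparable between domains.

fft_shift <- function(x) {
  n <- length(x)
  h <- n %/% 2
  c(x[(h + 1L):n], x[1L:h])
}

ifft_shift <- function(x) {
  n <- length(x)
  h <- n %/% 2
  c(x[(n - h + 1L):n], x[1L:(n - h)])
}

#' Transform a time-domain transient to a spectrum
#'
#' Unitary DFT with the zero-frequency bin shifted to the centre, so that
#' `sum(abs(fid)^2) == sum(abs(spec)^2)`.
#'
#' @param fid Complex time-domain samples.
#' @return Complex frequency-domain samples, frequencies increasing.
#' @export
fid_to_spec <- function(fid) {
  fft_shift(stats::fft(fid)) / sqrt(length(fid))
}

#' Inverse of [fid_to_spec()]
#' @param spec Complex frequency-domain samples (as from [fid_to_spec()]).
#' @return Complex time-domain samples.
#' @export
spec_to_fid <- function(spec) {
  n <- length(spec)
  stats::fft(ifft_shift(spec), inverse = TRUE) / sqrt(n)
}

## Axis helpers.  Frequency offsets are in Hz relative to the carrier, which
## sits on the water resonance (water_ppm, default 4.68 ppm).  The ppm value of
## an offset f is water_ppm + f / f0 with f0 the spectrometer frequency in MHz,
## so NAA at 2.01 ppm lies at about -329 Hz at 3 T.

time_axis <- function(n_points, spectral_width) {
  (seq_len(n_points) - 1L) / spectral_width
}

freq_axis <- function(n_points, spectral_width) {
  (seq_len(n_points) - 1L - n_points %/% 2L) * spectral_width / n_points
}

#' ppm axis for a spectrum
#'
#' @param n_points Number of complex points.
#' @param spectral_width Spectral width in Hz.
#' @param frequency_mhz Spectrometer frequency in MHz.
#' @param water_ppm Chemical shift of the carrier (water), in ppm.
#' @return Numeric vector of ppm values, strictly increasing.
#' @export
ppm_axis <- function(n_points, spectral_width, frequency_mhz, water_ppm = 4.68) {
  water_ppm + freq_axis(n_points, spectral_width) / frequency_mhz
}

ppm_to_hz <- function(ppm, frequency_mhz, water_ppm = 4.68) {
  (ppm - water_ppm) * frequency_mhz
}

## Time-domain Voigt line: Lorentz and Gauss widths are FWHM in Hz.
## Lorentzian decay exp(-pi*L*t); Gaussian decay exp(-(pi*G*t)^2 / (4 log 2)).
voigt_decay <- function(t, lorentz_fwhm, gauss_fwhm) {
  d <- exp(-pi * lorentz_fwhm * t)
  if (gauss_fwhm > 0) d <- d * exp(-(pi * gauss_fwhm * t)^2 / (4 * log(2)))
  d
}

## FID of a sum of Voigt lines. `lines` is a data frame with columns
## freq_hz, amp, lorentz_fwhm (per line); shared gauss FWHM, phase in radians.
lines_fid <- function(t, lines, gauss_fwhm = 0, phase_rad = 0, freq_shift_hz = 0) {
  fid <- complex(length.out = length(t))
  for (i in seq_len(nrow(lines))) {
    fid <- fid + lines$amp[i] *
      exp(1i * 2 * pi * (lines$freq_hz[i] + freq_shift_hz) * t) *
      voigt_decay(t, lines$lorentz_fwhm[i], gauss_fwhm)
  }
  fid * exp(1i * phase_rad)
}

## Phase unwrapping for eddy-current style corrections.
unwrap_phase <- function(phi) {
  dp <- diff(phi)
  dp <- dp - 2 * pi * round(dp / (2 * pi))
  cumsum(c(phi[1], dp))
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

## Deterministic seed splitting: derive child stream seeds from a master seed
## and integer indices, keeping everything below 2^31 (R integers are 32-bit).
derive_seed <- function(master, ...) {
  idx <- c(...)
  s <- as.double(master) %% 2147483647
  for (k in idx) {
    s <- (s * 48271 + as.double(k) * 2654435761) %% 2147483647
  }
  as.integer(s %% 2147483647)
}
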