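#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a spectrum
#'
#' Real part against chemical shift, ppm decreasing left to right as is
#' conventional in NMR.
#'
#' @param object An `mrs_spectrum`.
#' @param xlim ppm window to display (default 0.5-4.5).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mrs_spectrum <- function(object, xlim = c(0.5, 4.5), ...) {
  d <- tidy(object)
  d <- d[d$ppm >= xlim[1] & d$ppm <= xlim[2], ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$ppm, y = .data$real)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "chemical shift (ppm)", y = "signal (a.u.)") +
    ggplot2::theme_minimal()
}

#' Plot a linear-combination fit: data, model and residual
#'
#' @param object An `mrs_lcm_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mrs_lcm_fit <- function(object, ...) {
  idx <- object$prep$idx
  w <- length(idx)
  ppm <- ppm_axis(
    object$spectrum_meta$n, object$spectrum_meta$spectral_width,
    object$spectrum_meta$frequency_mhz, object$spectrum_meta$water_ppm
  )[idx]
  data_re <- object$b[seq_len(w)]
  resid_re <- object$residual[seq_len(w)]
  offset <- 1.1 * max(abs(data_re))
  d <- dplyr::bind_rows(
    tibble::tibble(ppm = ppm, y = data_re, trace = "data"),
    tibble::tibble(ppm = ppm, y = data_re - resid_re, trace = "fit"),
    tibble::tibble(ppm = ppm, y = resid_re + offset, trace = "residual")
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$ppm, .data$y, colour = .data$trace)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "chemical shift (ppm)", y = "signal (a.u.)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a water echo series and its two-compartment fit
#'
#' @param object An `mrs_water_series`.
#' @param fit Optional [fit_water_decay()] result to overlay.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mrs_water_series <- function(object, fit = NULL, ...) {
  d <- tidy(object)
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$te, .data$amplitude)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "TE (ms)", y = "water amplitude (a.u.)") +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    te <- seq(0, max(d$te), length.out = 200)
    curve <- tibble::tibble(
      te = te,
      amplitude = fit$s_par * exp(-te / fit$t2_par) +
        fit$s_csf * exp(-te / fit$t2_csf)
    )
    p <- p + ggplot2::geom_line(data = curve, colour = "steelblue")
  }
  p
}

#' Group dotplot of cohort metabolite ratios
#'
#' @param table Cohort tibble (as from [quantify_cohort()]).
#' @param outcomes Ratio columns to show.
#' @return A ggplot.
#' @export
plot_cohort <- function(table, outcomes = c("tnaa_tcr", "tcho_tcr", "mi_tcr")) {
  d <- tidyr::pivot_longer(
    table[c("subject_id", "group", intersect(outcomes, names(table)))],
    -c("subject_id", "group"),
    names_to = "outcome", values_to = "value"
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$group, .data$value)) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.7) +
    ggplot2::stat_summary(
      fun = stats::median, geom = "crossbar",
      width = 0.4, linewidth = 0.3, colour = "steelblue"
    ) +
    ggplot2::facet_wrap(~outcome, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "ratio to tCr") +
    ggplot2::theme_minimal()
}
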