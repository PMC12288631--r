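#' Two-compartment fit of the unsuppressed water echo series
#'
#' Least-squares fit of the biexponential TE decay
#' `S(TE) = S_par * exp(-TE/T2_par) + S_CSF * exp(-TE/T2_CSF)` to the
#' magnitude water amplitudes, separating the parenchymal from the CSF water
#' contribution.  If the optimum violates the `T2_par < T2_CSF` ordering the
#' compartments are relabelled.
#'
#' @param series An `mrs_water_series` (TE list in ms, magnitude amplitudes).
#' @param start Optional named starting values
#'   (`s_par`, `s_csf`, `t2_par`, `t2_csf`).
#' @return A tibble with one row: `s_par`, `s_csf`, `t2_par`, `t2_csf`,
#'   `s_total` (the TE=0 extrapolation `s_par + s_csf`), `rss`, `converged`.
#' @export
fit_water_decay <- function(series, start = NULL) {
  te <- series$te_list
  amp <- series$amplitudes
  if (length(unique(te)) < 5) {
    stop("need >= 5 distinct echo times", call. = FALSE)
  }
  if (length(te) != length(amp)) {
    stop("TE list and amplitudes differ in length", call. = FALSE)
  }
  if (is.null(start)) {
    a0 <- max(amp)
    start <- c(s_par = a0 * 0.9, s_csf = a0 * 0.1, t2_par = 80, t2_csf = 600)
  }
  resid_bi <- function(p) {
    amp - (abs(p[["s_par"]]) * exp(-te / abs(p[["t2_par"]])) +
      abs(p[["s_csf"]]) * exp(-te / abs(p[["t2_csf"]])))
  }
  resid_single <- function(p) {
    amp - abs(p[["s_par"]]) * exp(-te / abs(p[["t2_par"]]))
  }
  ctl <- minpack.lm::nls.lm.control(maxiter = 200)
  fit_bi <- minpack.lm::nls.lm(par = start, fn = resid_bi, control = ctl)
  fit_1 <- minpack.lm::nls.lm(
    par = start[c("s_par", "t2_par")], fn = resid_single, control = ctl
  )
  p <- abs(unlist(fit_bi$par))
  if (p[["t2_par"]] > p[["t2_csf"]]) {
    p <- p[c("s_csf", "s_par", "t2_csf", "t2_par")]
    names(p) <- c("s_par", "s_csf", "t2_par", "t2_csf")
  }
  ## a second compartment is only accepted when it is genuinely identified:
  ## distinct T2, non-negligible amplitude, and a real fit improvement --
  ## otherwise the decay collapses onto the degenerate single-compartment
  ## ridge and the parenchymal amplitude would be an arbitrary split
  use_bi <- fit_bi$deviance < 0.99 * fit_1$deviance &&
    p[["t2_csf"]] > 1.2 * p[["t2_par"]] &&
    p[["s_csf"]] > 1e-3 * (p[["s_par"]] + p[["s_csf"]])
  if (!use_bi) {
    q <- abs(unlist(fit_1$par))
    p <- c(
      s_par = q[["s_par"]], s_csf = 0,
      t2_par = q[["t2_par"]], t2_csf = Inf
    )
  }
  ## Gauss-Newton standard error of the parenchymal amplitude
  rss <- if (use_bi) fit_bi$deviance else fit_1$deviance
  n_par <- if (use_bi) 4L else 2L
  sigma2 <- rss / max(length(te) - n_par, 1)
  rf <- if (use_bi) resid_bi else resid_single
  pv <- if (use_bi) p[c("s_par", "s_csf", "t2_par", "t2_csf")] else p[c("s_par", "t2_par")]
  J <- num_jacobian(function(q) rf(q), pv)
  s_par_sd <- tryCatch(
    sqrt(sigma2 * solve(crossprod(J))[1, 1]),
    error = function(e) Inf
  )

  tibble::tibble(
    s_par = p[["s_par"]], s_csf = p[["s_csf"]],
    t2_par = p[["t2_par"]], t2_csf = p[["t2_csf"]],
    s_total = p[["s_par"]] + p[["s_csf"]],
    s_par_sd = s_par_sd,
    rss = rss,
    n_compartments = if (use_bi) 2L else 1L,
    converged = (if (use_bi) fit_bi$info else fit_1$info) %in% 1:4
  )
}

#' Quantification parameters for the absolute-concentration equation
#'
#' Every symbol of the millimolar conversion: metabolite and parenchymal
#' water signal (proton-scaled), sequence timing, metabolite relaxation
#' times, the semi-LASER T2 stretch factor, GM/WM volume fractions (CSF
#' excluded, so they must sum to 1), tissue water contents and the molar
#' water concentration.
#'
#' @param S_M Metabolite signal amplitude (per-molecule units).
#' @param S_H2O Parenchymal water amplitude at TE = 0, per-molecule units
#'   (i.e. already divided by the 2 protons of water).
#' @param TR,TE Sequence timing, ms.
#' @param T1,T2 Metabolite relaxation times, ms.
#' @param t2_stretch T2 stretch factor for semi-LASER (default 1.5).
#' @param f_GM,f_WM GM/WM volume fractions (sum to 1; CSF excluded).
#' @param d_GM,d_WM Tissue water contents (defaults 0.78 / 0.65).
#' @param H2O_molar Molar water concentration in mM (default 55500).
#' @return A list of class `mrs_quant_params`.
#' @export
quant_params <- function(S_M, S_H2O, TR, TE, T1, T2, t2_stretch = 1.5,
                         f_GM = 0.38, f_WM = 0.62,
                         d_GM = 0.78, d_WM = 0.65, H2O_molar = 55500) {
  if (abs(f_GM + f_WM - 1) > 1e-9) {
    stop("f_GM + f_WM must equal 1 (CSF excluded)", call. = FALSE)
  }
  if (any(c(TR, T1, T2) <= 0) || TE < 0) {
    stop("TR, T1, T2 must be positive and TE non-negative", call. = FALSE)
  }
  structure(
    list(
      S_M = S_M, S_H2O = S_H2O, TR = TR, TE = TE, T1 = T1, T2 = T2,
      t2_stretch = t2_stretch, f_GM = f_GM, f_WM = f_WM,
      d_GM = d_GM, d_WM = d_WM, H2O_molar = H2O_molar
    ),
    class = "mrs_quant_params"
  )
}

#' Absolute metabolite concentration in mM
#'
#' Implements the water-referenced conversion
#' \deqn{M = \frac{S_M}{S_{H2O}} \cdot \frac{1}{1 - e^{-TR/T_1}} \cdot
#'   \frac{1}{e^{-TE/(1.5\,T_2)}} \cdot
#'   (f_{GM} d_{GM} + f_{WM} d_{WM}) \cdot [H_2O]_{molar}}
#' with the 1.5 factor accounting for the slower apparent T2 relaxation under
#' semi-LASER refocusing.
#'
#' @param p An [quant_params()] object.
#' @return Concentration in mM.
#' @export
absolute_concentration <- function(p) {
  stopifnot(inherits(p, "mrs_quant_params"))
  t1_corr <- 1 / (1 - exp(-p$TR / p$T1))
  t2_corr <- 1 / exp(-p$TE / (p$t2_stretch * p$T2))
  tissue_water <- p$f_GM * p$d_GM + p$f_WM * p$d_WM
  (p$S_M / p$S_H2O) * t1_corr * t2_corr * tissue_water * p$H2O_molar
}

#' Relaxation-corrected amplitudes
#'
#' Divides fitted amplitudes by the T1 saturation and (stretched) T2 decay at
#' the protocol's TR/TE using the per-metabolite relaxation table, so ratios
#' compare concentrations rather than raw signals.
#'
#' @param amplitudes Named amplitude vector from an `mrs_lcm_fit`.
#' @param basis Basis set carrying the T1/T2 table.
#' @param TR,TE Sequence timing, ms.
#' @param t2_stretch T2 stretch factor (default 1.5).
#' @return Named vector over the basis metabolites.
#' @export
relaxation_correct <- function(amplitudes, basis, TR, TE, t2_stretch = 1.5) {
  att <- relax_attenuation(basis, TR, TE, t2_stretch)
  mets <- intersect(names(amplitudes), names(att))
  stats::setNames(amplitudes[mets] / att[mets], mets)
}

#' Metabolite ratios and mM calibration against total creatine
#'
#' Computes ratios to tCr (= Cr + PCr) from relaxation-corrected amplitudes
#' and, given an absolute tCr concentration, converts every metabolite to mM
#' by `mM = ratio * tCr_mM`.  The same calibration factor converts amplitude
#' CRLBs to mM.
#'
#' @param fit An `mrs_lcm_fit`.
#' @param tcr_mM Absolute tCr concentration in mM (from
#'   [absolute_concentration()]); `NA` leaves mM columns `NA`.
#' @param basis Basis set (defaults to the fit's).
#' @param TR,TE Sequence timing for the relaxation correction; when `NULL`,
#'   amplitudes are used uncorrected.
#' @return A tibble with one row per metabolite: `metabolite`, `amplitude`,
#'   `ratio_tcr`, `mM`, `crlb_amp`, `crlb_mM`, plus rows for the sums
#'   `tnaa`, `tcr`, `tcho` (ratio/mM only; no CRLBs for sums).
#' @export
calibrate_ratios <- function(fit, tcr_mM = NA_real_, basis = fit$basis,
                             TR = NULL, TE = NULL) {
  stopifnot(inherits(fit, "mrs_lcm_fit"))
  amps <- fit$amplitudes[metabolite_names(basis)]
  crlb <- fit$crlb[metabolite_names(basis)]
  if (!is.null(TR) && !is.null(TE)) {
    att <- relax_attenuation(basis, TR, TE)[names(amps)]
    amps <- amps / att
    crlb <- crlb / att[names(crlb)]
  }
  tcr_amp <- amps[["cr"]] + amps[["pcr"]]
  if (!is.finite(tcr_amp) || tcr_amp <= 0) {
    stop("tCr amplitude must be positive for calibration", call. = FALSE)
  }
  cal <- if (is.na(tcr_mM)) NA_real_ else tcr_mM / tcr_amp

  per_met <- tibble::tibble(
    metabolite = names(amps),
    amplitude = unname(amps),
    ratio_tcr = unname(amps) / tcr_amp,
    mM = unname(amps) * cal,
    crlb_amp = unname(crlb),
    crlb_mM = unname(crlb) * cal
  )
  sums <- tibble::tibble(
    metabolite = c("tnaa", "tcr", "tcho"),
    amplitude = c(
      amps[["naa"]] + amps[["naag"]], tcr_amp, amps[["gpc"]] + amps[["pcho"]]
    ),
    ratio_tcr = amplitude / tcr_amp,
    mM = amplitude * cal,
    crlb_amp = NA_real_, crlb_mM = NA_real_
  )
  dplyr::bind_rows(per_met, sums)
}
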