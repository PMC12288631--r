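#' Quantify one subject end-to-end
#'
#' Shot-level preprocessing, linear-combination fitting, two-compartment
#' water referencing and tCr-calibrated quantification in one call.
#'
#' @param transients An `mrs_transients` object.
#' @param water_series The subject's `mrs_water_series`.
#' @param mmbg The cohort [mmbg_model()].
#' @param basis Basis set.
#' @param f_GM,f_WM Voxel GM/WM volume fractions (CSF excluded); region
#'   defaults 0.38/0.62 (brain) and 0.36/0.64 (cord).
#' @param H2O_molar Molar water concentration, mM.
#' @param ... Passed to [preprocess_subject()].
#' @return A list: `quant` (the [calibrate_ratios()] tibble), `fit`
#'   (`mrs_lcm_fit`), `water_fit` ([fit_water_decay()] row), `tcr_mM`,
#'   `spectra` (preprocessed), `qc` (per-shot report).
#' @export
quantify_subject <- function(transients, water_series, mmbg,
                             basis = load_basis(),
                             f_GM = NULL, f_WM = NULL, H2O_molar = 55500,
                             ...) {
  acq <- transients$acq
  if (is.null(f_GM)) f_GM <- if (acq$region == "brain") 0.38 else 0.36
  if (is.null(f_WM)) f_WM <- if (acq$region == "brain") 0.62 else 0.64

  pp <- preprocess_subject(transients, ...)
  fit <- fit_lcm(pp$metabolite, basis, mmbg)
  wfit <- fit_water_decay(water_series)

  ## water amplitude per molecule: divide by the 2 protons of water
  s_h2o <- wfit$s_par / 2
  tcr_amp <- fit$amplitudes[["cr"]] + fit$amplitudes[["pcr"]]
  t1 <- basis$meta$t1_ms[basis$meta$metabolite == "cr"]
  t2 <- basis$meta$t2_ms[basis$meta$metabolite == "cr"]
  tcr_mM <- absolute_concentration(quant_params(
    S_M = tcr_amp, S_H2O = s_h2o, TR = acq$TR, TE = acq$TE,
    T1 = t1, T2 = t2, f_GM = f_GM, f_WM = f_WM, H2O_molar = H2O_molar
  ))
  quant <- calibrate_ratios(fit, tcr_mM, basis = basis, TR = acq$TR, TE = acq$TE)
  list(
    quant = quant, fit = fit, water_fit = wfit, tcr_mM = tcr_mM,
    spectra = pp[c("metabolite", "water")], qc = pp$qc
  )
}

#' Quantify a simulated cohort end-to-end
#'
#' Preprocesses every subject, estimates the MMBG shape from the
#' healthy-control average, fits and quantifies each subject, and applies
#' cohort QC gating.  The result feeds straight into [run_analysis()].
#'
#' @param cohort Tibble from [simulate_cohort()] (with `transients` and
#'   `water_series` list-columns).
#' @param basis Basis set.
#' @param policy QC policy; defaults to the cohort's region.
#' @param mmbg Optional precomputed MMBG model (skips estimation).
#' @param ... Passed to [quantify_subject()].
#' @return A list: `table` (per-subject tibble with `tnaa_tcr`, `tcho_tcr`,
#'   `mi_tcr`, `tcr`, `gauss_lw`, `qc_kept`), `crlb_table`, `qc`, `mmbg`,
#'   `results` (per-subject quantification lists).
#' @export
quantify_cohort <- function(cohort, basis = load_basis(), policy = NULL,
                            mmbg = NULL, ...) {
  region <- cohort$region[1]
  if (is.null(policy)) policy <- qc_policy(region)

  pp <- purrr::map(cohort$transients, preprocess_subject)
  if (is.null(mmbg)) {
    hc_spectra <- purrr::map(pp[cohort$group == "HC"], "metabolite")
    mmbg <- estimate_mmbg(hc_spectra, basis, region = region)
  }
  results <- purrr::pmap(
    list(cohort$transients, cohort$water_series, pp),
    function(tr, ws, p) {
      fit <- fit_lcm(p$metabolite, basis, mmbg)
      wfit <- fit_water_decay(ws)
      acq <- tr$acq
      f_GM <- if (acq$region == "brain") 0.38 else 0.36
      f_WM <- 1 - f_GM
      t1 <- basis$meta$t1_ms[basis$meta$metabolite == "cr"]
      t2 <- basis$meta$t2_ms[basis$meta$metabolite == "cr"]
      tcr_mM <- absolute_concentration(quant_params(
        S_M = fit$amplitudes[["cr"]] + fit$amplitudes[["pcr"]],
        S_H2O = wfit$s_par / 2, TR = acq$TR, TE = acq$TE,
        T1 = t1, T2 = t2, f_GM = f_GM, f_WM = f_WM
      ))
      quant <- calibrate_ratios(fit, tcr_mM,
        basis = basis, TR = acq$TR, TE = acq$TE
      )
      list(fit = fit, water_fit = wfit, tcr_mM = tcr_mM, quant = quant)
    }
  )

  get_ratio <- function(q, m) q$ratio_tcr[q$metabolite == m]
  table <- tibble::tibble(
    subject_id = cohort$subject_id, group = cohort$group,
    region = region,
    tnaa_tcr = purrr::map_dbl(results, ~ get_ratio(.x$quant, "tnaa")),
    tcho_tcr = purrr::map_dbl(results, ~ get_ratio(.x$quant, "tcho")),
    mi_tcr = purrr::map_dbl(results, ~ get_ratio(.x$quant, "mi")),
    tcr = purrr::map_dbl(results, "tcr_mM"),
    gauss_lw = purrr::map_dbl(results, ~ .x$fit$gauss_lw)
  )

  crlb_table <- dplyr::bind_cols(
    tibble::tibble(subject_id = cohort$subject_id),
    purrr::map_dfr(results, function(r) {
      q <- r$quant[!is.na(r$quant$crlb_mM), ]
      tibble::as_tibble(as.list(stats::setNames(q$crlb_mM, q$metabolite)))
    })
  )
  qc <- gate_spectra(
    crlb_table[c("subject_id", policy$analyzed_metabolites)],
    table[c("subject_id", "gauss_lw")], policy
  )
  table$qc_kept <- table$subject_id %in% qc$kept
  list(table = table, crlb_table = crlb_table, qc = qc, mmbg = mmbg, results = results)
}
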