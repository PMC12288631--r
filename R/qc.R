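#' Cohort-level spectral quality policy
#'
#' Region-specific gating rules: a spectrum is excluded when the absolute
#' CRLBs (in mM) of more than half of the analyzed metabolites exceed a
#' cutoff of `crlb_multiplier` times the cohort median CRLB of that
#' metabolite — 1.5x in the brain, 2.0x in the lumbar cord — or when the
#' common Gauss linewidth of the model fit exceeds 7.5 Hz (brain) or
#' 10 Hz (cord).  Whole spectra are excluded, never single metabolites.
#'
#' @param region `"brain"` or `"cord"`.
#' @param crlb_multiplier Cutoff multiplier; region default if `NULL`.
#' @param majority_fraction Fraction of metabolites that must exceed their
#'   cutoffs (strictly more than) for exclusion; default 0.5.
#' @param gauss_lw_max Maximum common Gauss linewidth in Hz; region default
#'   if `NULL`.
#' @param analyzed_metabolites Metabolites entering the CRLB rule.
#' @return A list of class `mrs_qc_policy`.
#' @export
qc_policy <- function(region = c("brain", "cord"),
                      crlb_multiplier = NULL,
                      majority_fraction = 0.5,
                      gauss_lw_max = NULL,
                      analyzed_metabolites = c(
                        "naa", "naag", "cr", "pcr", "gpc", "pcho", "mi"
                      )) {
  region <- match.arg(region)
  if (is.null(crlb_multiplier)) {
    crlb_multiplier <- if (region == "brain") 1.5 else 2.0
  }
  if (is.null(gauss_lw_max)) gauss_lw_max <- if (region == "brain") 7.5 else 10
  stopifnot(
    crlb_multiplier > 1, majority_fraction > 0, majority_fraction < 1,
    gauss_lw_max > 0
  )
  structure(
    list(
      region = region, crlb_multiplier = crlb_multiplier,
      majority_fraction = majority_fraction, gauss_lw_max = gauss_lw_max,
      analyzed_metabolites = analyzed_metabolites
    ),
    class = "mrs_qc_policy"
  )
}

#' Gate spectra on cohort CRLB and linewidth criteria
#'
#' Per metabolite, the cutoff is `crlb_multiplier` times the cohort median of
#' its absolute CRLB (all subjects pooled, single pass).  A subject is
#' excluded if strictly more than `majority_fraction` of the analyzed
#' metabolites exceed their cutoffs, or if its Gauss linewidth exceeds
#' `gauss_lw_max`.
#'
#' @param crlb_table Data frame with `subject_id` and one column per analyzed
#'   metabolite holding absolute CRLBs in mM.
#' @param linewidths Data frame with `subject_id` and `gauss_lw` (Hz).
#' @param policy A [qc_policy()].
#' @return A list: `kept`, `excluded` (subject ids), `report` (per-subject
#'   tibble with exceed counts and reasons), `cutoffs` (per-metabolite).
#' @export
gate_spectra <- function(crlb_table, linewidths, policy) {
  stopifnot(inherits(policy, "mrs_qc_policy"))
  mets <- policy$analyzed_metabolites
  missing_cols <- setdiff(mets, names(crlb_table))
  if (length(missing_cols)) {
    stop(
      "missing CRLB columns: ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  if (nrow(crlb_table) < 3) stop("cohort size must be >= 3", call. = FALSE)
  bad <- crlb_table$subject_id[!stats::complete.cases(crlb_table[mets])]
  if (length(bad)) {
    stop(
      "missing CRLB entries for subjects: ", paste(bad, collapse = ", "),
      call. = FALSE
    )
  }

  cutoffs <- vapply(
    crlb_table[mets],
    function(x) policy$crlb_multiplier * stats::median(x),
    numeric(1)
  )
  exceeds <- sweep(as.matrix(crlb_table[mets]), 2, cutoffs, `>`)
  n_exceed <- rowSums(exceeds)
  crlb_fail <- n_exceed > policy$majority_fraction * length(mets)

  lw <- linewidths$gauss_lw[match(crlb_table$subject_id, linewidths$subject_id)]
  if (anyNA(lw)) {
    stop("missing linewidths for some subjects", call. = FALSE)
  }
  lw_fail <- lw > policy$gauss_lw_max

  reason <- dplyr::case_when(
    crlb_fail & lw_fail ~ "crlb+linewidth",
    crlb_fail ~ "crlb",
    lw_fail ~ "linewidth",
    TRUE ~ ""
  )
  report <- tibble::tibble(
    subject_id = crlb_table$subject_id,
    n_exceed = n_exceed, n_analyzed = length(mets),
    gauss_lw = lw, kept = !(crlb_fail | lw_fail), reason = reason
  )
  list(
    kept = report$subject_id[report$kept],
    excluded = report$subject_id[!report$kept],
    report = report,
    cutoffs = cutoffs
  )
}
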