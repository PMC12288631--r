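#' Welch's two-sample t-test as a tidy comparison row
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' (via [stats::t.test()]), group summaries and the percent difference of the
#' means, in the reporting convention `100 * (mean_b - mean_a) / mean_a`.
#'
#' @param a,b Numeric samples (group A is the reference, e.g. HC).
#' @param alternative `"two.sided"`, `"less"` or `"greater"` (for the mean of
#'   `a` relative to `b`, as in [stats::t.test()]).
#' @param label Optional outcome label carried into the row.
#' @return A one-row tibble: `outcome`, `mean_a`, `sd_a`, `n_a`, `mean_b`,
#'   `sd_b`, `n_b`, `t`, `df`, `p`, `pct_diff`, `alternative`.
#' @export
welch_test <- function(a, b, alternative = "two.sided", label = NA_character_) {
  if (length(a) < 2 || length(b) < 2) {
    stop("each sample needs at least 2 observations", call. = FALSE)
  }
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    eq <- isTRUE(all.equal(mean(a), mean(b)))
    return(tibble::tibble(
      outcome = label, mean_a = mean(a), sd_a = 0, n_a = length(a),
      mean_b = mean(b), sd_b = 0, n_b = length(b),
      t = if (eq) 0 else sign(mean(a) - mean(b)) * Inf,
      df = length(a) + length(b) - 2,
      p = if (eq) 1 else 0,
      pct_diff = percent_difference(mean(a), mean(b)),
      alternative = alternative
    ))
  }
  ht <- stats::t.test(a, b, alternative = alternative, var.equal = FALSE)
  tibble::tibble(
    outcome = label,
    mean_a = mean(a), sd_a = stats::sd(a), n_a = length(a),
    mean_b = mean(b), sd_b = stats::sd(b), n_b = length(b),
    t = unname(ht$statistic), df = unname(ht$parameter),
    p = ht$p.value,
    pct_diff = percent_difference(mean(a), mean(b)),
    alternative = alternative
  )
}

#' Percent difference between group means
#'
#' `100 * (mean_sci - mean_hc) / mean_hc`, rounded to one decimal for
#' reporting (e.g. 1.94 vs 1.77 gives -8.8).
#'
#' @param mean_hc Reference (healthy-control) mean; must be nonzero.
#' @param mean_sci Comparison (patient) mean.
#' @param digits Decimals for reporting (default 1); `NA` for unrounded.
#' @return Percent difference.
#' @export
percent_difference <- function(mean_hc, mean_sci, digits = 1) {
  if (any(mean_hc == 0)) stop("reference mean must be nonzero", call. = FALSE)
  d <- 100 * (mean_sci - mean_hc) / mean_hc
  if (is.na(digits)) d else round(d, digits)
}

#' Pearson or Spearman correlation as a tidy row
#'
#' @param x,y Paired numeric samples, `n >= 3`.
#' @param method `"pearson"` or `"spearman"` (midrank ties).
#' @param label Optional outcome label.
#' @return One-row tibble: `outcome`, `method`, `n`, `estimate`, `p`,
#'   `flagged` (`TRUE` when an input is constant and the coefficient is
#'   undefined).
#' @export
correlate <- function(x, y, method = c("pearson", "spearman"),
                      label = NA_character_) {
  method <- match.arg(method)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(tibble::tibble(
      outcome = label, method = method, n = length(x),
      estimate = NA_real_, p = NA_real_, flagged = TRUE
    ))
  }
  ht <- suppressWarnings(stats::cor.test(x, y, method = method, exact = FALSE))
  tibble::tibble(
    outcome = label, method = method, n = length(x),
    estimate = unname(ht$estimate), p = ht$p.value, flagged = FALSE
  )
}

#' Run the planned cohort analysis
#'
#' Emits every planned group contrast (Welch tests, HC as reference) over the
#' metabolite ratios, tCr and the cord cross-sectional areas present in the
#' table, plus the correlation battery between ratios and clinical scores,
#' lesion metrics and time since injury in the patient group.  No
#' multiple-testing correction is applied by default; an optional
#' Benjamini-Hochberg adjustment can be switched on.
#'
#' @param table QC-gated cohort tibble with columns `subject_id`, `group`
#'   (`"HC"`/`"SCI"`) and any of `tnaa_tcr`, `tcho_tcr`, `mi_tcr`, `tcr`,
#'   `wma`, `gma` plus clinical columns (`lems`, `lelt`, `lepp`,
#'   `lesion_volume`, `tissue_bridges`, `time_since_injury`).
#' @param contrasts Outcome columns to compare between groups.
#' @param associations Clinical columns to correlate with each ratio in SCI.
#' @param alternative Test sidedness for all contrasts.
#' @param p_adjust Apply Benjamini-Hochberg across the contrast p-values.
#' @return A list with tibbles `contrasts` and `associations`.
#' @export
run_analysis <- function(table,
                         contrasts = c(
                           "tnaa_tcr", "tcho_tcr", "mi_tcr",
                           "tcr", "wma", "gma"
                         ),
                         associations = c(
                           "lems", "lelt", "lepp", "lesion_volume",
                           "tissue_bridges", "time_since_injury"
                         ),
                         alternative = "two.sided",
                         p_adjust = FALSE) {
  if (!all(c("subject_id", "group") %in% names(table))) {
    stop("table needs subject_id and group columns", call. = FALSE)
  }
  hc <- dplyr::filter(table, .data$group == "HC")
  sci <- dplyr::filter(table, .data$group == "SCI")
  if (nrow(hc) == 0 || nrow(sci) == 0) {
    stop("both HC and SCI groups must be non-empty", call. = FALSE)
  }

  rows <- list()
  for (v in contrasts) {
    if (!v %in% names(table)) {
      message("contrast skipped (missing column): ", v)
      next
    }
    a <- hc[[v]][is.finite(hc[[v]])]
    b <- sci[[v]][is.finite(sci[[v]])]
    if (length(a) < 2 || length(b) < 2) {
      message("contrast skipped (too few observations): ", v)
      next
    }
    rows[[v]] <- welch_test(a, b, alternative = alternative, label = v)
  }
  out_contrasts <- dplyr::bind_rows(rows)
  if (p_adjust && nrow(out_contrasts)) {
    out_contrasts$p_adj <- stats::p.adjust(out_contrasts$p, method = "BH")
  }

  assoc <- list()
  ratio_cols <- intersect(c("tnaa_tcr", "tcho_tcr", "mi_tcr"), names(table))
  for (rv in ratio_cols) {
    for (cv in intersect(associations, names(table))) {
      pair_ok <- sum(stats::complete.cases(sci[[rv]], sci[[cv]]))
      if (pair_ok < 3) next
      for (m in c("pearson", "spearman")) {
        assoc[[paste(rv, cv, m, sep = ".")]] <- correlate(
          sci[[rv]], sci[[cv]],
          method = m, label = paste(rv, "vs", cv)
        )
      }
    }
  }
  list(contrasts = out_contrasts, associations = dplyr::bind_rows(assoc))
}
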