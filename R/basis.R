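#' Load the parametric metabolite basis set
#'
#' The basis is a versioned JSON data file shipped with the package: for each
#' of the 18 metabolites (aspartate, creatine, GABA, glucose, glutamate,
#' glutamine, glutathione, glycine, GPC, lactate, myo-inositol, NAA, NAAG,
#' PCr, PCho, phosphorylethanolamine, scyllo-inositol, taurine) a simplified
#' multiplet model: chemical-shift positions in ppm, proton-weighted relative
#' intensities, and a per-line Lorentz width.  Together with the Voigt-line
#' macromolecular background (see [mmbg_model()]) this forms the 19-component
#' linear-combination basis.
#'
#' @param path Path to a basis JSON file; defaults to the packaged version.
#' @return A list of class `mrs_basis` with elements `lines` (a tibble with
#'   columns `metabolite`, `ppm`, `rel_int`, `lorentz_fwhm`), `meta` (a tibble
#'   with per-metabolite `protons`, `t1_ms`, `t2_ms`), `field_mhz`,
#'   `water_ppm`, and the macromolecular hump profile used by the simulator.
#' @export
load_basis <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "basis_3t_v1.json", package = "mrsquant")
  }
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  mets <- raw$metabolites
  lines <- purrr::map_dfr(names(mets), function(m) {
    ln <- mets[[m]]$lines
    tibble::tibble(
      metabolite = m,
      ppm = ln[, 1],
      rel_int = ln[, 2],
      lorentz_fwhm = raw$default_line_lorentz_fwhm_hz
    )
  })
  meta <- purrr::map_dfr(names(mets), function(m) {
    tibble::tibble(
      metabolite = m, long_name = mets[[m]]$name,
      protons = mets[[m]]$protons,
      t1_ms = mets[[m]]$t1_ms, t2_ms = mets[[m]]$t2_ms
    )
  })
  structure(
    list(
      lines = lines, meta = meta,
      field_mhz = raw$field_mhz, water_ppm = raw$water_ppm,
      water_protons = raw$water_protons,
      mmbg_hump = tibble::tibble(
        ppm = raw$mmbg_hump_ppm, amp = raw$mmbg_hump_amp,
        fwhm_hz = raw$mmbg_hump_fwhm_hz
      ),
      version = raw$version
    ),
    class = "mrs_basis"
  )
}

#' @export
print.mrs_basis <- function(x, ...) {
  cat("<mrs_basis> v", x$version, ": ", nrow(x$meta), " metabolites, ",
    nrow(x$lines), " lines at ", x$field_mhz, " MHz\n",
    sep = ""
  )
  invisible(x)
}

metabolite_names <- function(basis) basis$meta$metabolite

#' Restrict a basis set to selected metabolites
#'
#' Useful for reduced fits (e.g. an isolated line for uncertainty
#' validation).
#'
#' @param basis An `mrs_basis`.
#' @param metabolites Character vector of metabolite codes to keep.
#' @return An `mrs_basis` containing only those metabolites.
#' @export
basis_subset <- function(basis, metabolites) {
  missing <- setdiff(metabolites, basis$meta$metabolite)
  if (length(missing)) {
    stop("unknown metabolites: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  basis$lines <- basis$lines[basis$lines$metabolite %in% metabolites, ]
  basis$meta <- basis$meta[basis$meta$metabolite %in% metabolites, ]
  basis
}

## Complex FID matrix (n_points x n_metabolites) for unit concentration,
## at the basis' intrinsic per-line Lorentz widths, no Gauss broadening.
## Frequencies are offsets from the water carrier.
basis_fids <- function(basis, n_points, spectral_width) {
  t <- time_axis(n_points, spectral_width)
  mets <- metabolite_names(basis)
  out <- matrix(0i, nrow = n_points, ncol = length(mets))
  colnames(out) <- mets
  for (j in seq_along(mets)) {
    ln <- basis$lines[basis$lines$metabolite == mets[j], ]
    lines <- data.frame(
      freq_hz = ppm_to_hz(ln$ppm, basis$field_mhz, basis$water_ppm),
      amp = ln$rel_int,
      lorentz_fwhm = ln$lorentz_fwhm
    )
    out[, j] <- lines_fid(t, lines)
  }
  out
}

## Macromolecular background FID used by the simulator as ground truth.
## The background follows the same model the field fits it with: a comb of
## equally spaced Voigt lines (5 Hz spacing, 14 Hz Lorentz width, the
## region's Gauss width) whose amplitude profile traces a smooth envelope of
## broad humps at literature MM positions.  The profile (what a cohort
## estimation must recover) is the unknown; the line grid is the model.
mmbg_truth_fid <- function(basis, n_points, spectral_width, scale = 1,
                           region = "brain", window_ppm = c(0.5, 4.2)) {
  if (scale == 0) {
    return(complex(length.out = n_points))
  }
  comb <- mmbg_model(
    region = region, window_ppm = window_ppm,
    frequency_mhz = basis$field_mhz, water_ppm = basis$water_ppm
  )
  h <- basis$mmbg_hump
  hump_hz <- ppm_to_hz(h$ppm, basis$field_mhz, basis$water_ppm)
  env <- vapply(comb$freq_hz, function(f) {
    sum(h$amp * (h$fwhm_hz / 2)^2 / ((h$fwhm_hz / 2)^2 + (f - hump_hz)^2))
  }, numeric(1))
  comb$amplitudes <- scale * 3 * env
  mmbg_fid(comb, n_points, spectral_width)
}
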