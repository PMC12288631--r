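## Package interchange format: one JSON header describing the acquisition and
## the cycling map, plus a CSV body of interleaved real/imaginary samples
## (one row per shot).  All floats written at full double precision.

#' Write a transient set to the interchange format
#'
#' @param transients An `mrs_transients` object.
#' @param path Base path; `<path>.json` and `<path>.csv` are written.
#' @param truth_hash Optional string identifying the generating ground truth.
#' @return `path`, invisibly.
#' @export
write_transients <- function(transients, path, truth_hash = NULL) {
  acq <- transients$acq
  header <- list(
    format = "mrsquant-transients", format_version = "1.0",
    acquisition = unclass(acq),
    cycling = purrr::map_int(transients$shots, "cycling_state"),
    run_index = purrr::map_int(transients$shots, "run_index"),
    shot_index = purrr::map_int(transients$shots, "shot_index"),
    truth_hash = truth_hash
  )
  jsonlite::write_json(header, paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  m <- t(vapply(
    transients$shots,
    function(s) as.vector(rbind(Re(s$samples), Im(s$samples))),
    numeric(2L * acq$n_points)
  ))
  utils::write.table(
    format(m, digits = 17, scientific = TRUE, trim = TRUE),
    paste0(path, ".csv"),
    sep = ",", row.names = FALSE, col.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Read a transient set written by [write_transients()]
#' @param path Base path used when writing.
#' @return An `mrs_transients` object.
#' @export
read_transients <- function(path) {
  header <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (!identical(header$format, "mrsquant-transients")) {
    stop("not an mrsquant transient file: ", path, call. = FALSE)
  }
  acq <- header$acquisition
  acq <- acquisition_config(
    region = acq$region,
    spectrometer_frequency = acq$spectrometer_frequency,
    spectral_width = acq$spectral_width, n_points = acq$n_points,
    TR = acq$TR, TE = acq$TE, n_shots_per_run = acq$n_shots_per_run,
    n_runs = acq$n_runs, water_ppm = acq$water_ppm,
    water_te_list = acq$water_te_list, water_TR = acq$water_TR
  )
  m <- as.matrix(utils::read.table(paste0(path, ".csv"), sep = ","))
  shots <- purrr::map(seq_len(nrow(m)), function(i) {
    row <- m[i, ]
    list(
      samples = complex(
        real = row[seq(1, length(row), by = 2)],
        imaginary = row[seq(2, length(row), by = 2)]
      ),
      cycling_state = header$cycling[i],
      run_index = header$run_index[i],
      shot_index = header$shot_index[i]
    )
  })
  structure(list(shots = shots, acq = acq), class = "mrs_transients")
}

#' Write a spectrum (JSON header + complex samples CSV)
#' @param spectrum An `mrs_spectrum` object.
#' @param path Base path; `<path>.json` and `<path>.csv` are written.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  header <- list(
    format = "mrsquant-spectrum", format_version = "1.0",
    spectral_width = spectrum$spectral_width,
    frequency_mhz = spectrum$frequency_mhz,
    water_ppm = spectrum$water_ppm,
    provenance = spectrum$provenance
  )
  jsonlite::write_json(header, paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  utils::write.table(
    data.frame(
      re = format(Re(spectrum$values), digits = 17, trim = TRUE),
      im = format(Im(spectrum$values), digits = 17, trim = TRUE)
    ),
    paste0(path, ".csv"),
    sep = ",", row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Read a spectrum written by [write_spectrum()]
#' @param path Base path used when writing.
#' @return An `mrs_spectrum` object.
#' @export
read_spectrum <- function(path) {
  header <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (!identical(header$format, "mrsquant-spectrum")) {
    stop("not an mrsquant spectrum file: ", path, call. = FALSE)
  }
  d <- utils::read.csv(paste0(path, ".csv"))
  new_spectrum(
    complex(real = d$re, imaginary = d$im),
    spectral_width = header$spectral_width,
    frequency_mhz = header$frequency_mhz,
    water_ppm = header$water_ppm,
    provenance = header$provenance
  )
}
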