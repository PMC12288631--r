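test_that("a pure basis spectrum is recovered exactly", {
  basis <- load_basis()
  n <- 1024
  sw <- 4000
  fid <- mrsquant:::basis_fids(basis, n, sw)[, "naa"] # amplitude 1, no broadening
  sp <- new_spectrum(fid_to_spec(fid), sw, 123.25)
  # noiseless input: parts of the Fisher information are degenerate, which
  # compute_crlb flags; the amplitudes themselves are exact
  fit <- suppressWarnings(fit_lcm(sp, basis, mmbg_model("brain"),
    start = c(gauss = 0.5, lorentz = 0.1, shift = 0, phase = 0)
  ))
  expect_true(fit$converged)
  expect_equal(unname(fit$amplitudes[["naa"]]), 1, tolerance = 1e-6)
  others <- fit$amplitudes[setdiff(names(fit$amplitudes), c("naa", "mmbg"))]
  expect_lt(max(others), 1e-6)
  expect_lt(fit$gauss_lw, 1e-3)
})

test_that("amplitudes and CRLBs are scale-equivariant, ratios invariant", {
  basis <- load_basis()
  acq <- quick_acq(n_shots_per_run = 4L)
  sim <- simulate_subject(quick_truth(), acq, seed = 31)
  pp <- suppressWarnings(preprocess_subject(sim$transients))
  mmbg <- mmbg_model("brain")
  f1 <- suppressWarnings(fit_lcm(pp$metabolite, basis, mmbg))
  sp2 <- pp$metabolite
  sp2$values <- 3.7 * sp2$values
  f2 <- suppressWarnings(fit_lcm(sp2, basis, mmbg))
  nz <- names(which(f1$amplitudes > 1e-3))
  expect_equal(f2$amplitudes[nz] / f1$amplitudes[nz],
    rep(3.7, length(nz)),
    ignore_attr = TRUE, tolerance = 1e-3
  )
  expect_equal(f2$crlb[nz] / f1$crlb[nz],
    rep(3.7, length(nz)),
    ignore_attr = TRUE, tolerance = 1e-2
  )
  r1 <- calibrate_ratios(f1)
  r2 <- calibrate_ratios(f2)
  expect_equal(r1$ratio_tcr, r2$ratio_tcr, tolerance = 1e-3)
})

test_that("doubling the noise doubles every finite amplitude CRLB", {
  basis <- naa_basis()
  mmbg <- mmbg_model("brain")
  f1 <- fit_lcm(line_spectrum(noise_sd = 0.5, seed = 5), basis, mmbg)
  f2 <- fit_lcm(line_spectrum(noise_sd = 1.0, seed = 5), basis, mmbg)
  expect_equal(
    unname(f2$crlb[["naa"]] / f1$crlb[["naa"]]), 2,
    tolerance = 0.05
  )
})

test_that("the CRLB matches the Monte-Carlo spread of an isolated line", {
  basis <- naa_basis()
  mmbg <- mmbg_model("brain")
  res <- vapply(1:120, function(i) {
    f <- fit_lcm(line_spectrum(noise_sd = 0.5, seed = 1000 + i), basis, mmbg)
    c(f$amplitudes[["naa"]], f$crlb[["naa"]])
  }, numeric(2))
  expect_lt(abs(mean(res[2, ]) / stats::sd(res[1, ]) - 1), 0.2)
})

test_that("averaging more shots shrinks the CRLB as 1/sqrt(N)", {
  # noise in the averaged spectrum scales as 1/sqrt(n_shots); the bound is
  # linear in the noise, so quadrupling the shots must halve it
  basis <- naa_basis()
  mmbg <- mmbg_model("brain")
  crlb_at <- function(noise_sd) {
    mean(vapply(1:10, function(i) {
      fit_lcm(line_spectrum(noise_sd = noise_sd, seed = 50 + i), basis, mmbg)$crlb[["naa"]]
    }, numeric(1)))
  }
  expect_lt(abs(crlb_at(1) / crlb_at(0.5) - 2), 0.2)
})

test_that("overlapping Glu/Gln estimates are negatively correlated", {
  basis <- basis_subset(load_basis(), c("glu", "gln"))
  mmbg <- mmbg_model("brain")
  n <- 1024
  sw <- 4000
  t <- (seq_len(n) - 1) / sw
  bf <- mrsquant:::basis_fids(basis, n, sw)
  g <- mrsquant:::voigt_decay(t, 1, 3)
  res <- vapply(1:40, function(i) {
    set.seed(300 + i)
    fid <- (8.5 * bf[, "glu"] + 2.5 * bf[, "gln"]) * g +
      complex(real = rnorm(n, 0, 0.6), imaginary = rnorm(n, 0, 0.6))
    f <- fit_lcm(new_spectrum(fid_to_spec(fid), sw, 123.25), basis, mmbg)
    c(f$amplitudes[["glu"]], f$amplitudes[["gln"]])
  }, numeric(2))
  expect_lt(stats::cor(res[1, ], res[2, ]), 0)
})

test_that("recovered tNAA/tCr stays within the propagated uncertainty band", {
  basis <- basis_subset(load_basis(), c("naa", "cr", "pcr"))
  mmbg <- mmbg_model("brain")
  n <- 1024
  sw <- 4000
  t <- (seq_len(n) - 1) / sw
  bf <- mrsquant:::basis_fids(basis, n, sw)
  g <- mrsquant:::voigt_decay(t, 1, 3)
  fid0 <- (1.5 * bf[, "naa"] + 0.5 * bf[, "cr"] + 0.5 * bf[, "pcr"]) * g
  snr_noise <- max(Re(fid_to_spec(fid0))) / 20
  ok <- vapply(1:25, function(i) {
    set.seed(700 + i)
    fid <- fid0 + complex(
      real = rnorm(n, 0, snr_noise), imaginary = rnorm(n, 0, snr_noise)
    )
    f <- fit_lcm(new_spectrum(fid_to_spec(fid), sw, 123.25), basis, mmbg)
    S <- amplitude_covariance(f)
    tcr <- f$amplitudes[["cr"]] + f$amplitudes[["pcr"]]
    ratio <- f$amplitudes[["naa"]] / tcr
    # first-order variance of the ratio from the amplitude covariance
    gvec <- c(
      naa = 1 / tcr,
      cr = -ratio / tcr, pcr = -ratio / tcr
    )
    sd_ratio <- sqrt(drop(t(gvec) %*% S[names(gvec), names(gvec)] %*% gvec))
    abs(ratio - 1.5) <= 3 * sd_ratio
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("residual RMS in a signal-free band matches the noise estimate", {
  basis <- load_basis()
  sp <- line_spectrum(
    amp = 10, noise_sd = 0.4, seed = 9,
    basis = load_basis()
  )
  fit <- suppressWarnings(fit_lcm(sp, basis, mmbg_model("brain")))
  ppm <- spectrum_ppm(sp)[fit$prep$idx]
  w <- length(fit$prep$idx)
  free <- ppm >= 0.5 & ppm <= 1.1 # below the lowest simulated resonance
  rms <- stats::sd(fit$residual[seq_len(w)][free])
  expect_lt(abs(rms / fit$noise_sd - 1), 0.15)
})

test_that("MMBG models carry the regional Voigt-comb parameters", {
  mb <- mmbg_model("brain")
  mc <- mmbg_model("cord")
  expect_equal(mb$spacing_hz, 5)
  expect_equal(mb$lorentz_fwhm, 14)
  expect_equal(mb$gauss_fwhm, 7.8)
  expect_equal(mc$gauss_fwhm, 0.7)
  expect_equal(diff(mb$freq_hz)[1], 5)
})

test_that("MMBG estimation needs controls and finds nothing when absent", {
  basis <- load_basis()
  expect_error(
    estimate_mmbg(list(line_spectrum()), basis, "brain"),
    "at least 2"
  )
  # spectra without any macromolecular signal: line amplitudes at noise level
  acq <- quick_acq(n_shots_per_run = 8L)
  specs <- lapply(1:3, function(i) {
    sim <- simulate_subject(quick_truth(mmbg_scale = 0), acq, seed = 40 + i)
    suppressWarnings(preprocess_subject(sim$transients)$metabolite)
  })
  mmbg <- estimate_mmbg(specs, basis, "brain")
  noise <- estimate_noise_sd(specs[[1]])
  # comb line amplitude that would produce a peak at the noise level
  expect_lt(stats::median(mmbg$amplitudes), noise)
})

test_that("an injected broad hump is absorbed by the MMBG, not by NAA", {
  basis <- load_basis()
  acq <- quick_acq()
  n <- acq$n_points
  sw <- acq$spectral_width
  t <- (seq_len(n) - 1) / sw
  # smooth broad humps (not comb-representable) injected under the metabolites
  hump_lines <- data.frame(
    freq_hz = mrsquant:::ppm_to_hz(c(0.93, 1.45, 2.07, 3.05), 123.25, 4.68),
    amp = c(14, 9, 8, 6),
    lorentz_fwhm = c(28, 30, 34, 36)
  )
  hump <- mrsquant:::lines_fid(t, hump_lines)
  specs <- lapply(1:4, function(i) {
    sim <- simulate_subject(quick_truth(mmbg_scale = 0), acq, seed = 60 + i)
    pp <- suppressWarnings(preprocess_subject(sim$transients)$metabolite)
    pp$values <- pp$values + fid_to_spec(hump * mrsquant:::voigt_decay(t, 2, 3.4))
    pp
  })
  mmbg <- estimate_mmbg(specs, basis, "brain")
  fit <- suppressWarnings(fit_lcm(specs[[1]], basis, mmbg))

  # hump integral reduced by >= 80% after subtracting the fitted MMBG
  ppm <- spectrum_ppm(specs[[1]])
  win <- ppm >= 0.5 & ppm <= 4.2
  mm_fit <- fit$amplitudes[["mmbg"]] *
    fid_to_spec(mrsquant:::mmbg_fid(mmbg, n, sw) *
      mrsquant:::voigt_decay(t, fit$lorentz_lw, fit$gauss_lw))
  hump_spec <- fid_to_spec(hump * mrsquant:::voigt_decay(t, 2, 3.4))
  before <- sum(abs(hump_spec[win]))
  after <- sum(abs(hump_spec[win] - mm_fit[win]))
  expect_lt(after / before, 0.2)

  # NAA amplitude biased by < 5%
  att <- mrsquant:::relax_attenuation(basis, acq$TR, acq$TE)
  truth_naa <- quick_truth()$concentrations[["naa"]] * att[["naa"]]
  expect_lt(abs(fit$amplitudes[["naa"]] / truth_naa - 1), 0.05)
})

test_that("fits are deterministic given identical inputs", {
  basis <- load_basis()
  sp <- line_spectrum(amp = 8, noise_sd = 0.5, seed = 77, basis = basis)
  mmbg <- mmbg_model("brain")
  f1 <- suppressWarnings(fit_lcm(sp, basis, mmbg))
  f2 <- suppressWarnings(fit_lcm(sp, basis, mmbg))
  expect_identical(f1$amplitudes, f2$amplitudes)
  expect_identical(f1$crlb, f2$crlb)
})
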