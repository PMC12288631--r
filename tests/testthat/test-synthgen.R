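test_that("simulation is bit-reproducible given a seed", {
  acq <- quick_acq(n_shots_per_run = 4L)
  tr <- quick_truth(corrupt_shot_indices = 2L)
  s1 <- simulate_subject(tr, acq, seed = 9)
  s2 <- simulate_subject(tr, acq, seed = 9)
  expect_identical(
    s1$transients$shots[[3]]$samples,
    s2$transients$shots[[3]]$samples
  )
  expect_identical(s1$water_series$amplitudes, s2$water_series$amplitudes)
  # deterministic limit: no noise, drift or corruption
  tr0 <- ground_truth(noise_sd = 0)
  d1 <- simulate_subject(tr0, acq, seed = 1)
  d2 <- simulate_subject(tr0, acq, seed = 2)
  expect_identical(
    d1$transients$shots[[1]]$samples,
    d2$transients$shots[[1]]$samples
  )
})

test_that("additive complex noise matches the requested level", {
  acq <- quick_acq(n_shots_per_run = 2L)
  sim <- simulate_subject(noise_only_truth(noise_sd = 3), acq, seed = 4)
  x <- Re(sim$transients$shots[[1]]$samples)
  expect_lt(abs(stats::sd(x) / 3 - 1), 0.1)
})

test_that("metabolite cycling separates water from metabolites exactly", {
  acq <- quick_acq(n_shots_per_run = 2L)
  # water-only subject: the half-difference must cancel the water signal
  w <- simulate_subject(water_only_truth(), acq, seed = 1)$transients$shots
  expect_identical(w[[1]]$cycling_state, 1L)
  expect_identical(w[[2]]$cycling_state, -1L)
  met <- (w[[1]]$samples - w[[2]]$samples) / 2
  expect_lt(max(abs(met)) / max(abs(w[[1]]$samples)), 1e-9)
  # metabolite-only subject: the half-sum must cancel the metabolites
  m <- simulate_subject(
    ground_truth(noise_sd = 0, H2O_molar = 0), acq,
    seed = 1
  )$transients$shots
  wat <- (m[[1]]$samples + m[[2]]$samples) / 2
  expect_lt(max(abs(wat)) / max(abs(m[[1]]$samples)), 1e-9)
})

test_that("the unitary FFT convention preserves energy both ways", {
  acq <- quick_acq(n_shots_per_run = 2L)
  s <- simulate_subject(quick_truth(), acq, seed = 3)$transients$shots[[1]]
  sp <- fid_to_spec(s$samples)
  expect_equal(sum(abs(sp)^2), sum(abs(s$samples)^2), tolerance = 1e-12)
  expect_equal(spec_to_fid(sp), s$samples, tolerance = 1e-12)
})

test_that("water echo series extrapolates to the compartment amplitude sum", {
  tr <- ground_truth(noise_sd = 0)
  acq <- quick_acq(n_shots_per_run = 2L)
  ws <- simulate_subject(tr, acq, seed = 1)$water_series
  s_par <- mrsquant:::water_amp_parenchyma(tr)
  s_csf <- mrsquant:::water_amp_csf(tr)
  model0 <- s_par + s_csf
  # noiseless: amplitudes follow the biexponential decay exactly
  expect_equal(
    ws$amplitudes,
    s_par * exp(-ws$te_list / tr$water_T2_parenchyma) +
      s_csf * exp(-ws$te_list / tr$water_T2_CSF),
    tolerance = 1e-12
  )
  fit <- fit_water_decay(ws)
  expect_equal(fit$s_total, model0, tolerance = 1e-6)
})

test_that("invalid configurations are rejected", {
  expect_error(acquisition_config(n_points = 1000), "power of two")
  expect_error(acquisition_config(spectral_width = -1), "positive")
  expect_error(acquisition_config(n_shots_per_run = 7), "even")
  expect_error(ground_truth(f_GM = 0.5, f_WM = 0.6, f_CSF = 0), "must equal 1")
  expect_error(ground_truth(noise_sd = -1), ">= 0")
  acq <- quick_acq(n_shots_per_run = 4L)
  tr <- quick_truth(corrupt_shot_indices = 99L)
  expect_error(simulate_subject(tr, acq, seed = 1), "valid shot range")
})

test_that("regional protocol defaults follow the acquisition schemes", {
  brain <- acquisition_config("brain")
  expect_equal(
    c(brain$TR, brain$TE, brain$n_shots_per_run, brain$n_runs),
    c(2500, 35, 128, 2)
  )
  expect_equal(brain$water_te_list[1:2], c(35, 1000))
  cord <- acquisition_config("cord")
  expect_equal(
    c(cord$TR, cord$TE, cord$n_shots_per_run, cord$n_runs),
    c(2000, 41, 256, 2)
  )
  expect_equal(cord$water_te_list[1], 41)
  expect_equal(sort(cord$water_te_list), c(41, 50, 75, 100, 140, 200, 400, 1000))
})

test_that("cohort draws follow the group design", {
  # degenerate design: zero between-subject SD
  d0 <- cohort_design("brain",
    n_hc = 3, n_sci = 3,
    sds = list(
      HC = c(tcr = 0, tnaa_ratio = 0, tcho_ratio = 0, mi_ratio = 0),
      SCI = c(tcr = 0, tnaa_ratio = 0, tcho_ratio = 0, mi_ratio = 0)
    )
  )
  co <- simulate_cohort(d0, seed = 5, simulate = FALSE)
  hc_truths <- co$truth[co$group == "HC"]
  expect_identical(
    hc_truths[[1]]$concentrations,
    hc_truths[[2]]$concentrations
  )
  expect_equal(co$tnaa_ratio[co$group == "HC"], rep(1.94, 3))
  # large-n: sample means within 3 standard errors of the design means
  d <- cohort_design("brain", n_hc = 2000, n_sci = 0)
  big <- simulate_cohort(d, seed = 8, simulate = FALSE)
  for (v in c("tcr", "tnaa_ratio", "mi_ratio")) {
    mu <- d[[v]][d$group == "HC"]
    sdv <- d[[paste0(sub("_ratio", "", v), "_sd")]][d$group == "HC"]
    expect_lt(abs(mean(big[[v]]) - mu), 3 * sdv / sqrt(2000))
  }
  # reproducible per-subject seeds
  co2 <- simulate_cohort(d0, seed = 5, simulate = FALSE)
  expect_identical(co$seed, co2$seed)
})

test_that("cohort ground truths realise the drawn ratios", {
  d <- cohort_design("brain", n_hc = 4, n_sci = 0)
  co <- simulate_cohort(d, seed = 3, simulate = FALSE)
  for (i in seq_len(nrow(co))) {
    conc <- co$truth[[i]]$concentrations
    expect_equal(unname(conc["cr"] + conc["pcr"]), co$tcr[i])
    expect_equal(
      unname((conc["naa"] + conc["naag"]) / (conc["cr"] + conc["pcr"])),
      co$tnaa_ratio[i]
    )
    expect_equal(unname(conc["mi"] / (conc["cr"] + conc["pcr"])), co$mi_ratio[i])
  }
})

test_that("interchange files round-trip transients and spectra", {
  acq <- acquisition_config("brain", n_points = 512, n_shots_per_run = 2L)
  sim <- simulate_subject(quick_truth(), acq, seed = 6)
  path <- file.path(tempdir(), "roundtrip")
  write_transients(sim$transients, path, truth_hash = "abc")
  back <- read_transients(path)
  expect_equal(length(back$shots), length(sim$transients$shots))
  expect_equal(
    back$shots[[2]]$samples, sim$transients$shots[[2]]$samples,
    tolerance = 1e-14
  )
  expect_identical(back$shots[[2]]$cycling_state, -1L)
  expect_equal(back$acq$TR, acq$TR)

  sp <- new_spectrum(
    fid_to_spec(sim$transients$shots[[1]]$samples), 4000, 123.25,
    provenance = list(n_shots_kept = 2L)
  )
  write_spectrum(sp, path)
  sp2 <- read_spectrum(path)
  expect_equal(sp2$values, sp$values, tolerance = 1e-14)
  expect_equal(sp2$provenance$n_shots_kept, 2L)
})
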