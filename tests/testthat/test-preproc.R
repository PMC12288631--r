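test_that("water shot fit recovers a noiseless offset line precisely", {
  acq <- quick_acq(n_shots_per_run = 2L)
  tr <- water_only_truth(frequency_offset = 5, gauss_lw = 0)
  shot <- simulate_subject(tr, acq, seed = 1)$transients$shots[[1]]
  fit <- fit_water_shot(shot, acq)
  expect_true(fit$converged)
  expect_equal(fit$frequency, 5, tolerance = 1e-6)
  expect_equal(fit$linewidth, tr$water_lorentz_lw, tolerance = 1e-4)
  expect_lt(fit$amp_rel_unc, 1e-6)
})

test_that("halving the water SNR doubles the amplitude uncertainty", {
  acq <- quick_acq(n_shots_per_run = 2L)
  mean_unc <- function(noise_sd) {
    tr <- water_only_truth(noise_sd = noise_sd, gauss_lw = 0)
    unc <- vapply(1:25, function(i) {
      shot <- simulate_subject(tr, acq, seed = 100 + i)$transients$shots[[1]]
      fit_water_shot(shot, acq)$amp_rel_unc
    }, numeric(1))
    mean(unc)
  }
  u1 <- mean_unc(500)
  u2 <- mean_unc(1000)
  expect_lt(abs(u2 / u1 - 2), 0.15 * 2)
})

test_that("shots are rejected on uncertainty with a strict 5% boundary", {
  fits <- make_fits(8)
  fits$amp_rel_unc[3] <- 0.06
  fits$lw_rel_unc[5] <- 0.051
  rej <- reject_shots(fits)
  expect_setequal(rej$excluded, c(3L, 5L))
  expect_true(all(rej$report$reason[c(3, 5)] == "uncertainty"))
  # exactly 5.0% is kept ("exceeded" read as strict inequality)
  fits2 <- make_fits(8)
  fits2$amp_rel_unc[2] <- 0.05
  fits2$lw_rel_unc[4] <- 0.05
  expect_length(reject_shots(fits2)$excluded, 0)
})

test_that("a single frequency-jump outlier among clean shots is caught", {
  # brute-force median/MAD oracle on the constructed ensemble
  set.seed(42)
  n <- 128
  fits <- make_fits(n,
    frequency = rnorm(n, 0, 0.3),
    amplitude = 100 * (1 + rnorm(n, 0, 0.004)),
    linewidth = 6 + rnorm(n, 0, 0.05)
  )
  fits$frequency[77] <- fits$frequency[77] + 20
  k <- 3
  oracle_excluded <- which(apply(
    cbind(fits$frequency, fits$amplitude, fits$linewidth), 2,
    function(x) {
      dev <- abs(x - median(x))
      dev / (1.4826 * median(dev)) > k
    }
  ) |> rowSums() > 0)
  rej <- reject_shots(fits, mad_k = k)
  expect_identical(sort(rej$excluded), sort(as.integer(oracle_excluded)))
  expect_true(77L %in% rej$excluded)
  # identical noiseless fits: nothing is an outlier
  expect_length(reject_shots(make_fits(16))$excluded, 0)
})

test_that("lowering the MAD threshold never shrinks the excluded set", {
  set.seed(7)
  n <- 64
  fits <- make_fits(n,
    frequency = rnorm(n, 0, 1), amplitude = 100 + rnorm(n, 0, 2),
    linewidth = 6 + rnorm(n, 0, 0.3)
  )
  prev <- integer(0)
  for (k in c(6, 4, 3, 2.5, 2)) {
    cur <- reject_shots(fits, mad_k = k)$excluded
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("rejecting every shot is a hard error naming the reason", {
  fits <- make_fits(6, amp_rel_unc = 0.2)
  expect_error(reject_shots(fits), "uncertainty")
  expect_error(reject_shots(make_fits(3)), "at least 4")
})

test_that("cycling combination cancels water exactly for clean pairs", {
  acq <- quick_acq(n_shots_per_run = 4L)
  sim <- simulate_subject(water_only_truth(), acq, seed = 1)
  fits <- fit_water_shots(sim$transients)
  out <- correct_and_combine(sim$transients, fits, kept = fits$shot_index)
  water_peak <- max(abs(out$water$values))
  expect_lt(max(abs(out$metabolite$values)) / water_peak, 1e-9)
  expect_equal(out$metabolite$provenance$n_shots_kept, 8L)
})

test_that("frequency drift correction restores the water linewidth", {
  acq <- quick_acq(n_shots_per_run = 16L)
  tr <- water_only_truth(
    drift = list(type = "linear", freq_hz_per_shot = 0.1, phase_deg_per_shot = 0)
  )
  sim <- simulate_subject(tr, acq, seed = 2)
  fits <- fit_water_shots(sim$transients)
  corrected <- correct_and_combine(sim$transients, fits, fits$shot_index)
  null_fits <- fits
  null_fits$frequency <- 0
  null_fits$phase_deg <- 0
  uncorrected <- correct_and_combine(sim$transients, null_fits, fits$shot_index)
  lw <- function(spec) {
    shot <- list(samples = spec_to_fid(spec$values), shot_index = 1L)
    fit_water_shot(shot, acq)$linewidth
  }
  expect_lt(lw(corrected$water), lw(uncorrected$water))
})

test_that("averaging N shots shrinks the noise as 1/sqrt(N)", {
  noise_after_avg <- function(n_shots, seed) {
    acq <- quick_acq(n_shots_per_run = n_shots)
    sim <- simulate_subject(noise_only_truth(noise_sd = 5), acq, seed = seed)
    fits <- make_fits(n_shots * 2)
    out <- correct_and_combine(sim$transients, fits, fits$shot_index)
    stats::sd(Re(out$metabolite$values))
  }
  s8 <- vapply(1:12, function(i) noise_after_avg(4L, i), numeric(1))
  s32 <- vapply(1:12, function(i) noise_after_avg(16L, i), numeric(1))
  expect_lt(abs(mean(s8) / mean(s32) - 2), 0.2)
})

test_that("combination is invariant to shot order and drops orphans", {
  acq <- quick_acq(n_shots_per_run = 4L)
  sim <- simulate_subject(quick_truth(), acq, seed = 3)
  fits <- fit_water_shots(sim$transients)
  ref <- correct_and_combine(sim$transients, fits, fits$shot_index)
  perm <- sim$transients
  ord <- c(5, 2, 7, 1, 8, 3, 6, 4)
  perm$shots <- perm$shots[ord]
  out <- correct_and_combine(perm, fits[ord, ], fits$shot_index)
  expect_equal(out$metabolite$values, ref$metabolite$values, tolerance = 1e-12)
  # rejecting one member of a pair orphans (and drops) its partner
  expect_warning(
    out2 <- correct_and_combine(sim$transients, fits, setdiff(fits$shot_index, 2L)),
    "orphan"
  )
  expect_equal(out2$metabolite$provenance$n_shots_kept, 6L)
})

test_that("clean high-SNR data loses almost no shots, corrupt shots are found", {
  acq <- quick_acq(n_shots_per_run = 32L)
  clean <- simulate_subject(quick_truth(), acq, seed = 10)
  rej <- reject_shots(fit_water_shots(clean$transients))
  expect_lte(length(rej$excluded) / 64, 0.02)

  corrupt_idx <- sort(sample(seq_len(64), 6))
  tr <- quick_truth(
    corrupt_shot_indices = corrupt_idx,
    drift = list(type = "linear", freq_hz_per_shot = 0.02, phase_deg_per_shot = 0.05)
  )
  sim <- simulate_subject(tr, acq, seed = 11)
  rej <- reject_shots(fit_water_shots(sim$transients))
  sens <- mean(corrupt_idx %in% rej$excluded)
  false_excl <- length(setdiff(rej$excluded, corrupt_idx)) / (64 - 6)
  expect_gte(sens, 0.9)
  expect_lte(false_excl, 0.05)
})
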