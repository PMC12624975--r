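# Synthetic recording generator: link structure, Poisson statistics,
# reproducibility, shared-noise block.

test_that("impedance link follows the normalized strain monotonically", {
  s <- synthetic_strain_map(8, 8, jitter_sd = 0)
  # no link, no noise: all impedances at baseline
  gt0 <- synthetic_ground_truth(s, link_model(beta_z = 0, sigma_z = 0,
                                              session_sigma = 0), seed = 1)
  expect_equal(gt0$impedance, rep(4e5, 64))
  # strict negative link, no noise: perfect negative rank correlation
  gt1 <- synthetic_ground_truth(s, link_model(beta_z = -1, sigma_z = 0,
                                              session_sigma = 0), seed = 1)
  r <- spearman_corr(gt1$strain, gt1$impedance)
  expect_equal(r$statistic, -1)
  imp <- simulate_impedances(gt1, sessions = 1)
  expect_equal(imp$impedance, gt1$impedance)
})

test_that("noisy link recovers the Spearman correlation of its generative model", {
  s <- synthetic_strain_map(10, 10)
  # Monte-Carlo oracle for the expected rho of Z = exp(-s~ + 0.3 N)
  set.seed(99)
  oracle <- replicate(300, {
    st <- arraystrain:::normalize_minmax(s$avg_strain)
    z <- exp(-st) * exp(rnorm(100, 0, 0.3))
    cor(st, z, method = "spearman")
  })
  got <- vapply(1:60, function(k) {
    gt <- synthetic_ground_truth(s, link_model(beta_z = -1, sigma_z = 0.3),
                                 seed = 1000 + k)
    cor(gt$strain_norm, gt$impedance, method = "spearman")
  }, numeric(1))
  expect_lt(abs(mean(got) - mean(oracle)), 0.1)
})

test_that("dead electrodes saturate above every screening threshold", {
  s <- synthetic_strain_map(6, 6)
  gt <- synthetic_ground_truth(s, dead = c(3, 17), seed = 2)
  imp <- simulate_impedances(gt, sessions = 1)
  expect_true(all(imp$impedance[c(3, 17)] > 2e6))
  expect_false(any(impedance_screen(imp$impedance, "sirof")[c(3, 17)]))
  expect_false(any(impedance_screen(imp$impedance, "platinum")[c(3, 17)]))
})

test_that("generated recordings are bit-reproducible for a fixed seed", {
  s <- synthetic_strain_map(3, 3)
  gt <- synthetic_ground_truth(s, sessions = 2, seed = 5)
  r1 <- simulate_spontaneous(gt, duration = 0.2, seed = 11)
  r2 <- simulate_spontaneous(gt, duration = 0.2, seed = 11)
  expect_identical(r1$sessions, r2$sessions)
  expect_identical(r1$truth, r2$truth)
  r3 <- simulate_spontaneous(gt, duration = 0.2, seed = 12)
  expect_false(identical(r1$sessions[[1]], r3$sessions[[1]]))
})

test_that("planted spike counts follow the Poisson rate", {
  s <- synthetic_strain_map(3, 3)
  gt <- synthetic_ground_truth(s, rate = 10, seed = 8)
  rec <- simulate_spontaneous(gt, duration = 30, sessions = 1, seed = 21)
  counts <- lengths(rec$truth[[1]]$spike_times)
  # 300 expected per electrode; pooled over 9 electrodes the relative
  # sampling error is ~2%
  expect_equal(mean(counts), 300, tolerance = 0.1)
  # spacing respects the refractory gap
  gaps <- unlist(lapply(rec$truth[[1]]$spike_times, diff))
  expect_gt(min(gaps), 0.002 * rec$fs)
})

test_that("the spike template is biphasic, negative-first, unit peak-to-peak", {
  w <- spike_template()
  expect_equal(length(w), 45) # 1.5 ms at 30 kHz
  expect_equal(max(w) - min(w), 1)
  expect_lt(which.min(w), which.max(w))
})

test_that("a zero-amplitude electrode yields only Gaussian false crossings", {
  set.seed(31)
  x <- rnorm(900000, 0, 8)
  sn <- detect_and_extract(x, 30000)
  # expected downward crossings of the 4.5 RMS threshold for white noise
  p <- pnorm(-4.5)
  expected <- (length(x) - 1) * p * (1 - p)
  expect_lt(abs(length(sn$events) - expected), 4 * sqrt(expected) + 3)
})

test_that("a shared-noise block raises neighbor correlations", {
  s <- synthetic_strain_map(4, 4)
  block <- c(1, 2, 3, 4)
  lk <- link_model(shared_noise = list(electrodes = block, mix = 0.8))
  gt <- synthetic_ground_truth(s, lk, rate = 0, seed = 3)
  rec <- simulate_spontaneous(gt, duration = 0.5, sessions = 1, seed = 9)
  X <- bandpass_filter(rec$sessions[[1]], rec$fs)
  nc <- neighbor_correlation(X, neighbor_map(4, 4))
  expect_gt(mean(nc[block]), mean(nc[-block]) + 0.1)
})

test_that("evoked gain modulates the stimulation-window rate", {
  s <- synthetic_strain_map(2, 2)
  gt1 <- synthetic_ground_truth(s, link_model(g0 = 1, beta_g = 0), rate = 30,
                                noise_sd = 4, seed = 6)
  ev1 <- simulate_evoked(gt1, trials = 30, baseline = 0.15, stim = 0.15, seed = 13)
  snr1 <- evoked_snr_by_electrode(ev1)
  gt3 <- synthetic_ground_truth(s, link_model(g0 = 3, beta_g = 0), rate = 30,
                                noise_sd = 4, seed = 6)
  ev3 <- simulate_evoked(gt3, trials = 30, baseline = 0.15, stim = 0.15, seed = 13)
  snr3 <- evoked_snr_by_electrode(ev3)
  expect_true(all(snr3 > snr1))
  expect_gt(mean(snr3), 3)
  expect_lt(mean(abs(snr1)), 3)
})
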