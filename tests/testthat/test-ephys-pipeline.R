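# Recording-to-metric pipeline: screening thresholds, filter response,
# detection, PTPV, noise floor, eMUA, aggregation and normalization.

test_that("impedance screening applies the coating thresholds strictly above", {
  expect_equal(impedance_screen(c(0.5e6, 1.2e6), "sirof"), c(TRUE, FALSE))
  expect_true(impedance_screen(1.5e6, "platinum"))
  expect_false(impedance_screen(2.5e6, "platinum"))
  # an impedance exactly at the threshold stays functional
  expect_true(impedance_screen(1e6, "sirof"))
  expect_true(impedance_screen(2e6, "platinum"))
  expect_warning(m <- impedance_screen(c(NA, 5e5), "sirof"), "missing")
  expect_equal(m, c(FALSE, TRUE))
})

test_that("bandpass filter preserves the passband and rejects out-of-band tones", {
  fs <- 30000
  t <- seq(0, 1, by = 1 / fs)
  in_band <- sin(2 * pi * 1000 * t)
  y <- bandpass_filter(in_band, fs)
  mid <- seq(5000, length(y) - 5000)
  gain <- (max(y[mid]) - min(y[mid])) / 2
  expect_equal(gain, 1, tolerance = 0.05)
  low <- sin(2 * pi * 10 * t)
  ylow <- bandpass_filter(low, fs)
  expect_lt(max(abs(ylow[mid])), 10^(-20 / 20)) # >= 20 dB attenuation
  expect_equal(bandpass_filter(numeric(3000), fs), numeric(3000))
  expect_error(bandpass_filter(rnorm(10), fs), "warm-up")
  expect_error(bandpass_filter(rnorm(1000), fs = 9000), ">")
})

test_that("threshold crossing detection finds planted spikes", {
  fs <- 30000
  expect_length(detect_and_extract(rep(0, 3000), fs)$events, 0)
  # one planted -100 uV biphasic spike in 5 uV noise
  set.seed(12)
  x <- rnorm(30000, 0, 5)
  w <- spike_template(fs) * 100
  at <- 15000
  x[at:(at + 44)] <- x[at:(at + 44)] + w
  sn <- detect_and_extract(x, fs)
  expect_equal(length(sn$events), 1)
  planted_cross <- at + which.min(w) - 1
  expect_lte(abs(sn$events[1] - planted_cross), 3)
  expect_equal(ncol(sn$snippets), 46) # 0.5 ms pre + 1 ms post at 30 kHz
  # high-SNR planted train is recovered exactly
  s <- synthetic_strain_map(2, 2)
  gt <- synthetic_ground_truth(s, link_model(a0 = 300, beta_a = 0, sigma_a = 0,
                                             session_sigma = 0),
                               rate = 10, noise_sd = 5, seed = 4)
  rec <- simulate_spontaneous(gt, duration = 5, sessions = 1, seed = 5)
  xf <- bandpass_filter(rec$sessions[[1]][1, ], fs)
  sn2 <- detect_and_extract(xf, fs)
  expect_equal(length(sn2$events), length(rec$truth[[1]]$spike_times[[1]]))
})

test_that("representative PTPV averages the top 2% of snippets", {
  expect_equal(representative_ptpv(1:100), 99.5)
  expect_equal(representative_ptpv(1:10), 10)        # ceil(0.2) = 1
  expect_equal(representative_ptpv(rep(7, 33)), 7)
  expect_equal(representative_ptpv(1:150), mean(c(150, 149, 148)))
  expect_true(is.na(representative_ptpv(numeric(0))))
})

test_that("noise floor is twice the SD of the snippet-excised trace", {
  set.seed(77)
  fs <- 30000
  x <- rnorm(300000, 0, 10)
  sn <- detect_and_extract(x, fs)
  nf <- noise_floor_snr(x, sn)
  expect_equal(nf$noise_floor, 20, tolerance = 0.01)
  # excising planted spikes recovers the noise floor of the spike-free twin
  twin <- rnorm(300000, 0, 10)
  y <- twin
  w <- spike_template(fs) * 150
  at <- seq(5000, 295000, by = 3000)
  for (a in at) y[a:(a + 44)] <- y[a:(a + 44)] + w
  sny <- detect_and_extract(y, fs)
  expect_gt(length(sny$events), length(at) * 0.95)
  nfy <- noise_floor_snr(y, sny)
  nft <- noise_floor_snr(twin, detect_and_extract(twin, fs))
  expect_equal(nfy$noise_floor, nft$noise_floor, tolerance = 0.02)
  # SNR is the ratio of the two published quantities
  sn$ptpv <- rep(100, length(sn$ptpv))
  fake <- list(noise_floor = 20, snr = 100 / 20)
  expect_equal(representative_ptpv(rep(100, 5)) / 20, 5)
})

test_that("neighbor correlations behave at the two extremes", {
  nb <- neighbor_map(3, 3)
  x <- rnorm(30000)
  same <- matrix(rep(x, 9), nrow = 9, byrow = TRUE)
  expect_equal(neighbor_correlation(same, nb), rep(1, 9))
  set.seed(5)
  indep <- matrix(rnorm(9 * 900000 / 3), nrow = 9)
  nc <- neighbor_correlation(indep, nb)
  expect_true(all(abs(nc) < 0.01))
  # electrode with no connected neighbors is undefined
  con <- rep(TRUE, 9); con[c(2, 4, 5)] <- FALSE
  nb2 <- neighbor_map(3, 3, con)
  nc2 <- neighbor_correlation(same, nb2)
  expect_true(is.na(nc2[2]))
})

test_that("eMUA envelope tracks amplitude-modulated high-frequency activity", {
  fs <- 30000
  expect_equal(emua(numeric(30000), fs), numeric(1000))
  set.seed(9)
  x <- rnorm(30000, 0, 1)
  burst <- 14000:16000
  x[burst] <- x[burst] * 8
  env <- emua(x, fs)
  expect_equal(length(env), 1000)
  pk <- which.max(env)
  expect_lt(abs(pk * 30 - 15000), 1500) # peak within ~2x smoother scale of the burst
  # doubling the amplitude doubles the envelope scale
  env2 <- emua(2 * x, fs)
  expect_equal(env2, 2 * env, tolerance = 1e-10)
})

test_that("evoked SNR matches its definition on planted numbers", {
  base <- matrix(1, 10, 50) + matrix(rnorm(500, 0, 1e-9), 10)
  stim <- matrix(1, 10, 50)
  stim[, 25] <- 2
  M <- cbind(base, stim)
  # construct baseline with SD 0.2 around mean 1 on the trial average
  avg_target <- 1 + 0.2 * scale(rnorm(50))[, 1]
  Mb <- matrix(rep(avg_target, each = 10), 10)
  M2 <- cbind(Mb, stim)
  got <- evoked_snr(M2, 1:50, 51:100)
  expect_equal(got, (2 - 1) / 0.2, tolerance = 1e-6)
  # identical stim and baseline: near zero
  M3 <- cbind(Mb, Mb)
  expect_lt(evoked_snr(M3, 1:50, 51:100), 3)
  expect_error(evoked_snr(cbind(base * 0 + 1, stim), 1:50, 51:100), "SD")
})

test_that("aggregation averages sessions then min-max normalizes within array", {
  m <- data.frame(electrode_id = rep(1:3, each = 2), session = rep(1:2, 3),
                  val = c(2, 2, 4, 4, 10, 10))
  out <- normalize_and_aggregate(m, functional = rep(TRUE, 3), columns = "val")
  expect_equal(out$val_norm, c(0, 0.25, 1))
  expect_equal(out$val_sd, rep(0, 3))
  # nonfunctional electrodes never influence min/max
  out2 <- normalize_and_aggregate(m, functional = c(TRUE, TRUE, FALSE),
                                  columns = "val")
  expect_equal(out2$val_norm, c(0, 1, NA))
  # single functional electrode: degenerate, zeros with a warning
  expect_warning(
    out3 <- normalize_and_aggregate(m, functional = c(TRUE, FALSE, FALSE),
                                    columns = "val"),
    "degenerate")
  expect_equal(out3$val_norm, c(0, NA, NA))
  # undefined values propagate as missing, not zeros
  m$val[3] <- NA
  out4 <- normalize_and_aggregate(m, functional = rep(TRUE, 3), columns = "val")
  expect_equal(out4$val_mean[2], 4)
})

test_that("ring-dependent session variability is recovered from session SDs", {
  s <- synthetic_strain_map(6, 6)
  lk <- link_model(session_sigma = 0.02,
                   ring_session_sigma = list(ring1 = 0.3, corner = 0.3))
  gt <- synthetic_ground_truth(s, lk, sessions = 8, seed = 14)
  imp <- simulate_impedances(gt, sessions = 8)
  agg <- normalize_and_aggregate(imp, functional = rep(TRUE, 36),
                                 columns = "impedance")
  rl <- ring_labels(6, 6)
  high <- rl$group %in% c("ring1", "corner")
  rel_sd <- agg$impedance_sd / agg$impedance_mean
  expect_gt(median(rel_sd[high]), 3 * median(rel_sd[!high]))
})
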