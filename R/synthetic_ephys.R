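# Synthetic per-electrode impedances and 30 kHz broadband recordings with
# ground truth monotonically linked to a per-electrode strain map.  The
# generator emulates the statistical structure of chronic multielectrode
# recordings -- not their biophysics -- so the metric pipeline and the
# correlation stage can be exercised and calibrated without clinical data.
# All randomness flows through R's default RNG from a single `seed`
# argument (Mersenne-Twister; one stream per call), so outputs are
# bit-reproducible across platforms for a fixed seed.

#' Plausible per-electrode strain surrogate
#'
#' A deterministic strain map with the spatial signature of micromotion
#' loading (elevated strain at edges and corners, decaying towards the
#' interior) plus seeded multiplicative jitter.  Used to drive the
#' synthetic generator at full-array sizes without a finite-element
#' solve; for physical values use an [electrode_strain_table()].
#'
#' @param rows,cols Grid dimensions.
#' @param base Interior strain level (dimensionless, default 0.02).
#' @param edge_gain Relative elevation at the array edge.
#' @param decay Length scale (in electrode pitches) of the edge effect.
#' @param jitter_sd SD of multiplicative lognormal jitter.
#' @param seed RNG seed for the jitter.
#' @return data.frame: `electrode_id`, `row`, `col`, `group`,
#'   `is_corner`, `avg_strain`.
#' @export
synthetic_strain_map <- function(rows = 10, cols = 10, base = 0.02,
                                 edge_gain = 1.5, decay = 1.2,
                                 jitter_sd = 0.05, seed = 1) {
  rl <- ring_labels(rows, cols)
  d <- pmin(rl$row, rows - 1 - rl$row, rl$col, cols - 1 - rl$col)
  s <- base * (1 + edge_gain * exp(-d / decay) + 0.5 * edge_gain * rl$is_corner)
  set.seed(seed)
  s <- s * exp(stats::rnorm(length(s), 0, jitter_sd))
  data.frame(electrode_id = seq_along(s), row = rl$row, col = rl$col,
             group = rl$group, is_corner = rl$is_corner, avg_strain = s)
}

#' Strain-performance link model
#'
#' Monotone links between the within-array min-max normalized strain
#' \eqn{\tilde s_e \in [0,1]} and the generator's ground truth:
#' impedance \eqn{Z_e = z_0\exp(\beta_Z \tilde s_e)\eta_Z}, spike
#' amplitude \eqn{A_e = a_0\exp(\beta_A \tilde s_e)\eta_A} and evoked
#' gain \eqn{g_e = g_0(1 + \beta_G \tilde s_e)}, with lognormal noise
#' multipliers \eqn{\eta}.  The default signs emulate the motor-cortex
#' regime (higher strain, lower impedance and amplitude); a positive
#' `beta_g` emulates the visual-cortex evoked regime.
#'
#' @param z0 Baseline impedance, Ohm.
#' @param beta_z Impedance link strength (sign-configurable).
#' @param sigma_z Lognormal impedance noise SD.
#' @param a0 Baseline spike peak-to-peak amplitude, uV.
#' @param beta_a Amplitude link strength.
#' @param sigma_a Lognormal amplitude noise SD.
#' @param g0 Baseline evoked gain (stimulus firing-rate multiplier).
#' @param beta_g Evoked-gain link strength.
#' @param session_sigma SD of per-session lognormal multipliers applied
#'   to amplitudes and impedances (session-to-session variability).
#' @param ring_session_sigma Optional per-ring session SDs (named by ring
#'   group) overriding `session_sigma`, emulating location-dependent
#'   session variability.
#' @param shared_noise Optional `list(electrodes =, mix =)`: a block of
#'   electrodes receiving a common noise component with mixing
#'   coefficient `mix` (emulates edge insulation failure).
#' @export
link_model <- function(z0 = 4e5, beta_z = -0.8, sigma_z = 0.25,
                       a0 = 180, beta_a = -0.8, sigma_a = 0.2,
                       g0 = 2, beta_g = 1, session_sigma = 0.1,
                       ring_session_sigma = NULL, shared_noise = NULL) {
  stopifnot(z0 > 0, a0 > 0, g0 > 0, sigma_z >= 0, sigma_a >= 0,
            is.finite(beta_z), is.finite(beta_a), is.finite(beta_g))
  structure(list(z0 = z0, beta_z = beta_z, sigma_z = sigma_z,
                 a0 = a0, beta_a = beta_a, sigma_a = sigma_a,
                 g0 = g0, beta_g = beta_g, session_sigma = session_sigma,
                 ring_session_sigma = ring_session_sigma,
                 shared_noise = shared_noise), class = "link_model")
}

normalize_minmax <- function(x) {
  m <- min(x, na.rm = TRUE)
  r <- max(x - m, na.rm = TRUE)
  if (r <= 0) return(ifelse(is.na(x), NA_real_, 0))
  (x - m) / r
}

strain_vector <- function(strain) {
  if (is.data.frame(strain)) strain$avg_strain else as.numeric(strain)
}

#' Synthetic ground truth for one array
#'
#' Draws the per-electrode truth (amplitudes, impedances, evoked gains,
#' firing rates, noise SDs, per-session multipliers) from the link model
#' and the strain map.  The returned object plus a seed fully determines
#' every generated recording.
#'
#' @param strain Per-electrode strain: numeric vector or a data.frame
#'   with an `avg_strain` column ([electrode_strain_table()] or
#'   [synthetic_strain_map()]).
#' @param link A [link_model()].
#' @param rate Spontaneous firing rate, Hz.
#' @param noise_sd Recording noise SD, uV.
#' @param sessions Number of repeated sessions (default 5).
#' @param dead Electrode ids rendered nonfunctional (impedance driven
#'   above any screening threshold; no spikes).
#' @param groups Optional ring-group factor (required when
#'   `link$ring_session_sigma` is used; taken from `strain` when it is a
#'   table with a `group` column).
#' @param seed RNG seed.
#' @export
synthetic_ground_truth <- function(strain, link = link_model(), rate = 15,
                                   noise_sd = 8, sessions = 5,
                                   dead = integer(0), groups = NULL, seed = 1) {
  s <- strain_vector(strain)
  ne <- length(s)
  if (is.null(groups) && is.data.frame(strain) && !is.null(strain$group))
    groups <- strain$group
  set.seed(seed)
  st <- normalize_minmax(s)
  Z <- link$z0 * exp(link$beta_z * st) * exp(stats::rnorm(ne, 0, link$sigma_z))
  A <- link$a0 * exp(link$beta_a * st) * exp(stats::rnorm(ne, 0, link$sigma_a))
  g <- link$g0 * (1 + link$beta_g * st)
  sess_sd <- rep(link$session_sigma, ne)
  if (!is.null(link$ring_session_sigma)) {
    if (is.null(groups)) stop("ring_session_sigma requires electrode groups")
    sd_map <- link$ring_session_sigma
    hit <- as.character(groups) %in% names(sd_map)
    sess_sd[hit] <- unlist(sd_map[as.character(groups)[hit]])
  }
  sess_mult <- matrix(exp(stats::rnorm(ne * sessions, 0, rep(sess_sd, sessions))),
                      nrow = ne)
  dead <- as.integer(dead)
  if (length(dead)) {
    Z[dead] <- 1e7 # above any screening threshold
    A[dead] <- 0
  }
  structure(list(
    n_electrodes = ne, strain = s, strain_norm = st,
    amplitude = A, impedance = Z, gain = g, rate = rate,
    noise_sd = noise_sd, sessions = sessions, session_mult = sess_mult,
    dead = dead, link = link, groups = groups, seed = seed
  ), class = "synthetic_ground_truth")
}

#' Simulate per-electrode 1 kHz impedances
#'
#' @param gt A [synthetic_ground_truth()].
#' @param sessions Number of measurement sessions (per-session lognormal
#'   multipliers applied; defaults to the ground truth's session count).
#' @param seed Seed for the session noise (the electrode-level impedance
#'   draw lives in the ground truth).
#' @return data.frame: `electrode_id`, `session`, `impedance` (Ohm).
#' @export
simulate_impedances <- function(gt, sessions = gt$sessions, seed = gt$seed + 1) {
  set.seed(seed)
  ne <- gt$n_electrodes
  out <- do.call(rbind, lapply(seq_len(sessions), function(k) {
    mult <- if (k <= ncol(gt$session_mult)) gt$session_mult[, k] else
      exp(stats::rnorm(ne, 0, gt$link$session_sigma))
    z <- gt$impedance * mult
    z[gt$dead] <- gt$impedance[gt$dead] # dead electrodes stay saturated
    data.frame(electrode_id = seq_len(ne), session = k, impedance = z)
  }))
  out
}

#' Biphasic spike template
#'
#' Fixed-shape difference-of-Gaussians waveform, negative phase first,
#' 1.5 ms support, scaled to unit peak-to-peak amplitude.  Only the
#' amplitude varies across electrodes; the pipeline measures peak-to-peak
#' voltage and SNR, not waveform shape.
#'
#' @param fs Sampling rate, Hz.
#' @export
spike_template <- function(fs = 30000) {
  n <- round(0.0015 * fs) # 45 samples at 30 kHz
  t <- (seq_len(n) - 1) / fs * 1000 # ms
  w <- -exp(-((t - 0.45)^2) / (2 * 0.09^2)) + 0.55 * exp(-((t - 0.85)^2) / (2 * 0.18^2))
  w <- w / (max(w) - min(w))
  attr(w, "trough") <- which.min(w)
  w
}

poisson_spike_times <- function(rate, n_samples, fs, refractory = 0.002) {
  if (rate <= 0) return(integer(0))
  n_exp <- rate * n_samples / fs
  k <- stats::rpois(1, n_exp)
  if (k == 0) return(integer(0))
  tt <- sort(sample.int(n_samples, min(k, n_samples)))
  # enforce a refractory gap so templates never self-overlap
  keep <- c(TRUE, diff(tt) > refractory * fs)
  tt[keep]
}

add_spikes <- function(trace, times, template) {
  nt <- length(template)
  ns <- length(trace)
  for (t0 in times) {
    i1 <- t0; i2 <- min(t0 + nt - 1, ns)
    trace[i1:i2] <- trace[i1:i2] + template[seq_len(i2 - i1 + 1)]
  }
  trace
}

#' Simulate spontaneous multichannel recordings
#'
#' Each electrode trace is white Gaussian noise plus a Poisson spike
#' train convolved with the biphasic template scaled to the electrode's
#' (session-modulated) peak-to-peak amplitude.  An optional shared-noise
#' component is mixed into the configured electrode block.  Ground-truth
#' spike times are recorded per session.
#'
#' @param gt A [synthetic_ground_truth()].
#' @param duration Seconds per session (>= 1 in study use; shorter allowed
#'   for calibration sweeps).
#' @param sessions Number of sessions (default from the ground truth).
#' @param fs Sampling rate, Hz (30 kHz).
#' @param seed RNG seed.
#' @return `recording_set`: `sessions` (list of electrodes x samples
#'   matrices, uV), `fs`, `truth` (spike times and per-session
#'   amplitudes).
#' @export
simulate_spontaneous <- function(gt, duration = 30, sessions = gt$sessions,
                                 fs = 30000, seed = gt$seed + 2) {
  set.seed(seed)
  ne <- gt$n_electrodes
  ns <- round(duration * fs)
  tmpl <- spike_template(fs)
  out <- vector("list", sessions)
  truth <- vector("list", sessions)
  for (k in seq_len(sessions)) {
    X <- matrix(stats::rnorm(ne * ns, 0, gt$noise_sd), nrow = ne)
    mult <- if (k <= ncol(gt$session_mult)) gt$session_mult[, k] else 1
    amp <- gt$amplitude * mult
    st <- vector("list", ne)
    for (e in seq_len(ne)) {
      if (amp[e] <= 0) { st[[e]] <- integer(0); next }
      tt <- poisson_spike_times(gt$rate, ns - length(tmpl), fs)
      st[[e]] <- tt
      if (length(tt)) X[e, ] <- add_spikes(X[e, ], tt, amp[e] * tmpl)
    }
    sn <- gt$link$shared_noise
    if (!is.null(sn)) {
      common <- stats::rnorm(ns, 0, gt$noise_sd)
      X[sn$electrodes, ] <- X[sn$electrodes, , drop = FALSE] +
        sn$mix * matrix(common, nrow = length(sn$electrodes), ncol = ns, byrow = TRUE)
    }
    out[[k]] <- X
    truth[[k]] <- list(spike_times = st, amplitude = amp)
  }
  structure(list(sessions = out, fs = fs, truth = truth, gt = gt,
                 duration = duration), class = "recording_set")
}

#' Simulate stimulus-evoked trials
#'
#' Each trial is a baseline window followed by a stimulation window in
#' which the firing rate is multiplied by the electrode's evoked gain
#' \eqn{g_e}.
#'
#' @param gt A [synthetic_ground_truth()].
#' @param trials Number of trials (>= 2).
#' @param baseline,stim Window durations, seconds.
#' @param fs Sampling rate, Hz.
#' @param seed RNG seed.
#' @return `evoked_set`: `trials` (list of electrodes x samples
#'   matrices), `baseline_idx`, `stim_idx`, `fs`.
#' @export
simulate_evoked <- function(gt, trials = 50, baseline = 0.3, stim = 0.3,
                            fs = 30000, seed = gt$seed + 3) {
  stopifnot(trials >= 2)
  set.seed(seed)
  ne <- gt$n_electrodes
  nb <- round(baseline * fs)
  nst <- round(stim * fs)
  ns <- nb + nst
  tmpl <- spike_template(fs)
  out <- vector("list", trials)
  for (tr in seq_len(trials)) {
    X <- matrix(stats::rnorm(ne * ns, 0, gt$noise_sd), nrow = ne)
    for (e in seq_len(ne)) {
      if (gt$amplitude[e] <= 0) next
      tb <- poisson_spike_times(gt$rate, nb - length(tmpl), fs)
      ts <- nb + poisson_spike_times(gt$rate * gt$gain[e], nst - length(tmpl), fs)
      tt <- c(tb, ts)
      if (length(tt)) X[e, ] <- add_spikes(X[e, ], tt, gt$amplitude[e] * tmpl)
    }
    out[[tr]] <- X
  }
  structure(list(trials = out, baseline_idx = seq_len(nb),
                 stim_idx = nb + seq_len(nst), fs = fs, gt = gt),
            class = "evoked_set")
}
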