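# Recording-to-metric pipeline: impedance screening, bandpass filtering,
# threshold-crossing snippet extraction, PTPV, noise floor, SNR, envelope
# multi-unit activity, evoked SNR, neighbor correlations, session
# aggregation and within-array min-max normalization.

#' Impedance screening
#'
#' Electrodes with 1 kHz impedance strictly above the coating threshold
#' (1 MOhm for SIROF, 2 MOhm for platinum) are deemed nonfunctional and
#' excluded before averaging and normalization.  An impedance exactly at
#' the threshold is functional.
#'
#' @param impedance Numeric vector, Ohm (NA excluded with a warning).
#' @param coating `"sirof"` or `"platinum"`.
#' @return Logical functional mask.
#' @export
impedance_screen <- function(impedance, coating = c("sirof", "platinum")) {
  coating <- match.arg(coating)
  thr <- if (coating == "sirof") 1e6 else 2e6
  if (anyNA(impedance)) warning("electrodes with missing impedance excluded")
  !is.na(impedance) & impedance <= thr
}

#' Bandpass filter a recording
#'
#' 2nd-order Butterworth bandpass (300-5000 Hz by default), applied
#' zero-phase (forward-backward) by default to avoid spike-shape
#' distortion; single-pass causal filtering is available by flag.
#'
#' @param x Numeric vector, or electrodes x samples matrix (filtered
#'   row-wise).
#' @param fs Sampling rate, Hz (must exceed twice the upper cutoff).
#' @param low,high Cutoff frequencies, Hz.
#' @param order Butterworth order.
#' @param zero_phase Forward-backward filtering if `TRUE`.
#' @export
bandpass_filter <- function(x, fs = 30000, low = 300, high = 5000,
                            order = 2, zero_phase = TRUE) {
  stopifnot(fs > 2 * high)
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  n <- if (is.matrix(x)) ncol(x) else length(x)
  if (n < 9 * max(length(bf$a), length(bf$b)))
    stop("trace shorter than filter warm-up")
  if (!zero_phase) {
    app <- function(v) as.numeric(signal::filter(bf, v))
    return(if (is.matrix(x)) t(apply(x, 1, app)) else app(x))
  }
  if (is.matrix(x)) t(filtfilt_cols(bf$b, bf$a, t(x))) else
    as.numeric(filtfilt_cols(bf$b, bf$a, matrix(x, ncol = 1)))
}

# Zero-phase IIR filtering of matrix columns: the direct form is split
# into its moving-average part (stats::filter, convolution) and recursive
# part (stats::filter, recursive), applied forward and backward with
# reflection padding to suppress edge transients.  Column-vectorized: one
# call filters a whole session or trial block.
filtfilt_cols <- function(b, a, M) {
  b <- b / a[1]; a <- a / a[1]
  npad <- min(nrow(M) - 1L, 250L)
  iir <- function(X) {
    Y <- stats::filter(X, b, method = "convolution", sides = 1)
    Y[seq_len(length(b) - 1), ] <- X[seq_len(length(b) - 1), , drop = FALSE] * 0
    if (length(a) > 1) Y <- stats::filter(Y, -a[-1], method = "recursive")
    matrix(as.numeric(Y), nrow(X), ncol(X))
  }
  pad_top <- 2 * M[rep(1L, npad), , drop = FALSE] -
    M[npad + 1L - seq_len(npad), , drop = FALSE]
  pad_bot <- 2 * M[rep(nrow(M), npad), , drop = FALSE] -
    M[nrow(M) - seq_len(npad), , drop = FALSE]
  X <- rbind(pad_top, M, pad_bot)
  X <- iir(X)
  X <- X[rev(seq_len(nrow(X))), , drop = FALSE]
  X <- iir(X)
  X <- X[rev(seq_len(nrow(X))), , drop = FALSE]
  X[npad + seq_len(nrow(M)), , drop = FALSE]
}

#' Threshold-crossing detection and snippet extraction
#'
#' Events are negative crossings of `mean(x) - 4.5 * RMS(x)` (RMS over
#' the full filtered trace), with a 1 ms lockout after each event.
#' Snippets span 0.5 ms before to 1 ms after the crossing sample;
#' snippets clipped by the trace edges are discarded.
#'
#' @param x Filtered trace, uV.
#' @param fs Sampling rate, Hz.
#' @param k Threshold multiplier (default 4.5).
#' @return `snippet_set`: `events` (crossing sample indices), `snippets`
#'   (events x window matrix), `ptpv` (per-snippet max - min, uV),
#'   `threshold`, `pre`/`post` window sizes in samples.
#' @export
detect_and_extract <- function(x, fs = 30000, k = 4.5) {
  mu <- mean(x)
  rms <- sqrt(mean((x - mu)^2))
  thr <- mu - k * rms
  pre <- round(0.0005 * fs)
  post <- round(0.001 * fs)
  lockout <- round(0.001 * fs)
  below <- x < thr
  cross <- which(below & !c(FALSE, below[-length(below)]))
  events <- integer(0)
  last <- -Inf
  for (i in cross) {
    if (i - last <= lockout) next
    events <- c(events, i)
    last <- i
  }
  keep <- events > pre & events + post <= length(x)
  events <- events[keep]
  snips <- if (length(events))
    t(vapply(events, function(i) x[(i - pre):(i + post)], numeric(pre + post + 1)))
  else matrix(numeric(0), 0, pre + post + 1)
  structure(list(events = events, snippets = snips,
                 ptpv = if (nrow(snips)) apply(snips, 1, function(s) max(s) - min(s))
                 else numeric(0),
                 threshold = thr, pre = pre, post = post, fs = fs),
            class = "snippet_set")
}

#' Representative peak-to-peak voltage
#'
#' Mean PTPV of the largest 2% of snippets (`ceiling(0.02 N)`, at least
#' one), estimating the maximum achievable PTPV on the electrode.
#' Returns `NA` for an empty snippet set: the metric is undefined, never
#' zero.
#'
#' @param snips A `snippet_set` (or numeric vector of snippet PTPVs).
#' @export
representative_ptpv <- function(snips) {
  p <- if (inherits(snips, "snippet_set")) snips$ptpv else as.numeric(snips)
  n <- length(p)
  if (n == 0) return(NA_real_)
  ntop <- max(1L, ceiling(0.02 * n))
  mean(sort(p, decreasing = TRUE)[seq_len(ntop)])
}

#' Noise floor and SNR
#'
#' Noise floor is twice the standard deviation of the filtered trace
#' after excising all snippet windows; SNR is the representative PTPV
#' divided by the noise floor.
#'
#' @param x Filtered trace.
#' @param snips `snippet_set` for the same trace.
#' @return List: `noise_floor` (uV), `snr`, `ptpv`.
#' @export
noise_floor_snr <- function(x, snips) {
  keep <- rep(TRUE, length(x))
  for (i in snips$events) {
    lo <- max(1, i - snips$pre)
    hi <- min(length(x), i + snips$post)
    keep[lo:hi] <- FALSE
  }
  if (!any(keep)) stop("snippets cover the entire trace")
  nf <- 2 * stats::sd(x[keep])
  p <- representative_ptpv(snips)
  list(noise_floor = nf, snr = p / nf, ptpv = p)
}

#' Mean correlation with neighboring electrodes
#'
#' Pearson correlation of each electrode's bandpass-filtered trace with
#' every connected Moore neighbor (3-8 electrodes), averaged.  Undefined
#' (NA) for electrodes without connected neighbors.
#'
#' @param traces Filtered electrodes x samples matrix.
#' @param neighbors Neighbor list from [neighbor_map()].
#' @export
neighbor_correlation <- function(traces, neighbors) {
  ne <- nrow(traces)
  stopifnot(length(neighbors) == ne)
  out <- rep(NA_real_, ne)
  for (e in seq_len(ne)) {
    nb <- neighbors[[e]]
    if (length(nb) == 0) next
    out[e] <- mean(vapply(nb, function(j) stats::cor(traces[e, ], traces[j, ]),
                          numeric(1)))
  }
  out
}

#' Envelope multi-unit activity
#'
#' Bandpass (500-5000 Hz), full-wave rectification, low-pass (200 Hz) and
#' downsampling to 1 kHz; all four parameters configurable.
#'
#' @param x Raw trace, uV.
#' @param fs Sampling rate, Hz.
#' @param band High-frequency band, Hz.
#' @param lowpass Envelope smoothing cutoff, Hz.
#' @param out_fs Output sampling rate, Hz (must divide `fs`).
#' @export
emua <- function(x, fs = 30000, band = c(500, 5000), lowpass = 200,
                 out_fs = 1000) {
  stopifnot(fs %% out_fs == 0)
  M <- if (is.matrix(x)) t(x) else matrix(x, ncol = 1)
  env <- emua_cols(M, fs, band, lowpass, out_fs)
  if (is.matrix(x)) t(env) else as.numeric(env)
}

# column-vectorized eMUA used for trial blocks
emua_cols <- function(M, fs, band = c(500, 5000), lowpass = 200, out_fs = 1000) {
  bf <- signal::butter(2, band / (fs / 2), type = "pass")
  y <- abs(filtfilt_cols(bf$b, bf$a, M))
  lf <- signal::butter(2, lowpass / (fs / 2), type = "low")
  env <- filtfilt_cols(lf$b, lf$a, y)
  env[seq(1, nrow(env), by = fs / out_fs), , drop = FALSE]
}

#' Evoked SNR from trial eMUA
#'
#' Peak of the trial-averaged eMUA in the stimulation window, minus the
#' mean baseline eMUA, divided by the SD of the (trial-averaged) baseline
#' eMUA.
#'
#' @param emua_trials trials x samples matrix of eMUA traces.
#' @param baseline_idx,stim_idx Column indices of the two windows.
#' @export
evoked_snr <- function(emua_trials, baseline_idx, stim_idx) {
  stopifnot(nrow(emua_trials) >= 2)
  avg <- colMeans(emua_trials)
  base_sd <- stats::sd(avg[baseline_idx])
  if (base_sd <= 0) stop("zero baseline SD: evoked SNR undefined")
  (max(avg[stim_idx]) - mean(avg[baseline_idx])) / base_sd
}

#' Session averaging and within-array min-max normalization
#'
#' Per-electrode metrics are averaged across sessions (functional
#' electrodes only -- screening precedes averaging and normalization),
#' then normalized within the array as `(x - min) / max(x - min)` over
#' functional electrodes, guaranteeing values in \[0, 1\].  Session SD is
#' retained as the session-to-session variability measure.  Undefined
#' per-session values (e.g. electrodes with no snippets) propagate as
#' missing, never as zeros.
#'
#' @param metrics Long data.frame with `electrode_id`, `session`, and
#'   metric columns.
#' @param functional Logical mask over electrode ids.
#' @param columns Metric columns to aggregate.
#' @return data.frame: per electrode, `<col>_mean`, `<col>_sd`,
#'   `<col>_norm` (NA for nonfunctional electrodes).
#' @export
normalize_and_aggregate <- function(metrics, functional,
                                    columns = setdiff(names(metrics),
                                                      c("electrode_id", "session"))) {
  ids <- sort(unique(metrics$electrode_id))
  stopifnot(length(functional) >= max(ids))
  out <- data.frame(electrode_id = ids, functional = functional[ids])
  for (cl in columns) {
    mn <- tapply(metrics[[cl]], metrics$electrode_id, mean, na.rm = TRUE)[as.character(ids)]
    sdv <- tapply(metrics[[cl]], metrics$electrode_id, stats::sd, na.rm = TRUE)[as.character(ids)]
    mn[!out$functional] <- NA
    mn[is.nan(mn)] <- NA
    if (all(is.na(mn))) {
      out[[paste0(cl, "_mean")]] <- as.numeric(mn)
      out[[paste0(cl, "_sd")]] <- as.numeric(sdv)
      out[[paste0(cl, "_norm")]] <- rep(NA_real_, length(mn))
      next
    }
    rng <- range(mn, na.rm = TRUE)
    if (!all(is.finite(rng))) {
      nrm <- rep(NA_real_, length(mn))
    } else if (rng[2] - rng[1] <= 0) {
      warning("degenerate normalization for '", cl, "': all values equal")
      nrm <- ifelse(is.na(mn), NA_real_, 0)
    } else {
      nrm <- (mn - rng[1]) / (rng[2] - rng[1])
    }
    out[[paste0(cl, "_mean")]] <- as.numeric(mn)
    out[[paste0(cl, "_sd")]] <- as.numeric(sdv)
    out[[paste0(cl, "_norm")]] <- as.numeric(nrm)
  }
  out
}

#' Full recording-to-metric pipeline
#'
#' Runs impedance screening, then per session: bandpass filtering,
#' threshold-crossing extraction, representative PTPV, noise floor, SNR
#' and neighbor correlations; finally session averaging and within-array
#' normalization.
#'
#' @param rec A `recording_set` from [simulate_spontaneous()].
#' @param impedances data.frame from [simulate_impedances()]
#'   (`electrode_id`, `session`, `impedance`).
#' @param coating `"sirof"` or `"platinum"`.
#' @param neighbors Optional neighbor list for the neighbor-correlation
#'   metric.
#' @param connected Logical connectivity mask (unconnected electrodes are
#'   dropped from all metrics).
#' @return List of class `electrode_metrics`: `session_metrics` (long
#'   per-session table), `electrode_metrics` (aggregated + normalized),
#'   `functional` mask.
#' @export
run_metric_pipeline <- function(rec, impedances, coating = "sirof",
                                neighbors = NULL,
                                connected = rep(TRUE, nrow(rec$sessions[[1]]))) {
  ne <- nrow(rec$sessions[[1]])
  zbar <- tapply(impedances$impedance, impedances$electrode_id, mean)
  zvec <- rep(NA_real_, ne)
  zvec[as.integer(names(zbar))] <- as.numeric(zbar)
  functional <- impedance_screen(zvec, coating) & connected
  rows <- list()
  for (k in seq_along(rec$sessions)) {
    X <- rec$sessions[[k]]
    Xf <- bandpass_filter(X, rec$fs)
    nc <- if (!is.null(neighbors)) neighbor_correlation(Xf, neighbors) else
      rep(NA_real_, ne)
    zk <- impedances$impedance[impedances$session == k]
    for (e in seq_len(ne)) {
      if (!functional[e]) next
      sn <- detect_and_extract(Xf[e, ], rec$fs)
      m <- if (length(sn$events)) noise_floor_snr(Xf[e, ], sn) else
        list(noise_floor = 2 * stats::sd(Xf[e, ]), snr = NA_real_, ptpv = NA_real_)
      rows[[length(rows) + 1]] <- data.frame(
        electrode_id = e, session = k,
        impedance = if (length(zk) >= e) zk[e] else zvec[e],
        ptpv = m$ptpv, noise_floor = m$noise_floor, snr = m$snr,
        neighbor_corr = nc[e], n_snippets = length(sn$events))
    }
  }
  sm <- do.call(rbind, rows)
  agg <- normalize_and_aggregate(sm, functional,
                                 columns = c("impedance", "ptpv", "noise_floor",
                                             "snr", "neighbor_corr"))
  structure(list(session_metrics = sm, electrode_metrics = agg,
                 functional = functional, coating = coating),
            class = "electrode_metrics")
}

#' Evoked SNR for every electrode of an evoked set
#'
#' @param ev An `evoked_set` from [simulate_evoked()].
#' @return Numeric vector of per-electrode evoked SNRs.
#' @export
evoked_snr_by_electrode <- function(ev) {
  ne <- nrow(ev$trials[[1]])
  fs <- ev$fs
  dec <- fs / 1000
  bl <- unique(ceiling(ev$baseline_idx / dec))
  stm <- unique(ceiling(ev$stim_idx / dec))
  out <- numeric(ne)
  for (e in seq_len(ne)) {
    # samples x trials block, filtered in one vectorized pass
    B <- vapply(ev$trials, function(X) X[e, ],
                numeric(length(ev$baseline_idx) + length(ev$stim_idx)))
    M <- t(emua_cols(B, fs))
    nbl <- bl[bl <= ncol(M)]
    nst <- stm[stm <= ncol(M)]
    out[e] <- evoked_snr(M, nbl, nst)
  }
  out
}
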