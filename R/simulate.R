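#' Synthetic spike, LFP and ECoG generators
#'
#' The generators emulate the statistical structure of the recordings the
#' pipeline was designed for: pattern-selective spiking with trial-to-trial
#' noise (inhomogeneous Poisson by thinning), stimulus-evoked negative LFP
#' deflections in broadband noise, and ECoG with alternating synchronized
#' (high 0-12 Hz power) and desynchronized (low 0-12 Hz power) epochs.
#'
#' @name simulate
NULL

#' Neuron response model specification
#'
#' Rate model per trial: lambda(t) = baseline + sum of expressed Gaussian rate
#' bumps; each bump is expressed independently per trial with probability
#' `reliability`.
#'
#' @param baseline_rate baseline firing rate, Hz.
#' @param profiles named list (one entry per pattern label) of data frames with
#'   columns `peak_time` (ms), `peak_rate` (Hz), `peak_width` (ms, Gaussian SD).
#' @param reliability per-trial probability that a bump is expressed, in [0,1].
#' @param area_tag one of "S1", "non-S1", "V1".
#' @param depth recording depth from the cortical surface, micrometres.
#' @return a `neuron_spec`.
#' @export
neuron_spec <- function(baseline_rate, profiles, reliability = 1,
                        area_tag = "S1", depth = 600) {
  if (baseline_rate < 0) stop("baseline_rate must be >= 0")
  if (reliability < 0 || reliability > 1) stop("reliability must be in [0,1]")
  for (pr in profiles) {
    if (nrow(pr) > 0 && (any(pr$peak_rate < 0) || any(pr$peak_width <= 0))) {
      stop("peak rates must be >= 0 and widths > 0")
    }
  }
  structure(list(baseline_rate = baseline_rate, profiles = profiles,
                 reliability = reliability, area_tag = area_tag, depth = depth),
            class = "neuron_spec")
}

#' Random pattern-selective neuron specification
#'
#' Draws `n_bumps` pattern-specific Gaussian rate bumps per pattern with peak
#' times uniform over `peak_range`.
#'
#' @param seed integer seed.
#' @param labels pattern labels.
#' @param baseline_rate Hz.
#' @param n_bumps bumps per pattern.
#' @param peak_rate,peak_width bump height (Hz) and Gaussian SD (ms).
#' @param peak_range ms range the bump peaks are drawn from.
#' @param reliability per-trial bump expression probability.
#' @param area_tag,depth neuron metadata.
#' @return a `neuron_spec`.
#' @export
random_neuron_spec <- function(seed, labels = CANONICAL_LABELS,
                               baseline_rate = 5, n_bumps = 3,
                               peak_rate = 30, peak_width = 10,
                               peak_range = c(30, 550), reliability = 0.8,
                               area_tag = "S1", depth = 600) {
  set.seed(seed)
  profiles <- lapply(labels, function(lb) {
    data.frame(
      peak_time = sort(stats::runif(n_bumps, peak_range[1], peak_range[2])),
      peak_rate = rep(peak_rate, n_bumps),
      peak_width = rep(peak_width, n_bumps)
    )
  })
  names(profiles) <- labels
  neuron_spec(baseline_rate, profiles, reliability, area_tag, depth)
}

new_sweep_set <- function(neuron_id, sweeps, pre_span, post_span,
                          area_tag = "S1", depth = 600, trial_ids = NULL) {
  stopifnot(length(sweeps) >= 1)
  structure(list(neuron_id = neuron_id, area_tag = area_tag, depth = depth,
                 sweeps = sweeps, pretrigger_span = pre_span,
                 posttrigger_span = post_span, trial_ids = trial_ids),
            class = "sweep_set")
}

#' @export
print.sweep_set <- function(x, ...) {
  cat(sprintf("<sweep_set %s [%s, %.0f um]: %d patterns, %d sweeps, spans -%.0f/+%.0f ms>\n",
              x$neuron_id, x$area_tag, x$depth, length(x$sweeps),
              sum(lengths(x$sweeps)), x$pretrigger_span, x$posttrigger_span))
  invisible(x)
}

# inhomogeneous Poisson sample on [t0, t1] by thinning a homogeneous
# process at the rate ceiling
rpois_thin <- function(rate_fn, t0, t1, rate_max) {
  if (rate_max <= 0) return(numeric(0))
  n <- stats::rpois(1L, rate_max * (t1 - t0) / 1000)
  if (n == 0L) return(numeric(0))
  cand <- sort(stats::runif(n, t0, t1))
  keep <- stats::runif(n) < rate_fn(cand) / rate_max
  cand[keep]
}

#' Generate spike sweeps for one neuron
#'
#' Per trial, spikes are drawn from an inhomogeneous Poisson process by
#' thinning, with rate baseline + the sum of the bumps expressed on that trial.
#' Spike times are stored relative to stimulus onset (negative = pretrigger).
#'
#' @param spec a `neuron_spec`.
#' @param schedule a `session_schedule`.
#' @param seed integer seed.
#' @param pre_span_ms,post_span_ms stored sweep spans around onset (ms).
#' @return a `sweep_set` mapping pattern label to a list of spike-time vectors.
#' @export
generate_sweeps <- function(spec, schedule, seed = 1L,
                            pre_span_ms = 500, post_span_ms = 1000) {
  stopifnot(inherits(spec, "neuron_spec"), inherits(schedule, "session_schedule"))
  if (length(schedule$trial_onsets) == 0) stop("schedule is empty")
  if (pre_span_ms < 500 || post_span_ms < 1000) {
    stop("sweeps must store >= 500 ms pretrigger and >= 1000 ms post-trigger")
  }
  set.seed(seed)
  labels <- unique(schedule$trial_labels)
  sweeps <- stats::setNames(lapply(labels, function(x) list()), labels)
  trial_ids <- stats::setNames(lapply(labels, function(x) integer(0)), labels)
  for (i in seq_along(schedule$trial_onsets)) {
    lb <- schedule$trial_labels[i]
    prof <- spec$profiles[[lb]]
    if (is.null(prof)) prof <- data.frame(peak_time = numeric(0),
                                          peak_rate = numeric(0),
                                          peak_width = numeric(0))
    expressed <- if (nrow(prof) > 0) {
      prof[stats::runif(nrow(prof)) < spec$reliability, , drop = FALSE]
    } else prof
    rate_fn <- function(t) {
      r <- rep(spec$baseline_rate, length(t))
      for (j in seq_len(nrow(expressed))) {
        r <- r + expressed$peak_rate[j] *
          exp(-0.5 * ((t - expressed$peak_time[j]) / expressed$peak_width[j])^2)
      }
      r
    }
    rate_max <- spec$baseline_rate + sum(expressed$peak_rate)
    st <- rpois_thin(rate_fn, -pre_span_ms, post_span_ms, rate_max)
    sweeps[[lb]] <- c(sweeps[[lb]], list(st))
    trial_ids[[lb]] <- c(trial_ids[[lb]], i)
  }
  new_sweep_set(paste0("sim-", seed), sweeps, pre_span_ms, post_span_ms,
                area_tag = spec$area_tag, depth = spec$depth,
                trial_ids = trial_ids)
}

#' Generate a co-recorded synthetic population
#'
#' All neurons share the session schedule (and therefore trial indices), as in
#' simultaneous recording; their spikes are conditionally independent given
#' the schedule.
#'
#' @param specs list of `neuron_spec`.
#' @param schedule shared `session_schedule`.
#' @param seed integer seed; neuron i uses seed + i.
#' @inheritParams generate_sweeps
#' @return list of `sweep_set`.
#' @export
generate_population <- function(specs, schedule, seed = 1L,
                                pre_span_ms = 500, post_span_ms = 1000) {
  out <- lapply(seq_along(specs), function(i) {
    ss <- generate_sweeps(specs[[i]], schedule, seed = seed + i,
                          pre_span_ms = pre_span_ms, post_span_ms = post_span_ms)
    ss$neuron_id <- sprintf("n%02d", i)
    ss
  })
  out
}

new_trace <- function(values, sampling_rate, start_time = 0) {
  if (sampling_rate <= 0) stop("sampling_rate must be > 0")
  structure(list(sampling_rate = sampling_rate, start_time = start_time,
                 values = values),
            class = "continuous_trace")
}

#' @export
print.continuous_trace <- function(x, ...) {
  cat(sprintf("<continuous_trace: %d samples @ %g Hz, start %.0f ms>\n",
              length(x$values), x$sampling_rate, x$start_time))
  invisible(x)
}

#' Generate a voltage trace with stimulus-evoked negative LFP deflections
#'
#' Gaussian white noise plus, after each trial onset, a negative-going
#' deflection (half-sine) of the stated amplitude. Local sensory-evoked LFPs
#' in the superficial cortex are negative, so `response_amplitude` should be
#' <= 0; amplitude 0 yields pure noise.
#'
#' @param schedule a `session_schedule` (onsets in ms).
#' @param response_amplitude deflection peak, signal units (negative or 0).
#' @param noise_sd white-noise SD (>= 0).
#' @param seed integer seed.
#' @param sampling_rate_hz sampling rate (synthetic traces use 10 kHz).
#' @param latency_ms deflection onset after the trigger.
#' @param width_ms deflection duration.
#' @return a `continuous_trace` starting 500 ms before the first onset.
#' @export
generate_lfp_trace <- function(schedule, response_amplitude, noise_sd,
                               seed = 1L, sampling_rate_hz = 10000,
                               latency_ms = 8, width_ms = 25) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  set.seed(seed)
  t0 <- min(schedule$trial_onsets) - 500
  t1 <- max(schedule$trial_onsets) + 1000
  n <- round((t1 - t0) * sampling_rate_hz / 1000)
  v <- stats::rnorm(n, 0, noise_sd)
  dt_ms <- 1000 / sampling_rate_hz
  w_n <- max(1L, round(width_ms / dt_ms))
  bump <- response_amplitude * sin(pi * seq_len(w_n) / (w_n + 1))
  for (on in schedule$trial_onsets) {
    i0 <- round((on + latency_ms - t0) / dt_ms) + 1L
    idx <- i0:(i0 + w_n - 1L)
    ok <- idx >= 1L & idx <= n
    v[idx[ok]] <- v[idx[ok]] + bump[ok]
  }
  new_trace(v, sampling_rate_hz, start_time = t0)
}

#' Cut a continuous trace into trigger-aligned sweeps
#'
#' @param trace a `continuous_trace`.
#' @param onsets trigger times, ms.
#' @param pre_ms,post_ms spans around each trigger, ms.
#' @return matrix (sweeps x samples); sample 1 is at -pre_ms.
#' @export
cut_trace_sweeps <- function(trace, onsets, pre_ms, post_ms) {
  dt_ms <- 1000 / trace$sampling_rate
  n_samp <- round((pre_ms + post_ms) / dt_ms)
  out <- matrix(NA_real_, nrow = length(onsets), ncol = n_samp)
  for (i in seq_along(onsets)) {
    i0 <- round((onsets[i] - pre_ms - trace$start_time) / dt_ms) + 1L
    idx <- i0:(i0 + n_samp - 1L)
    if (any(idx < 1L) || any(idx > length(trace$values))) {
      stop("sweep window outside the recorded trace")
    }
    out[i, ] <- trace$values[idx]
  }
  attr(out, "pre_ms") <- pre_ms
  attr(out, "sampling_rate") <- trace$sampling_rate
  out
}

#' Generate an ECoG trace with labelled brain-state epochs
#'
#' Synchronized epochs carry strong low-frequency (0-12 Hz) oscillatory power;
#' desynchronized epochs carry weak broadband power. Sampled at 1 kHz.
#'
#' @param duration_ms total duration.
#' @param state_schedule data frame with columns `start`, `end` (ms) and
#'   `state` in {"synchronized","desynchronized"}; intervals must not overlap
#'   and must cover [0, duration_ms).
#' @param seed integer seed.
#' @param sync_amplitude,desync_amplitude oscillation / broadband scales.
#' @return a `continuous_trace` at 1 kHz.
#' @export
generate_ecog_trace <- function(duration_ms, state_schedule, seed = 1L,
                                sync_amplitude = 50, desync_amplitude = 5) {
  ss <- state_schedule[order(state_schedule$start), , drop = FALSE]
  if (nrow(ss) == 0) stop("state_schedule must be non-empty")
  if (any(ss$end <= ss$start)) stop("state intervals must have end > start")
  if (nrow(ss) > 1 && any(ss$start[-1] < ss$end[-nrow(ss)])) {
    stop("state intervals must not overlap")
  }
  if (ss$start[1] > 0 || ss$end[nrow(ss)] < duration_ms) {
    stop("state_schedule must cover the full duration")
  }
  set.seed(seed)
  fs <- 1000
  n <- round(duration_ms * fs / 1000)
  t_s <- (seq_len(n) - 1) / fs
  v <- stats::rnorm(n, 0, desync_amplitude)  # broadband floor everywhere
  # low-frequency oscillation components, gated by synchronized epochs
  freqs <- c(1, 2, 3.5, 5, 8)
  phases <- stats::runif(length(freqs), 0, 2 * pi)
  osc <- rowSums(sapply(seq_along(freqs), function(i) {
    sin(2 * pi * freqs[i] * t_s + phases[i])
  })) * sync_amplitude / sqrt(length(freqs))
  gate <- rep(FALSE, n)
  for (i in seq_len(nrow(ss))) {
    if (ss$state[i] == "synchronized") {
      i0 <- max(1L, floor(ss$start[i] * fs / 1000) + 1L)
      i1 <- min(n, ceiling(ss$end[i] * fs / 1000))
      gate[i0:i1] <- TRUE
    }
  }
  v[gate] <- v[gate] + osc[gate]
  new_trace(v, fs, start_time = 0)
}
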