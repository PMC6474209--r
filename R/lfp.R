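#' Local field potential event detection
#'
#' Two detectors: single-pulse sensory-evoked LFPs (SE-LFP) found in the
#' outlier-trimmed average of aligned sweeps against a -5 SD gate, and
#' pattern-evoked LFP events found in a boxcar-smoothed, decimated,
#' band-passed single segment as drops of at least 2 SDs below the pretrigger
#' baseline lasting at least 10 ms.
#'
#' @name lfp_analysis
NULL

# running median (or moving average) with an arbitrary window length;
# even windows are supported (stats::runmed requires odd)
running_filter <- function(x, width = 10L, method = c("median", "mean")) {
  method <- match.arg(method)
  f <- if (method == "median") stats::median else mean
  n <- length(x)
  lead <- (width - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    i0 <- max(1L, i - lead)
    f(x[i0:min(n, i0 + width - 1L)])
  }, numeric(1))
}

#' Detect a single-pulse sensory-evoked LFP
#'
#' The aligned sweeps are trimmed per time point to their central 50% of
#' values (removing the 50% most extreme) and averaged. Baseline mean and SD
#' come from the 100 ms pretrigger of the trimmed average. A response is
#' detected if the trimmed average drops below -5 SD within 100 ms after the
#' trigger. On detection the average is passed through a 10-sample running
#' median filter and the latency (the downward -2 SD crossing leading into the
#' response trough), duration (time until the -2 SD recrossing) and amplitude
#' (the minimum inside the response) are extracted from the filtered signal.
#'
#' @param sweeps matrix of aligned trace segments (rows = sweeps), as from
#'   [cut_trace_sweeps()]; needs >= 4 sweeps and >= 100 ms pretrigger.
#' @param sampling_rate_hz sampling rate; defaults to the matrix attribute.
#' @param pre_ms pretrigger span of the segments; defaults to the attribute.
#' @param filter_method running "median" (default) or moving "mean".
#' @param filter_width filter window, samples.
#' @return list: `detected`; when detected also `latency_ms`, `duration_ms`,
#'   `amplitude` (signal units, negative).
#' @export
detect_se_lfp <- function(sweeps, sampling_rate_hz = attr(sweeps, "sampling_rate"),
                          pre_ms = attr(sweeps, "pre_ms"),
                          filter_method = "median", filter_width = 10L) {
  if (nrow(sweeps) < 4) stop("need >= 4 sweeps")
  if (is.null(pre_ms) || pre_ms < 100) stop("need >= 100 ms pretrigger")
  dt_ms <- 1000 / sampling_rate_hz
  n_col <- ncol(sweeps)
  # per-timepoint symmetric trim to the central 50% of values
  n_drop <- floor(nrow(sweeps) / 4)
  avg <- apply(sweeps, 2, function(col) {
    s <- sort(col)
    mean(s[(n_drop + 1L):(length(s) - n_drop)])
  })
  t_ms <- (seq_len(n_col) - 1) * dt_ms - pre_ms
  base_idx <- which(t_ms >= -100 & t_ms < 0)
  b_mean <- mean(avg[base_idx])
  b_sd <- stats::sd(avg[base_idx])
  post100 <- which(t_ms >= 0 & t_ms < 100)
  if (!(min(avg[post100]) < b_mean - 5 * b_sd)) {
    return(list(detected = FALSE))
  }
  filt <- running_filter(avg, filter_width, filter_method)
  thr <- b_mean - 2 * b_sd
  post <- which(t_ms >= 0)
  # anchor the -2 SD crossings to the response trough that passed the -5 SD
  # gate, so single-sample noise excursions cannot define the response
  trough <- post100[which.min(filt[post100])]
  i_tr <- match(trough, post)
  pre_above <- which(filt[post[seq_len(i_tr)]] >= thr)
  i_on <- if (length(pre_above)) max(pre_above) + 1L else 1L
  i_off <- i_tr
  while (i_off <= length(post) && filt[post[i_off]] < thr) i_off <- i_off + 1L
  seg <- post[i_on:min(i_off, length(post))]
  list(detected = TRUE,
       latency_ms = t_ms[post[i_on]],
       duration_ms = (i_off - i_on) * dt_ms,
       amplitude = min(filt[seg]))
}

#' Detect pattern-evoked LFP events in one 400 + 400 ms segment
#'
#' Processing chain: 10 ms rolling boxcar mean, decimation to 1 kHz,
#' first-order Butterworth band-pass (50-499 Hz, applied forward-backward for
#' zero phase), DC removal by subtracting the pretrigger median. Baseline mean
#' and SD come from the pretrigger epoch; an event is a drop of at least
#' `threshold_sd` SDs below baseline lasting at least `min_duration_ms`.
#' Events that start before the trigger and continue past it are tagged "pre".
#'
#' @param segment numeric vector covering `pre_ms` + `post_ms` of signal, or a
#'   one-row matrix from [cut_trace_sweeps()].
#' @param sampling_rate_hz input sampling rate (nominally 100 kHz; synthetic
#'   traces use 10 kHz and the decimation factor rescales accordingly).
#' @param pre_ms,post_ms epoch spans (400 ms each).
#' @param threshold_sd detection threshold, baseline SDs (default 2).
#' @param min_duration_ms minimum event duration (default 10).
#' @return data frame of events: `onset_ms` (relative to the trigger),
#'   `duration_ms`, `amplitude` (baseline-relative minimum, negative),
#'   `epoch` ("pre"/"post").
#' @export
detect_pattern_lfps <- function(segment, sampling_rate_hz = 10000,
                                pre_ms = 400, post_ms = 400,
                                threshold_sd = 2, min_duration_ms = 10) {
  x <- as.numeric(segment)
  if (length(x) < round((pre_ms + post_ms) * sampling_rate_hz / 1000)) {
    stop("segment shorter than the pre + post epochs")
  }
  if (pre_ms < 400 || post_ms < 400) stop("epochs must cover 400 ms each")
  # 10 ms rolling boxcar mean (edges use shrinking windows)
  w <- max(1L, round(10 * sampling_rate_hz / 1000))
  sm <- running_filter(x, w, "mean")
  # decimate to 1 kHz
  factor <- round(sampling_rate_hz / 1000)
  y <- sm[seq(1L, length(sm), by = factor)]
  t_ms <- seq_along(y) - 1 - pre_ms
  # pull the DC level out before filtering so the zero-phase pass is free of
  # offset-driven edge transients (the filter is linear, so this commutes)
  y <- y - stats::median(y[t_ms < 0])
  # first-order Butterworth band-pass 50-499 Hz at 1 kHz, zero-phase
  bf <- signal::butter(1, c(50, 499) / 500, type = "pass")
  y <- signal::filtfilt(bf, y)
  y <- y - stats::median(y[t_ms < 0])
  b_mean <- mean(y[t_ms < 0])
  b_sd <- stats::sd(y[t_ms < 0])
  below <- y < b_mean - threshold_sd * b_sd
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values & r$lengths >= min_duration_ms)
  if (!length(keep)) {
    return(data.frame(onset_ms = numeric(0), duration_ms = numeric(0),
                      amplitude = numeric(0), epoch = character(0)))
  }
  data.frame(
    onset_ms = t_ms[starts[keep]],
    duration_ms = r$lengths[keep],
    amplitude = vapply(keep, function(k) {
      min(y[starts[k]:ends[k]]) - b_mean
    }, numeric(1)),
    epoch = ifelse(t_ms[starts[keep]] < 0, "pre", "post")
  )
}

#' Boxcar AUC reconstruction of LFP events
#'
#' Each event is replaced by a boxcar of height |amplitude| and length equal
#' to its duration; the AUC of each boxcar is |amplitude| x duration.
#'
#' @param events event data frame from [detect_pattern_lfps()].
#' @return numeric vector of per-event AUCs (signal units x ms).
#' @export
lfp_boxcar_auc <- function(events) {
  if (nrow(events) == 0) return(numeric(0))
  if (any(events$duration_ms <= 0)) stop("event durations must be > 0")
  abs(events$amplitude) * events$duration_ms
}

#' Paired pre/post comparison of LFP event statistics
#'
#' Summarises the chosen measure per sweep in the pre and post epochs and
#' applies the Wilcoxon signed-rank test to the paired values.
#'
#' @param events_per_sweep list of event data frames, one per sweep.
#' @param measure "count", "duration" (mean), "amplitude" (mean), or "auc"
#'   (summed boxcar AUC).
#' @return list with `statistic`, `p_value`, `n`, and the paired summaries;
#'   `degenerate = TRUE` (with `p_value = NA`) when fewer than 2 sweeps or all
#'   paired differences are zero.
#' @export
compare_pre_post <- function(events_per_sweep,
                             measure = c("count", "duration", "amplitude", "auc")) {
  measure <- match.arg(measure)
  summarise <- function(ev) {
    if (nrow(ev) == 0) return(0)
    switch(measure,
           count = nrow(ev),
           duration = mean(ev$duration_ms),
           amplitude = mean(ev$amplitude),
           auc = sum(lfp_boxcar_auc(ev)))
  }
  pre <- vapply(events_per_sweep,
                function(ev) summarise(ev[ev$epoch == "pre", , drop = FALSE]),
                numeric(1))
  post <- vapply(events_per_sweep,
                 function(ev) summarise(ev[ev$epoch == "post", , drop = FALSE]),
                 numeric(1))
  if (length(pre) < 2 || all(post - pre == 0)) {
    return(list(statistic = NA_real_, p_value = NA_real_, n = length(pre),
                pre = pre, post = post, degenerate = TRUE))
  }
  wt <- suppressWarnings(stats::wilcox.test(post, pre, paired = TRUE,
                                            exact = FALSE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n = length(pre), pre = pre, post = post, degenerate = FALSE)
}
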