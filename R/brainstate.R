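#' ECoG brain-state segmentation and state-conditioned decoding
#'
#' The ECoG spectral density is computed over 1,000 ms segments with 125 ms
#' overlap and constant (mean) detrending; the 0-12 Hz (delta + theta + alpha)
#' power is summed per segment into a compound value. A desynchronized epoch
#' occurs where the compound value drops below its recording-wide median for
#' at least two segments in sequence. A stimulus presentation counts as
#' desynchronized only if it starts inside a desynchronized interval with
#' more than 350 ms of it remaining.
#'
#' @name brain_state
NULL

#' Segment an ECoG trace into synchronized / desynchronized states
#'
#' @param ecog a `continuous_trace` at 1 kHz (>= 2 segments long).
#' @param segment_ms analysis segment length (default 1000).
#' @param overlap_ms overlap between consecutive segments (default 125).
#' @param band_hz summed frequency band, inclusive (default c(0, 12)).
#' @param min_run below-median segments required in sequence (default 2).
#' @return a `state_segmentation`: per-segment times and compound 0-12 Hz
#'   power, the median, and labelled state intervals tiling the recording.
#' @export
segment_states <- function(ecog, segment_ms = 1000, overlap_ms = 125,
                           band_hz = c(0, 12), min_run = 2L) {
  fs <- ecog$sampling_rate
  x <- ecog$values
  seg_n <- round(segment_ms * fs / 1000)
  step_n <- round((segment_ms - overlap_ms) * fs / 1000)
  if (length(x) < seg_n + step_n) stop("trace shorter than 2 segments")
  starts <- seq(1L, length(x) - seg_n + 1L, by = step_n)
  freqs <- (seq_len(seg_n) - 1) * fs / seg_n
  band <- freqs >= band_hz[1] & freqs <= band_hz[2]
  power <- vapply(starts, function(i0) {
    seg <- x[i0:(i0 + seg_n - 1L)]
    seg <- seg - mean(seg)  # constant (mean) detrend
    p <- abs(stats::fft(seg))^2 / seg_n
    sum(p[band])
  }, numeric(1))
  med <- stats::median(power)
  below <- power < med
  r <- rle(below)
  ends <- cumsum(r$lengths)
  run_starts <- ends - r$lengths + 1L
  seg_start_ms <- ecog$start_time + (starts - 1L) / fs * 1000
  seg_end_ms <- seg_start_ms + segment_ms
  rec_end <- ecog$start_time + length(x) / fs * 1000
  desync <- which(r$values & r$lengths >= min_run)
  intervals <- data.frame(start = numeric(0), end = numeric(0),
                          state = character(0))
  for (k in desync) {
    intervals <- rbind(intervals, data.frame(
      start = seg_start_ms[run_starts[k]],
      end = min(seg_end_ms[ends[k]], rec_end),
      state = "desynchronized"))
  }
  # synchronized intervals fill the complement so states tile the recording
  intervals <- intervals[order(intervals$start), , drop = FALSE]
  tiled <- data.frame(start = numeric(0), end = numeric(0), state = character(0))
  cursor <- ecog$start_time
  for (i in seq_len(nrow(intervals))) {
    if (intervals$start[i] > cursor) {
      tiled <- rbind(tiled, data.frame(start = cursor,
                                       end = intervals$start[i],
                                       state = "synchronized"))
    }
    tiled <- rbind(tiled, intervals[i, ])
    cursor <- intervals$end[i]
  }
  if (cursor < rec_end) {
    tiled <- rbind(tiled, data.frame(start = cursor, end = rec_end,
                                     state = "synchronized"))
  }
  rownames(tiled) <- NULL
  structure(list(segment_times = seg_start_ms, compound_power = power,
                 median_power = med, state_intervals = tiled),
            class = "state_segmentation")
}

#' @export
print.state_segmentation <- function(x, ...) {
  de <- x$state_intervals$state == "desynchronized"
  cat(sprintf("<state_segmentation: %d segments, %d desynchronized interval(s), %.0f ms desync>\n",
              length(x$compound_power), sum(de),
              sum(x$state_intervals$end[de] - x$state_intervals$start[de])))
  invisible(x)
}

#' Classify a stimulus presentation by concurrent brain state
#'
#' Desynchronized iff the onset falls inside a desynchronized interval and
#' more than `margin_ms` (350 ms) of that interval remains after the onset.
#'
#' @param onset_ms stimulus onset time(s).
#' @param seg a `state_segmentation`.
#' @param margin_ms required remaining desynchronized time (default 350).
#' @return character vector: "synchronized" or "desynchronized".
#' @export
classify_stimulus_state <- function(onset_ms, seg, margin_ms = 350) {
  iv <- seg$state_intervals
  span <- range(iv$start, iv$end)
  vapply(onset_ms, function(on) {
    if (on < span[1] || on >= span[2]) stop("onset outside the segmented span")
    hit <- which(iv$state == "desynchronized" & iv$start <= on & on < iv$end)
    if (length(hit) && (iv$end[hit[1]] - on) > margin_ms) "desynchronized"
    else "synchronized"
  }, character(1))
}

#' State-conditioned decoding
#'
#' Runs the decoder separately on the trials of each brain state with
#' bootstrap group size N = 3 (the state-segmented subsets are small).
#' Patterns whose bootstrap fails within a state are omitted with a warning;
#' a state where every pattern fails yields an error recorded in the result.
#'
#' @param sweepset a `sweep_set` with per-pattern `trial_ids`.
#' @param trial_states named list (per pattern) of state labels aligned with
#'   the pattern's sweeps, or a vector of states indexed by session trial id.
#' @param windows the neuron's `time_window_set`.
#' @param params a `decoder_params`; `group_size` is forced to `state_group_size`.
#' @param state_group_size bootstrap N for state-conditioned runs (default 3).
#' @return named list with one `decoding_result` (or error message) per state.
#' @export
state_conditioned_decoding <- function(sweepset, trial_states, windows,
                                       params = decoder_params(),
                                       state_group_size = 3L) {
  params$group_size <- as.integer(state_group_size)
  per_pattern <- if (is.list(trial_states)) {
    trial_states
  } else {
    lapply(sweepset$trial_ids, function(ids) trial_states[ids])
  }
  out <- list()
  for (st in c("synchronized", "desynchronized")) {
    filt <- lapply(names(sweepset$sweeps), function(p) {
      which(per_pattern[[p]] == st)
    })
    names(filt) <- names(sweepset$sweeps)
    out[[st]] <- tryCatch({
      flat <- sweepset_auc_matrix(sweepset, windows, params, trial_filter = filt)
      decode_core(flat$auc, flat$labels, flat$nonempty, params)
    }, error = function(e) {
      structure(list(message = conditionMessage(e)), class = "state_failure")
    })
  }
  out
}
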