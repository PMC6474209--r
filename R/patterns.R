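#' Stimulation patterns and session schedules
#'
#' A stimulation pattern is a labelled spatiotemporal schedule of electrical
#' pulses delivered through four skin channels. The canonical experiment uses
#' eight patterns (F5, S5, F10, S10, F20, S20, Finf, Sinf), each lasting less
#' than 350 ms, presented 50-100 times each in pseudo-random order with 1.8 s
#' between consecutive onsets.
#'
#' @name patterns
NULL

CANONICAL_LABELS <- c("F5", "S5", "F10", "S10", "F20", "S20", "Finf", "Sinf")

new_stim_pattern <- function(label, channel_pulses, duration) {
  stopifnot(is.character(label), length(label) == 1L)
  if (!is.list(channel_pulses)) stop("channel_pulses must be a list")
  for (ch in channel_pulses) {
    if (length(ch) > 0) {
      if (any(ch < 0)) stop("pulse times must be non-negative")
      if (is.unsorted(ch, strictly = TRUE)) {
        stop("pulse times must be strictly increasing per channel")
      }
    }
  }
  if (duration <= 0) stop("duration must be positive")
  structure(
    list(label = label, channel_pulses = channel_pulses, duration = duration),
    class = "stim_pattern"
  )
}

#' Generate stimulation patterns
#'
#' In canonical mode (`n_patterns = 8`, `canonical = TRUE`) returns the eight
#' labelled patterns from the packaged event lists (synthetic, illustrative
#' pulse schedules following the F/S fast/slow structure of the canonical set).
#' In generic mode, invents `n_patterns` pairwise-distinct random pulse
#' schedules.
#'
#' @param seed integer seed; generic-mode output is deterministic given it.
#' @param n_patterns number of patterns (>= 2).
#' @param n_channels number of stimulation channels (canonical: 4).
#' @param duration_ms pattern duration in ms (< 350 in canonical mode).
#' @param canonical if TRUE and `n_patterns == 8`, return the canonical set.
#' @return list of `stim_pattern` objects.
#' @export
generate_patterns <- function(seed = 1L, n_patterns = 8L, n_channels = 4L,
                              duration_ms = 300, canonical = n_patterns == 8L) {
  if (n_patterns < 2L) stop("n_patterns must be >= 2")
  if (duration_ms <= 0) stop("duration_ms must be positive")
  if (canonical) {
    if (duration_ms >= 350) stop("canonical patterns must last < 350 ms")
    return(canonical_patterns())
  }
  set.seed(seed)
  pats <- vector("list", n_patterns)
  for (i in seq_len(n_patterns)) {
    repeat {
      chans <- lapply(seq_len(n_channels), function(ch) {
        n_pulses <- sample(3:12, 1L)
        sort(sample(seq(0, duration_ms - 1), n_pulses))
      })
      cand <- new_stim_pattern(sprintf("P%02d", i), chans, duration_ms)
      distinct <- all(vapply(pats[seq_len(i - 1L)], function(p) {
        pattern_hamming(p, cand) > 0
      }, logical(1)))
      if (distinct) break
    }
    pats[[i]] <- cand
  }
  pats
}

#' @rdname generate_patterns
#' @export
canonical_patterns <- function() {
  path <- system.file("extdata", "canonical_patterns_synthetic.json",
                      package = "spikedecoder")
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(p) {
    new_stim_pattern(p$label,
                     lapply(p$channel_pulses, function(ch) unlist(ch, use.names = FALSE)),
                     p$duration)
  })
}

#' Hamming distance between two patterns on a 1 ms pulse-train discretization
#'
#' Each channel is binarised to 1 ms bins (pulse present / absent); the
#' distance is the number of differing bins summed over channels.
#' @param a,b `stim_pattern` objects.
#' @param resolution_ms bin width for discretization.
#' @return non-negative integer count of differing bins.
#' @export
pattern_hamming <- function(a, b, resolution_ms = 1) {
  span <- ceiling(max(a$duration, b$duration) / resolution_ms)
  n_ch <- max(length(a$channel_pulses), length(b$channel_pulses))
  total <- 0L
  for (ch in seq_len(n_ch)) {
    ba <- bb <- logical(span)
    if (ch <= length(a$channel_pulses)) {
      ba[pmin(span, floor(a$channel_pulses[[ch]] / resolution_ms) + 1L)] <- TRUE
    }
    if (ch <= length(b$channel_pulses)) {
      bb[pmin(span, floor(b$channel_pulses[[ch]] / resolution_ms) + 1L)] <- TRUE
    }
    total <- total + sum(ba != bb)
  }
  total
}

#' Build a pseudo-random session schedule
#'
#' Presentations of each pattern are interleaved in repeated randomized order
#' (each block presents every pattern once in a fresh random order), separated
#' by a fixed inter-trial interval.
#'
#' @param labels pattern labels to present.
#' @param repetitions presentations per pattern (50-100 in the canonical design).
#' @param inter_trial_interval_ms onset-to-onset separation, ms.
#' @param seed integer seed.
#' @return a `session_schedule`: trial onsets (ms), labels, interval, repetitions.
#' @export
build_schedule <- function(labels = CANONICAL_LABELS, repetitions = 100L,
                           inter_trial_interval_ms = 1800, seed = 1L) {
  if (repetitions < 1L) stop("repetitions must be >= 1")
  if (repetitions < 50L || repetitions > 100L) {
    warning("canonical design uses 50-100 repetitions per pattern")
  }
  set.seed(seed)
  order <- unlist(lapply(seq_len(repetitions), function(i) sample(labels)))
  onsets <- (seq_along(order) - 1L) * inter_trial_interval_ms
  structure(
    list(trial_onsets = onsets, trial_labels = order,
         inter_trial_interval = inter_trial_interval_ms,
         repetitions_per_pattern = repetitions),
    class = "session_schedule"
  )
}

#' @export
print.stim_pattern <- function(x, ...) {
  cat(sprintf("<stim_pattern %s: %d channels, %d pulses, %.0f ms>\n",
              x$label, length(x$channel_pulses),
              sum(lengths(x$channel_pulses)), x$duration))
  invisible(x)
}

#' @export
print.session_schedule <- function(x, ...) {
  cat(sprintf("<session_schedule: %d trials, %d patterns x %d reps, ITI %.0f ms>\n",
              length(x$trial_onsets), length(unique(x$trial_labels)),
              x$repetitions_per_pattern, x$inter_trial_interval))
  invisible(x)
}
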