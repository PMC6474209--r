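# shared builders for synthetic fixtures; all randomness is seeded by callers

# small session over `k` pattern labels
tiny_schedule <- function(k = 8, repetitions = 24, seed = 1) {
  suppressWarnings(build_schedule(paste0("P", seq_len(k)),
                                  repetitions = repetitions, seed = seed))
}

# neuron whose patterns are separated by well-spaced, strong response peaks
separable_spec <- function(k = 8, baseline = 3, peak_rate = 120,
                           reliability = 1, width = 10) {
  labels <- paste0("P", seq_len(k))
  profiles <- lapply(seq_len(k), function(i) {
    data.frame(peak_time = 50 + (i - 1) * 500 / k,
               peak_rate = peak_rate, peak_width = width)
  })
  names(profiles) <- labels
  neuron_spec(baseline, profiles, reliability = reliability)
}

# neuron with identical response statistics for every pattern (no signal)
signal_free_spec <- function(k = 8, baseline = 8) {
  labels <- paste0("P", seq_len(k))
  profiles <- lapply(labels, function(l) {
    data.frame(peak_time = 100, peak_rate = 20, peak_width = 15)
  })
  names(profiles) <- labels
  neuron_spec(baseline, profiles, reliability = 1)
}

# hand-built density curve on a uniform 1 ms grid
make_curve <- function(values, from = 0, bandwidth = 10) {
  structure(list(time_grid = seq(from, from + length(values) - 1),
                 values = values, bandwidth = bandwidth,
                 n_spikes = 100L, n_sweeps = 10L, zero_spikes = FALSE),
            class = "density_curve")
}

gaussian_bump <- function(grid, mu, sd, height = 1) {
  height * exp(-0.5 * ((grid - mu) / sd)^2)
}

# two co-recorded neurons that each discriminate a disjoint half of 4 patterns
complementary_pop <- function(sched, seed) {
  labels <- paste0("P", 1:4)
  early <- lapply(1:4, function(i) {
    data.frame(peak_time = if (i <= 2) 80 + (i - 1) * 150 else 120,
               peak_rate = 50, peak_width = 10)
  })
  late <- lapply(1:4, function(i) {
    data.frame(peak_time = if (i > 2) 80 + (i - 3) * 150 else 120,
               peak_rate = 50, peak_width = 10)
  })
  names(early) <- names(late) <- labels
  generate_population(list(neuron_spec(5, early), neuron_spec(5, late)),
                      sched, seed = seed)
}

# quick decoder params for scaled-down tests
fast_params <- function(..., seed = 1) {
  decoder_params(group_size = 3L, target_combinations = 50L, k_neighbors = 5L,
                 n_iterations = 3L, span_ms = 600, seed = seed, ...)
}
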