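test_that("alternating high/low delta-power epochs are recovered from ECoG", {
  epochs <- data.frame(start = seq(0, 55000, by = 5000),
                       end = seq(5000, 60000, by = 5000),
                       state = rep(c("synchronized", "desynchronized"), 6))
  tr <- generate_ecog_trace(60000, epochs, seed = 1)
  seg <- segment_states(tr)
  iv <- seg$state_intervals
  # Jaccard overlap between true and recovered desynchronized time
  grid <- seq(0, 59999)
  truth <- rep(FALSE, length(grid))
  for (i in which(epochs$state == "desynchronized")) {
    truth[grid >= epochs$start[i] & grid < epochs$end[i]] <- TRUE
  }
  found <- rep(FALSE, length(grid))
  for (i in which(iv$state == "desynchronized")) {
    found[grid >= iv$start[i] & grid < iv$end[i]] <- TRUE
  }
  jaccard <- sum(truth & found) / sum(truth | found)
  expect_gt(jaccard, 0.8)
  # intervals tile the recording
  expect_equal(iv$start[1], 0)
  expect_true(all(abs(iv$start[-1] - iv$end[-nrow(iv)]) < 1e-9))
})

test_that("single below-median segments stay synchronized; blocks turn desynchronized", {
  # build a trace whose per-segment 0-12 Hz power we control: strong 5 Hz
  # oscillation in "s" segments, weak broadband noise in "d" segments
  states <- c("s", "s", "d", "s", "d", "d", "s", "s")
  x <- unlist(lapply(states, function(st) {
    t <- seq(0, 0.999, by = 0.001)
    if (st == "s") 100 * sin(2 * pi * 5 * t) else stats::rnorm(1000, 0, 0.5)
  }))
  tr <- structure(list(sampling_rate = 1000, start_time = 0, values = x),
                  class = "continuous_trace")
  sg <- segment_states(tr, overlap_ms = 0)
  below <- sg$compound_power < sg$median_power
  expect_equal(below, states == "d")
  iv <- sg$state_intervals
  de <- iv[iv$state == "desynchronized", ]
  # only the 2-segment block at segments 5-6 qualifies; the isolated segment 3
  # stays synchronized
  expect_equal(nrow(de), 1)
  expect_equal(de$start, 4000)
  expect_equal(de$end, 6000)
})

test_that("a contiguous half of below-median segments becomes one desync interval", {
  states <- rep(c("s", "d"), each = 5)
  x <- unlist(lapply(states, function(st) {
    t <- seq(0, 0.999, by = 0.001)
    if (st == "s") 100 * sin(2 * pi * 3 * t) else stats::rnorm(1000, 0, 0.5)
  }))
  tr <- structure(list(sampling_rate = 1000, start_time = 0, values = x),
                  class = "continuous_trace")
  sg <- segment_states(tr, overlap_ms = 0)
  de <- sg$state_intervals[sg$state_intervals$state == "desynchronized", ]
  expect_equal(nrow(de), 1)
  expect_equal(de$start, 5000)
})

test_that("stimulus classification honours the 350 ms remaining-time rule", {
  seg <- structure(list(
    segment_times = 0, compound_power = 1, median_power = 1,
    state_intervals = data.frame(
      start = c(0, 2000, 5000), end = c(2000, 5000, 8000),
      state = c("synchronized", "desynchronized", "synchronized"))),
    class = "state_segmentation")
  # inside desync with 400 ms remaining
  expect_equal(classify_stimulus_state(4600, seg), "desynchronized")
  # 100 ms before the desync interval ends
  expect_equal(classify_stimulus_state(4900, seg), "synchronized")
  # exactly 350 ms remaining does not exceed the margin
  expect_equal(classify_stimulus_state(4650, seg), "synchronized")
  # in a synchronized interval
  expect_equal(classify_stimulus_state(1000, seg), "synchronized")
  expect_error(classify_stimulus_state(9000, seg), "outside")
})

test_that("state-conditioned decoding uses N = 3 and drops undersized patterns", {
  sched <- tiny_schedule(k = 4, repetitions = 30, seed = 2)
  ss <- generate_sweeps(separable_spec(k = 4), sched, seed = 3)
  dp <- decoder_params(n_iterations = 3, k_neighbors = 5L,
                       target_combinations = 50L, seed = 4)
  win <- derive_windows(ss, dp)
  n_trials <- length(sched$trial_onsets)
  states <- rep("synchronized", n_trials)
  # desynchronized trials: plenty for P1-P3 but only 2 sweeps of P4 (< N = 3)
  for (p in c("P1", "P2", "P3")) {
    states[ss$trial_ids[[p]][1:15]] <- "desynchronized"
  }
  states[ss$trial_ids$P4[1:2]] <- "desynchronized"
  res <- suppressWarnings(
    state_conditioned_decoding(ss, states, win, dp, state_group_size = 3))
  expect_s3_class(res$synchronized, "decoding_result")
  expect_s3_class(res$desynchronized, "decoding_result")
  # P4 cannot bootstrap in the desynchronized state: its row stays empty
  expect_equal(unname(res$desynchronized$mean_confusion["P4", ]), rep(0, 4))
  expect_gt(res$desynchronized$n_omitted, 0)
})

test_that("desynchronised-state trials with better signal decode better", {
  sched <- tiny_schedule(k = 4, repetitions = 40, seed = 5)
  n_trials <- length(sched$trial_onsets)
  set.seed(6)
  states <- rep(c("synchronized", "desynchronized"), length.out = n_trials)
  diffs <- vapply(1:5, function(s) {
    reliable <- generate_sweeps(separable_spec(k = 4, reliability = 1),
                                sched, seed = 10 + s)
    noisy <- generate_sweeps(separable_spec(k = 4, reliability = 0.25),
                             sched, seed = 20 + s)
    # desync trials come from the reliable model, sync from the noisy one
    mixed <- reliable
    for (p in names(mixed$sweeps)) {
      sync_here <- states[mixed$trial_ids[[p]]] == "synchronized"
      mixed$sweeps[[p]][sync_here] <- noisy$sweeps[[p]][sync_here]
    }
    dp <- decoder_params(n_iterations = 3, k_neighbors = 5L,
                         target_combinations = 50L, seed = 30 + s)
    win <- derive_windows(mixed, dp)
    res <- suppressWarnings(
      state_conditioned_decoding(mixed, states, win, dp))
    res$desynchronized$mean_decoding_performance -
      res$synchronized$mean_decoding_performance
  }, numeric(1))
  expect_gt(stats::median(diffs), 0)
})
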