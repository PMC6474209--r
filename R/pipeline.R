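#' End-to-end synthetic experiment runner
#'
#' Orchestrates the full pipeline on generated data: stimulation patterns and
#' schedule, a co-recorded neuron population, qualification, window
#' segmentation, decoding with shuffled controls, cooperative decoding, LFP
#' event detection, ECoG state segmentation with state-conditioned decoding,
#' and the cohort report. Every stage draws its randomness from the single
#' config seed, so a bundle is reproducible from (config, seed).
#'
#' @name pipeline_cli
NULL

#' Default run configuration
#'
#' Every method constant has a named key holding its standard value (kernel
#' tau 5 ms, N = 10, 200 combinations, k = 9, 50 iterations, 2.5% AUC floor,
#' 600 ms span, 1.8 s inter-trial interval).
#'
#' @param seed integer master seed.
#' @param out_dir bundle directory, or `NULL` to skip writing.
#' @return nested config list, YAML round-trip stable.
#' @export
default_config <- function(seed = 1L, out_dir = NULL) {
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    generator = list(n_neurons = 4L, labels = CANONICAL_LABELS,
                     repetitions = 24L, inter_trial_interval_ms = 1800,
                     baseline_rate = 5, n_bumps = 3, peak_rate = 30,
                     peak_width = 10, reliability = 0.8),
    decoder = list(kernel_tau = 5, group_size = 10L,
                   target_combinations = 200L, k_neighbors = 9L,
                   n_iterations = 50L, auc_floor = 0.025,
                   split_fraction = 0.5, span_ms = 600),
    cooperative = list(durations_ms = c(300, 600), max_neurons = 10L),
    lfp = list(response_amplitude = -40, noise_sd = 5,
               sampling_rate_hz = 10000),
    ecog = list(epoch_ms = 5000, sync_amplitude = 50, desync_amplitude = 5,
                state_group_size = 3L)
  )
}

#' Run the full synthetic experiment
#'
#' @param config nested list as from [default_config()], or a path to a YAML
#'   file with the same structure.
#' @return results bundle: per-stage results plus a manifest (seed, stage
#'   timings, package version). Written under `config$out_dir` when set.
#' @export
run_experiment <- function(config = default_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  gc_ <- config$generator
  if (is.null(gc_$n_neurons) || gc_$n_neurons < 1) {
    stop("config must request at least one neuron")
  }
  dp <- do.call(decoder_params, c(config$decoder, list(seed = config$seed)))
  timings <- c()
  tick <- function() Sys.time()
  stage_time <- function(t0) as.numeric(difftime(Sys.time(), t0, units = "secs"))

  t0 <- tick()
  patterns <- generate_patterns(seed = config$seed,
                                n_patterns = length(gc_$labels),
                                canonical = identical(sort(gc_$labels),
                                                      sort(CANONICAL_LABELS)))
  schedule <- build_schedule(gc_$labels, repetitions = gc_$repetitions,
                             inter_trial_interval_ms = gc_$inter_trial_interval_ms,
                             seed = config$seed)
  areas <- rep(c("S1", "non-S1"), length.out = gc_$n_neurons)
  depths <- seq(300, 1400, length.out = gc_$n_neurons)
  specs <- lapply(seq_len(gc_$n_neurons), function(i) {
    random_neuron_spec(config$seed * 131L + i, labels = gc_$labels,
                       baseline_rate = gc_$baseline_rate,
                       n_bumps = gc_$n_bumps, peak_rate = gc_$peak_rate,
                       peak_width = gc_$peak_width,
                       reliability = gc_$reliability,
                       area_tag = areas[i], depth = depths[i])
  })
  population <- generate_population(specs, schedule, seed = config$seed * 977L)
  timings["generate"] <- stage_time(t0)

  t0 <- tick()
  qual <- lapply(population, function(nn) {
    kdes <- pattern_kdes(nn, from_ms = -nn$pretrigger_span, to_ms = 1000)
    list(kdes = kdes, qualification = qualify_neuron(kdes))
  })
  qualified <- which(vapply(qual, function(q) q$qualification$qualified,
                            logical(1)))
  timings["qualify"] <- stage_time(t0)

  t0 <- tick()
  decoding <- list()
  for (i in qualified) {
    nn <- population[[i]]
    kdes_post <- lapply(qual[[i]]$kdes, clip_curve, 0, 1000)
    windows <- derive_windows(nn, dp, kdes = kdes_post)
    dec <- decode_neuron(nn, windows, dp)
    shuf <- shuffled_control(nn, windows, dp)
    decoding[[nn$neuron_id]] <- list(windows = windows, decoding = dec,
                                     shuffled = shuf)
  }
  if (length(decoding) == 0) stop("no neuron qualified for decoding")
  timings["decode"] <- stage_time(t0)

  t0 <- tick()
  coop <- cooperative_decode(population[qualified], dp,
                             durations_ms = config$cooperative$durations_ms,
                             max_neurons = config$cooperative$max_neurons)
  timings["cooperative"] <- stage_time(t0)

  t0 <- tick()
  lfp_trace <- generate_lfp_trace(schedule, config$lfp$response_amplitude,
                                  config$lfp$noise_sd,
                                  seed = config$seed * 389L,
                                  sampling_rate_hz = config$lfp$sampling_rate_hz)
  se_sweeps <- cut_trace_sweeps(lfp_trace, schedule$trial_onsets[1:20],
                                pre_ms = 100, post_ms = 100)
  se_result <- detect_se_lfp(se_sweeps)
  pat_sweeps <- cut_trace_sweeps(lfp_trace, schedule$trial_onsets[1:20],
                                 pre_ms = 400, post_ms = 400)
  pattern_events <- lapply(seq_len(nrow(pat_sweeps)), function(i) {
    detect_pattern_lfps(pat_sweeps[i, ],
                        sampling_rate_hz = config$lfp$sampling_rate_hz)
  })
  lfp_tests <- compare_pre_post(pattern_events, "count")
  timings["lfp"] <- stage_time(t0)

  t0 <- tick()
  n_trials <- length(schedule$trial_onsets)
  ecog_dur <- n_trials * schedule$inter_trial_interval
  ep <- config$ecog$epoch_ms
  edges <- seq(0, ecog_dur, by = ep)
  if (edges[length(edges)] < ecog_dur) edges <- c(edges, ecog_dur)
  state_sched <- data.frame(
    start = edges[-length(edges)], end = edges[-1],
    state = rep(c("synchronized", "desynchronized"),
                length.out = length(edges) - 1L))
  ecog <- generate_ecog_trace(ecog_dur, state_sched,
                              seed = config$seed * 547L,
                              sync_amplitude = config$ecog$sync_amplitude,
                              desync_amplitude = config$ecog$desync_amplitude)
  seg <- segment_states(ecog)
  trial_states <- classify_stimulus_state(
    pmin(schedule$trial_onsets, ecog_dur - 1), seg)
  first_q <- qualified[1]
  state_dec <- state_conditioned_decoding(
    population[[first_q]], trial_states,
    decoding[[population[[first_q]]$neuron_id]]$windows, dp,
    state_group_size = config$ecog$state_group_size)
  timings["states"] <- stage_time(t0)

  t0 <- tick()
  neuron_results <- do.call(rbind, lapply(qualified, function(i) {
    nn <- population[[i]]
    data.frame(neuron_id = nn$neuron_id, area_tag = nn$area_tag,
               depth = nn$depth,
               performance = decoding[[nn$neuron_id]]$decoding$mean_decoding_performance,
               shuffled_performance = decoding[[nn$neuron_id]]$shuffled$mean_decoding_performance)
  }))
  report <- build_report(neuron_results)
  timings["report"] <- stage_time(t0)

  bundle <- list(
    config = config,
    manifest = list(seed = config$seed,
                    package_version = as.character(utils::packageVersion("spikedecoder")),
                    stage_seconds = as.list(timings)),
    patterns = patterns, schedule = schedule,
    qualification = lapply(qual, `[[`, "qualification"),
    qualified = qualified, decoding = decoding, cooperative = coop,
    lfp = list(se = se_result, pre_post = lfp_tests),
    states = list(segmentation = seg, trial_states = trial_states,
                  decoding = state_dec),
    neuron_results = neuron_results, report = report)

  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

# one directory per stage: JSON metadata + delimited tables
write_bundle <- function(bundle, out_dir) {
  for (d in c("generate", "decode", "cooperative", "lfp", "states", "report")) {
    dir.create(file.path(out_dir, d), recursive = TRUE, showWarnings = FALSE)
  }
  write_patterns(bundle$patterns, file.path(out_dir, "generate", "patterns.json"))
  utils::write.table(
    data.frame(onset_ms = bundle$schedule$trial_onsets,
               pattern_label = bundle$schedule$trial_labels),
    file.path(out_dir, "generate", "schedule.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE)
  for (id in names(bundle$decoding)) {
    utils::write.table(
      as.data.frame(bundle$decoding[[id]]$decoding$mean_confusion),
      file.path(out_dir, "decode", paste0(id, "_confusion.tsv")),
      sep = "\t", row.names = TRUE, quote = FALSE)
    write_windows(bundle$decoding[[id]]$windows,
                  file.path(out_dir, "decode", paste0(id, "_windows.json")))
  }
  jsonlite::write_json(lapply(bundle$cooperative, unclass),
                       file.path(out_dir, "cooperative", "cooperative.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(bundle$lfp,
                       file.path(out_dir, "lfp", "lfp.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  write_state_intervals(bundle$states$segmentation,
                        file.path(out_dir, "states", "intervals.tsv"))
  utils::write.table(bundle$neuron_results,
                     file.path(out_dir, "report", "neurons.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(bundle$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Shuffled-control calibration on a synthetic cohort
#'
#' Generates a cohort of pattern-selective neurons (8 patterns, Gaussian-bump
#' response profiles over a shared pseudo-random session), runs the full
#' qualification / segmentation / decoding pipeline on each with per-iteration
#' label shuffling, and reports the per-neuron shuffled mean decoding
#' performance. With labels shuffled before every split the decoder sees
#' label-independent data, so the cohort mean calibrates the empirical chance
#' level (12.5% for 8 patterns).
#'
#' @param n_neurons cohort size (default 20).
#' @param repetitions presentations per pattern (default 60).
#' @param seed integer master seed.
#' @param params a `decoder_params` (N = 10, k = 9, 50 iterations by default).
#' @param n_bumps,peak_rate,peak_width,baseline_rate,reliability neuron model
#'   settings shared by the cohort.
#' @param shuffle run the shuffled control (default) or the plain decoder.
#' @return list: `per_neuron` data frame (neuron, qualified, performance) and
#'   `cohort_mean` / `cohort_sd` over the qualified neurons.
#' @export
run_shuffled_calibration <- function(n_neurons = 20L, repetitions = 60L,
                                     seed = 1L,
                                     params = decoder_params(seed = seed),
                                     n_bumps = 3L, peak_rate = 30,
                                     peak_width = 10, baseline_rate = 5,
                                     reliability = 0.8, shuffle = TRUE) {
  sched <- build_schedule(repetitions = repetitions, seed = seed)
  rows <- vector("list", n_neurons)
  for (i in seq_len(n_neurons)) {
    spec <- random_neuron_spec((seed + 613L * i) %% .Machine$integer.max,
                               baseline_rate = baseline_rate,
                               n_bumps = n_bumps, peak_rate = peak_rate,
                               peak_width = peak_width,
                               reliability = reliability)
    ss <- generate_sweeps(spec, sched,
                          seed = (seed + 977L * i) %% .Machine$integer.max)
    kdes <- pattern_kdes(ss, from_ms = -ss$pretrigger_span, to_ms = 1000)
    q <- qualify_neuron(kdes)
    perf <- NA_real_
    if (q$qualified) {
      p_i <- params
      p_i$seed <- (params$seed + 389L * i) %% .Machine$integer.max
      win <- derive_windows(ss, p_i, kdes = lapply(kdes, clip_curve, 0, 1000))
      res <- decode_neuron(ss, win, p_i, shuffle = shuffle)
      perf <- res$mean_decoding_performance
    }
    rows[[i]] <- data.frame(neuron = i, qualified = q$qualified,
                            performance = perf)
  }
  per_neuron <- do.call(rbind, rows)
  ok <- per_neuron$performance[per_neuron$qualified]
  list(per_neuron = per_neuron, cohort_mean = mean(ok, na.rm = TRUE),
       cohort_sd = stats::sd(ok[!is.na(ok)]))
}
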