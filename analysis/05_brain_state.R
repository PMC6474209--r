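#!/usr/bin/env Rscript
# Stage 5: ECoG brain-state segmentation and state-conditioned decoding.
#
# A 1 kHz ECoG alternates 10 s synchronized epochs (strong 0-12 Hz power)
# with 5 s desynchronized epochs. The segmentation (1000 ms windows, 125 ms
# overlap, 0-12 Hz compound power, below-median runs >= 2 segments) labels
# each stimulus presentation; the decoder then runs per state with N = 3.

suppressPackageStartupMessages(library(spikedecoder))

data_dir <- "results/analysis/data"
out <- "results/analysis/brain_state"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 20260306

schedule <- build_schedule(repetitions = 60, seed = 20260301)
dur <- max(schedule$trial_onsets) + 1800
edges <- seq(0, dur + 15000, by = 5000)
states <- rep(c("synchronized", "synchronized", "desynchronized"),
              length.out = length(edges) - 1)
epochs <- data.frame(start = edges[-length(edges)], end = edges[-1],
                     state = states)
ecog <- generate_ecog_trace(max(edges), epochs, seed = seed)

seg <- segment_states(ecog)
write_state_intervals(seg, file.path(out, "state_intervals.tsv"))
de <- seg$state_intervals$state == "desynchronized"
frac <- sum(seg$state_intervals$end[de] - seg$state_intervals$start[de]) /
  max(seg$state_intervals$end)
message(sprintf("desynchronized fraction of recording: %.1f%% (generated: ~33%%)",
                100 * frac))

trial_states <- classify_stimulus_state(schedule$trial_onsets, seg)
message(sprintf("presentations classified desynchronized: %.1f%%",
                100 * mean(trial_states == "desynchronized")))

ss <- read_sweeps(file.path(data_dir, "n01_sweeps.tsv"))
params <- decoder_params(n_iterations = 10, seed = seed)
win <- derive_windows(ss, params)
res <- suppressWarnings(
  state_conditioned_decoding(ss, trial_states, win, params,
                             state_group_size = 3))
tab <- do.call(rbind, lapply(names(res), function(st) {
  r <- res[[st]]
  if (inherits(r, "decoding_result")) {
    data.frame(state = st, performance = r$mean_decoding_performance,
               omitted_pattern_iterations = r$n_omitted)
  } else data.frame(state = st, performance = NA, omitted_pattern_iterations = NA)
}))
write.table(tab, file.path(out, "state_decoding.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)
message(paste(capture.output(print(tab)), collapse = "\n"))
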