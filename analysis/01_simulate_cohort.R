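#!/usr/bin/env Rscript
# Stage 1: generate the synthetic experiment the rest of the workflow analyses.
#
# Eight spatiotemporal stimulation patterns (4 skin channels, < 350 ms) are
# presented 60 times each in repeated randomized order, 1.8 s apart, to a
# co-recorded cohort of six pattern-selective neurons (5 Hz baseline, three
# pattern-specific Gaussian rate bumps, 80% per-trial bump reliability,
# inhomogeneous-Poisson spiking). Sweeps go to results/analysis/data/ as tidy
# TSV for the later stages.

suppressPackageStartupMessages(library(spikedecoder))

seed <- 20260301
out <- "results/analysis/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

patterns <- generate_patterns(seed = seed, n_patterns = 8, canonical = TRUE)
write_patterns(patterns, file.path(out, "patterns.json"))

schedule <- build_schedule(repetitions = 60, seed = seed)
write.table(data.frame(onset_ms = schedule$trial_onsets,
                       pattern_label = schedule$trial_labels),
            file.path(out, "schedule.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)

areas <- rep(c("S1", "non-S1"), each = 3)
depths <- c(350, 700, 1100, 400, 800, 1250)
specs <- lapply(1:6, function(i) {
  random_neuron_spec(seed + i, baseline_rate = 5, n_bumps = 3,
                     peak_rate = 30, peak_width = 10, reliability = 0.8,
                     area_tag = areas[i], depth = depths[i])
})
population <- generate_population(specs, schedule, seed = seed + 100)

for (nn in population) {
  write_sweeps(nn, file.path(out, paste0(nn$neuron_id, "_sweeps.tsv")))
}

counts <- vapply(population, function(nn) sum(lengths(nn$sweeps)), numeric(1))
message(sprintf("simulated %d neurons x %d trials (%.0f sweeps each); data in %s",
                length(population), length(schedule$trial_onsets),
                mean(counts), out))
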