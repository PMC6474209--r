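# spikedecoder

Decoding spatiotemporal tactile stimulation patterns from cortical spike
trains.

## The problem

When a set of highly reproducible spatiotemporal electrical pulse patterns is
delivered to the skin (eight patterns — F5, S5, F10, S10, F20, S20, F∞, S∞ —
over four channels, each lasting under 350 ms, repeated 50–100 times 1.8 s
apart), do the spike responses of individual neocortical neurons carry enough
information to identify *which* pattern was delivered? The question matters
because tactile-evoked activity can be recorded far outside the primary
somatosensory cortex, including in visual cortex, and a decoding analysis
quantifies whether that spatially unbounded activity carries stimulus
identity rather than mere stimulus presence.

`spikedecoder` implements the full analysis chain as a tested R package,
together with seeded generators that emulate the statistical structure of
such recordings (pattern-selective inhomogeneous-Poisson spiking,
stimulus-evoked LFP deflections, and ECoG with alternating brain states), so
every stage can be exercised and calibrated end to end on synthetic data.

## The method

For one neuron with spike sweeps grouped by stimulation pattern:

1. **Spike density estimation.** Each pattern's pooled spike times are turned
   into a continuous spike density function: a sum of Gaussian kernels on a
   1 ms grid, with the kernel bandwidth *w* chosen by minimising the
   cross-validation cost
   C(w) = Σᵢⱼ ∫k_w(x−tᵢ)k_w(x−tⱼ)dx − 2Σ_{i≠j} k_w(tᵢ−tⱼ)
   over a candidate grid (the kernel-bandwidth optimisation of the spike-rate
   estimation literature).
2. **Time-window segmentation.** The eight density curves are superimposed
   and their pointwise maximum forms the *compound density*. Each interior
   local minimum is a window boundary; per-window AUC (baseline = the lowest
   value within the window) is normalised to the largest window AUC, and
   windows under 2.5 % of it are dropped. Neurons qualify only if at least
   three peaks across their curves exceed 200 % of the curve baseline within
   50 ms of the deviation onset.
3. **Decoding.** Sweeps are convolved with a causal exponential kernel
   (τ = 5 ms). Per iteration: stratified 50/50 train/test split per pattern;
   each set is expanded by *bootstrap recombination* (sums of N = 10 distinct
   non-empty sweeps, 200 target combinations, every sweep covered); each
   combined response becomes a vector of per-window AUCs normalised to the
   per-set per-window maximum; test responses are classified by k-nearest
   neighbours (k = 9, Euclidean distance) against the training set. Confusion
   matrices (rows = true pattern, summing to 100 %) are averaged over 50
   iterations; the **mean decoding performance** is the diagonal mean, with
   chance at 100/K % (12.5 % for 8 patterns). A **shuffled control** permutes
   the pattern labels before every split and must sit at chance.
4. **Population analyses.** Responses of different neurons to the *same*
   pattern are discriminated with the same machinery (classes = neurons,
   chance 100/M %), and *cooperative decoding* greedily adds the neuron whose
   concatenated window features most improve joint decoding, per response
   duration (100–1000 ms).
5. **LFP and brain state.** Sensory-evoked LFPs are detected in
   outlier-trimmed sweep averages against a −5 SD gate (latency and duration
   from the −2 SD crossings); pattern-evoked LFP events are ≥ 10 ms drops
   below −2 SD after a 10 ms boxcar, decimation to 1 kHz and a first-order
   50–499 Hz Butterworth, compared pre vs post trigger by Wilcoxon
   signed-rank. ECoG is segmented into synchronized/desynchronized states
   from summed 0–12 Hz spectral power (1000 ms segments, 125 ms overlap,
   below-median runs ≥ 2 segments), and decoding is re-run per state with
   N = 3.

## Worked example

```r
library(spikedecoder)

schedule <- build_schedule(repetitions = 60, seed = 42)
spec   <- random_neuron_spec(7, baseline_rate = 5, n_bumps = 3,
                             peak_rate = 30, peak_width = 10, reliability = 0.8)
neuron <- generate_sweeps(spec, schedule, seed = 42)
#> <sweep_set sim-42 [S1, 600 um]: 8 patterns, 480 sweeps, spans -500/+1000 ms>

kdes <- pattern_kdes(neuron, from_ms = -500, to_ms = 1000)
qualify_neuron(kdes)$qualified            # TRUE (10 qualifying peaks)

params  <- decoder_params(n_iterations = 10, seed = 42)
windows <- derive_windows(neuron, params, kdes = lapply(kdes, clip_curve, 0, 1000))
#> <time_window_set: 17 windows (14 kept) on [0, 600] ms>

decode_neuron(neuron, windows, params)
#> <decoding_result: 8 classes, mean decoding 88.6%>
shuffled_control(neuron, windows, params)
#> <decoding_result (shuffled control): 8 classes, mean decoding 12.9%>
```

A pattern-selective synthetic neuron (three Gaussian response bumps per
pattern, 80 % per-trial reliability) decodes at 88.6 % — far above the 12.5 %
eight-class chance — while its shuffled control sits at 12.9 %, confirming
the pipeline introduces no label bias. The confusion matrix
(`$mean_confusion`) shows which patterns are mistaken for which; diagonal
entries for this neuron range from ~76 % to ~97 %.

## The analysis workflow

Numbered drivers under `analysis/` run the whole study on a simulated cohort
and write their tables under `results/analysis/`:

| script | what it does |
|---|---|
| `01_simulate_cohort.R` | patterns, schedule, six co-recorded neurons → TSV |
| `02_single_neuron_decoding.R` | qualification, windows, decoding + shuffled control per neuron |
| `03_population_decoding.R` | inter-neuron confusion; greedy cooperative decoding |
| `04_lfp_events.R` | SE-LFP detection; pattern-evoked events; pre/post tests |
| `05_brain_state.R` | ECoG state segmentation; state-conditioned decoding |
| `06_cohort_report.R` | laminar assignment, area comparisons, summary tables |

`run_experiment(default_config())` runs the same pipeline programmatically
from a single seeded configuration.

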