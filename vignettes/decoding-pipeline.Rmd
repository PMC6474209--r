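---
title: "Methods: decoding tactile stimulation patterns from spike trains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: decoding tactile stimulation patterns from spike trains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models, parameters, and design choices behind
`spikedecoder`: a pipeline that quantifies how well single neocortical
neurons — and small populations — discriminate eight spatiotemporal tactile
stimulation patterns from their spike responses, together with the LFP and
brain-state analyses that accompany such experiments.

## The experimental structure being modelled

The experiment the pipeline targets delivers eight labelled pulse patterns
(F5, S5, F10, S10, F20, S20, F∞, S∞) through four skin channels. Each pattern
lasts under 350 ms; presentations are separated by 1.8 s and repeated 50–100
times in repeated randomized order. Per neuron, each presentation yields a
spike-time sweep aligned to stimulus onset, stored with at least 500 ms of
pretrigger and 1000 ms of post-trigger span. Continuous voltage is recorded
alongside: a high-rate trace for LFP analysis and a 1 kHz ECoG for
brain-state tracking.

## The synthetic-data generator

All inputs can be generated synthetically with seeded reproducibility; the
generators define the study conditions for every calibration the package
reports.

* **Spiking** (`generate_sweeps`): an inhomogeneous Poisson process sampled
  by thinning — exact for this model and trivially cross-checkable against
  closed-form Poisson statistics. The per-trial rate is a constant baseline
  plus pattern-specific Gaussian rate bumps, each expressed on a trial with
  probability `reliability`. Defaults used throughout the calibrations:
  baseline 5 Hz, three bumps per pattern, peak 30 Hz, width (SD) 10 ms, peak
  times uniform in [30, 550] ms (inside the standard 600 ms analysis span),
  reliability 0.8. These are ordinary values for stimulus-driven cortical
  firing under anaesthesia and produce neurons that pass the qualification
  criterion while retaining visible trial-to-trial noise. The generator
  reproduces Fano factors near 1 for baseline-only spiking.
* **Stimulation patterns** (`generate_patterns`): the canonical eight-pattern
  set ships as a synthetic illustrative fixture (no published pulse-time
  tables exist, so event lists follow the fast/slow-adapting structure of the
  pattern family); all quantitative tests use generated generic patterns, for
  which pairwise distinctness is guaranteed by a 1 ms discretized Hamming
  distance.
* **LFP traces** (`generate_lfp_trace`): Gaussian white noise plus a
  negative half-sine deflection after each trial onset (local sensory-evoked
  LFPs in the superficial cortex are negative). Synthetic traces are sampled
  at 10 kHz and the detector's decimation factor rescales accordingly; the
  nominal acquisition rate in the modelled experiment is 100 kHz.
* **ECoG** (`generate_ecog_trace`): synchronized epochs carry a strong
  multi-component 1–8 Hz oscillation over a weak broadband floor;
  desynchronized epochs carry the floor alone. This caricature reproduces
  the spectral contrast the state segmentation keys on.

What the generators deliberately do *not* model: bursting and refractory
structure, spike-sorting errors, correlated noise across neurons,
non-stationary baselines, volume-conducted LFP mixtures, or realistic ECoG
1/f spectra. Passing calibrations therefore demonstrate the correctness and
internal consistency of the analysis chain under its own assumptions — not
the decodability of any particular real dataset.

## Spike density estimation

PSTHs use 5 ms bins with baseline mean and SD from the pretrigger bins;
response latency is the first of at least two consecutive post-trigger bins
exceeding baseline + 3 SD, and response intensity is the maximal change from
baseline in SD units from the latency onward.

The density representation sums a Gaussian kernel at each pooled spike time
on a 1 ms grid. The bandwidth minimises the kernel cross-validation cost

$$C(w) = \sum_{i,j} \int k_w(x-t_i)k_w(x-t_j)\,dx \;-\; 2\sum_{i \ne j} k_w(t_i - t_j)$$

evaluated in closed form for the Gaussian kernel, over 50 log-spaced
candidates in [1, 200] ms (ties resolved to the smallest candidate; fewer
than two spikes falls back to a configured 20 ms default). Above 1200 spikes
the pairwise cost uses a deterministic even-rank thinning of the sorted spike
times — a compute bound that leaves the minimiser essentially unchanged at
these densities. Spikes are pooled across trials before optimisation (the
alternative, per-trial optimisation, is under-determined at realistic trial
counts). Density is reported as spikes·s⁻¹ per trial (kernel sum divided by
the number of sweeps) so curves from different trial counts are comparable;
kernels are truncated at ±5 bandwidths and no boundary correction is applied —
windows are defined relative to within-grid peaks, so edge bias is shared
across patterns and cancels in the comparison.

## Window segmentation and qualification

The compound density is the pointwise maximum of the eight per-pattern
curves. Interior local minima are window boundaries; a flat run that is a
local minimum contributes a single boundary at its midpoint (this plateau
rule avoids zero-width windows; exact ties are measure-zero on real
densities). Window AUC uses the trapezoidal rule after subtracting the
window's own minimum; AUCs are normalised to the largest window and windows
below 2.5 % of it are dropped *before* windows are counted. The default
analysis span is 600 ms (configurable 100–1000 ms; the time-evolution
analysis re-derives windows per truncated span).

Qualification demands at least three peaks, pooled across the eight curves,
that exceed 200 % of the curve's baseline within 50 ms of the peak's
deviation onset. Two phrases needed operationalisation: the *baseline
(100 %)* is the mean curve value over the pretrigger span, and the *deviation
onset* is the last upward crossing of that baseline preceding the peak (the
grid start if the curve never dips below baseline). These readings match the
percent phrasing of the criterion and behave correctly on flat, degenerate
and strongly-driven curves.

## The decoder

Sweeps become continuous signals by causal exponential convolution
(τ = 5 ms). Each iteration of the decoding loop:

1. splits each pattern's sweeps 50/50 into training and test sets
   (stratified; an odd sweep goes to training, keeping kNN priors balanced);
2. excludes sweeps without spikes, then expands each set by summing N = 10
   distinct sweeps per bootstrap combination, targeting 200 combinations
   (all of them when fewer exist), with every remaining sweep covered by at
   least one combination — coverage is established by chunking a shuffled
   sweep list, then random distinct subsets top up to the target. Fewer than
   N usable sweeps is a bootstrap failure: the pattern is omitted from that
   iteration (a logged warning), and a neuron errors only if every pattern
   fails;
3. computes per-window trapezoidal AUCs of each combined response and
   normalises each window dimension to its maximum within the set — training
   and test sets are normalised independently, exactly as specified for the
   method (this leaks no labels; it is faithful rather than conventional);
4. classifies each test response by plurality among its k = 9 nearest
   training responses (Euclidean distance in window space). Ties between
   leading labels are broken by the nearest neighbour belonging to a tied
   label — a strict majority of 9 among 8 classes would leave most queries
   unclassifiable, so plurality is the only workable reading. Exact distance
   ties keep training-set order.

Confusion matrices average over 50 iterations; rows sum to 100 %. The
windows are fixed once per neuron from the full data rather than re-derived
per split, matching the single per-neuron window definition of the method.
The shuffled control permutes the sweep-to-pattern assignment before every
split. An implementation note: because the trapezoidal AUC is linear in the
signal, the decoder featurises single sweeps once and sums AUC vectors over
each bootstrap subset — bit-identical to summing signals first (the
equivalence is property-tested) and an order of magnitude faster.

## Population analyses

Inter-neuron discrimination feeds the raw responses of 4–5 neurons to one
pattern through the same machinery with neuron identity as the class label
(chance 100/M %); windows come from the compound density pooled over the
compared neurons' curves for that pattern.

Cooperative decoding greedily selects neurons per response duration: the
best single decoder first, then whichever remaining neuron maximises joint
decoding on features concatenated across the selection. Joint features are
per-neuron featurised then concatenated, so each neuron's geometry (and its
per-window normalisation) is preserved; dimensionality grows by each added
neuron's window count. Within one selection step every candidate is
evaluated with the same seed, sharing splits and bootstrap draws for
fairness; performance ties keep the lower neuron index. Neurons co-recorded
on one schedule share trial indices, and joint combinations are built from
the same trial subsets across neurons; a trial enters the joint bootstrap if
any member neuron has spikes in it (the empty-sweep exclusion guards against
all-zero responses, which cannot arise jointly unless all members are
empty). Selection stops at 10 neurons.

## LFP detectors

*Single-pulse SE-LFP*: aligned sweeps are trimmed per time point to their
central 50 % of values (symmetric trimming — the criterion removes "50 %
outliers" without stating laterality) and averaged; baseline statistics come
from the 100 ms pretrigger of that trimmed average. Detection requires the
average to drop below −5 SD within 100 ms post-trigger. The description of
the subsequent smoothing is self-contradictory ("10-order one-dimensional
median filter (moving average)"); the package implements a running median of
window 10 — the primary term — with a config switch to a moving average.
Latency and duration come from the −2 SD crossings of the filtered average,
anchored to the response trough that passed the −5 SD gate (so an isolated
single-sample noise excursion cannot define the response onset); amplitude
is the minimum inside the response.

*Pattern-evoked events*: 400 ms pre + 400 ms post segments are smoothed by a
10 ms rolling boxcar, decimated to 1 kHz, band-passed 50–499 Hz with a
first-order Butterworth, and DC-corrected by subtracting the pretrigger
median. The filter runs forward–backward (zero phase) to keep onsets
unbiased, and the DC level is removed before filtering as well — the filter
is linear, so this commutes, and it eliminates offset-driven edge transients
that would otherwise corrupt the baseline SD. Events are drops of ≥ 2 SD
below baseline lasting ≥ 10 ms; events beginning before the trigger count as
pretrigger events. Pre/post comparisons (count, duration, amplitude, boxcar
AUC = |amplitude| × duration) use the Wilcoxon signed-rank test on paired
per-sweep summaries.

## Brain-state segmentation

Spectral density per 1000 ms segment (125 ms overlap, constant/mean
detrending, plain periodogram — no taper, matching the stated detrending-only
preprocessing) is summed over 0–12 Hz inclusive. Desynchronized epochs are
runs of at least two consecutive segments below the recording-wide median;
merged runs form desynchronized *intervals*, and the state intervals tile
the recording. A stimulus presentation counts as desynchronized only if its
onset lies inside a desynchronized interval with more than 350 ms of the
interval remaining — the interval (merged-run) reading of the rule, chosen
over the single-segment reading because overlapping 1000 ms segments do not
partition time. State-conditioned decoding re-runs the decoder per state
with N = 3 (state-segmented subsets are small); patterns that cannot
bootstrap within a state are dropped with a warning.

## Cohort statistics

Depths map to layers by half-open bins on the boundaries L1|L2/3 = 157 µm,
L2/3|L4 = 575 µm, L4|L5 = 900 µm, L5|L6 = 1411 µm, L6|WM = 1973 µm (a depth
equal to a boundary joins the deeper layer; the convention is stated because
the boundary membership is otherwise ambiguous). Group comparisons dispatch
to the standard rank-sum, signed-rank, Kruskal–Wallis and Pearson routines.
Raw p-values are reported by default, matching post-hoc reporting practice
for this analysis; a flag enables Holm correction.

## Numerical choices and degenerate inputs

* All grids are uniform at 1 ms; AUCs are trapezoidal.
* Zero-spike patterns yield flat zero density curves (flagged), an all-zero
  compound yields zero windows (flagged), and a zero-SD baseline raises a
  degenerate-baseline error rather than silently dividing by zero.
* A duration whose windows all fall below the AUC floor returns a
  chance-level placeholder flagged `no_windows`.
* Every generator and the decoding loop take explicit integer seeds; the
  full pipeline is bit-reproducible from (config, seed).

## Calibration scales

The package's calibrations run at the following problem sizes, chosen to
exercise the full method at meaningful statistical power: the
shuffled-control cohort uses 20 neurons × 8 patterns × 60 trials at the full
50 iterations; chance-level null simulations use 30 trials and 10
iterations per class count K ∈ {2, 4, 5, 8}; oracle equivalences use ≥ 20
seeded instances each; detector calibrations use 200 null runs (20–30 sweeps
each) and 20 injected-deflection recoveries; the state-recovery check uses a
60 s ECoG with 5 s epochs. Module tests use further-scaled-down cohorts
whose expected behaviour is pinned by the same oracles.

## Known limitations

* The canonical pattern fixture is illustrative, not a digitisation of the
  published pattern set; analyses that depend on specific pulse timings
  should generate their own patterns.
* The per-set feature normalisation follows the method description exactly;
  users comparing against other kNN pipelines should note it differs from
  train-set-anchored normalisation.
* Real-data decoding levels (for example mean performances around 15–20 % in
  cortical recordings) reflect noise sources the generator does not model;
  synthetic performances here are systematically higher and serve as upper
  bounds and correctness checks, not as predictions.
* The SE-LFP detector assumes negative-going responses (superficial
  recording depths); positive deflections are not detected.
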