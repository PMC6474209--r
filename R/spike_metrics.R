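#' Peristimulus histograms, response measures and spike-density estimation
#'
#' @name spike_metrics
NULL

#' Peristimulus time histogram
#'
#' Rates are pooled spike counts divided by (number of sweeps x bin width);
#' baseline mean and SD are computed from the pretrigger bins only.
#'
#' @param sweeps list of spike-time vectors (ms relative to stimulus onset,
#'   negative = pretrigger), or a `sweep_set` pooled over all patterns.
#' @param bin_size bin width, ms (default 5).
#' @param pre_span,post_span analysed spans around the trigger, ms.
#' @return a `psth` with bin edges, rates (Hz), and baseline statistics.
#' @export
compute_psth <- function(sweeps, bin_size = 5, pre_span = 500, post_span = 500) {
  if (inherits(sweeps, "sweep_set")) sweeps <- unlist(sweeps$sweeps, recursive = FALSE)
  if (length(sweeps) == 0) stop("empty sweep list")
  if (bin_size <= 0) stop("bin_size must be > 0")
  edges <- seq(-pre_span, post_span, by = bin_size)
  if (length(edges) < 2) stop("spans do not cover a single bin")
  spikes <- unlist(sweeps, use.names = FALSE)
  spikes <- spikes[spikes >= -pre_span & spikes < post_span]
  counts <- if (length(spikes)) {
    tabulate(findInterval(spikes, edges), nbins = length(edges) - 1L)
  } else rep(0L, length(edges) - 1L)
  rates <- counts / (length(sweeps) * bin_size) * 1000  # Hz
  pre_bins <- which(edges[-length(edges)] < 0)          # bins fully pretrigger
  baseline_mean <- if (length(pre_bins)) mean(rates[pre_bins]) else NA_real_
  baseline_sd <- if (length(pre_bins) >= 2) stats::sd(rates[pre_bins]) else NA_real_
  structure(list(bin_size = bin_size, bin_edges = edges, rates = rates,
                 n_sweeps = length(sweeps),
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd),
            class = "psth")
}

#' Response onset latency from a PSTH
#'
#' The latency is the start time of the first post-trigger bin in a run of at
#' least `min_consecutive` consecutive bins whose rate exceeds
#' baseline_mean + `threshold_sd` x baseline_sd. Bins touching t = 0 are
#' included in the search.
#'
#' @param psth a `psth` with valid baseline statistics.
#' @param threshold_sd threshold in baseline SD units (default 3).
#' @param min_consecutive required run length (default 2).
#' @return latency in ms, or `NA` when no qualifying run exists.
#' @export
response_latency <- function(psth, threshold_sd = 3, min_consecutive = 2) {
  if (is.na(psth$baseline_sd)) {
    stop("baseline SD undefined: need >= 2 pretrigger bins")
  }
  starts <- psth$bin_edges[-length(psth$bin_edges)]
  post <- which(starts >= 0)
  if (!length(post)) return(NA_real_)
  thr <- psth$baseline_mean + threshold_sd * psth$baseline_sd
  above <- psth$rates[post] > thr
  run <- 0L
  for (i in seq_along(above)) {
    run <- if (above[i]) run + 1L else 0L
    if (run >= min_consecutive) return(starts[post[i - min_consecutive + 1L]])
  }
  NA_real_
}

#' Response intensity in baseline-SD units
#'
#' Maximal spike frequency change from baseline over the period from the onset
#' latency to the end of the post-trigger span, expressed as a number of
#' pretrigger-baseline SDs.
#'
#' @param psth a `psth`.
#' @param latency onset latency, ms (from [response_latency()]).
#' @return intensity in SD units.
#' @export
response_intensity <- function(psth, latency) {
  if (is.na(latency)) stop("latency must be defined")
  if (is.na(psth$baseline_sd) || psth$baseline_sd == 0) {
    stop("degenerate baseline: SD is zero or undefined")
  }
  starts <- psth$bin_edges[-length(psth$bin_edges)]
  sel <- starts >= latency
  max((psth$rates[sel] - psth$baseline_mean) / psth$baseline_sd)
}

#' Gaussian-kernel bandwidth selection cost
#'
#' Cross-validation cost for a fixed-bandwidth Gaussian kernel rate estimate
#' (the kernel bandwidth optimisation of Shimazaki & Shinomoto):
#' C(w) = sum_{i,j} int k_w(x-t_i) k_w(x-t_j) dx - 2 sum_{i!=j} k_w(t_i-t_j),
#' which for a Gaussian kernel has the closed form used here.
#'
#' @param spike_times pooled spike times, ms.
#' @param w candidate bandwidth(s), ms (Gaussian SD).
#' @return cost value per candidate (lower is better).
#' @export
ss_cost <- function(spike_times, w) {
  n <- length(spike_times)
  d2 <- as.vector(outer(spike_times, spike_times, "-"))^2
  vapply(w, function(wi) {
    e1 <- sum(exp(-d2 / (4 * wi^2)))
    e2 <- sum(exp(-d2 / (2 * wi^2))) - n  # exclude i = j terms
    e1 / (2 * sqrt(pi) * wi) - 2 * e2 / (sqrt(2 * pi) * wi)
  }, numeric(1))
}

#' Cost-minimising Gaussian kernel bandwidth
#'
#' Minimises [ss_cost()] over a candidate grid (50 log-spaced values in
#' [1, 200] ms by default; ties resolved to the smallest bandwidth). For very
#' large spike counts the pairwise cost is evaluated on a deterministic
#' even-rank subsample of the sorted spike times.
#'
#' @param spike_times pooled spike times, ms (>= 2 spikes).
#' @param candidates_ms candidate bandwidth grid, ms.
#' @param max_spikes pairwise-evaluation cap; above it, spikes are thinned by
#'   even rank.
#' @return bandwidth in ms.
#' @export
optimal_bandwidth <- function(spike_times,
                              candidates_ms = exp(seq(log(1), log(200),
                                                      length.out = 50)),
                              max_spikes = 1200L) {
  if (length(spike_times) < 2) stop("need >= 2 spikes to optimise bandwidth")
  st <- sort(spike_times)
  if (length(st) > max_spikes) {
    st <- st[unique(round(seq(1, length(st), length.out = max_spikes)))]
  }
  costs <- ss_cost(st, candidates_ms)
  candidates_ms[which(costs == min(costs))[1]]  # grid sorted: tie -> smallest
}

#' Spike density function (Gaussian KDE) for one stimulation pattern
#'
#' Sums a Gaussian kernel at every pooled spike time on a uniform 1 ms grid.
#' Density is expressed as spikes per second per trial (kernel sum divided by
#' the number of sweeps), so curves from different trial counts are
#' comparable. Kernels are truncated at +/- 5 bandwidths; no boundary
#' correction is applied.
#'
#' @param sweeps_for_pattern list of spike-time vectors for a single pattern.
#' @param from_ms,to_ms grid span (default the post-trigger analysis span
#'   [0, 1000] ms).
#' @param bandwidth_ms Gaussian SD in ms; `NULL` selects it with
#'   [optimal_bandwidth()].
#' @param fallback_bandwidth_ms used when fewer than 2 spikes are available.
#' @return a `density_curve` with `time_grid`, `values` (spikes/s/trial),
#'   `bandwidth`, `n_spikes`; zero-spike input yields a flat zero curve with
#'   `zero_spikes = TRUE`.
#' @export
compute_kde <- function(sweeps_for_pattern, from_ms = 0, to_ms = 1000,
                        bandwidth_ms = NULL, fallback_bandwidth_ms = 20) {
  n_sweeps <- length(sweeps_for_pattern)
  if (n_sweeps == 0) stop("no sweeps supplied")
  grid <- seq(from_ms, to_ms, by = 1)
  spikes <- unlist(sweeps_for_pattern, use.names = FALSE)
  if (length(spikes) == 0) {
    return(structure(list(time_grid = grid, values = rep(0, length(grid)),
                          bandwidth = fallback_bandwidth_ms, n_spikes = 0L,
                          n_sweeps = n_sweeps, zero_spikes = TRUE),
                     class = "density_curve"))
  }
  if (is.null(bandwidth_ms)) {
    bandwidth_ms <- if (length(spikes) >= 2) optimal_bandwidth(spikes)
                    else fallback_bandwidth_ms
  }
  vals <- kernel_sum(spikes, grid, bandwidth_ms) / n_sweeps * 1000
  structure(list(time_grid = grid, values = vals, bandwidth = bandwidth_ms,
                 n_spikes = length(spikes), n_sweeps = n_sweeps,
                 zero_spikes = FALSE),
            class = "density_curve")
}

# sum of Gaussian kernels (unit mass per spike, per-ms units) on a uniform
# grid, truncated at +/- 5 bandwidths
kernel_sum <- function(spikes, grid, bw) {
  vals <- numeric(length(grid))
  g0 <- grid[1]
  half <- ceiling(5 * bw)
  for (s in spikes) {
    i0 <- max(1L, floor(s - half - g0) + 1L)
    i1 <- min(length(grid), ceiling(s + half - g0) + 1L)
    if (i0 > i1) next
    idx <- i0:i1
    vals[idx] <- vals[idx] + stats::dnorm(grid[idx], mean = s, sd = bw)
  }
  vals
}

#' @export
print.density_curve <- function(x, ...) {
  cat(sprintf("<density_curve: [%g, %g] ms, bw %.2f ms, %d spikes / %d sweeps>\n",
              x$time_grid[1], x$time_grid[length(x$time_grid)], x$bandwidth,
              x$n_spikes, x$n_sweeps))
  invisible(x)
}

#' Per-pattern density curves for a neuron
#'
#' @param sweepset a `sweep_set`.
#' @inheritParams compute_kde
#' @return named list of `density_curve`, one per pattern.
#' @export
pattern_kdes <- function(sweepset, from_ms = 0, to_ms = 1000,
                         bandwidth_ms = NULL) {
  lapply(sweepset$sweeps, compute_kde, from_ms = from_ms, to_ms = to_ms,
         bandwidth_ms = bandwidth_ms)
}
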