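#' Compound density, peak-defined time windows and neuron qualification
#'
#' The per-pattern spike density curves of a neuron are superimposed and the
#' pointwise maximum (at 1 ms resolution) forms the compound density function.
#' Its interior local minima - boundaries between consecutive response peaks -
#' partition the analysis span into time windows. Window AUCs (baseline = the
#' lowest value within the window) are normalised to the largest window AUC,
#' and windows below 2.5% of it are excluded.
#'
#' @name response_segmentation
NULL

#' Restrict a density curve to a sub-span
#' @param curve a `density_curve` or `compound_density`.
#' @param from_ms,to_ms span to keep (inclusive).
#' @return curve of the same class on the restricted grid.
#' @export
clip_curve <- function(curve, from_ms, to_ms) {
  keep <- curve$time_grid >= from_ms & curve$time_grid <= to_ms
  if (!any(keep)) stop("requested span outside the curve grid")
  curve$time_grid <- curve$time_grid[keep]
  curve$values <- curve$values[keep]
  curve
}

#' Compound density function
#'
#' Pointwise maximum of the per-pattern density curves on their shared grid.
#'
#' @param kdes list of `density_curve` objects on identical grids.
#' @return a `compound_density` (time_grid, values).
#' @export
compound_density <- function(kdes) {
  if (length(kdes) == 0) stop("no curves supplied")
  grid <- kdes[[1]]$time_grid
  for (k in kdes) {
    if (length(k$time_grid) != length(grid) || any(k$time_grid != grid)) {
      stop("density curves must share the same time grid")
    }
  }
  vals <- do.call(pmax, lapply(kdes, `[[`, "values"))
  structure(list(time_grid = grid, values = vals), class = "compound_density")
}

# interior local minima of a series, with plateau rule: a flat run strictly
# below both neighbours contributes one boundary at its midpoint index
local_minima_idx <- function(v) {
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- integer(0)
  if (length(r$values) < 3) return(out)
  for (k in 2:(length(r$values) - 1L)) {
    if (r$values[k] < r$values[k - 1L] && r$values[k] < r$values[k + 1L]) {
      out <- c(out, floor((starts[k] + ends[k]) / 2))
    }
  }
  out
}

# interior local maxima (plateau midpoint rule), same convention
local_maxima_idx <- function(v) local_minima_idx(-v)

# trapezoidal AUC on a uniform 1 ms grid
trapz <- function(y) {
  if (length(y) < 2) return(0)
  sum((y[-1] + y[-length(y)]) / 2)
}

#' Segment a compound density into peak-defined time windows
#'
#' Boundaries are placed at each interior local minimum of the compound
#' density (plateau minima contribute one boundary at their midpoint). Each
#' window's AUC is computed by the trapezoidal rule after subtracting the
#' lowest value occurring within that window; AUCs are normalised to the
#' largest window AUC and windows below `auc_floor` of it are dropped.
#'
#' @param compound a `compound_density` (already clipped to the analysis span,
#'   600 ms by default in the decoding pipeline).
#' @param auc_floor minimum normalised AUC retained (default 0.025).
#' @return a `time_window_set`: `boundaries` (ms, including the span ends),
#'   `window_aucs`, `normalized_aucs`, `kept_mask`, `degenerate` flag.
#' @export
segment_windows <- function(compound, auc_floor = 0.025) {
  v <- compound$values
  g <- compound$time_grid
  if (length(v) < 2) stop("compound density too short to segment")
  if (all(v == 0)) {
    return(structure(list(boundaries = c(g[1], g[length(g)]),
                          window_aucs = 0, normalized_aucs = 0,
                          kept_mask = FALSE, degenerate = TRUE),
                     class = "time_window_set"))
  }
  cut_idx <- local_minima_idx(v)
  bounds_idx <- unique(c(1L, cut_idx, length(v)))
  n_win <- length(bounds_idx) - 1L
  aucs <- numeric(n_win)
  for (j in seq_len(n_win)) {
    seg <- v[bounds_idx[j]:bounds_idx[j + 1L]]
    aucs[j] <- trapz(seg - min(seg))
  }
  mx <- max(aucs)
  norm <- if (mx > 0) aucs / mx else rep(0, n_win)
  structure(list(boundaries = g[bounds_idx], window_aucs = aucs,
                 normalized_aucs = norm,
                 kept_mask = if (mx > 0) norm >= auc_floor else rep(FALSE, n_win),
                 degenerate = mx == 0),
            class = "time_window_set")
}

#' @export
print.time_window_set <- function(x, ...) {
  cat(sprintf("<time_window_set: %d windows (%d kept) on [%g, %g] ms>\n",
              length(x$window_aucs), sum(x$kept_mask),
              x$boundaries[1], x$boundaries[length(x$boundaries)]))
  invisible(x)
}

#' Neuron qualification criterion
#'
#' A neuron qualifies for the decoding analysis if, pooled across the density
#' curves of all stimulation patterns, at least `min_peaks` peaks exceed 200%
#' of the curve's baseline (100%) within 50 ms of the peak's deviation onset
#' from the baseline. The baseline is the mean curve value over the
#' pretrigger span; the deviation onset is the last upward crossing of the
#' baseline preceding the peak (the start of the grid if the curve never dips
#' below baseline).
#'
#' @param kdes list of `density_curve` objects whose grids cover a pretrigger
#'   span (times < 0).
#' @param min_peaks required number of qualifying peaks (default 3).
#' @param amplitude_factor peak threshold as a multiple of baseline (default 2).
#' @param rise_ms maximum onset-to-peak time (default 50).
#' @return list with `qualified` (logical), `n_peaks`, and a per-curve
#'   diagnostics data frame.
#' @export
qualify_neuron <- function(kdes, min_peaks = 3L, amplitude_factor = 2,
                           rise_ms = 50) {
  if (length(kdes) == 0) stop("no curves supplied")
  diag <- list()
  n_total <- 0L
  for (i in seq_along(kdes)) {
    k <- kdes[[i]]
    pre <- k$time_grid < 0
    if (!any(pre)) stop("curves must cover a pretrigger span for qualification")
    baseline <- mean(k$values[pre])
    if (baseline <= 0) stop("degenerate baseline: pretrigger density is zero")
    post_idx <- which(k$time_grid >= 0)
    v <- k$values[post_idx]
    g <- k$time_grid[post_idx]
    peaks <- local_maxima_idx(v)
    peaks <- peaks[v[peaks] > amplitude_factor * baseline]
    n_ok <- 0L
    for (p in peaks) {
      below <- which(v[seq_len(p)] <= baseline)
      onset <- if (length(below)) g[max(below)] else g[1]
      if (g[p] - onset <= rise_ms) n_ok <- n_ok + 1L
    }
    n_total <- n_total + n_ok
    diag[[i]] <- data.frame(curve = i, baseline = baseline,
                            n_candidate_peaks = length(peaks),
                            n_qualifying_peaks = n_ok)
  }
  list(qualified = n_total >= min_peaks, n_peaks = n_total,
       per_curve = do.call(rbind, diag))
}
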