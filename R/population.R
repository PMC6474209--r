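#' Inter-neuron response discrimination and cooperative population decoding
#'
#' @name population_decoding
NULL

#' Confusion matrix between neurons responding to the same pattern
#'
#' The response classes are neuron identities rather than stimulation
#' patterns: the raw responses of the compared neurons (typically 4-5) to one
#' stimulation pattern are run through the same split / bootstrap / kNN
#' machinery. Chance level is 100/M % for M neurons. Time windows are derived
#' from the compound density pooled over the compared neurons' density curves
#' for that pattern.
#'
#' @param neurons list of `sweep_set` (>= 2).
#' @param pattern_label the stimulation pattern whose responses are compared.
#' @param params a `decoder_params`.
#' @return a `decoding_result` with neuron ids as labels.
#' @export
inter_neuron_confusion <- function(neurons, pattern_label,
                                   params = decoder_params()) {
  if (length(neurons) < 2) stop("need >= 2 neurons to compare")
  kdes <- lapply(neurons, function(nn) {
    if (!pattern_label %in% names(nn$sweeps)) {
      stop(sprintf("neuron %s has no sweeps for pattern %s",
                   nn$neuron_id, pattern_label))
    }
    compute_kde(nn$sweeps[[pattern_label]], from_ms = 0, to_ms = params$span_ms)
  })
  windows <- segment_windows(compound_density(kdes), auc_floor = params$auc_floor)
  if (sum(windows$kept_mask) == 0) stop("no kept time windows for this pattern")
  grid <- seq(0, params$span_ms, by = 1)
  sigs <- list(); labels <- character(0)
  for (nn in neurons) {
    for (s in nn$sweeps[[pattern_label]]) {
      sigs[[length(sigs) + 1L]] <- sweep_to_signal(s, params$kernel_tau, grid)
    }
    labels <- c(labels, rep(nn$neuron_id, length(nn$sweeps[[pattern_label]])))
  }
  sig_mat <- do.call(rbind, sigs)
  decode_core(signal_window_aucs(sig_mat, windows), labels,
              rowSums(sig_mat) > 0, params)
}

#' Greedy cooperative decoding over a neuron population
#'
#' For each response duration, every neuron's decoding within that span is
#' computed and the best neuron is kept; at each later step the remaining
#' neurons are scanned and the one maximising the joint decoding - on
#' window-AUC features concatenated across the selected neurons (shared trial
#' indices, per-neuron windows) - is added, up to `max_neurons`. Neurons with
#' no kept windows within the span are skipped. Within one selection step all
#' candidates are evaluated with the same seed, so they share splits and
#' bootstrap draws; performance ties keep the lower neuron index.
#'
#' @param neurons list of co-recorded `sweep_set` objects (same schedule).
#' @param params a `decoder_params`.
#' @param durations_ms response durations analysed.
#' @param max_neurons selection cap (default 10).
#' @return list (one per duration) of `cooperative_result`: selected neuron
#'   ids, performance after each added neuron (%), cumulative feature
#'   dimensionality per step.
#' @export
cooperative_decode <- function(neurons, params = decoder_params(),
                               durations_ms = c(600), max_neurons = 10L) {
  if (length(neurons) == 0) stop("empty neuron list")
  all_kdes <- lapply(neurons, pattern_kdes, from_ms = 0,
                     to_ms = max(durations_ms))
  labels0 <- NULL
  out <- list()
  for (d in durations_ms) {
    p_d <- params
    p_d$span_ms <- d
    flats <- vector("list", length(neurons))
    usable <- logical(length(neurons))
    for (i in seq_along(neurons)) {
      clipped <- lapply(all_kdes[[i]], clip_curve, 0, d)
      win <- segment_windows(compound_density(clipped),
                             auc_floor = params$auc_floor)
      if (sum(win$kept_mask) == 0) next
      flats[[i]] <- sweepset_auc_matrix(neurons[[i]], win, p_d)
      usable[i] <- TRUE
      # joint features require trial-aligned rows across neurons
      if (is.null(labels0)) labels0 <- flats[[i]]$labels
      if (!identical(flats[[i]]$labels, labels0)) {
        stop("neurons must share the session schedule for cooperative decoding")
      }
    }
    avail <- which(usable)
    if (!length(avail)) {
      out[[as.character(d)]] <- structure(
        list(duration = d, selected_neurons = character(0),
             performance_per_step = numeric(0),
             dimensionality_per_step = integer(0)),
        class = "cooperative_result")
      next
    }
    selected <- integer(0)
    perf <- numeric(0)
    dims <- integer(0)
    for (step in seq_len(min(max_neurons, length(avail)))) {
      remaining <- setdiff(avail, selected)
      step_seed <- (params$seed + 7919L * step) %% .Machine$integer.max
      best <- -Inf; best_i <- NA_integer_
      for (i in remaining) {
        members <- c(selected, i)
        auc <- do.call(cbind, lapply(flats[members], `[[`, "auc"))
        nonempty <- Reduce(`|`, lapply(flats[members], `[[`, "nonempty"))
        p_step <- p_d
        p_step$seed <- step_seed
        res <- tryCatch(
          suppressWarnings(decode_core(auc, flats[[i]]$labels, nonempty, p_step)),
          error = function(e) NULL)
        if (is.null(res)) next
        if (res$mean_decoding_performance > best) {  # tie keeps lower index
          best <- res$mean_decoding_performance
          best_i <- i
        }
      }
      if (is.na(best_i)) break
      selected <- c(selected, best_i)
      perf <- c(perf, best)
      dims <- c(dims, sum(vapply(flats[selected],
                                 function(f) ncol(f$auc), integer(1))))
    }
    out[[as.character(d)]] <- structure(
      list(duration = d,
           selected_neurons = vapply(neurons[selected], `[[`, character(1),
                                     "neuron_id"),
           performance_per_step = perf,
           dimensionality_per_step = dims),
      class = "cooperative_result")
  }
  out
}

#' @export
print.cooperative_result <- function(x, ...) {
  cat(sprintf("<cooperative_result @ %g ms: %s; perf %s%%>\n", x$duration,
              paste(x$selected_neurons, collapse = " + "),
              paste(sprintf("%.1f", x$performance_per_step), collapse = " -> ")))
  invisible(x)
}
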