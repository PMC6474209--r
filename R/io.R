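#' Readers and writers for sweeps, traces, patterns and window sets
#'
#' Sweeps travel as tidy delimited text (neuron_id, trial_id, pattern_label,
#' spike_time_ms); continuous traces as single-column delimited text with a
#' JSON sidecar carrying sampling_rate and start_time; patterns and window
#' sets as JSON.
#'
#' @name io
NULL

#' @param sweepset a `sweep_set`.
#' @param path output TSV path.
#' @rdname io
#' @export
write_sweeps <- function(sweepset, path) {
  rows <- list()
  for (p in names(sweepset$sweeps)) {
    sw <- sweepset$sweeps[[p]]
    ids <- sweepset$trial_ids[[p]]
    if (is.null(ids)) ids <- seq_along(sw)
    for (i in seq_along(sw)) {
      if (length(sw[[i]]) == 0) next
      rows[[length(rows) + 1L]] <- data.frame(
        neuron_id = sweepset$neuron_id, trial_id = ids[i], pattern_label = p,
        spike_time_ms = sw[[i]])
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(neuron_id = character(0), trial_id = integer(0),
               pattern_label = character(0), spike_time_ms = numeric(0))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  sidecar <- sub("\\.tsv$", ".json", path)
  ids <- sweepset$trial_ids
  if (is.null(ids)) ids <- lapply(sweepset$sweeps, seq_along)
  jsonlite::write_json(list(neuron_id = sweepset$neuron_id,
                            area_tag = sweepset$area_tag,
                            depth = sweepset$depth,
                            pretrigger_span = sweepset$pretrigger_span,
                            posttrigger_span = sweepset$posttrigger_span,
                            trial_ids = ids),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname io
#' @export
read_sweeps <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(sub("\\.tsv$", ".json", path),
                              simplifyVector = TRUE)
  sweeps <- list()
  trial_ids <- list()
  for (p in names(meta$trial_ids)) {
    sub_df <- df[df$pattern_label == p, ]
    ids <- meta$trial_ids[[p]]  # full id list, so empty sweeps survive
    sweeps[[p]] <- lapply(ids, function(id) {
      sub_df$spike_time_ms[sub_df$trial_id == id]
    })
    trial_ids[[p]] <- ids
  }
  new_sweep_set(meta$neuron_id, sweeps, meta$pretrigger_span,
                meta$posttrigger_span, area_tag = meta$area_tag,
                depth = meta$depth, trial_ids = trial_ids)
}

#' @param trace a `continuous_trace`.
#' @rdname io
#' @export
write_trace <- function(trace, path) {
  utils::write.table(data.frame(value = trace$values), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(sampling_rate = trace$sampling_rate,
                            start_time = trace$start_time),
                       sub("\\.tsv$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname io
#' @export
read_trace <- function(path) {
  v <- utils::read.table(path, sep = "\t", header = TRUE)$value
  meta <- jsonlite::read_json(sub("\\.tsv$", ".json", path),
                              simplifyVector = TRUE)
  new_trace(v, meta$sampling_rate, meta$start_time)
}

#' @param patterns list of `stim_pattern`.
#' @rdname io
#' @export
write_patterns <- function(patterns, path) {
  jsonlite::write_json(lapply(patterns, unclass), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @param windows a `time_window_set`.
#' @rdname io
#' @export
write_windows <- function(windows, path) {
  jsonlite::write_json(unclass(windows), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname io
#' @export
read_windows <- function(path) {
  w <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(w, class = "time_window_set")
}

#' @param curve a `density_curve` or `compound_density`.
#' @rdname io
#' @export
write_curve <- function(curve, path) {
  utils::write.table(data.frame(time_ms = curve$time_grid,
                                value = curve$values),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @param seg a `state_segmentation`.
#' @rdname io
#' @export
write_state_intervals <- function(seg, path) {
  utils::write.table(seg$state_intervals, path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
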