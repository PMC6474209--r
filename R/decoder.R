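#' Single-neuron pattern decoding
#'
#' Raw spike sweeps are convolved with a causal exponential kernel (tau = 5
#' ms) into continuous response signals. Per iteration the sweeps of each
#' pattern are split 50/50 into training and test sets, each set is expanded
#' by bootstrap recombination (sums of N = 10 distinct sweeps, 200 target
#' combinations), responses are featurised as normalised per-window AUCs, and
#' test responses are classified against the training set with a k = 9
#' nearest-neighbour rule. Confusion matrices are averaged over 50 iterations;
#' the mean decoding performance is the diagonal mean.
#'
#' @name pattern_decoder
NULL

#' Decoder parameters
#'
#' @param kernel_tau exponential kernel time constant, ms.
#' @param group_size N, sweeps summed per bootstrap combination (10 as a rule;
#'   3 in the ECoG-state-conditioned analysis).
#' @param target_combinations bootstrap combinations per set per pattern.
#' @param k_neighbors neighbours used by the kNN rule.
#' @param n_iterations split/bootstrap iterations averaged.
#' @param auc_floor normalised-AUC retention floor for time windows.
#' @param split_fraction fraction of sweeps assigned to the test set.
#' @param span_ms analysis span (standard 600 ms).
#' @param seed integer seed for the decoding loop.
#' @return a `decoder_params` list.
#' @export
decoder_params <- function(kernel_tau = 5, group_size = 10L,
                           target_combinations = 200L, k_neighbors = 9L,
                           n_iterations = 50L, auc_floor = 0.025,
                           split_fraction = 0.5, span_ms = 600, seed = 1L) {
  stopifnot(kernel_tau > 0, group_size >= 1, target_combinations >= 1,
            k_neighbors >= 1, n_iterations >= 1,
            split_fraction > 0, split_fraction < 1, span_ms > 0)
  structure(list(kernel_tau = kernel_tau, group_size = as.integer(group_size),
                 target_combinations = as.integer(target_combinations),
                 k_neighbors = as.integer(k_neighbors),
                 n_iterations = as.integer(n_iterations),
                 auc_floor = auc_floor, split_fraction = split_fraction,
                 span_ms = span_ms, seed = as.integer(seed)),
            class = "decoder_params")
}

#' Convolve a spike sweep with a causal exponential kernel
#'
#' signal(t) = sum over spikes s of exp(-(t - s)/tau) for t >= s, 0 before.
#'
#' @param spike_times spike times, ms.
#' @param tau kernel time constant, ms.
#' @param grid uniform 1 ms evaluation grid.
#' @return numeric vector of signal values on the grid.
#' @export
sweep_to_signal <- function(spike_times, tau = 5, grid = seq(0, 600, by = 1)) {
  vals <- numeric(length(grid))
  if (length(spike_times) == 0) return(vals)
  g0 <- grid[1]
  n <- length(grid)
  reach <- ceiling(-tau * log(1e-12))  # beyond this the kernel is negligible
  for (s in spike_times) {
    i0 <- max(1L, ceiling(s - g0) + 1L)
    if (grid[min(i0, n)] < s) i0 <- i0 + 1L
    i1 <- min(n, i0 + reach)
    if (i0 > n || grid[i0] < s) next
    idx <- i0:i1
    vals[idx] <- vals[idx] + exp(-(grid[idx] - s) / tau)
  }
  vals
}

# distinct N-subsets of seq_len(n_avail): all of them when few enough,
# otherwise `target` random distinct subsets with every element covered
sample_combinations <- function(n_avail, N, target) {
  if (n_avail < N) stop("fewer available sweeps than the group size")
  n_comb <- suppressWarnings(choose(n_avail, N))
  if (is.finite(n_comb) && n_comb <= target) {
    return(t(utils::combn(n_avail, N)))
  }
  # coverage pass: chunk a shuffled index list into groups of N
  perm <- sample.int(n_avail)
  n_chunks <- ceiling(n_avail / N)
  cov <- matrix(0L, n_chunks, N)
  for (i in seq_len(n_chunks)) {
    take <- perm[((i - 1L) * N + 1L):min(i * N, n_avail)]
    if (length(take) < N) {
      take <- c(take, sample(setdiff(seq_len(n_avail), take), N - length(take)))
    }
    cov[i, ] <- sort(take)
  }
  combos <- cov
  while (nrow(combos) < target) {  # batch top-up; repeats only on collisions
    n_draw <- target - nrow(combos) + 8L
    draws <- t(vapply(seq_len(n_draw),
                      function(i) sort(sample.int(n_avail, N)),
                      integer(N)))
    combos <- rbind(combos, draws)
    keys <- do.call(paste, c(as.data.frame(combos), sep = ","))
    combos <- combos[!duplicated(keys), , drop = FALSE]
  }
  combos[seq_len(min(target, nrow(combos))), , drop = FALSE]
}

#' Bootstrap recombination of continuous response signals
#'
#' Sums N distinct response sweeps per combination; sweeps without any spikes
#' (all-zero signals) are excluded first. Up to `target` distinct combinations
#' are drawn (all of them when fewer exist) and every remaining sweep appears
#' in at least one combination.
#'
#' @param signals list of signal vectors (or a matrix with one row per sweep)
#'   for one pattern within one set.
#' @param N sweeps per combination.
#' @param target combinations to generate.
#' @return matrix of combined responses (one row each) with attribute
#'   `combinations` (row indices into the non-empty sweeps) and
#'   `nonempty_idx` (indices into the input).
#' @export
bootstrap_combine <- function(signals, N = 10L, target = 200L) {
  m <- if (is.matrix(signals)) signals else do.call(rbind, signals)
  nonempty <- which(rowSums(abs(m)) > 0)
  if (length(nonempty) < N) {
    stop(structure(class = c("bootstrap_failure", "error", "condition"),
                   list(message = sprintf(
                     "bootstrapping failed: %d non-empty sweeps < N = %d",
                     length(nonempty), N), call = sys.call(-1))))
  }
  combos <- sample_combinations(length(nonempty), N, target)
  out <- matrix(0, nrow = nrow(combos), ncol = ncol(m))
  for (i in seq_len(nrow(combos))) {
    out[i, ] <- colSums(m[nonempty[combos[i, ]], , drop = FALSE])
  }
  attr(out, "combinations") <- combos
  attr(out, "nonempty_idx") <- nonempty
  out
}

# kept-window index ranges on a 1 ms grid starting at windows$boundaries[1]
window_index_ranges <- function(windows) {
  b <- windows$boundaries
  idx <- round(b - b[1]) + 1L
  kept <- which(windows$kept_mask)
  lapply(kept, function(j) idx[j]:idx[j + 1L])
}

# per-sweep (rows) kept-window trapezoidal AUCs of signal rows
signal_window_aucs <- function(signal_matrix, windows) {
  ranges <- window_index_ranges(windows)
  out <- matrix(0, nrow = nrow(signal_matrix), ncol = length(ranges))
  for (j in seq_along(ranges)) {
    r <- ranges[[j]]
    seg <- signal_matrix[, r, drop = FALSE]
    out[, j] <- 0.5 * (seg[, 1] + seg[, length(r)]) +
      if (length(r) > 2) rowSums(seg[, -c(1, length(r)), drop = FALSE]) else 0
  }
  out
}

#' Featurise combined responses by windowed AUC
#'
#' Computes the trapezoidal AUC of each combined response within each kept
#' time window, then (by default) normalises each window dimension to the
#' largest AUC observed for it across all supplied responses - the per-set
#' normalisation of the decoding analysis. Windows whose maximum is zero are
#' set to 0 for every response.
#'
#' @param combined matrix of combined responses (rows) on the window grid, or
#'   a single signal vector.
#' @param windows a `time_window_set` on the same span.
#' @param normalize apply the per-set max normalisation.
#' @return feature matrix (rows = responses, cols = kept windows), values in
#'   [0, 1] when normalised.
#' @export
featurize <- function(combined, windows, normalize = TRUE) {
  if (!is.matrix(combined)) combined <- matrix(combined, nrow = 1)
  a <- signal_window_aucs(combined, windows)
  if (normalize) a <- normalize_features(a)
  a
}

normalize_features <- function(a) {
  mx <- apply(a, 2, max)
  mx[mx == 0] <- 1  # zero-max window dimension stays 0 for all responses
  sweep(a, 2, mx, "/")
}

#' k-nearest-neighbour classification in window-feature space
#'
#' Plurality vote among the k nearest training features (Euclidean distance);
#' ties between leading labels are broken by the label of the nearest
#' neighbour belonging to a tied label. Exact distance ties keep training-set
#' order.
#'
#' @param test_features matrix (rows = test responses) or single vector.
#' @param training_features matrix of training responses.
#' @param training_labels label per training row.
#' @param k neighbours (default 9).
#' @return character vector of assigned labels.
#' @export
knn_classify <- function(test_features, training_features, training_labels,
                         k = 9L) {
  if (!is.matrix(test_features)) test_features <- matrix(test_features, nrow = 1)
  if (nrow(training_features) < k) stop("fewer than k training points")
  d2 <- cross_dist2(test_features, training_features)
  apply_knn_vote(d2, training_labels, k)
}

# squared Euclidean cross-distances, rows of a vs rows of b
cross_dist2 <- function(a, b) {
  an <- rowSums(a^2)
  bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

apply_knn_vote <- function(d2, training_labels, k) {
  n_test <- nrow(d2)
  labf <- factor(training_labels)
  li <- as.integer(labf)
  K <- nlevels(labf)
  rows <- seq_len(n_test)
  # k passes of max.col extract the k nearest neighbours per test row;
  # ties.method = "first" keeps training-set order on exact distance ties
  nb_lab <- matrix(0L, n_test, k)
  nd <- -d2
  for (j in seq_len(k)) {
    nbj <- max.col(nd, ties.method = "first")
    nb_lab[, j] <- li[nbj]
    nd[cbind(rows, nbj)] <- -Inf
  }
  cnt <- matrix(0L, n_test, K)
  for (j in seq_len(k)) {
    idx <- cbind(rows, nb_lab[, j])
    cnt[idx] <- cnt[idx] + 1L
  }
  win <- max.col(cnt, ties.method = "first")
  mx <- cnt[cbind(rows, win)]
  tied <- which(rowSums(cnt == mx) > 1L)
  for (i in tied) {  # plurality tie: nearest neighbour among tied labels wins
    top <- which(cnt[i, ] == mx[i])
    win[i] <- nb_lab[i, which(nb_lab[i, ] %in% top)[1L]]
  }
  levels(labf)[win]
}

# core decoding engine on a per-sweep window-AUC matrix.
# auc_mat: (total sweeps) x (kept windows); labels: pattern per row;
# nonempty: logical per row. Returns a decoding_result.
decode_core <- function(auc_mat, labels, nonempty, params, shuffle = FALSE) {
  set.seed(params$seed)
  pat <- sort(unique(labels))
  K <- length(pat)
  conf_sum <- matrix(0, K, K, dimnames = list(true = pat, assigned = pat))
  conf_n <- matrix(0, K, K, dimnames = dimnames(conf_sum))
  perf_iter <- numeric(params$n_iterations)
  n_warn <- 0L
  for (it in seq_len(params$n_iterations)) {
    lab_it <- if (shuffle) sample(labels) else labels
    tr_feat <- list(); tr_lab <- character(0)
    te_feat <- list(); te_lab <- list()
    for (p in pat) {
      idx <- which(lab_it == p)
      idx <- idx[sample.int(length(idx))]
      n_test <- floor(length(idx) * params$split_fraction)  # odd -> extra to train
      te_idx <- idx[seq_len(n_test)]
      tr_idx <- idx[-seq_len(n_test)]
      tr_ne <- tr_idx[nonempty[tr_idx]]
      te_ne <- te_idx[nonempty[te_idx]]
      if (length(tr_ne) < params$group_size || length(te_ne) < params$group_size) {
        n_warn <- n_warn + 1L
        next  # bootstrap failure: pattern omitted from this iteration
      }
      ctr <- sample_combinations(length(tr_ne), params$group_size,
                                 params$target_combinations)
      cte <- sample_combinations(length(te_ne), params$group_size,
                                 params$target_combinations)
      ftr <- combo_features(auc_mat, tr_ne, ctr)
      fte <- combo_features(auc_mat, te_ne, cte)
      tr_feat[[p]] <- ftr
      tr_lab <- c(tr_lab, rep(p, nrow(ftr)))
      te_feat[[p]] <- fte
      te_lab[[p]] <- rep(p, nrow(fte))
    }
    if (length(tr_feat) == 0) next
    train <- normalize_features(do.call(rbind, tr_feat))
    test <- normalize_features(do.call(rbind, te_feat))
    true_lab <- unlist(te_lab, use.names = FALSE)
    if (nrow(train) < params$k_neighbors) next
    assigned <- apply_knn_vote(cross_dist2(test, train), tr_lab,
                               params$k_neighbors)
    present <- names(te_feat)
    diag_it <- numeric(0)
    for (p in present) {
      sel <- true_lab == p
      row_pct <- 100 * vapply(pat, function(q) mean(assigned[sel] == q),
                              numeric(1))
      conf_sum[p, ] <- conf_sum[p, ] + row_pct
      conf_n[p, ] <- conf_n[p, ] + 1
      diag_it <- c(diag_it, row_pct[p])
    }
    perf_iter[it] <- mean(diag_it)
  }
  if (all(conf_n == 0)) stop("bootstrapping failed for every pattern")
  if (n_warn > 0) {
    warning(sprintf("bootstrap failure in %d pattern-iteration(s); omitted", n_warn))
  }
  mean_conf <- conf_sum / pmax(conf_n, 1)
  structure(list(labels = pat, mean_confusion = mean_conf,
                 mean_decoding_performance = mean(diag(mean_conf)),
                 per_iteration_performance = perf_iter,
                 shuffled = shuffle, n_omitted = n_warn),
            class = "decoding_result")
}

combo_features <- function(auc_mat, rows, combos) {
  picked <- auc_mat[rows[t(combos)], , drop = FALSE]
  out <- rowsum(picked, rep(seq_len(nrow(combos)), each = ncol(combos)),
                reorder = FALSE)
  dimnames(out) <- NULL
  out
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("<decoding_result%s: %d classes, mean decoding %.1f%%>\n",
              if (x$shuffled) " (shuffled control)" else "",
              length(x$labels), x$mean_decoding_performance))
  invisible(x)
}

# flatten a sweep_set into (signal AUC matrix, labels, nonempty) on the
# kept windows of `windows`; sweeps restricted to trials in `trial_filter`
# when given (named list per pattern of positions to keep)
sweepset_auc_matrix <- function(sweepset, windows, params,
                                trial_filter = NULL) {
  span <- windows$boundaries[length(windows$boundaries)]
  grid <- seq(windows$boundaries[1], span, by = 1)
  labels <- character(0)
  sigs <- list()
  for (p in names(sweepset$sweeps)) {
    sw <- sweepset$sweeps[[p]]
    if (!is.null(trial_filter)) sw <- sw[trial_filter[[p]]]
    for (s in sw) {
      sigs[[length(sigs) + 1L]] <- sweep_to_signal(s, params$kernel_tau, grid)
    }
    labels <- c(labels, rep(p, length(sw)))
  }
  sig_mat <- do.call(rbind, sigs)
  list(auc = signal_window_aucs(sig_mat, windows), labels = labels,
       nonempty = rowSums(sig_mat) > 0)
}

#' Derive the decoding time windows for a neuron
#'
#' Computes the per-pattern spike density curves, clips them to the analysis
#' span, forms the compound density and segments it.
#'
#' @param sweepset a `sweep_set`.
#' @param params a `decoder_params` (uses `span_ms` and `auc_floor`).
#' @param kdes optionally, precomputed per-pattern `density_curve`s covering
#'   the span.
#' @return a `time_window_set`.
#' @export
derive_windows <- function(sweepset, params = decoder_params(), kdes = NULL) {
  if (is.null(kdes)) kdes <- pattern_kdes(sweepset, from_ms = 0, to_ms = 1000)
  clipped <- lapply(kdes, clip_curve, from_ms = 0, to_ms = params$span_ms)
  segment_windows(compound_density(clipped), auc_floor = params$auc_floor)
}

#' Decode the stimulation pattern from one neuron's responses
#'
#' Full decoding loop: per iteration, stratified 50/50 split, bootstrap
#' recombination of both sets, per-set AUC featurisation, and kNN
#' classification of every test response, summarised as a confusion matrix.
#' The result averages the confusion matrices over `params$n_iterations`
#' iterations; patterns whose bootstrap fails in an iteration are omitted from
#' that iteration with a warning.
#'
#' @param sweepset a `sweep_set` (the neuron should pass [qualify_neuron()]).
#' @param windows the neuron's `time_window_set` (fixed across iterations).
#' @param params a `decoder_params`.
#' @param shuffle permute pattern labels before each split (the shuffled
#'   control).
#' @return a `decoding_result`: mean confusion matrix (rows sum to 100%),
#'   mean decoding performance (diagonal mean, %), per-iteration performance.
#' @export
decode_neuron <- function(sweepset, windows, params = decoder_params(),
                          shuffle = FALSE) {
  if (sum(windows$kept_mask) == 0) stop("no kept time windows for this neuron")
  flat <- sweepset_auc_matrix(sweepset, windows, params)
  decode_core(flat$auc, flat$labels, flat$nonempty, params, shuffle = shuffle)
}

#' @rdname decode_neuron
#' @export
shuffled_control <- function(sweepset, windows, params = decoder_params()) {
  decode_neuron(sweepset, windows, params, shuffle = TRUE)
}

#' Decoding performance across integration time windows
#'
#' Re-derives the time windows on each truncated span and decodes within it.
#'
#' @param sweepset a `sweep_set`.
#' @param params a `decoder_params`.
#' @param durations_ms analysed span durations (default 100-1000 ms in 100 ms
#'   steps).
#' @return named list of `decoding_result` (chance-level placeholder with
#'   `no_windows = TRUE` where no window survives the AUC floor).
#' @export
time_window_evolution <- function(sweepset, params = decoder_params(),
                                  durations_ms = seq(100, 1000, by = 100)) {
  kdes <- pattern_kdes(sweepset, from_ms = 0, to_ms = max(durations_ms))
  out <- list()
  for (d in durations_ms) {
    p_d <- params
    p_d$span_ms <- d
    win <- derive_windows(sweepset, p_d,
                          kdes = lapply(kdes, clip_curve, 0, max(durations_ms)))
    if (sum(win$kept_mask) == 0) {
      K <- length(sweepset$sweeps)
      res <- structure(list(labels = names(sweepset$sweeps),
                            mean_confusion = matrix(100 / K, K, K),
                            mean_decoding_performance = 100 / K,
                            per_iteration_performance = numeric(0),
                            shuffled = FALSE, no_windows = TRUE),
                       class = "decoding_result")
    } else {
      res <- decode_neuron(sweepset, win, p_d)
    }
    out[[as.character(d)]] <- res
  }
  out
}
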