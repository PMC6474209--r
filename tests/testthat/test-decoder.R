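test_that("exponential-kernel conversion matches its definition and a double loop", {
  grid <- 0:100
  one <- sweep_to_signal(0, tau = 5, grid = grid)
  expect_equal(one[grid == 5], exp(-1) * one[grid == 0])
  expect_equal(sweep_to_signal(c(10, 10), grid = grid),
               2 * sweep_to_signal(10, grid = grid))
  expect_equal(sweep_to_signal(numeric(0), grid = grid), numeric(101))
  for (s in 1:20) {
    set.seed(s)
    spikes <- sort(stats::runif(12, -20, 90))
    got <- sweep_to_signal(spikes, tau = 5, grid = grid)
    oracle <- numeric(length(grid))
    for (i in seq_along(grid)) {
      for (sp in spikes) {
        if (grid[i] >= sp) oracle[i] <- oracle[i] + exp(-(grid[i] - sp) / 5)
      }
    }
    expect_equal(got, oracle, tolerance = 1e-10)
  }
})

test_that("bootstrap recombination enumerates, covers, and fails as specified", {
  set.seed(1)
  sigs <- lapply(1:12, function(i) stats::runif(50) + 0.1)
  comb <- bootstrap_combine(sigs, N = 10, target = 200)
  expect_equal(nrow(comb), choose(12, 10))  # 66: all distinct subsets
  combos <- attr(comb, "combinations")
  expect_true(all(seq_len(12) %in% as.vector(combos)))
  # sums match a direct evaluation
  i <- 17
  expect_equal(comb[i, ], Reduce(`+`, sigs[combos[i, ]]))
  # sampled regime: distinct subsets, coverage, target respected
  sigs40 <- lapply(1:40, function(i) stats::runif(50) + 0.1)
  comb40 <- bootstrap_combine(sigs40, N = 10, target = 150)
  c40 <- attr(comb40, "combinations")
  expect_equal(nrow(c40), 150)
  expect_false(any(duplicated(apply(c40, 1, paste, collapse = ","))))
  expect_true(all(seq_len(40) %in% as.vector(c40)))
  # empty sweeps are excluded first; < N non-empty sweeps is a failure
  sigs9 <- c(lapply(1:9, function(i) stats::runif(50) + 0.1),
             list(numeric(50)))
  expect_error(bootstrap_combine(sigs9, N = 10), class = "bootstrap_failure")
})

test_that("window featurisation normalises per set and matches quadrature", {
  win <- structure(list(boundaries = c(0, 50, 100), window_aucs = c(1, 1),
                        normalized_aucs = c(1, 1), kept_mask = c(TRUE, TRUE),
                        degenerate = FALSE), class = "time_window_set")
  expect_equal(featurize(numeric(101), win), matrix(0, 1, 2))
  set.seed(2)
  m <- rbind(stats::runif(101), stats::runif(101) + 5)  # row 2 dominates
  f <- featurize(m, win)
  expect_equal(f[2, ], c(1, 1))
  expect_true(all(f >= 0 & f <= 1))
  # quadrature oracle: rectangle sum on a 0.1 ms refinement of the signal
  sm <- matrix(gaussian_bump(0:100, 40, 15), 1)
  raw <- featurize(sm, win, normalize = FALSE)
  fine <- function(a, b) {
    xs <- seq(a, b - 0.1, by = 0.1)
    sum(approx(0:100, sm[1, ], xout = xs)$y) * 0.1
  }
  rect <- c(fine(0, 50), fine(50, 100))
  expect_lt(max(abs(raw - rect) / rect), 0.005)
})

test_that("kNN classification matches an exhaustive distance-sort oracle", {
  for (s in 1:20) {
    set.seed(s)
    train <- matrix(stats::runif(600), ncol = 3)
    lab <- sample(letters[1:4], 200, replace = TRUE)
    test <- matrix(stats::runif(30), ncol = 3)
    got <- knn_classify(test, train, lab, k = 9)
    oracle <- apply(test, 1, function(x) {
      d <- sqrt(colSums((t(train) - x)^2))
      nb <- lab[order(d)[1:9]]
      tt <- table(nb)
      top <- names(tt)[tt == max(tt)]
      if (length(top) == 1) top else nb[nb %in% top][1]
    })
    expect_equal(got, oracle)
  }
  expect_error(knn_classify(matrix(0, 1, 2), matrix(0, 5, 2),
                            letters[1:5], k = 9), "fewer")
})

test_that("kNN plurality votes and breaks ties with the nearest tied neighbour", {
  # 9 nearest all one label
  train <- matrix(c(rep(0, 9), rep(10, 9)), ncol = 1)
  lab <- rep(c("A", "B"), each = 9)
  expect_equal(knn_classify(matrix(0.1), train, lab, k = 9), "A")
  # 4-4-1 split: nearest point's label B wins the tie
  train2 <- matrix(c(1, 2, 3, 4, 1.5, 2.5, 3.5, 4.5, 6), ncol = 1)
  lab2 <- c(rep("A", 4), rep("B", 4), "C")
  expect_equal(knn_classify(matrix(1.4), train2, lab2, k = 9), "B")
})

test_that("a separable neuron decodes far above chance with rows summing to 100%", {
  sched <- tiny_schedule(k = 8, repetitions = 24, seed = 1)
  ss <- generate_sweeps(separable_spec(k = 8), sched, seed = 2)
  dp <- decoder_params(n_iterations = 5, seed = 3)
  win <- derive_windows(ss, dp)
  res <- decode_neuron(ss, win, dp)
  expect_gt(res$mean_decoding_performance, 90)
  expect_equal(unname(rowSums(res$mean_confusion)), rep(100, 8),
               tolerance = 1e-8)
  expect_true(all(res$mean_confusion >= 0))
  # deterministic given (data, seed)
  res2 <- decode_neuron(ss, win, dp)
  expect_identical(res$mean_confusion, res2$mean_confusion)
})

test_that("label-independent responses decode at the 8-class chance level", {
  sched <- tiny_schedule(k = 8, repetitions = 24, seed = 4)
  ss <- generate_sweeps(signal_free_spec(k = 8), sched, seed = 5)
  dp <- decoder_params(n_iterations = 10, seed = 6)
  win <- derive_windows(ss, dp)
  res <- decode_neuron(ss, win, dp)
  sd_it <- stats::sd(res$per_iteration_performance)
  expect_lt(abs(res$mean_decoding_performance - 12.5), max(3 * sd_it, 4))
})

test_that("the shuffled control shuffles labels uniformly and sits at chance", {
  sched <- tiny_schedule(k = 2, repetitions = 30, seed = 7)
  ss <- generate_sweeps(separable_spec(k = 2), sched, seed = 8)
  dp <- decoder_params(n_iterations = 20, seed = 9)
  win <- derive_windows(ss, dp)
  shuf <- shuffled_control(ss, win, dp)
  expect_true(shuf$shuffled)
  # 2-pattern reduction: shuffled performance close to 50%
  expect_lt(abs(shuf$mean_decoding_performance - 50),
            3 * stats::sd(shuf$per_iteration_performance) /
              sqrt(length(shuf$per_iteration_performance)) + 5)
  # permutation uniformity: label assignments of a fixed position are balanced
  set.seed(10)
  labels <- rep(c("A", "B", "C", "D"), each = 5)
  first <- replicate(4000, sample(labels)[1])
  chi <- stats::chisq.test(table(first))
  expect_gt(chi$p.value, 0.001)
})

test_that("decoding improves monotonically with pattern separation", {
  sched <- tiny_schedule(k = 4, repetitions = 20, seed = 11)
  perf_at_sep <- function(sep_scale, seed) {
    labels <- paste0("P", 1:4)
    profiles <- lapply(1:4, function(i) {
      data.frame(peak_time = 100 + (i - 1) * sep_scale, peak_rate = 50,
                 peak_width = 10)
    })
    names(profiles) <- labels
    ss <- generate_sweeps(neuron_spec(5, profiles, reliability = 1),
                          sched, seed = seed)
    dp <- fast_params(seed = seed)
    win <- derive_windows(ss, dp)
    decode_neuron(ss, win, dp)$mean_decoding_performance
  }
  seps <- c(5, 40, 120)
  med <- vapply(seps, function(sp) {
    stats::median(vapply(1:5, function(s) perf_at_sep(sp, s), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(med) >= 0))
})

test_that("time-window evolution returns one result per duration and is consistent", {
  sched <- tiny_schedule(k = 4, repetitions = 16, seed = 12)
  ss <- generate_sweeps(separable_spec(k = 4), sched, seed = 13)
  dp <- fast_params(seed = 14)
  durations <- seq(100, 1000, by = 100)
  evo <- time_window_evolution(ss, dp, durations)
  expect_length(evo, 10)
  expect_named(evo, as.character(durations))
  perfs <- vapply(evo, `[[`, numeric(1), "mean_decoding_performance")
  expect_true(all(perfs >= 0 & perfs <= 100))
})

test_that("a late discriminative peak is invisible to short integration windows", {
  sched <- tiny_schedule(k = 4, repetitions = 20, seed = 15)
  labels <- paste0("P", 1:4)
  profiles <- lapply(1:4, function(i) {
    data.frame(peak_time = 250 + (i - 1) * 60, peak_rate = 60, peak_width = 8)
  })
  names(profiles) <- labels
  ss <- generate_sweeps(neuron_spec(5, profiles, reliability = 1),
                        sched, seed = 16)
  evo <- time_window_evolution(ss, fast_params(seed = 17), c(100, 600))
  expect_lt(evo[["100"]]$mean_decoding_performance, 45)
  expect_gt(evo[["600"]]$mean_decoding_performance, 70)
})
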