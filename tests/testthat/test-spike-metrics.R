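test_that("PSTH rates follow the pooled count arithmetic", {
  sweeps <- replicate(10, 2.5, simplify = FALSE)  # 1 spike each in [0, 5)
  p <- compute_psth(sweeps, bin_size = 5, pre_span = 500, post_span = 500)
  bin0 <- which(p$bin_edges[-length(p$bin_edges)] == 0)
  expect_equal(p$rates[bin0], 200)  # 10 spikes / (10 sweeps x 5 ms)
  expect_true(all(p$rates[-bin0] == 0))
  expect_equal(p$baseline_mean, 0)
  expect_equal(p$baseline_sd, 0)

  empty <- compute_psth(list(numeric(0), numeric(0)))
  expect_true(all(empty$rates == 0))
  expect_equal(empty$baseline_sd, 0)
  expect_error(compute_psth(list()), "empty")
})

test_that("homogeneous Poisson sweeps recover their rate as the PSTH baseline", {
  set.seed(7)
  sweeps <- replicate(200, {
    n <- stats::rpois(1, 20)  # 20 Hz over [-500, 500] = 20 expected spikes
    sort(stats::runif(n, -500, 500))
  }, simplify = FALSE)
  p <- compute_psth(sweeps)
  pre <- p$rates[p$bin_edges[-length(p$bin_edges)] < 0]
  se <- stats::sd(pre) / sqrt(length(pre))
  expect_lt(abs(p$baseline_mean - 20), 3 * se)
})

make_psth <- function(rates, bin_size = 5, pre_bins = 100) {
  n <- length(rates)
  edges <- seq(-pre_bins * bin_size, (n - pre_bins) * bin_size, by = bin_size)
  structure(list(bin_size = bin_size, bin_edges = edges, rates = rates,
                 n_sweeps = 10,
                 baseline_mean = mean(rates[1:pre_bins]),
                 baseline_sd = stats::sd(rates[1:pre_bins])),
            class = "psth")
}

test_that("latency detection needs two consecutive supra-threshold bins", {
  base <- rep(c(10, 12), 50)  # baseline mean 11, sd ~1
  r <- c(base, rep(11, 100))
  r[100 + 4] <- r[100 + 5] <- 11 + 4 * stats::sd(base)  # bins at 15 and 20 ms
  expect_equal(response_latency(make_psth(r)), 15)
  r2 <- c(base, rep(11, 100))
  r2[100 + 4] <- 11 + 10 * stats::sd(base)  # single isolated bin
  expect_true(is.na(response_latency(make_psth(r2))))
  expect_true(is.na(response_latency(make_psth(c(base, rep(11, 100))))))
  one_pre <- make_psth(rep(1, 10), pre_bins = 1)
  one_pre$baseline_sd <- NA_real_
  expect_error(response_latency(one_pre), "baseline")
})

test_that("latency rule agrees with a brute-force run scan on random histograms", {
  for (s in 1:25) {
    set.seed(s)
    base <- stats::rnorm(100, 10, 1)
    post <- stats::rnorm(100, 10, 1) + sample(c(0, 8), 100, replace = TRUE)
    p <- make_psth(c(base, post))
    thr <- p$baseline_mean + 3 * p$baseline_sd
    starts <- p$bin_edges[-length(p$bin_edges)]
    oracle <- NA_real_
    for (i in which(starts >= 0)) {
      if (i + 1 <= length(p$rates) && p$rates[i] > thr && p$rates[i + 1] > thr) {
        oracle <- starts[i]; break
      }
    }
    expect_identical(response_latency(p), oracle)
  }
})

test_that("response intensity is the maximal SD change from baseline", {
  base <- rep(c(8, 12), 50)  # mean 10, sd ~2.01
  r <- c(base, rep(10, 100)); r[150] <- 30
  p <- make_psth(r)
  p$baseline_mean <- 10; p$baseline_sd <- 2
  expect_equal(response_intensity(p, 0), 10)  # (30 - 10) / 2
  flat <- make_psth(c(base, rep(10, 100)))
  flat$baseline_mean <- 10; flat$baseline_sd <- 2
  expect_equal(response_intensity(flat, 0), 0)
  degen <- flat; degen$baseline_sd <- 0
  expect_error(response_intensity(degen, 0), "degenerate")
  expect_error(response_intensity(flat, NA), "latency")
})

test_that("bandwidth optimisation matches a fine grid scan of the same cost", {
  for (s in 1:5) {
    set.seed(s)
    spikes <- c(stats::rnorm(15, 100, 10), stats::rnorm(15, 300, 10))
    bw <- optimal_bandwidth(spikes)
    fine <- seq(0.5, 220, by = 0.1)
    w_star <- fine[which.min(ss_cost(spikes, fine))]
    cand <- exp(seq(log(1), log(200), length.out = 50))
    lo <- max(cand[cand <= w_star], min(cand))
    hi <- min(cand[cand >= w_star], max(cand))
    expect_true(bw >= lo - 1e-9 && bw <= hi + 1e-9)
  }
})

test_that("bandwidth scales with the data and stays well below cluster separation", {
  set.seed(11)
  spikes <- stats::rnorm(40, 200, 15)
  b1 <- optimal_bandwidth(spikes)
  b2 <- optimal_bandwidth(spikes * 2)
  step <- log(200) / 49  # candidate grid log spacing
  expect_lt(abs(log(b2 / b1) - log(2)), 2 * step + 1e-9)
  two_clusters <- c(stats::rnorm(30, 100, 5), stats::rnorm(30, 300, 5))
  expect_lt(optimal_bandwidth(two_clusters), 60)
  expect_error(optimal_bandwidth(5), ">= 2")
})

test_that("KDE values equal the direct Gaussian-sum oracle", {
  set.seed(3)
  sweeps <- replicate(5, sort(stats::runif(8, 0, 600)), simplify = FALSE)
  k <- compute_kde(sweeps, from_ms = 0, to_ms = 1000, bandwidth_ms = 12)
  spikes <- unlist(sweeps)
  pts <- sample(seq_along(k$time_grid), 20)
  for (i in pts) {
    oracle <- sum(stats::dnorm(k$time_grid[i], spikes, 12)) / 5 * 1000
    expect_equal(k$values[i], oracle, tolerance = 1e-3)
  }
  one <- compute_kde(list(100), bandwidth_ms = 10)
  expect_equal(one$time_grid[which.max(one$values)], 100)
  z <- compute_kde(list(numeric(0), numeric(0)))
  expect_true(z$zero_spikes)
  expect_true(all(z$values == 0))
})

test_that("normalised KDE tracks the normalised 5 ms PSTH on bump data", {
  set.seed(21)
  sweeps <- replicate(1000, {  # dense data so PSTH bin noise is small
    n <- stats::rpois(1, 30)
    stats::rnorm(n, 250, 40)
  }, simplify = FALSE)
  k <- compute_kde(sweeps, from_ms = 0, to_ms = 500)
  p <- compute_psth(sweeps, bin_size = 5, pre_span = 0, post_span = 500)
  centers <- p$bin_edges[-length(p$bin_edges)] + 2.5
  kde_at <- approx(k$time_grid, k$values, xout = centers)$y
  expect_lt(max(abs(kde_at / max(kde_at) - p$rates / max(p$rates))), 0.15)
})
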