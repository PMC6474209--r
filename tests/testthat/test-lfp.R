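test_that("the SE-LFP gate rejects sub-threshold deflections and needs pretrigger", {
  set.seed(1)
  fs <- 10000
  n <- 2000  # 100 ms pre + 100 ms post at 10 kHz
  sw <- matrix(stats::rnorm(30 * n), nrow = 30)
  attr(sw, "pre_ms") <- 100; attr(sw, "sampling_rate") <- fs
  # -3 SD (of the trimmed average) deflection only: 5 SD gate holds
  base_sd <- stats::sd(apply(sw[, 1:1000], 2, function(x) {
    s <- sort(x); mean(s[8:23])
  }))
  dip <- sw
  idx <- 1080:1130
  dip[, idx] <- dip[, idx] - 3 * base_sd
  expect_false(detect_se_lfp(dip)$detected)
  expect_error(detect_se_lfp(sw[1:3, , drop = FALSE]), ">= 4")
  no_pre <- sw; attr(no_pre, "pre_ms") <- 50
  expect_error(detect_se_lfp(no_pre), "pretrigger")
})

test_that("injected SE-LFP deflections are recovered with latency and amplitude", {
  fs <- 10000
  n <- 2000
  t_ms <- (seq_len(n) - 1) / 10 - 100
  bump <- -8 * exp(-0.5 * ((t_ms - 12) / 3)^2)  # deep deflection around 12 ms
  # deterministic -2 SD onset of the injected shape sits near 6-7 ms; allow
  # +/- 4 ms recovery error around it plus sub-ms trim/filter jitter
  for (r in 1:10) {
    set.seed(100 + r)
    sw <- matrix(stats::rnorm(30 * n, 0, 1), nrow = 30)
    sw <- sweep(sw, 2, bump, "+")
    attr(sw, "pre_ms") <- 100; attr(sw, "sampling_rate") <- fs
    res <- detect_se_lfp(sw)
    expect_true(res$detected)
    expect_true(res$latency_ms >= 2.5 && res$latency_ms <= 10.5)
    expect_lt(abs(res$amplitude - min(bump)), 1.5)
  }
})

test_that("pattern-LFP events respect the 2 SD / 10 ms rule through the filter chain", {
  fs <- 10000
  n <- 800 * fs / 1000
  flat <- rep(0, n)
  expect_equal(nrow(detect_pattern_lfps(flat, fs)), 0)
  set.seed(3)
  noise <- stats::rnorm(n, 0, 1)
  ev0 <- detect_pattern_lfps(noise, fs)
  # injected 20 ms rectangular dip at +50 ms, much deeper than baseline SD
  t_ms <- (seq_len(n) - 1) / 10 - 400
  dip <- noise; dip[t_ms >= 50 & t_ms < 70] <- dip[t_ms >= 50 & t_ms < 70] - 30
  ev <- detect_pattern_lfps(dip, fs)
  post_new <- ev[ev$epoch == "post" & ev$onset_ms > 30 & ev$onset_ms < 80, ]
  expect_equal(nrow(post_new), 1)
  expect_gte(post_new$duration_ms, 10)
  expect_lt(post_new$amplitude, 0)
  # duration gate: the same sub-threshold excursion is kept by a 10 ms gate
  # but rejected when the required duration exceeds it
  expect_equal(nrow(detect_pattern_lfps(dip, fs, min_duration_ms = 10)), 1)
  expect_equal(nrow(detect_pattern_lfps(dip, fs, min_duration_ms = 40)), 0)
  expect_error(detect_pattern_lfps(noise[1:100], fs), "shorter")
})

test_that("the filter chain is linear and offset-invariant", {
  set.seed(4)
  fs <- 10000
  n <- 800 * fs / 1000
  t_ms <- (seq_len(n) - 1) / 10 - 400
  x <- stats::rnorm(n, 0, 1)
  x[t_ms >= 100 & t_ms < 130] <- x[t_ms >= 100 & t_ms < 130] - 25
  ev1 <- detect_pattern_lfps(x, fs)
  ev2 <- detect_pattern_lfps(3 * x, fs)
  expect_equal(ev1$onset_ms, ev2$onset_ms)
  expect_equal(ev1$duration_ms, ev2$duration_ms)
  expect_equal(ev2$amplitude, 3 * ev1$amplitude, tolerance = 1e-8)
  ev3 <- detect_pattern_lfps(x + 42, fs)
  expect_equal(ev1, ev3, tolerance = 1e-8)
})

test_that("boxcar AUC reconstruction equals amplitude x duration and its integral", {
  ev <- data.frame(onset_ms = c(10, 100), duration_ms = c(20, 15),
                   amplitude = c(-3, -1.5), epoch = c("post", "post"))
  expect_equal(lfp_boxcar_auc(ev), c(60, 22.5))
  # signal-reconstruction oracle: integrate the boxcar train
  sig <- numeric(400)
  for (i in 1:2) {
    idx <- (ev$onset_ms[i] + 1):(ev$onset_ms[i] + ev$duration_ms[i])
    sig[idx] <- sig[idx] + ev$amplitude[i]
  }
  expect_equal(sum(lfp_boxcar_auc(ev)), sum(abs(sig)))
  bad <- ev; bad$duration_ms[1] <- 0
  expect_error(lfp_boxcar_auc(bad), "> 0")
})

test_that("pre/post comparison is calibrated under the null and detects shifts", {
  set.seed(5)
  make_events <- function(n_pre, n_post) {
    pre <- if (n_pre > 0) data.frame(onset_ms = stats::runif(n_pre, -400, -10),
                                     duration_ms = 12, amplitude = -2,
                                     epoch = "pre") else NULL
    post <- if (n_post > 0) data.frame(onset_ms = stats::runif(n_post, 0, 390),
                                       duration_ms = 12, amplitude = -2,
                                       epoch = "post") else NULL
    out <- rbind(pre, post)
    if (is.null(out)) data.frame(onset_ms = numeric(0), duration_ms = numeric(0),
                                 amplitude = numeric(0), epoch = character(0))
    else out
  }
  # null: pre and post counts iid -> ~5% rejections at alpha = 0.05
  pvals <- replicate(200, {
    evs <- lapply(1:30, function(i) make_events(stats::rpois(1, 2),
                                                stats::rpois(1, 2)))
    compare_pre_post(evs, "count")$p_value
  })
  expect_gt(mean(pvals < 0.05, na.rm = TRUE), 0.005)
  expect_lt(mean(pvals < 0.05, na.rm = TRUE), 0.12)
  # post = pre + 2 events on every sweep: detected at n = 30
  evs <- lapply(1:30, function(i) {
    k <- stats::rpois(1, 2); make_events(k, k + 2)
  })
  expect_lt(compare_pre_post(evs, "count")$p_value, 0.01)
  # single sweep: degenerate
  expect_true(compare_pre_post(evs[1], "count")$degenerate)
})
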