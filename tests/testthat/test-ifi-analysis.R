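test_that("IFIs are first differences of the frame times", {
  expect_equal(compute_ifis(timestamp_series(c(0, 0.1, 0.2)))$ifi_s, c(0.1, 0.1))
  # nominal 82 fps: every interval is 1/82 s (about 12.2 ms)
  const <- timestamp_series(seq(0, 2, by = 1 / 82))
  expect_equal(compute_ifis(const)$ifi_s, rep(1 / 82, 164))
  # random monotone series equals brute-force pairwise subtraction
  set.seed(1)
  t <- cumsum(runif(50, 0.01, 0.03))
  got <- compute_ifis(timestamp_series(t))$ifi_s
  expect_equal(got, t[-1] - t[-50])
  expect_error(compute_ifis(timestamp_series(0.5)), "at least 2")
})

test_that("identical IFIs are reported as unimodal", {
  fit <- fit_bimodal(rep(0.0122, 20))
  expect_equal(fit$fraction, c(1, 0))
  expect_true(is.na(fit$rate_fps[2]))
  # centres closer than twice the quantization collapse to unimodal too
  x <- rep(c(0.01, 0.010001), 10)
  fit2 <- fit_bimodal(x, quantization = 1e-3)
  expect_equal(fit2$fraction, c(1, 0))
})

test_that("a hand-built mixture splits at the exhaustive optimum", {
  x <- c(rep(0.010, 6), rep(0.020, 4))
  fit <- fit_bimodal(x)
  expect_equal(fit$rate_fps, c(100, 50))
  expect_equal(fit$fraction, c(0.6, 0.4))
  oracle <- oracle_2partition(x)
  expect_equal(sort(fit$ifi_s), sort(oracle$centres))
  expect_equal(sort(fit$fraction), sort(oracle$fractions))
  # permutation invariance
  set.seed(2)
  expect_equal(fit_bimodal(sample(x)), fit)
  expect_error(fit_bimodal(rep(0.01, 5)), "at least 10")
})

test_that("the generator's bimodal mixture is recovered at trial scale", {
  ts <- generate_true_frame_times(timing_preset("telemed82"), 218, seed = 11)
  ifis <- compute_ifis(ts)
  fit <- fit_bimodal(ifis, quantization = 1e-7)
  n <- nrow(ifis)
  expect_lt(abs(fit$fraction[1] - 0.9272), 0.006)
  expect_lt(abs(fit$rate_fps[1] - 83.5), 0.5)
  expect_lt(abs(fit$rate_fps[2] - 62.5), 0.5)
  expect_gt(n, 17000)
})

test_that("over-long intervals are flagged with the right missing count", {
  expect_identical(nrow(detect_dropped_frames(rep(0.025, 50), 0.025)), 0L)
  # intervals of 0.025 s with 0.05 s gaps: one frame missing per gap
  x <- rep(0.025, 30)
  x[c(5, 18)] <- 0.05
  d <- detect_dropped_frames(x, 0.025)
  expect_equal(d$transition_index, c(4L, 17L))
  expect_equal(d$n_missing, c(1, 1))
  # a triple-length gap means two frames missing
  d2 <- detect_dropped_frames(c(rep(0.01, 10), 0.03), 0.01)
  expect_equal(d2$n_missing, 2)
})

test_that("variability classification separates wobble from drift", {
  set.seed(4)
  jitter <- 1 / 82 + rnorm(1000, 0, 2e-4)
  expect_identical(classify_variability(jitter, 82)$variability_class,
                   "non-cumulative")
  expect_identical(classify_variability(rep(1 / 82, 100), 82)$variability_class,
                   "non-cumulative")
  # the bimodal mixture has mean IFI != 1/82 by construction, so the error
  # accumulates: mean = w/83.5 + (1-w)/62.5
  ts <- generate_true_frame_times(timing_preset("telemed82"), 60, seed = 5)
  cls <- classify_variability(compute_ifis(ts), 82)
  expect_identical(cls$variability_class, "cumulative")
  mixture_mean <- 0.9272 / 83.5 + (1 - 0.9272) / 62.5
  expect_lt(abs(cls$mean_ifi_s - mixture_mean), 3e-4)
  # dropped-frame gaps are split back before testing, so drops alone do not
  # masquerade as drift
  x <- rep(1 / 82, 400)
  x[c(50, 200)] <- 2 / 82
  expect_identical(classify_variability(x, 82)$variability_class,
                   "non-cumulative")
})

test_that("the IFI report assembles consistent diagnostics", {
  const <- timestamp_series(seq(0, 2, by = 1 / 82))
  rep1 <- summarize_ifis(const, 82)
  expect_equal(rep1$mean_rate, 82)
  expect_equal(rep1$sd_rate, 0)
  expect_identical(glance(rep1)$variability_class, "non-cumulative")

  # alternating 10/20 ms: mean of instantaneous rates is (100 + 50) / 2
  t2 <- cumsum(c(0, rep(c(0.01, 0.02), 20)))
  rep2 <- summarize_ifis(timestamp_series(t2), 75)
  expect_equal(rep2$mean_rate, 75)
  expect_equal(rep2$sd_rate, sd(rep(c(100, 50), 20)))
  expect_equal(tidy(rep2)$rate_fps, c(100, 50))
  expect_equal(tidy(rep2)$fraction, c(0.5, 0.5))

  ts <- generate_true_frame_times(timing_preset("telemed82"), 30, seed = 6)
  g <- glance(summarize_ifis(ts, 82))
  expect_lt(abs(g$dominant_rate - 83.5), 0.5)
  expect_lt(abs(g$dominant_fraction - 0.9272), 0.03)
  expect_identical(g$n_dropped_frames, 0)
  expect_identical(g$variability_class, "cumulative")
})

test_that("frame rate scales inversely with the receive-element count", {
  expect_equal(element_count_rate_model(64, 150.7, 64), 150.7)
  r <- element_count_rate_model(64, 150.7, c(96, 128, 256))
  expect_equal(r[2], 150.7 / 2)
  expect_equal(element_count_rate_model(64, 150.7, 128) * 2,
               element_count_rate_model(64, 150.7, 64))
  expect_equal(timing_resolution(40e6), 25e-9)
})

test_that("hardware/software comparison counts drops and ranks variance", {
  m <- timing_model(100, quantization = 0)
  ts <- generate_true_frame_times(m, 10, seed = 7)
  hw <- hardware_timestamps(ts, 25e-6)

  same <- compare_hw_sw(hw, hw)
  expect_identical(same$n_dropped, 0L)
  expect_equal(same$var_ifi_hw, same$var_ifi_sw)

  m2 <- timing_model(100, drop_prob = 0.05, quantization = 0)
  deg <- degrade_to_software_timestamps(ts, m2, seed = 8)
  cmp <- compare_hw_sw(hw, deg$timestamps)
  expect_identical(cmp$n_dropped, length(deg$dropped_indices))
  expect_identical(sort(cmp$dropped_hw_indices), sort(deg$dropped_indices))

  m3 <- timing_model(100, jitter_sd = 5e-4, quantization = 0)
  jit <- degrade_to_software_timestamps(ts, m3, seed = 9)
  cmp3 <- compare_hw_sw(hw, jit$timestamps)
  expect_identical(cmp3$n_dropped, 0L)
  expect_gt(cmp3$var_ifi_sw, cmp3$var_ifi_hw)
  expect_true(cmp3$hw_constant)
  g <- glance(cmp3)
  expect_identical(g$n_dropped, 0L)
})

test_that("cumulating IFIs and differencing them is the identity", {
  set.seed(10)
  for (i in 1:5) {
    ifis <- runif(100, 0.008, 0.02)
    t <- cumsum(c(0, ifis))
    expect_equal(compute_ifis(timestamp_series(t))$ifi_s, ifis)
  }
})

test_that("single-frame drops are recovered perfectly under small jitter", {
  # 20-seed version; the acceptance suite runs the full 100 seeds
  m <- timing_model(82, c(82, 82), 1, jitter_sd = 0.08 / 82, quantization = 0)
  ts <- generate_true_frame_times(m, 6, seed = 1)
  n <- nrow(ts)
  for (s in 1:20) {
    set.seed(s)
    drops <- sort(sample(seq(2L, n - 3L), 5))
    drops <- drops[c(TRUE, diff(drops) > 1)]  # keep them single
    deg <- degrade_to_software_timestamps(ts, m, seed = s, drop_indices = drops)
    det <- detect_dropped_frames(compute_ifis(deg$timestamps), 1 / 82)
    # perfect precision and recall: one flagged gap per dropped frame
    expect_identical(nrow(det), length(drops))
    expect_true(all(det$n_missing == 1))
    # each flagged gap sits exactly where the dropped frame was removed
    expect_identical(det$transition_index + 1L,
                     drops - (seq_along(drops) - 1L))
  }
})
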