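test_that("a degenerate mixture yields perfectly constant frame times", {
  m <- timing_model(82, c(82, 82), mode_weight = 1, quantization = 0)
  ts <- generate_true_frame_times(m, duration = 1, seed = 1)
  ifis <- compute_ifis(ts)$ifi_s
  expect_equal(ifis, rep(1 / 82, length(ifis)))
  expect_equal(ts$timestamp_s[1], 0)
  expect_true(all(diff(ts$timestamp_s) > 0))
  expect_lte(max(ts$timestamp_s), 1)
})

test_that("the dominant-mode fraction is recovered at trial scale", {
  ts <- generate_true_frame_times(timing_preset("telemed82"), 217, seed = 42)
  ifis <- compute_ifis(ts)$ifi_s
  n <- length(ifis)
  frac <- mean(abs(ifis - 1 / 83.5) < abs(ifis - 1 / 62.5))
  w <- 0.9272
  expect_lt(abs(frac - w), 3 * sqrt(w * (1 - w) / n))
})

test_that("the mixture mean IFI matches its closed form", {
  # oracle: direct average of the two intervals at equal weight
  m <- timing_model(75, c(100, 50), mode_weight = 0.5, quantization = 0)
  ts <- generate_true_frame_times(m, duration = 15000, seed = 9)
  ifis <- compute_ifis(ts)$ifi_s
  expected <- 0.5 * (1 / 100) + 0.5 * (1 / 50)
  ifi_sd <- 0.5 * (1 / 50 - 1 / 100)
  expect_gt(length(ifis), 9e5)
  expect_lt(abs(mean(ifis) - expected), 3 * ifi_sd / sqrt(length(ifis)))
})

test_that("the mode fraction concentrates at its binomial rate across seeds", {
  w <- 0.8562
  m <- timing_model(42, c(41.5, 36), w, quantization = 0)
  ok <- purrr::map_lgl(1:100, function(s) {
    ts <- generate_true_frame_times(m, 25, seed = s)  # ~1000 intervals
    ifis <- diff(ts$timestamp_s)
    n <- length(ifis)
    frac <- mean(abs(ifis - 1 / 41.5) < abs(ifis - 1 / 36))
    abs(frac - w) <= 4 * sqrt(w * (1 - w) / n)
  })
  expect_gte(sum(ok), 99)
})

test_that("invalid generator arguments are rejected", {
  expect_error(generate_true_frame_times(timing_preset("telemed82"), 0, 1))
  expect_error(generate_true_frame_times(timing_preset("telemed82"), -5, 1))
  expect_error(timing_model(82, mode_weight = 1.2))
  expect_error(timing_model(82, drop_prob = 1))
  expect_error(twitch_schedule(onsets = c(5, 5)))
})

test_that("software degradation is the identity when nothing degrades", {
  ts <- generate_true_frame_times(timing_preset("telemed82"), 3, seed = 2)
  out <- degrade_to_software_timestamps(ts, timing_preset("telemed82"), seed = 3)
  expect_equal(out$timestamps$timestamp_s, ts$timestamp_s)
  expect_length(out$dropped_indices, 0)
  expect_equal(out$clamp_count, 0L)
})

test_that("a forced drop telescopes two true intervals into one", {
  m <- timing_model(50, quantization = 0)
  ts <- generate_true_frame_times(m, 2, seed = 4)
  k <- 10L
  out <- degrade_to_software_timestamps(ts, m, seed = 5, drop_indices = k)
  true_ifis <- diff(ts$timestamp_s)
  sw_ifis <- diff(out$timestamps$timestamp_s)
  expect_equal(sw_ifis[k], true_ifis[k] + true_ifis[k + 1])
  expect_equal(out$dropped_indices, k)
})

test_that("random drop counts follow the binomial model", {
  m <- timing_model(100, drop_prob = 0.1, quantization = 0)
  ts <- generate_true_frame_times(m, 100, seed = 6)  # 1e4 frames
  n <- nrow(ts)
  out <- degrade_to_software_timestamps(ts, m, seed = 7)
  expect_lt(abs(length(out$dropped_indices) - 0.1 * n),
            3 * sqrt(n * 0.1 * 0.9))
})

test_that("software + dropped always partition the true frames", {
  m <- timing_model(80, jitter_sd = 2e-4, drop_prob = 0.08, quantization = 0)
  ts <- generate_true_frame_times(m, 10, seed = 1)
  for (s in 1:20) {
    out <- degrade_to_software_timestamps(ts, m, seed = s)
    expect_identical(nrow(out$timestamps) + length(out$dropped_indices), nrow(ts))
  }
})

test_that("hardware timestamps quantize and nothing more", {
  ts <- generate_true_frame_times(timing_preset("telemed82"), 2, seed = 8)
  expect_equal(hardware_timestamps(ts, 0)$timestamp_s, ts$timestamp_s)
  q <- 25e-6
  hw <- hardware_timestamps(ts, q)
  expect_lte(max(abs(hw$timestamp_s - ts$timestamp_s)), q / 2)
  # constant-IFI input: residual IFI variance below the measurement accuracy
  const <- timestamp_series(seq(0, 1, by = 1 / 82))
  hw2 <- hardware_timestamps(const, q)
  expect_lte(var(diff(hw2$timestamp_s)), q^2)
  expect_identical(nrow(hw), nrow(ts))
})

test_that("a motionless schedule produces zero ground truth and pure-noise frames", {
  ts <- timestamp_series(seq(0, 0.5, by = 0.02))
  sch <- twitch_schedule(onsets = 0.2, peak_displacement = c(0, 0),
                         region_centre = c(32, 32), region_sd = 10)
  sp <- generate_speckle_sequence(ts, sch, image_size = c(64, 64),
                                  noise_sd = 0, seed = 3)
  expect_true(all(sp$ground_truth$centre_dx == 0))
  expect_true(all(sp$ground_truth$centre_dy == 0))
  expect_identical(sp$frames[[1]], sp$frames[[10]])
})

test_that("the warp at the profile peak matches its analytic form", {
  # frame exactly at onset + latency + rise_time, where the profile is 1
  sch <- twitch_schedule(onsets = 0.2, duration = 0.07, rise_time = 0.01,
                         latency = 0.01, region_centre = c(32, 32),
                         region_sd = 10, peak_displacement = c(3, 0))
  ts <- timestamp_series(c(0, 0.1, 0.22, 0.4))
  sp <- generate_speckle_sequence(ts, sch, image_size = c(64, 64),
                                  noise_sd = 0, seed = 5)
  expect_equal(twitch_profile(0.22, sch), 1)
  # oracle: evaluate the warp formula directly on the resting frame
  base <- sp$frames[[1]]
  X <- matrix(rep(0:63, each = 64), 64, 64)
  Y <- matrix(rep(0:63, times = 64), 64, 64)
  W <- exp(-((X - 32)^2 + (Y - 32)^2) / (2 * 10^2))
  warped <- matrix(usifi:::bilinear_sample(base, X - 3 * W, Y), 64, 64)
  # the oracle warps the already-8-bit frame, so allow one quantization level
  expect_lte(max(abs(sp$frames[[3]] - usifi:::quantize_8bit(warped))), 2 / 255)
  # at the centre the warp is an exact integer 3 px shift: bit-exact check
  expect_identical(sp$frames[[3]][33, 33], sp$frames[[1]][33, 30])
  # at the region centre the warp is the full 3 px
  k <- which(sp$ground_truth$transition_index == 1)
  expect_equal(sp$ground_truth$centre_dx[k],
               3 * (twitch_profile(0.22, sch) - twitch_profile(0.1, sch)))
})

test_that("the default schedule holds 8 stimuli over 40 s and truncation warns", {
  sch <- twitch_schedule()
  expect_identical(sch$onsets, seq(5, 40, by = 5))
  ts <- generate_true_frame_times(timing_model(82, quantization = 0), 40, seed = 1)
  expect_warning(
    sp <- generate_speckle_sequence(ts, sch, image_size = c(64, 64),
                                    noise_sd = 0, seed = 1),
    "truncat"
  )
  # movement episodes visible in ground truth: all but the truncated final one
  moving <- abs(sp$ground_truth$centre_dx) > 0
  episodes <- sum(diff(c(FALSE, moving)) == 1)
  expect_gte(episodes, 7)
  expect_true(sp$truncated)
})

test_that("EMG noise floor, sample count and M-wave onset are as modelled", {
  m <- emg_model(noise_sd = 0.05)
  e <- generate_emg(numeric(0), m, duration = 10, seed = 2)
  n <- nrow(e)
  expect_identical(n, 20000L)
  se <- 0.05 / sqrt(2 * (n - 1))  # SE of a sample SD of normal data
  expect_lt(abs(sd(e$emg_mV) - 0.05), 3 * se)

  e40 <- generate_emg(numeric(0), emg_model(), duration = 40, seed = 1)
  expect_identical(nrow(e40), 80000L)

  # single stimulus, no noise: first half-amplitude crossing after the
  # artifact matches direct evaluation of the damped sinusoid
  m0 <- emg_model(noise_sd = 0)
  e1 <- generate_emg(5, m0, duration = 6, seed = 1)
  after <- e1$time_s > 5 + 2 / m0$fs  # skip the biphasic artifact samples
  t_cross <- e1$time_s[after][which(e1$emg_mV[after] >= m0$mwave_amplitude / 2)[1]]
  tau <- e1$time_s - 5 - m0$mwave_latency
  oracle <- ifelse(tau >= 0,
                   m0$mwave_amplitude * sin(2 * pi * m0$mwave_freq * tau) *
                     exp(-m0$mwave_decay * tau), 0)
  t_oracle <- e1$time_s[after][which(oracle[after] >= m0$mwave_amplitude / 2)[1]]
  expect_equal(t_cross, t_oracle)
  expect_lt(t_cross - (5 + m0$mwave_latency), 0.002)
})
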