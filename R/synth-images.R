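#' Generate a synthetic speckle image sequence with known twitch motion
#'
#' Builds a static speckle texture (low-pass-filtered white noise with
#' correlation length about `grain` pixels), then renders one 8-bit frame per
#' timestamp. During a twitch the texture is warped by a spatially
#' Gaussian-windowed displacement field: the pixel at `(x, y)` moves by
#' `peak_displacement * exp(-r^2 / (2 region_sd^2)) * p(t)` where `r` is its
#' distance to `region_centre` and `p(t)` is the temporal profile of
#' [twitch_schedule()] (raised-cosine rise, raised-cosine relaxation,
#' starting `latency` seconds after the stimulus onset). Independent
#' Gaussian pixel noise of SD `noise_sd` is added to every frame before
#' 8-bit quantization.
#'
#' The per-transition ground truth reports the displacement step at the
#' region centre (where the Gaussian window equals 1), i.e. the motion a
#' perfect tracker should recover between consecutive frames.
#'
#' @param frame_times A `timestamp_series` giving the acquisition time of
#'   every frame.
#' @param schedule A [twitch_schedule()].
#' @param image_size `c(rows, cols)` in pixels, at least 64 each.
#' @param grain Speckle correlation length in pixels (>= 1).
#' @param noise_sd Per-frame additive intensity noise SD (image range is
#'   `[0, 1]`).
#' @param seed Integer seed.
#' @return A list of class `speckle_sequence`: `frames` (list of numeric
#'   matrices in `[0, 1]`, 8-bit quantized), `times` (numeric seconds),
#'   `ground_truth` (tibble `transition_index`, `centre_dx`, `centre_dy`,
#'   `mean_abs_displacement`), `image_size`, `truncated` (TRUE if a twitch
#'   extended past the last frame).
#' @export
#' @examples
#' ts <- generate_true_frame_times(timing_model(50, quantization = 0), 1, seed = 1)
#' seq <- generate_speckle_sequence(ts, twitch_schedule(onsets = 0.4),
#'   image_size = c(64, 64), seed = 1)
#' length(seq$frames)
generate_speckle_sequence <- function(frame_times, schedule,
                                      image_size = c(128, 128),
                                      grain = 3,
                                      noise_sd = 0.02,
                                      seed = 1) {
  assert_timestamp_series(frame_times)
  stopifnot(inherits(schedule, "twitch_schedule"))
  if (length(image_size) != 2L || any(image_size < 64)) {
    abort("`image_size` must be c(rows, cols) with both >= 64.")
  }
  if (!is_scalar_number(grain) || grain < 1) abort("`grain` must be >= 1 pixel.")
  nr <- as.integer(image_size[1]); nc <- as.integer(image_size[2])
  times <- frame_times$timestamp_s
  n <- length(times)
  if (n < 1L) abort("`frame_times` is empty.")

  old <- .Random.seed_guard(derive_seed(seed, "speckle"))
  on.exit(old(), add = TRUE)

  base <- gaussian_smooth_fft(matrix(rnorm(nr * nc), nr, nc), grain / 2)
  base <- 0.5 + 0.16 * (base - mean(base)) / sd(base)

  # spatial Gaussian window and coordinate grids (0-based)
  X <- matrix(rep(0:(nc - 1), each = nr), nr, nc)
  Y <- matrix(rep(0:(nr - 1), times = nc), nr, nc)
  cx <- schedule$region_centre[1]; cy <- schedule$region_centre[2]
  W <- exp(-((X - cx)^2 + (Y - cy)^2) / (2 * schedule$region_sd^2))

  p <- twitch_profile(times, schedule)
  truncated <- any(schedule$onsets + schedule$latency + schedule$duration >
    times[n] & schedule$onsets <= times[n])
  if (truncated) {
    warn("a twitch window extends past the last frame and is truncated.")
  }

  px <- schedule$peak_displacement[1]
  py <- schedule$peak_displacement[2]
  frames <- vector("list", n)
  for (k in seq_len(n)) {
    if (p[k] == 0) {
      f <- base
    } else {
      f <- matrix(
        bilinear_sample(base, X - p[k] * px * W, Y - p[k] * py * W),
        nr, nc
      )
    }
    if (noise_sd > 0) f <- f + matrix(rnorm(nr * nc, sd = noise_sd), nr, nc)
    frames[[k]] <- quantize_8bit(f)
  }

  dp <- diff(p)
  gt <- tibble(
    transition_index = seq_len(max(n - 1L, 0L)) - 1L,
    centre_dx = px * dp,
    centre_dy = py * dp,
    mean_abs_displacement = sqrt(px^2 + py^2) * abs(dp) * mean(W)
  )

  structure(
    list(
      frames = frames, times = times, ground_truth = gt,
      image_size = c(nr, nc), truncated = truncated
    ),
    class = "speckle_sequence"
  )
}

#' Temporal twitch profile
#'
#' Normalized displacement amplitude at times `t` for a [twitch_schedule()]:
#' 0 outside twitches; within a twitch starting at `onset + latency`, a
#' raised-cosine rise from 0 to 1 over `rise_time`, then a raised-cosine
#' relaxation back to 0 over `duration - rise_time`. Contributions from
#' different stimuli are summed (with the default 5 s spacing they never
#' overlap).
#'
#' @param t Numeric vector of times (s).
#' @param schedule A [twitch_schedule()].
#' @return Numeric vector of amplitudes in `[0, 1]`.
#' @export
twitch_profile <- function(t, schedule) {
  out <- numeric(length(t))
  tr <- schedule$rise_time
  td <- schedule$duration - schedule$rise_time
  for (onset in schedule$onsets) {
    tau <- t - onset - schedule$latency
    rise <- tau >= 0 & tau < tr
    fall <- tau >= tr & tau <= schedule$duration
    out[rise] <- out[rise] + 0.5 * (1 - cos(pi * tau[rise] / tr))
    out[fall] <- out[fall] + 0.5 * (1 + cos(pi * (tau[fall] - tr) / td))
  }
  pmin(out, 1)
}

#' @export
print.speckle_sequence <- function(x, ...) {
  cat(sprintf(
    "<speckle_sequence> %d frames of %dx%d px, %.3f s, %d transitions\n",
    length(x$frames), x$image_size[1], x$image_size[2],
    if (length(x$times)) max(x$times) else 0, nrow(x$ground_truth)
  ))
  invisible(x)
}
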