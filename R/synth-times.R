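#' Build a timestamp series tibble
#'
#' The common container for per-frame acquisition times: a tibble with
#' columns `frame_index` (0-based integer), `timestamp_s` (seconds) and
#' `source` (one of `"metadata"`, `"software"`, `"hardware"`, `"assumed"`),
#' carrying the timestamp resolution as attribute `quantization`.
#'
#' @param timestamp_s Non-decreasing numeric times in seconds.
#' @param source Source tag for every row.
#' @param quantization Timestamp resolution in seconds (0 = continuous).
#' @param frame_index Optional 0-based frame indices; defaults to
#'   `0:(n-1)`.
#' @return A `timestamp_series` tibble.
#' @export
timestamp_series <- function(timestamp_s,
                             source = c("metadata", "software", "hardware", "assumed"),
                             quantization = 0,
                             frame_index = NULL) {
  source <- match.arg(source)
  if (is.null(frame_index)) frame_index <- seq_along(timestamp_s) - 1L
  out <- tibble(
    frame_index = as.integer(frame_index),
    timestamp_s = as.numeric(timestamp_s),
    source = source
  )
  attr(out, "quantization") <- quantization
  class(out) <- c("timestamp_series", class(out))
  out
}

ts_quantization <- function(series) {
  attr(series, "quantization") %||% 0
}

assert_timestamp_series <- function(series, strict = TRUE) {
  if (!is.data.frame(series) || !all(c("frame_index", "timestamp_s") %in% names(series))) {
    abort("expected a timestamp series with columns `frame_index` and `timestamp_s`.")
  }
  d <- diff(series$timestamp_s)
  if (strict && length(d) && any(d <= 0)) {
    abort("timestamps must be strictly increasing.")
  }
  invisible(series)
}

#' Generate true (metadata) frame times from a timing model
#'
#' Draws inter-frame intervals i.i.d. from the model's two-point mixture
#' (the dominant interval `1/mode_rates[1]` with probability `mode_weight`,
#' the minor interval otherwise), accumulates them from 0 until `duration`
#' and quantizes the running times to the model's metadata resolution.
#' This is the ground-truth transmission clock of the simulation.
#'
#' @param model A [timing_model()].
#' @param duration Trial length in seconds (> 0).
#' @param seed Integer seed; the draw is fully reproducible.
#' @return A `timestamp_series` tibble with `source = "metadata"`; the drawn
#'   IFIs (s) are attached as attribute `ifi_s`.
#' @export
#' @examples
#' ts <- generate_true_frame_times(timing_preset("telemed82"), duration = 2, seed = 1)
#' head(ts)
generate_true_frame_times <- function(model, duration, seed) {
  stopifnot(inherits(model, "timing_model"))
  if (!is_scalar_number(duration) || duration <= 0) {
    abort("`duration` must be a positive number of seconds.")
  }
  ifi_modes <- 1 / model$mode_rates
  n_max <- ceiling(duration / min(ifi_modes)) + 1L
  withr_seed <- derive_seed(seed, "true-frame-times")
  old <- .Random.seed_guard(withr_seed)
  on.exit(old(), add = TRUE)
  pick <- runif(n_max) < model$mode_weight
  ifis <- ifelse(pick, ifi_modes[1], ifi_modes[2])
  times <- quantize(c(0, cumsum(ifis)), model$quantization)
  times <- times[times <= duration]
  out <- timestamp_series(times, "metadata", quantization = model$quantization)
  attr(out, "ifi_s") <- diff(times)
  out
}

# Set the RNG seed and return a restorer closure.
.Random.seed_guard <- function(seed) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }
}

#' Degrade true frame times into a software-timestamp record
#'
#' Emulates what acquisition software records: some frames are dropped
#' (each independently with probability `model$drop_prob`, or exactly the
#' frames named in `drop_indices`), zero-mean Gaussian read-out jitter of
#' SD `model$jitter_sd` is added, times are quantized to the software clock
#' resolution, and monotonicity is enforced by clamping any timestamp that
#' would run backwards to just after its predecessor.
#'
#' @param true_times A `timestamp_series` of true frame times.
#' @param model A [timing_model()] supplying `drop_prob`, `jitter_sd` and
#'   `software_quantization`.
#' @param seed Integer seed.
#' @param drop_indices Optional explicit 0-based frame indices to drop
#'   (overrides random dropping; useful for constructing known gaps).
#' @return A list with `timestamps` (a `timestamp_series`, `source =
#'   "software"`, re-indexed 0..m-1), `dropped_indices` (0-based indices into
#'   the true series) and `clamp_count` (number of monotonicity clamps).
#' @export
degrade_to_software_timestamps <- function(true_times, model, seed,
                                           drop_indices = NULL) {
  assert_timestamp_series(true_times)
  stopifnot(inherits(model, "timing_model"))
  n <- nrow(true_times)
  old <- .Random.seed_guard(derive_seed(seed, "software-timestamps"))
  on.exit(old(), add = TRUE)
  if (is.null(drop_indices)) {
    dropped <- which(runif(n) < model$drop_prob) - 1L
  } else {
    dropped <- sort(unique(as.integer(drop_indices)))
    if (length(dropped) && (min(dropped) < 0 || max(dropped) >= n)) {
      abort("`drop_indices` out of range for the true series.")
    }
  }
  keep <- setdiff(seq_len(n) - 1L, dropped)
  t_kept <- true_times$timestamp_s[keep + 1L]
  if (model$jitter_sd > 0) {
    t_kept <- t_kept + rnorm(length(t_kept), sd = model$jitter_sd)
  }
  t_kept <- quantize(t_kept, model$software_quantization)
  # enforce strict monotonicity: clamp backwards-running stamps
  clamp_count <- 0L
  eps <- max(model$software_quantization, 1e-9)
  if (length(t_kept) > 1L) {
    for (i in seq.int(2L, length(t_kept))) {
      if (t_kept[i] <= t_kept[i - 1L]) {
        t_kept[i] <- t_kept[i - 1L] + eps
        clamp_count <- clamp_count + 1L
      }
    }
  }
  if (clamp_count > 0L) {
    inform(sprintf("degrade_to_software_timestamps: clamped %d timestamp(s) to keep monotonic order.", clamp_count))
  }
  list(
    timestamps = timestamp_series(t_kept, "software",
      quantization = model$software_quantization
    ),
    dropped_indices = dropped,
    clamp_count = clamp_count
  )
}

#' Hardware-trigger timestamps
#'
#' The hardware timing signal marks every transmitted frame; it never drops
#' frames and carries no software jitter. Its only imperfection is the
#' resolution of the instrument that records it, so the true times are simply
#' quantized to that resolution (default 25 microseconds, the measurement
#' accuracy of a 400 kS/s acquisition card after pulse stretching).
#'
#' @param true_times A `timestamp_series` of true frame times.
#' @param quantization Recording resolution in seconds; 0 returns the input
#'   times unchanged.
#' @return A `timestamp_series` with `source = "hardware"`.
#' @export
hardware_timestamps <- function(true_times, quantization = 25e-6) {
  assert_timestamp_series(true_times)
  stopifnot(is_scalar_number(quantization), quantization >= 0)
  timestamp_series(
    quantize(true_times$timestamp_s, quantization),
    "hardware",
    quantization = quantization
  )
}
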