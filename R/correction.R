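#' Frame times under a constant-rate assumption
#'
#' The naive clock: frame `k` (0-based) is assumed to occur at
#' `k / nominal_rate`.
#'
#' @param n_frames Number of frames.
#' @param nominal_rate Assumed constant frame rate (frames/s).
#' @return A `timestamp_series` with `source = "assumed"`.
#' @export
#' @examples
#' frame_times_assumed(3, 10)
frame_times_assumed <- function(n_frames, nominal_rate) {
  stopifnot(n_frames >= 1, is_scalar_number(nominal_rate), nominal_rate > 0)
  timestamp_series((seq_len(n_frames) - 1) / nominal_rate, "assumed")
}

#' Timing drift between assumed and actual frame times
#'
#' `drift[k] = actual[k] - assumed[k]`, which equals the cumulative sum of
#' the per-frame IFI errors up to frame `k`: the synchronization error that
#' accumulates when a constant frame rate is assumed but the true intervals
#' differ.
#'
#' @param assumed,actual `timestamp_series` tibbles (or numeric time
#'   vectors) of equal length.
#' @return A tibble `frame_index`, `drift_s`.
#' @export
timing_drift <- function(assumed, actual) {
  ta <- if (is.data.frame(assumed)) assumed$timestamp_s else as.numeric(assumed)
  tb <- if (is.data.frame(actual)) actual$timestamp_s else as.numeric(actual)
  if (length(ta) != length(tb)) {
    abort("`assumed` and `actual` must have the same number of frames.")
  }
  tibble(frame_index = seq_along(ta) - 1L, drift_s = tb - ta)
}

#' Resample a twitch trace onto new times
#'
#' Linear interpolation of the MI scores at `target_times`. Queries outside
#' the support of the (non-missing) trace samples are returned as `NA`,
#' never extrapolated; `NA` scores in the input are excluded from the
#' interpolation support.
#'
#' @param trace A `twitch_trace` tibble (strictly increasing `time_s`).
#' @param target_times Numeric times (s) to evaluate at.
#' @return A tibble `time_s`, `mi_bits`.
#' @export
resample_trace <- function(trace, target_times) {
  stopifnot(all(c("time_s", "mi_bits") %in% names(trace)))
  ok <- !is.na(trace$mi_bits)
  t <- trace$time_s[ok]
  if (length(t) && any(diff(t) <= 0)) abort("trace times must be strictly increasing.")
  if (sum(ok) < 2L) {
    return(tibble(time_s = as.numeric(target_times),
                  mi_bits = rep(NA_real_, length(target_times))))
  }
  v <- approx(t, trace$mi_bits[ok], xout = target_times, method = "linear",
              rule = 1)$y
  tibble(time_s = as.numeric(target_times), mi_bits = v)
}

#' Estimate a constant trigger offset between stimuli and trace
#'
#' Scans a lag grid from `-search_window` to `+search_window` in steps of
#' `step`, scoring each lag by the summed interpolated trace value at
#' `onsets + lag`; the best-scoring lag is the constant delay between the
#' stimulus clock and the imaging clock. Ties are broken toward the
#' smallest `|lag|`, and between `-lag` and `+lag` toward the negative lag.
#'
#' @param trace A `twitch_trace` tibble.
#' @param onsets Stimulus onset times (s), at least 2.
#' @param search_window Half-width of the lag grid (s).
#' @param step Grid spacing (s).
#' @return The offset in seconds (attribute `degenerate` is TRUE when the
#'   trace carried no usable contrast and 0 is returned).
#' @export
estimate_constant_offset <- function(trace, onsets, search_window = 0.5,
                                     step = 0.001) {
  if (length(onsets) < 2L) abort("need at least 2 stimulus onsets.")
  lags <- seq(-search_window, search_window, by = step)
  score <- vapply(lags, function(l) {
    v <- resample_trace(trace, onsets + l)$mi_bits
    if (all(is.na(v))) -Inf else sum(v, na.rm = TRUE)
  }, numeric(1))
  if (!any(is.finite(score)) || diff(range(score[is.finite(score)])) == 0) {
    warn("trace is flat over the whole lag grid; offset is degenerate, returning 0.")
    return(structure(0, degenerate = TRUE))
  }
  smax <- max(score[is.finite(score)])
  # scores within numerical noise of the maximum count as tied
  best <- which(score >= smax - 1e-12 * max(1, abs(smax)))
  # ties: smallest |lag|, then the negative lag first
  best <- best[order(abs(lags[best]), lags[best])][1]
  structure(lags[best], degenerate = FALSE)
}

#' Stimulus-to-twitch latencies
#'
#' Matches each stimulus to a detected twitch event and reports
#' `latency = event_time - onset` (positive = movement after the stimulus).
#' Matching modes:
#' \describe{
#'   \item{`"causal_nearest"` (default)}{first event in
#'     `(onset, onset + max_latency]`; if none, the nearest event within
#'     `max_latency` of the onset on either side — this is what exposes the
#'     physiologically impossible negative latencies produced by an
#'     uncorrected, drifting frame clock.}
#'   \item{`"causal"`}{strictly causal matching only.}
#'   \item{`"nearest"`}{nearest event within `max_latency` either side.}
#' }
#' Each event can serve at most one stimulus (earlier stimuli claim first);
#' unmatched stimuli get `NA` latency.
#'
#' @param events Event tibble from [detect_events()].
#' @param onsets Stimulus onset times (s).
#' @param max_latency Longest permissible |latency| (s); default 2.5, half
#'   the default 5 s inter-stimulus interval, so a stimulus can never match
#'   its neighbour's twitch.
#' @param mode Matching mode, see above.
#' @return A tibble `stim_index` (0-based), `onset_s`, `event_time_s`,
#'   `latency_s`, `matched`.
#' @export
stimulus_latencies <- function(events, onsets, max_latency = 2.5,
                               mode = c("causal_nearest", "causal", "nearest")) {
  mode <- match.arg(mode)
  onsets <- as.numeric(onsets)
  et <- events$time_s
  used <- rep(FALSE, length(et))
  res <- purrr::map(seq_along(onsets), function(i) {
    onset <- onsets[i]
    cand_causal <- which(!used & et > onset & et <= onset + max_latency)
    cand_near <- which(!used & abs(et - onset) <= max_latency)
    j <- NA_integer_
    if (mode %in% c("causal_nearest", "causal") && length(cand_causal)) {
      j <- cand_causal[which.min(et[cand_causal])]
    } else if (mode %in% c("causal_nearest", "nearest") && length(cand_near)) {
      j <- cand_near[which.min(abs(et[cand_near] - onset))]
    }
    if (!is.na(j)) used[j] <<- TRUE
    tibble(
      stim_index = i - 1L,
      onset_s = onset,
      event_time_s = if (is.na(j)) NA_real_ else et[j],
      latency_s = if (is.na(j)) NA_real_ else et[j] - onset,
      matched = !is.na(j)
    )
  })
  dplyr::bind_rows(res)
}

#' Evaluate stimulus-to-twitch synchronization for one timing assumption
#'
#' Bundles the correction-side analysis: detects events in the trace,
#' matches them to the stimulus schedule, estimates the constant offset
#' between the two clocks, and (when the actual frame times are supplied)
#' the per-frame drift of the constant-rate assumption.
#'
#' @param trace A `twitch_trace` whose `time_s` reflect the timing
#'   assumption under evaluation.
#' @param onsets Stimulus onset times (s).
#' @param nominal_rate Stated frame rate (frames/s).
#' @param actual_times Optional `timestamp_series` of true frame times; when
#'   given, the drift of the constant-rate clock against it is reported.
#' @param max_latency,match_mode Passed to [stimulus_latencies()].
#' @param threshold_sds,min_separation Passed to [detect_events()].
#' @param offset_window,offset_step Passed to [estimate_constant_offset()].
#' @return An object of class `sync_result` with fields `latencies`,
#'   `events`, `constant_offset`, `drift`, `nominal_ifi`. `tidy()` returns
#'   the per-stimulus latencies, `glance()` a one-row summary.
#' @export
evaluate_sync <- function(trace, onsets, nominal_rate,
                          actual_times = NULL,
                          max_latency = 2.5,
                          match_mode = "causal_nearest",
                          threshold_sds = 4, min_separation = 1,
                          offset_window = 0.5, offset_step = 0.001) {
  events <- detect_events(trace, threshold_sds, min_separation)
  lat <- stimulus_latencies(events, onsets, max_latency, match_mode)
  offset <- tryCatch(
    estimate_constant_offset(trace, onsets, offset_window, offset_step),
    warning = function(w) structure(0, degenerate = TRUE)
  )
  drift <- NULL
  if (!is.null(actual_times)) {
    n <- if (is.data.frame(actual_times)) nrow(actual_times) else length(actual_times)
    drift <- timing_drift(frame_times_assumed(n, nominal_rate), actual_times)
  }
  structure(
    list(
      latencies = lat,
      events = events,
      constant_offset = as.numeric(offset),
      offset_degenerate = isTRUE(attr(offset, "degenerate")),
      drift = drift,
      nominal_ifi = 1 / nominal_rate,
      nominal_rate = nominal_rate
    ),
    class = "sync_result"
  )
}

#' @export
print.sync_result <- function(x, ...) {
  cat("<sync_result>\n")
  m <- x$latencies$matched
  cat(sprintf("  stimuli: %d, matched events: %d\n", length(m), sum(m)))
  if (any(m)) {
    l <- x$latencies$latency_s[m]
    cat(sprintf("  latencies: %.1f .. %.1f ms (%d negative)\n",
                1000 * min(l), 1000 * max(l), sum(l < 0)))
  }
  cat(sprintf("  constant offset: %.1f ms, nominal IFI %.2f ms\n",
              1000 * x$constant_offset, 1000 * x$nominal_ifi))
  if (!is.null(x$drift)) {
    cat(sprintf("  drift at last frame: %.1f ms\n",
                1000 * x$drift$drift_s[nrow(x$drift)]))
  }
  invisible(x)
}

#' Tidy a synchronization result
#'
#' @param x A `sync_result`.
#' @param ... Unused.
#' @return The per-stimulus latency tibble.
#' @export
tidy.sync_result <- function(x, ...) x$latencies

#' One-row summary of a synchronization result
#'
#' @param x A `sync_result`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.sync_result <- function(x, ...) {
  l <- x$latencies$latency_s[x$latencies$matched]
  tibble(
    n_stimuli = nrow(x$latencies),
    n_matched = sum(x$latencies$matched),
    n_negative = sum(l < 0),
    min_latency_s = if (length(l)) min(l) else NA_real_,
    max_latency_s = if (length(l)) max(l) else NA_real_,
    constant_offset_s = x$constant_offset,
    nominal_ifi_s = x$nominal_ifi,
    final_drift_s = if (is.null(x$drift)) NA_real_ else
      x$drift$drift_s[nrow(x$drift)]
  )
}
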