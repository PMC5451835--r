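#' Inter-frame intervals of a timestamp series
#'
#' First differences of the frame times: `ifi[i]` is the interval between
#' frames `i` and `i+1` (frame rate = 1/IFI).
#'
#' @param series A `timestamp_series` tibble (or numeric vector of times).
#' @return A tibble `transition_index` (0-based), `ifi_s` (seconds).
#' @export
#' @examples
#' compute_ifis(timestamp_series(c(0, 0.1, 0.2)))
compute_ifis <- function(series) {
  t <- if (is.data.frame(series)) series$timestamp_s else as.numeric(series)
  if (length(t) < 2L) abort("need at least 2 timestamps to form an IFI.")
  d <- diff(t)
  if (any(d < 0)) abort("timestamps must be non-decreasing.")
  tibble(transition_index = seq_along(d) - 1L, ifi_s = d)
}

ifi_vector <- function(ifis) {
  if (is.data.frame(ifis)) ifis$ifi_s else as.numeric(ifis)
}

#' Decompose an IFI distribution into two modes
#'
#' Two-class 1-D k-means (Lloyd, deterministically initialized at the
#' smallest and largest IFI) splits the intervals into a dominant and a
#' minor cluster; centres are reported both as intervals and as frame rates.
#' If the two centres differ by less than twice the timestamp quantization
#' the distribution is declared unimodal and the minor fraction is 0.
#'
#' @param ifis Numeric IFIs in seconds, or the tibble from [compute_ifis()].
#' @param quantization Timestamp resolution (s) used for the unimodality
#'   rule; default 0.
#' @return A tibble with rows `dominant`, `minor` and columns `mode`,
#'   `rate_fps`, `ifi_s`, `fraction` (fractions sum to 1). For a unimodal
#'   input the minor row has `NA` centres and fraction 0.
#' @export
#' @examples
#' fit_bimodal(c(rep(0.010, 6), rep(0.020, 4)))
fit_bimodal <- function(ifis, quantization = 0) {
  x <- ifi_vector(ifis)
  if (length(x) < 10L) abort("need at least 10 IFIs to fit a bimodal split.")
  unimodal <- tibble(
    mode = c("dominant", "minor"),
    rate_fps = c(1 / mean(x), NA_real_),
    ifi_s = c(mean(x), NA_real_),
    fraction = c(1, 0)
  )
  if (diff(range(x)) <= .Machine$double.eps * max(abs(x))) return(unimodal)
  km <- kmeans(x, centers = matrix(c(min(x), max(x))), algorithm = "Lloyd",
               iter.max = 200)
  centres <- as.numeric(km$centers)
  if (abs(diff(centres)) < 2 * quantization) return(unimodal)
  frac <- as.numeric(km$size) / length(x)
  dom <- which.max(frac)
  mnr <- setdiff(1:2, dom)
  tibble(
    mode = c("dominant", "minor"),
    rate_fps = 1 / centres[c(dom, mnr)],
    ifi_s = centres[c(dom, mnr)],
    fraction = frac[c(dom, mnr)]
  )
}

#' Flag dropped frames from over-long intervals
#'
#' An interval longer than 1.5 times the dominant IFI (halfway between one
#' and two frame periods) indicates at least one frame missing from the
#' record; the estimated number missing in each gap is
#' `round(ifi / dominant_ifi) - 1`.
#'
#' @param ifis Numeric IFIs (s) or the tibble from [compute_ifis()].
#' @param dominant_ifi Dominant-mode interval (s), e.g. from [fit_bimodal()].
#' @return A tibble `transition_index`, `ifi_s`, `n_missing` with one row
#'   per flagged gap (zero rows when no frames were dropped).
#' @export
detect_dropped_frames <- function(ifis, dominant_ifi) {
  stopifnot(is_scalar_number(dominant_ifi), dominant_ifi > 0)
  x <- ifi_vector(ifis)
  idx <- which(x > 1.5 * dominant_ifi)
  tibble(
    transition_index = idx - 1L,
    ifi_s = x[idx],
    n_missing = pmax(round(x[idx] / dominant_ifi) - 1, 1)
  )
}

#' Classify IFI variability as cumulative or non-cumulative
#'
#' Tests whether the mean IFI equals the nominal interval `1/nominal_rate`
#' (one-sample z test, normal approximation). Gaps caused by dropped frames
#' are first split back into their estimated constituent intervals so that
#' drops do not masquerade as drift. A rejected test means per-frame timing
#' errors accumulate ("cumulative"); otherwise deviations average out and a
#' constant-IFI assumption only wobbles, it does not drift
#' ("non-cumulative").
#'
#' @param ifis Numeric IFIs (s) or the tibble from [compute_ifis()].
#' @param nominal_rate Stated frame rate (frames/s).
#' @param alpha Test level; default 0.01.
#' @param dominant_ifi Dominant interval used for drop correction; estimated
#'   with [fit_bimodal()] when omitted.
#' @return A one-row tibble: `variability_class`, `mean_ifi_s`,
#'   `mean_deviation_s`, `z`, `p_value`, `n`.
#' @export
classify_variability <- function(ifis, nominal_rate, alpha = 0.01,
                                 dominant_ifi = NULL) {
  x <- ifi_vector(ifis)
  if (length(x) < 30L) abort("need at least 30 IFIs to classify variability.")
  stopifnot(is_scalar_number(nominal_rate), nominal_rate > 0)
  if (is.null(dominant_ifi)) {
    dominant_ifi <- fit_bimodal(x)$ifi_s[1]
  }
  drops <- detect_dropped_frames(x, dominant_ifi)
  if (nrow(drops)) {
    keep <- x[-(drops$transition_index + 1L)]
    pieces <- unlist(purrr::map2(drops$ifi_s, drops$n_missing,
                                 ~ rep(.x / (.y + 1), .y + 1)))
    x <- c(keep, pieces)
  }
  nominal_ifi <- 1 / nominal_rate
  n <- length(x)
  s <- sd(x)
  if (s == 0) {
    # perfectly regular record: any mean offset is deterministic drift
    z <- if (mean(x) == nominal_ifi) 0 else Inf
  } else {
    z <- (mean(x) - nominal_ifi) / (s / sqrt(n))
  }
  p <- 2 * pnorm(-abs(z))
  tibble(
    variability_class = if (p < alpha) "cumulative" else "non-cumulative",
    mean_ifi_s = mean(x),
    mean_deviation_s = mean(x) - nominal_ifi,
    z = z,
    p_value = p,
    n = n
  )
}

#' Full IFI diagnostic report for a timestamp series
#'
#' Assembles the interval diagnostics in one object: bimodal decomposition,
#' mean and SD of the instantaneous frame rate (computed over per-interval
#' rates 1/IFI), dropped-frame list and the cumulative/non-cumulative
#' classification against the stated nominal rate.
#'
#' @param series A `timestamp_series` tibble.
#' @param nominal_rate Frame rate stated on the device (frames/s).
#' @param alpha Level for the variability test.
#' @return An object of class `ifi_report`; see [tidy.ifi_report()],
#'   [glance.ifi_report()] and [autoplot.ifi_report()].
#' @export
#' @examples
#' ts <- generate_true_frame_times(timing_preset("telemed82"), 5, seed = 1)
#' summarize_ifis(ts, nominal_rate = 82)
summarize_ifis <- function(series, nominal_rate, alpha = 0.01) {
  assert_timestamp_series(series, strict = FALSE)
  ifis <- compute_ifis(series)
  x <- ifis$ifi_s
  q <- ts_quantization(series)
  modes <- if (length(x) >= 10L) {
    fit_bimodal(x, quantization = q)
  } else {
    tibble(mode = c("dominant", "minor"),
           rate_fps = c(1 / mean(x), NA_real_),
           ifi_s = c(mean(x), NA_real_),
           fraction = c(1, 0))
  }
  drops <- detect_dropped_frames(x, modes$ifi_s[1])
  variability <- if (length(x) >= 30L) {
    classify_variability(x, nominal_rate, alpha, dominant_ifi = modes$ifi_s[1])
  } else {
    tibble(variability_class = NA_character_, mean_ifi_s = mean(x),
           mean_deviation_s = mean(x) - 1 / nominal_rate,
           z = NA_real_, p_value = NA_real_, n = length(x))
  }
  rates <- 1 / x[x > 0]
  structure(
    list(
      modes = modes,
      mean_rate = mean(rates),
      sd_rate = if (length(rates) > 1) sd(rates) else 0,
      n_frames = nrow(series),
      dropped = drops,
      variability = variability,
      nominal_rate = nominal_rate,
      quantization = q,
      source = if ("source" %in% names(series)) series$source[1] else NA_character_,
      ifi_s = x
    ),
    class = "ifi_report"
  )
}

#' @export
print.ifi_report <- function(x, ...) {
  cat("<ifi_report>\n")
  cat(sprintf("  frames: %d (source: %s), nominal rate %.4g fps\n",
              x$n_frames, x$source, x$nominal_rate))
  cat(sprintf("  mean rate: %.2f fps (SD %.2f) over instantaneous 1/IFI\n",
              x$mean_rate, x$sd_rate))
  m <- x$modes
  if (m$fraction[2] > 0) {
    cat(sprintf("  bimodal: %.1f%% at %.2f fps, %.1f%% at %.2f fps\n",
                100 * m$fraction[1], m$rate_fps[1],
                100 * m$fraction[2], m$rate_fps[2]))
  } else {
    cat(sprintf("  unimodal at %.2f fps\n", m$rate_fps[1]))
  }
  cat(sprintf("  dropped-frame gaps: %d (%d frames missing)\n",
              nrow(x$dropped), sum(x$dropped$n_missing)))
  cat(sprintf("  variability: %s (mean IFI deviation %.3g s, p = %.3g)\n",
              x$variability$variability_class,
              x$variability$mean_deviation_s, x$variability$p_value))
  invisible(x)
}

#' Tidy an IFI report
#'
#' @param x An `ifi_report`.
#' @param ... Unused.
#' @return The per-mode tibble: `mode`, `rate_fps`, `ifi_s`, `fraction`.
#' @export
tidy.ifi_report <- function(x, ...) x$modes

#' One-row summary of an IFI report
#'
#' @param x An `ifi_report`.
#' @param ... Unused.
#' @return A one-row tibble with the headline diagnostics.
#' @export
glance.ifi_report <- function(x, ...) {
  tibble(
    n_frames = x$n_frames,
    nominal_rate = x$nominal_rate,
    mean_rate = x$mean_rate,
    sd_rate = x$sd_rate,
    dominant_rate = x$modes$rate_fps[1],
    dominant_fraction = x$modes$fraction[1],
    minor_rate = x$modes$rate_fps[2],
    n_dropped_gaps = nrow(x$dropped),
    n_dropped_frames = sum(x$dropped$n_missing),
    variability_class = x$variability$variability_class
  )
}

#' Predict frame rate from the receive-element count
#'
#' On array scanners the time to form a frame scales with the number of
#' receive elements, so the frame rate is inversely proportional to the
#' element count. Anchored at one measured configuration, the model
#' predicts `rate = anchor_rate * anchor_elements / query_elements`.
#'
#' @param anchor_elements,anchor_rate_fps The measured configuration.
#' @param query_elements Element counts to predict for (vectorized).
#' @return Predicted frame rates (fps).
#' @export
#' @examples
#' element_count_rate_model(64, 150.7, c(96, 128, 256))
element_count_rate_model <- function(anchor_elements, anchor_rate_fps,
                                     query_elements) {
  stopifnot(anchor_elements > 0, anchor_rate_fps > 0, all(query_elements > 0))
  anchor_rate_fps * anchor_elements / query_elements
}

#' Clock period from a clock frequency
#'
#' Converts a frequency in Hz to the duration of one cycle in seconds —
#' e.g. the pulse length of a hardware frame trigger driven by the scanner's
#' internal clock.
#'
#' @param frequency_hz Clock frequency (Hz).
#' @return Period in seconds.
#' @export
#' @examples
#' timing_resolution(40e6)  # 25 ns
timing_resolution <- function(frequency_hz) {
  stopifnot(all(frequency_hz > 0))
  1 / frequency_hz
}

#' Compare hardware and software timestamp records of one acquisition
#'
#' Matches every software frame to its nearest hardware frame in time;
#' hardware frames left unmatched are the dropped frames. Also contrasts
#' the IFI variance of the two records against the hardware recording
#' resolution.
#'
#' @param hw,sw `timestamp_series` objects from the same acquisition; the
#'   hardware record is assumed complete (no drops).
#' @return An object of class `hw_sw_comparison` with fields `n_hw`, `n_sw`,
#'   `n_dropped`, `dropped_hw_indices`, `var_ifi_hw`, `var_ifi_sw`,
#'   `hw_constant` (TRUE when the hardware IFI variance is below the squared
#'   recording resolution) and `verdict` strings; `glance()` returns the
#'   numbers as a one-row tibble.
#' @export
compare_hw_sw <- function(hw, sw) {
  assert_timestamp_series(hw)
  assert_timestamp_series(sw, strict = FALSE)
  th <- hw$timestamp_s
  tsw <- sw$timestamp_s
  nearest <- vapply(tsw, function(t) which.min(abs(th - t)), integer(1))
  matched <- unique(nearest)
  dropped <- setdiff(seq_along(th), matched) - 1L
  q_hw <- ts_quantization(hw)
  var_hw <- if (length(th) > 2) var(diff(th)) else 0
  var_sw <- if (length(tsw) > 2) var(diff(tsw)) else 0
  hw_constant <- var_hw <= max(q_hw^2, .Machine$double.eps)
  verdict <- c(
    if (hw_constant) {
      "hardware IFIs constant to within the recording resolution"
    } else {
      "hardware IFIs vary beyond the recording resolution"
    },
    if (length(dropped)) {
      sprintf("%d frame(s) present in the hardware record are missing from the software record", length(dropped))
    } else {
      "no dropped frames"
    },
    if (var_sw > var_hw) {
      "software timestamps show more IFI variance than hardware timing"
    } else {
      "software and hardware IFI variance comparable"
    }
  )
  structure(
    list(
      n_hw = length(th), n_sw = length(tsw), n_dropped = length(dropped),
      dropped_hw_indices = dropped,
      var_ifi_hw = var_hw, var_ifi_sw = var_sw,
      hw_quantization = q_hw, hw_constant = hw_constant,
      verdict = verdict
    ),
    class = "hw_sw_comparison"
  )
}

#' @export
print.hw_sw_comparison <- function(x, ...) {
  cat("<hw_sw_comparison>\n")
  cat(sprintf("  hardware frames: %d, software frames: %d, dropped: %d\n",
              x$n_hw, x$n_sw, x$n_dropped))
  cat(sprintf("  IFI variance: hw %.3g s^2, sw %.3g s^2\n",
              x$var_ifi_hw, x$var_ifi_sw))
  for (v in x$verdict) cat("  - ", v, "\n", sep = "")
  invisible(x)
}

#' @rdname compare_hw_sw
#' @param x An `hw_sw_comparison`.
#' @param ... Unused.
#' @export
glance.hw_sw_comparison <- function(x, ...) {
  tibble(
    n_hw = x$n_hw, n_sw = x$n_sw, n_dropped = x$n_dropped,
    var_ifi_hw = x$var_ifi_hw, var_ifi_sw = x$var_ifi_sw,
    hw_constant = x$hw_constant
  )
}
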