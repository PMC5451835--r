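#' Mutual information between feature position and displacement
#'
#' The motion-coherence statistic: each tracked vector contributes a pair
#' (X, Y) where X is the index of the spatial cell containing the feature on
#' a `spatial_grid` x `spatial_grid` partition of the image, and Y is its
#' displacement quantized component-wise on equal-width bins of width
#' `2 * max_displacement / displacement_bins`, centred so that zero
#' displacement falls in the middle of a bin (small tracking jitter around
#' rest therefore occupies a single bin instead of straddling a bin edge).
#' The plug-in mutual information MI(X;Y) (bits) is returned,
#' optionally with the Miller-Madow bias correction, floored at 0. Random
#' uncorrelated jitter gives MI near 0; a coherent, spatially localized
#' twitch makes displacement predictable from position and MI rises.
#'
#' @param field A `motion_field` (tibble with `x`, `y`, `dx`, `dy`); its
#'   `image_size` attribute locates the spatial grid.
#' @param spatial_grid Cells per image side.
#' @param displacement_bins Bins per displacement component.
#' @param max_displacement Half-range (pixels) of the displacement binning;
#'   values beyond it are clamped into the edge bins.
#' @param image_size `c(rows, cols)`; taken from the field attribute when
#'   omitted.
#' @param bias_correction Apply the Miller-Madow correction (default TRUE).
#' @return MI in bits (>= 0), or `NA` if the field has fewer than 2 vectors.
#' @export
motion_mutual_information <- function(field, spatial_grid = 4,
                                      displacement_bins = 8,
                                      max_displacement = 5,
                                      image_size = NULL,
                                      bias_correction = TRUE) {
  image_size <- image_size %||% attr(field, "image_size")
  if (is.null(image_size)) {
    abort("`image_size` must be supplied or present as a field attribute.")
  }
  n <- nrow(field)
  if (is.null(n) || n < 2L) return(NA_real_)
  nr <- image_size[1]; nc <- image_size[2]
  cellx <- pmin(pmax(floor(field$x / nc * spatial_grid), 0), spatial_grid - 1)
  celly <- pmin(pmax(floor(field$y / nr * spatial_grid), 0), spatial_grid - 1)
  X <- cellx * spatial_grid + celly
  binw <- 2 * max_displacement / displacement_bins
  half <- floor(displacement_bins / 2)
  bx <- pmin(pmax(round(field$dx / binw), -half), half)
  by <- pmin(pmax(round(field$dy / binw), -half), half)
  Y <- (bx + half) * (2 * half + 1) + (by + half)
  discrete_mutual_information(X, Y, bias_correction)
}

# Plug-in MI of two integer-coded discrete vectors, in bits, with optional
# Miller-Madow correction; floored at 0.
discrete_mutual_information <- function(X, Y, bias_correction = TRUE) {
  n <- length(X)
  joint <- table(X, Y)
  px <- rowSums(joint) / n
  py <- colSums(joint) / n
  pxy <- joint / n
  hx <- -sum(px[px > 0] * log(px[px > 0]))
  hy <- -sum(py[py > 0] * log(py[py > 0]))
  hxy <- -sum(pxy[pxy > 0] * log(pxy[pxy > 0]))
  mi <- hx + hy - hxy
  if (bias_correction) {
    kx <- sum(px > 0); ky <- sum(py > 0); kxy <- sum(pxy > 0)
    mi <- mi + ((kx - 1) + (ky - 1) - (kxy - 1)) / (2 * n)
  }
  max(mi / log(2), 0)
}

#' Twitch-likelihood trace from a tracked sequence
#'
#' Scores every frame transition with [motion_mutual_information()] and
#' assigns each transition the midpoint of its two frame times. Transitions
#' with fewer than 2 tracked vectors get an `NA` score.
#'
#' @param fields Output of [track_sequence()] (vectors for all transitions),
#'   or a list of `motion_field` objects.
#' @param times A `timestamp_series` (or numeric vector of frame times) with
#'   exactly one more frame than there are transitions.
#' @param spatial_grid,displacement_bins,max_displacement,bias_correction
#'   Passed to [motion_mutual_information()].
#' @return A `twitch_trace` tibble: `transition_index`, `time_s`, `mi_bits`.
#' @export
twitch_trace <- function(fields, times, spatial_grid = 4,
                         displacement_bins = 8, max_displacement = 5,
                         bias_correction = TRUE) {
  t_frames <- if (is.data.frame(times)) times$timestamp_s else as.numeric(times)
  if (is.data.frame(fields)) {
    image_size <- attr(fields, "image_size")
    n_tr <- length(t_frames) - 1L
    idx <- fields$transition_index
    if (length(idx) && (min(idx) < 0 || max(idx) >= n_tr)) {
      abort("`fields` transition indices do not match `times`: need length(times) == n_transitions + 1.")
    }
    split_fields <- split(fields[c("x", "y", "dx", "dy")], factor(idx, levels = 0:(n_tr - 1L)))
  } else {
    n_tr <- length(fields)
    if (length(t_frames) != n_tr + 1L) {
      abort("`times` must have exactly one more frame than there are fields.")
    }
    image_size <- attr(fields[[1]], "image_size")
    split_fields <- fields
  }
  scores <- purrr::map_dbl(split_fields, function(f) {
    motion_mutual_information(f, spatial_grid, displacement_bins,
                              max_displacement, image_size = image_size,
                              bias_correction = bias_correction)
  })
  out <- tibble(
    transition_index = 0:(n_tr - 1L),
    time_s = (t_frames[-length(t_frames)] + t_frames[-1]) / 2,
    mi_bits = unname(scores)
  )
  class(out) <- unique(c("twitch_trace", class(out)))
  out
}

#' Detect twitch events in a trace
#'
#' Events are local maxima of the MI trace above a robust threshold
#' `median + threshold_sds * sigma`, where `sigma` is the MAD-based SD
#' estimate of the scores (falling back to the sample SD when the MAD is 0,
#' as happens when most scores are exactly 0). Maxima closer together than
#' `min_separation` are merged greedily, keeping the larger score.
#'
#' @param trace A `twitch_trace` tibble (`NA` scores are ignored).
#' @param threshold_sds Threshold height in robust SDs above the median.
#' @param min_separation Minimum time (s) between reported events.
#' @return A tibble `event_index`, `time_s`, `mi_bits` with strictly
#'   increasing times (zero rows if nothing crosses the threshold).
#' @export
detect_events <- function(trace, threshold_sds = 4, min_separation = 1) {
  stopifnot(all(c("time_s", "mi_bits") %in% names(trace)))
  s <- trace$mi_bits
  t <- trace$time_s
  ok <- !is.na(s)
  empty <- tibble(event_index = integer(), time_s = numeric(), mi_bits = numeric())
  if (sum(ok) < 3L) return(empty)
  sigma <- mad(s[ok])
  if (sigma == 0) sigma <- sd(s[ok])
  thr <- median(s[ok]) + threshold_sds * sigma
  n <- length(s)
  sprev <- c(-Inf, s[-n]); snext <- c(s[-1], -Inf)
  is_peak <- ok & s > thr &
    (is.na(sprev) | s >= sprev) & (is.na(snext) | s >= snext)
  idx <- which(is_peak)
  if (!length(idx)) return(empty)
  # greedy: strongest first, suppress anything within min_separation
  ord <- idx[order(-s[idx])]
  kept <- numeric(0)
  kept_idx <- integer(0)
  for (i in ord) {
    if (!length(kept) || all(abs(t[i] - kept) >= min_separation)) {
      kept <- c(kept, t[i])
      kept_idx <- c(kept_idx, i)
    }
  }
  o <- order(kept)
  tibble(
    event_index = seq_along(kept_idx) - 1L,
    time_s = kept[o],
    mi_bits = s[kept_idx][o]
  )
}
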