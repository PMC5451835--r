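#' Plot an IFI report
#'
#' Histogram of instantaneous frame rates (1/IFI) with the fitted mode
#' centres and the nominal rate marked.
#'
#' @param object An `ifi_report`.
#' @param bins Histogram bin count.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ifi_report <- function(object, bins = 60, ...) {
  df <- tibble(rate_fps = 1 / object$ifi_s[object$ifi_s > 0])
  modes <- object$modes[!is.na(object$modes$rate_fps), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rate_fps)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey35") +
    ggplot2::geom_vline(data = modes,
                        ggplot2::aes(xintercept = .data$rate_fps,
                                     colour = .data$mode),
                        linetype = 2) +
    ggplot2::geom_vline(xintercept = object$nominal_rate, colour = "black") +
    ggplot2::labs(x = "instantaneous frame rate (fps)", y = "transitions",
                  colour = "mode",
                  title = sprintf("IFI distribution (n = %d frames)",
                                  object$n_frames))
}

#' Plot a twitch trace with detected events
#'
#' @param object A `twitch_trace`.
#' @param events Optional event tibble from [detect_events()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.twitch_trace <- function(object, events = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = .data$mi_bits)) +
    ggplot2::geom_line(colour = "steelblue", na.rm = TRUE) +
    ggplot2::labs(x = "time (s)", y = "mutual information (bits)",
                  title = "twitch-likelihood trace")
  if (!is.null(events) && nrow(events)) {
    p <- p + ggplot2::geom_point(data = events, colour = "firebrick", size = 2)
  }
  p
}

#' Plot per-stimulus latencies of a synchronization result
#'
#' Latency against stimulus onset time; negative latencies (movement
#' apparently preceding its stimulus) sit below the dashed zero line, and
#' the dotted line marks the nominal IFI.
#'
#' @param object A `sync_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sync_result <- function(object, ...) {
  df <- object$latencies[object$latencies$matched, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$onset_s,
                                   y = 1000 * .data$latency_s)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_hline(yintercept = 1000 * object$nominal_ifi,
                        linetype = 3) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "stimulus onset (s)", y = "latency (ms)",
                  title = "stimulus-to-twitch latency")
}
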