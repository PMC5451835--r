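#' Generate a synthetic surface-EMG trace
#'
#' Uniformly sampled EMG at `model$fs`: baseline Gaussian noise, a biphasic
#' stimulation artifact (one positive then one negative sample of
#' `artifact_amplitude`) at each stimulus onset, and an M-wave — a damped
#' sinusoid `A sin(2 pi f tau) exp(-decay tau)` — starting `mwave_latency`
#' seconds after each onset.
#'
#' @param onsets Stimulus onset times (s), or a [twitch_schedule()] whose
#'   `onsets` are used.
#' @param model An [emg_model()].
#' @param duration Trace length in seconds (> 0); the trace has
#'   `round(duration * fs)` samples.
#' @param seed Integer seed.
#' @return A tibble with columns `time_s` and `emg_mV`.
#' @export
#' @examples
#' emg <- generate_emg(c(1, 2), emg_model(), duration = 3, seed = 1)
#' nrow(emg)
generate_emg <- function(onsets, model = emg_model(), duration, seed = 1) {
  if (inherits(onsets, "twitch_schedule")) onsets <- onsets$onsets
  stopifnot(inherits(model, "emg_model"))
  if (!is_scalar_number(duration) || duration <= 0) {
    abort("`duration` must be a positive number of seconds.")
  }
  n <- round(duration * model$fs)
  t <- (seq_len(n) - 1) / model$fs
  old <- .Random.seed_guard(derive_seed(seed, "emg"))
  on.exit(old(), add = TRUE)
  y <- if (model$noise_sd > 0) rnorm(n, sd = model$noise_sd) else numeric(n)
  for (onset in onsets) {
    k <- which(t >= onset)[1]
    if (is.na(k)) next
    y[k] <- y[k] + model$artifact_amplitude
    if (k + 1 <= n) y[k + 1] <- y[k + 1] - model$artifact_amplitude
    tau <- t - onset - model$mwave_latency
    act <- tau >= 0
    y[act] <- y[act] + model$mwave_amplitude *
      sin(2 * pi * model$mwave_freq * tau[act]) * exp(-model$mwave_decay * tau[act])
  }
  tibble(time_s = t, emg_mV = y)
}
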