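#' Frame-timing model for a simulated ultrasound acquisition
#'
#' Describes how a device spaces, jitters and loses frames. True inter-frame
#' intervals (IFIs) are drawn i.i.d. from a two-point mixture: with probability
#' `mode_weight` the dominant interval `1/mode_rates[1]`, otherwise the minor
#' interval `1/mode_rates[2]`. The software record of those times additionally
#' suffers read-out jitter and dropped frames.
#'
#' @param nominal_rate Frame rate stated on the device display (frames/s).
#' @param mode_rates Length-2 numeric, dominant and minor mode frame rates
#'   (frames/s) of the bimodal IFI distribution.
#' @param mode_weight Fraction of IFIs drawn from the dominant mode, in `[0,1]`.
#' @param jitter_sd Standard deviation (s) of zero-mean software-timestamp
#'   read-out jitter.
#' @param drop_prob Per-frame probability that the software record misses the
#'   frame, in `[0,1)`.
#' @param quantization Resolution (s) of the metadata timestamps. Default
#'   1e-7 s (timestamps accurate to 100 ns).
#' @param software_quantization Resolution (s) of the software clock used for
#'   software timestamps; 0 leaves software timestamps unquantized.
#'
#' @return An object of class `timing_model` (a named list).
#' @seealso [timing_preset()] for ready-made device presets.
#' @export
#' @examples
#' timing_model(82, c(83.5, 62.5), 0.9272)
timing_model <- function(nominal_rate,
                         mode_rates = c(nominal_rate, nominal_rate),
                         mode_weight = 1,
                         jitter_sd = 0,
                         drop_prob = 0,
                         quantization = 1e-7,
                         software_quantization = 0) {
  stopifnot(is_scalar_number(nominal_rate), nominal_rate > 0)
  if (length(mode_rates) != 2L || any(!is.finite(mode_rates)) || any(mode_rates <= 0)) {
    abort("`mode_rates` must be two positive finite rates (dominant, minor).")
  }
  if (!is_scalar_number(mode_weight) || mode_weight < 0 || mode_weight > 1) {
    abort("`mode_weight` must lie in [0, 1].")
  }
  if (!is_scalar_number(jitter_sd) || jitter_sd < 0) abort("`jitter_sd` must be >= 0.")
  if (!is_scalar_number(drop_prob) || drop_prob < 0 || drop_prob >= 1) {
    abort("`drop_prob` must lie in [0, 1).")
  }
  if (!is_scalar_number(quantization) || quantization < 0) {
    abort("`quantization` must be >= 0.")
  }
  if (!is_scalar_number(software_quantization) || software_quantization < 0) {
    abort("`software_quantization` must be >= 0.")
  }
  structure(
    list(
      nominal_rate = nominal_rate,
      mode_rates = as.numeric(mode_rates),
      mode_weight = mode_weight,
      jitter_sd = jitter_sd,
      drop_prob = drop_prob,
      quantization = quantization,
      software_quantization = software_quantization
    ),
    class = "timing_model"
  )
}

#' Ready-made timing models for the two studied device behaviours
#'
#' `"telemed82"` and `"telemed42"` reproduce the bimodal-IFI behaviour of a
#' linear-process scanner whose metadata timestamps are accurate to 100 ns:
#' at a stated 82 fps, 92.72% of IFIs cluster at 83.5 fps and the rest at
#' 62.5 fps; at a stated 42 fps the split is 85.62% at 41.5 fps versus 36 fps.
#' `"sonix"` models a device whose transmission is metronomic (constant true
#' IFI at 150.7 fps, the 64-receive-element configuration) but whose software
#' timestamps show jitter, a 27.937 microsecond clock resolution and dropped
#' frames caused by memory saturation.
#'
#' @param name One of `"telemed82"`, `"telemed42"`, `"sonix"`.
#' @return A [timing_model()].
#' @export
#' @examples
#' timing_preset("telemed82")
timing_preset <- function(name = c("telemed82", "telemed42", "sonix")) {
  name <- match.arg(name)
  switch(name,
    telemed82 = timing_model(82, c(83.5, 62.5), 0.9272),
    telemed42 = timing_model(42, c(41.5, 36.0), 0.8562),
    sonix = timing_model(150.7, c(150.7, 150.7), 1,
      jitter_sd = 5e-4, drop_prob = 0.05,
      quantization = 0, software_quantization = 27.937e-6
    )
  )
}

#' Stimulation and twitch-kinematics schedule
#'
#' Defines when electrical stimuli occur and how the evoked twitch displaces
#' the imaged tissue. Displacement is spatially Gaussian-windowed around
#' `region_centre` and follows an asymmetric temporal profile: a raised-cosine
#' rise over `rise_time` to `peak_displacement`, then a raised-cosine decay
#' over the remaining `duration - rise_time` (fast contraction, slower
#' relaxation). Movement starts `latency` seconds after each stimulus onset.
#'
#' @param onsets Strictly increasing stimulus onset times (s). Default one
#'   pulse every 5 s from 5 to 40 s.
#' @param duration Total twitch duration (s), rise plus relaxation.
#' @param rise_time Duration (s) of the contraction phase; must be < `duration`.
#' @param latency Stimulus-to-movement delay (s).
#' @param region_centre Pixel coordinates `c(x, y)` of the twitch centre
#'   (0-based, x = column, y = row).
#' @param region_sd Spatial standard deviation (pixels) of the Gaussian
#'   displacement window.
#' @param peak_displacement Peak displacement `c(dx, dy)` in pixels.
#'
#' @return An object of class `twitch_schedule`.
#' @export
#' @examples
#' twitch_schedule(onsets = c(5, 10), peak_displacement = c(3, 0))
twitch_schedule <- function(onsets = seq(5, 40, by = 5),
                            duration = 0.07,
                            rise_time = 0.01,
                            latency = 0.01,
                            region_centre = c(64, 64),
                            region_sd = 24,
                            peak_displacement = c(3, 0)) {
  if (length(onsets) && any(diff(onsets) <= 0)) {
    abort("`onsets` must be strictly increasing.")
  }
  stopifnot(
    is_scalar_number(duration), duration > 0,
    is_scalar_number(rise_time), rise_time > 0, rise_time < duration,
    is_scalar_number(latency), latency >= 0,
    length(region_centre) == 2L, length(peak_displacement) == 2L,
    is_scalar_number(region_sd), region_sd > 0
  )
  structure(
    list(
      onsets = as.numeric(onsets),
      duration = duration,
      rise_time = rise_time,
      latency = latency,
      region_centre = as.numeric(region_centre),
      region_sd = region_sd,
      peak_displacement = as.numeric(peak_displacement)
    ),
    class = "twitch_schedule"
  )
}

#' Surface-EMG generative model
#'
#' Parameters of the simulated EMG channel: baseline Gaussian noise, a
#' biphasic stimulation artifact at each stimulus onset, and a delayed damped
#' sinusoid standing for the M-wave (the direct muscle response).
#'
#' @param fs Sampling rate (samples/s). Default 2000 (2 kHz acquisition).
#' @param noise_sd Baseline noise SD (mV).
#' @param artifact_amplitude Stimulation-artifact amplitude (mV).
#' @param mwave_amplitude M-wave amplitude (mV).
#' @param mwave_latency Stimulus-to-M-wave delay (s).
#' @param mwave_freq M-wave oscillation frequency (Hz).
#' @param mwave_decay M-wave exponential decay constant (1/s).
#'
#' @return An object of class `emg_model`.
#' @export
emg_model <- function(fs = 2000,
                      noise_sd = 0.02,
                      artifact_amplitude = 2,
                      mwave_amplitude = 1,
                      mwave_latency = 0.008,
                      mwave_freq = 150,
                      mwave_decay = 60) {
  stopifnot(
    is_scalar_number(fs), fs > 0,
    noise_sd >= 0, artifact_amplitude >= 0, mwave_amplitude >= 0,
    mwave_latency >= 0, mwave_freq > 0, mwave_decay >= 0
  )
  structure(
    list(
      fs = fs, noise_sd = noise_sd,
      artifact_amplitude = artifact_amplitude,
      mwave_amplitude = mwave_amplitude,
      mwave_latency = mwave_latency,
      mwave_freq = mwave_freq,
      mwave_decay = mwave_decay
    ),
    class = "emg_model"
  )
}
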