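# Shared fixtures, built once per test run and memoized.

.fixture_cache <- new.env(parent = emptyenv())

memoize_fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

# A short twitch dataset (cheap enough for unit tests): 12 s, two stimuli.
small_twitch_dataset <- function() {
  memoize_fixture("small_twitch", function() {
    ds <- suppressWarnings(simulate_dataset(
      duration = 12,
      schedule = twitch_schedule(onsets = c(5, 10)),
      image_size = c(128, 128),
      seed = 7
    ))
    fields <- track_sequence(ds$images)
    trace <- twitch_trace(fields, ds$true_times)
    list(ds = ds, fields = fields, trace = trace)
  })
}

# The full-length default trial used by the artefact-reproduction and
# discrimination checks: 40 s, stimuli every 5 s from 5 s, bimodal 82 fps
# timing, 128 x 128 px frames.
default_trial <- function() {
  memoize_fixture("default_trial", function() {
    ds <- suppressWarnings(simulate_dataset(seed = 1))
    fields <- track_sequence(ds$images)
    n <- nrow(ds$true_times)
    list(
      ds = ds,
      fields = fields,
      trace_metadata = twitch_trace(fields, ds$true_times),
      trace_assumed = twitch_trace(
        fields, frame_times_assumed(n, ds$params$timing.nominal_rate))
    )
  })
}
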