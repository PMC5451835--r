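#' Read a per-frame timestamp CSV
#'
#' The timestamp dialect is a plain CSV with mandatory header
#' `frame_index,timestamp_s,source` (0-based frame index, decimal seconds,
#' source one of `metadata`, `software`, `hardware`, `assumed`), optionally
#' preceded by comment lines such as `# quantization_s=1e-07` carrying the
#' timestamp resolution. Timestamps must be non-decreasing.
#'
#' @param path Path to the CSV file.
#' @return A `timestamp_series` tibble.
#' @export
read_timestamps <- function(path) {
  if (!file.exists(path)) abort(sprintf("timestamp file not found: %s", path))
  header <- readLines(path, n = 25L)
  q <- 0
  qline <- grep("^#\\s*quantization_s\\s*=", header, value = TRUE)
  if (length(qline)) {
    q <- as.numeric(sub("^#\\s*quantization_s\\s*=\\s*", "", qline[1]))
  }
  first_data <- header[!startsWith(header, "#")][1]
  if (is.na(first_data) ||
      !grepl("^frame_index\\s*,\\s*timestamp_s", first_data)) {
    format_error(sprintf(
      "%s: missing mandatory header `frame_index,timestamp_s,source`.", path))
  }
  tbl <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (!all(c("frame_index", "timestamp_s") %in% names(tbl))) {
    format_error(sprintf("%s: columns `frame_index` and `timestamp_s` are required.", path))
  }
  # base-R numeric conversion round-trips the full double precision
  tbl$frame_index <- as.integer(tbl$frame_index)
  tbl$timestamp_s <- as.numeric(tbl$timestamp_s)
  if (anyNA(tbl$timestamp_s)) {
    format_error(sprintf("%s: non-numeric timestamp at data row %d.",
                         path, which(is.na(tbl$timestamp_s))[1]))
  }
  d <- diff(tbl$timestamp_s)
  if (length(d) && any(d < 0)) {
    row <- which(d < 0)[1] + 1L
    format_error(sprintf(
      "%s: timestamp decreases at data row %d (frame_index %s).",
      path, row, tbl$frame_index[row]))
  }
  src <- if ("source" %in% names(tbl) && nrow(tbl)) tbl$source[1] else "metadata"
  timestamp_series(tbl$timestamp_s, src, quantization = q,
                   frame_index = tbl$frame_index)
}

format_error <- function(msg) {
  abort(msg, class = "usifi_format_error")
}

#' Write a timestamp series to CSV
#'
#' Inverse of [read_timestamps()]; the quantization attribute is stored in a
#' `# quantization_s=` comment line so the series round-trips exactly.
#'
#' @param series A `timestamp_series`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_timestamps <- function(series, path) {
  assert_timestamp_series(series, strict = FALSE)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(sprintf("# quantization_s=%.17g", ts_quantization(series)), con)
  writeLines("frame_index,timestamp_s,source", con)
  writeLines(sprintf("%d,%.17g,%s", series$frame_index, series$timestamp_s,
                     series$source), con)
  invisible(path)
}

#' Simulate a complete synthetic acquisition
#'
#' Generates everything one trial produces, with full ground truth: true
#' (metadata) frame times from the timing model, their software-timestamp
#' degradation and hardware-trigger record, the speckle image sequence with
#' its twitch displacements, the EMG trace, and the stimulus schedule.
#'
#' @param timing A [timing_model()]; default the bimodal 82 fps preset.
#' @param schedule A [twitch_schedule()].
#' @param emg An [emg_model()].
#' @param duration Trial length (s); default 40.
#' @param image_size,grain,noise_sd Passed to [generate_speckle_sequence()].
#' @param hw_quantization Hardware recording resolution (s).
#' @param seed One integer seed; per-component seeds are derived from it
#'   deterministically.
#' @return A list of class `usifi_dataset` with elements `true_times`,
#'   `software` (list: `timestamps`, `dropped_indices`, `clamp_count`),
#'   `hardware`, `images` (a `speckle_sequence`), `emg`, `stimuli`,
#'   `params`.
#' @export
#' @examples
#' ds <- simulate_dataset(duration = 6, image_size = c(64, 64),
#'   schedule = twitch_schedule(onsets = c(2, 4)), seed = 1)
#' names(ds)
simulate_dataset <- function(timing = timing_preset("telemed82"),
                             schedule = twitch_schedule(),
                             emg = emg_model(),
                             duration = 40,
                             image_size = c(128, 128),
                             grain = 3,
                             noise_sd = 0.02,
                             hw_quantization = 25e-6,
                             seed = 1) {
  true_times <- generate_true_frame_times(timing, duration, seed)
  software <- degrade_to_software_timestamps(true_times, timing, seed)
  hardware <- hardware_timestamps(true_times, hw_quantization)
  images <- generate_speckle_sequence(true_times, schedule, image_size,
                                      grain, noise_sd, seed)
  emg_trace <- generate_emg(schedule$onsets, emg, duration, seed)
  stimuli <- tibble(stim_index = seq_along(schedule$onsets) - 1L,
                    onset_s = schedule$onsets)
  params <- c(
    list(duration = duration, image_rows = image_size[1],
         image_cols = image_size[2], grain = grain, noise_sd = noise_sd,
         hw_quantization = hw_quantization, seed = seed),
    stats::setNames(unclass(timing), paste0("timing.", names(unclass(timing)))),
    stats::setNames(unclass(schedule), paste0("schedule.", names(unclass(schedule)))),
    stats::setNames(unclass(emg), paste0("emg.", names(unclass(emg))))
  )
  structure(
    list(true_times = true_times, software = software, hardware = hardware,
         images = images, emg = emg_trace, stimuli = stimuli, params = params),
    class = "usifi_dataset"
  )
}

#' @export
print.usifi_dataset <- function(x, ...) {
  cat(sprintf(
    "<usifi_dataset> %d frames, %d stimuli, %d dropped in software record, seed %s\n",
    nrow(x$true_times), nrow(x$stimuli), length(x$software$dropped_indices),
    x$params$seed))
  invisible(x)
}

#' Write a simulated dataset to a directory
#'
#' Produces the on-disk form of a [simulate_dataset()] result: an 8-bit
#' multi-page TIFF of the frames, one timestamp CSV per source, EMG and
#' stimulus CSVs, ground-truth CSVs (movement onsets, dropped frame indices,
#' per-transition displacement), and a flat `config.txt` echoing all
#' generation parameters and the seed. All outputs are deterministic given
#' the dataset.
#'
#' @param dataset A `usifi_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "usifi_dataset"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    abort(sprintf("cannot create output directory: %s", dir))
  }
  tiff::writeTIFF(dataset$images$frames, file.path(dir, "images.tif"),
                  bits.per.sample = 8L, compression = "none")
  write_timestamps(dataset$true_times, file.path(dir, "timestamps_metadata.csv"))
  write_timestamps(dataset$software$timestamps,
                   file.path(dir, "timestamps_software.csv"))
  write_timestamps(dataset$hardware, file.path(dir, "timestamps_hardware.csv"))
  readr::write_csv(dataset$emg, file.path(dir, "emg.csv"), progress = FALSE)
  readr::write_csv(dataset$stimuli, file.path(dir, "stimuli.csv"), progress = FALSE)
  sched <- dataset$params
  gt_tw <- tibble(
    stim_index = dataset$stimuli$stim_index,
    onset_s = dataset$stimuli$onset_s,
    movement_onset_s = dataset$stimuli$onset_s + sched$schedule.latency,
    peak_time_s = dataset$stimuli$onset_s + sched$schedule.latency +
      sched$schedule.rise_time
  )
  readr::write_csv(gt_tw, file.path(dir, "ground_truth_twitches.csv"),
                   progress = FALSE)
  readr::write_csv(tibble(dropped_index = dataset$software$dropped_indices),
                   file.path(dir, "ground_truth_dropped.csv"), progress = FALSE)
  readr::write_csv(dataset$images$ground_truth,
                   file.path(dir, "ground_truth_displacement.csv"),
                   progress = FALSE)
  write_flat_config(dataset$params, file.path(dir, "config.txt"))
  invisible(dir)
}

#' Read a dataset directory written by [write_dataset()]
#'
#' @param dir Dataset directory.
#' @return A list with `frames` (list of matrices), `true_times`,
#'   `software_times`, `hardware_times` (timestamp series), `emg`,
#'   `stimuli`, `ground_truth` (list of tibbles) and `config` (named list).
#' @export
read_dataset <- function(dir) {
  if (!dir.exists(dir)) abort(sprintf("dataset directory not found: %s", dir))
  frames <- tiff::readTIFF(file.path(dir, "images.tif"), all = TRUE)
  frames <- purrr::map(frames, function(f) {
    if (length(dim(f)) == 3L) f <- f[, , 1]
    f
  })
  list(
    frames = frames,
    true_times = read_timestamps(file.path(dir, "timestamps_metadata.csv")),
    software_times = read_timestamps(file.path(dir, "timestamps_software.csv")),
    hardware_times = read_timestamps(file.path(dir, "timestamps_hardware.csv")),
    emg = readr::read_csv(file.path(dir, "emg.csv"), show_col_types = FALSE,
                          progress = FALSE),
    stimuli = readr::read_csv(file.path(dir, "stimuli.csv"),
                              show_col_types = FALSE, progress = FALSE),
    ground_truth = list(
      twitches = readr::read_csv(file.path(dir, "ground_truth_twitches.csv"),
                                 show_col_types = FALSE, progress = FALSE),
      dropped = readr::read_csv(file.path(dir, "ground_truth_dropped.csv"),
                                show_col_types = FALSE, progress = FALSE),
      displacement = readr::read_csv(
        file.path(dir, "ground_truth_displacement.csv"),
        show_col_types = FALSE, progress = FALSE)
    ),
    config = read_flat_config(file.path(dir, "config.txt"))
  )
}

# Flat `key = value` config files -------------------------------------------

write_flat_config <- function(params, path) {
  fmt <- function(v) {
    if (is.numeric(v)) paste(sprintf("%.17g", v), collapse = ",")
    else paste(as.character(v), collapse = ",")
  }
  lines <- vapply(names(params), function(k) {
    sprintf("%s = %s", k, fmt(params[[k]]))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

read_flat_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) < 2) format_error(sprintf("malformed config line: %s", ln))
    key <- trimws(parts[1])
    val <- trimws(paste(parts[-1], collapse = "="))
    vals <- strsplit(val, ",", fixed = TRUE)[[1]]
    num <- suppressWarnings(as.numeric(vals))
    out[[key]] <- if (!anyNA(num)) num else vals
  }
  out
}

#' Write a twitch trace or event list to CSV
#'
#' @param x A `twitch_trace` or event tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(x, path) {
  readr::write_csv(x, path, progress = FALSE)
  invisible(path)
}

#' Read a twitch trace CSV
#'
#' @param path Path to a CSV with columns `transition_index,time_s,mi_bits`.
#' @return A `twitch_trace` tibble.
#' @export
read_trace <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("time_s", "mi_bits") %in% names(tbl))) {
    format_error(sprintf("%s: columns `time_s` and `mi_bits` are required.", path))
  }
  class(tbl) <- unique(c("twitch_trace", class(tbl)))
  tbl
}
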