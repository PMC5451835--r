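Package: usifi
Title: Frame-Timing Diagnostics and Synchronization Correction for
    B-Mode Ultrasound Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify inter-frame-interval (IFI) variability in
    B-mode ultrasound image sequences and to correct the synchronization
    artefacts it produces. Includes a Kanade-Lucas-Tomasi (KLT) feature
    tracker with Shi-Tomasi feature selection, a mutual-information
    motion-coherence statistic that scores each frame transition for the
    presence of a coherent tissue twitch, diagnostics for frame-timestamp
    records (bimodal IFI decomposition, dropped-frame detection, hardware
    versus software timestamp comparison, drift classification), and
    routines that re-time frame-by-frame measures with per-frame IFIs to
    recover stimulus-to-movement latencies. A synthetic-data generator
    produces speckle image sequences, timestamp records and EMG traces
    with known ground truth so the whole chain is testable without an
    ultrasound device.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
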