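Package: somnidex
Title: Automated Overnight EEG Analysis of Slow-Wave Slope and Epileptic Spikes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A fully automated pipeline for overnight pediatric EEG: EDF
    reading and preprocessing (0.3-40 Hz bandpass, 50 Hz notch,
    contralateral-mastoid re-referencing, downsampling to 128 Hz), LSTM-based
    detection of epileptic spikes and of NREM2/3 sleep, slow-wave detection
    with ascending-slope measurement, post-spike wave exclusion,
    first-vs-last-hour amplitude matching, and the SOMNIDEX overnight
    synaptic-renormalization index together with the spike-wave index (SWI).
    Includes a synthetic overnight-EEG generator with full ground truth
    (hypnogram, spike times, slow-wave inventory) for training and
    validation, plus classifier-performance and correlation statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
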