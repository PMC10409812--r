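#' Simulate a hypnogram
#'
#' Generates one sleep-stage label per complete 20-s epoch from
#' `{W, N1, N2, N3, REM}` using a deterministic cycle template with seeded
#' jitter. The default pediatric template runs a short sleep-onset wake/N1
#' latency and then repeats W -> N1 -> N2 -> N3 -> N2 -> REM cycles with
#' N3-heavy early-night proportions.
#'
#' @param config a [sim_config()].
#' @return A tibble of class `hypnogram` with `epoch_index` (1-based) and
#'   `stage` (factor W/N1/N2/N3/REM).
#' @export
simulate_hypnogram <- function(config) {
  n_epochs <- floor(config$duration_s / EPOCH_S)
  if (n_epochs < 1L) abort("empty hypnogram: duration shorter than one 20-s epoch")

  labels <- withr::with_seed(child_seed(config$seed, 11L), {
    switch(config$hypnogram_preset,
      all_n2 = rep("N2", n_epochs),
      all_wake = rep("W", n_epochs),
      nrem_dominant = hyp_nrem_dominant(n_epochs),
      pediatric_night = hyp_pediatric(n_epochs, config$cycle_len_epochs)
    )
  })

  structure(
    tibble(epoch_index = seq_len(n_epochs),
           stage = factor(labels, levels = c("W", "N1", "N2", "N3", "REM"))),
    class = c("hypnogram", "tbl_df", "tbl", "data.frame")
  )
}

# short wake onset, then alternating N2/N3 blocks; compact recordings keep
# enough NREM epochs for first/last-hour selection
hyp_nrem_dominant <- function(n_epochs) {
  lab <- c(rep("W", 6L), rep("N1", 2L))
  while (length(lab) < n_epochs) {
    lab <- c(lab,
             rep("N2", 10L + sample.int(5L, 1L)),
             rep("N3", 20L + sample.int(8L, 1L)))
  }
  lab[seq_len(n_epochs)]
}

# cyclic template; stage proportions per cycle roughly match an N3-rich
# pediatric night (N2+N3 about 70-75% of sleep)
hyp_pediatric <- function(n_epochs, cycle_len) {
  template <- c(W = 0.04, N1 = 0.06, N2 = 0.33, N3 = 0.36, N2b = 0.06,
                REM = 0.15)
  lab <- c(rep("W", 12L), rep("N1", 6L))  # sleep-onset latency ~6 min
  cyc <- 0L
  while (length(lab) < n_epochs) {
    cyc <- cyc + 1L
    jit <- runif(length(template), 0.8, 1.2)
    durs <- setNames(pmax(1, round(template * cycle_len * jit)),
                     names(template))
    stages <- sub("b$", "", names(template))
    # REM share grows and N3 share shrinks over the night, as in real sleep
    if (cyc >= 3L) {
      durs["N3"] <- max(1L, round(durs["N3"] * 0.6))
      durs["REM"] <- round(durs["REM"] * 1.5)
    }
    lab <- c(lab, rep(stages, times = durs))
  }
  lab[seq_len(n_epochs)]
}

#' Binary NREM2/3 mask of a hypnogram
#' @param hypnogram a tibble with a `stage` column (5-stage dialect) or a
#'   `label` column (binary dialect, values `"NREM23"`/`"other"`).
#' @return logical vector, `TRUE` for NREM2/3 epochs.
#' @export
nrem_mask <- function(hypnogram) {
  if ("stage" %in% names(hypnogram)) {
    hypnogram$stage %in% c("N2", "N3")
  } else if ("label" %in% names(hypnogram)) {
    hypnogram$label == "NREM23"
  } else {
    abort("hypnogram needs a `stage` or `label` column")
  }
}
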