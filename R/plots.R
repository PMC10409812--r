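#' Plot a hypnogram
#'
#' Step plot of stage (5-stage dialect) or NREM2/3 posterior / binary label
#' over the night.
#'
#' @param object a hypnogram tibble.
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.hypnogram <- function(object, ...) {
  hours <- (object$epoch_index - 1) * EPOCH_S / 3600
  if ("stage" %in% names(object)) {
    df <- tibble(hours = hours,
                 stage = factor(object$stage,
                                levels = rev(c("W", "REM", "N1", "N2", "N3"))))
    ggplot2::ggplot(df, ggplot2::aes(x = hours, y = stage, group = 1)) +
      ggplot2::geom_step() +
      ggplot2::labs(x = "time (h)", y = NULL, title = "Hypnogram")
  } else {
    df <- tibble(hours = hours, nrem = as.integer(object$label == "NREM23"))
    ggplot2::ggplot(df, ggplot2::aes(x = hours, y = nrem)) +
      ggplot2::geom_step() +
      ggplot2::scale_y_continuous(breaks = c(0, 1),
                                  labels = c("other", "NREM2/3")) +
      ggplot2::labs(x = "time (h)", y = NULL, title = "Detected NREM2/3 sleep")
  }
}

#' Plot matched first/last-hour slope distributions
#'
#' @param object a `matched_waves` object.
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.matched_waves <- function(object, ...) {
  df <- tidy.matched_waves(object)
  df$hour <- factor(toupper(df$hour), levels = c("FH", "LH"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$hour, y = .data$slope_uv_per_s)) +
    ggplot2::geom_violin(fill = "grey85") +
    ggplot2::stat_summary(fun = mean, geom = "point", size = 2) +
    ggplot2::labs(x = NULL, y = "ascending slope (uV/s)",
                  title = "Amplitude-matched slow-wave slopes")
}

#' Plot per-channel spike-wave index
#'
#' @param object a `swi_result`.
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.swi_result <- function(object, ...) {
  df <- tidy.swi_result(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$channel, y = .data$swi_percent,
                                   fill = .data$focus)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "firebrick",
                                          `FALSE` = "grey60")) +
    ggplot2::labs(x = NULL, y = "SWI (% of 10-s NREM intervals with spikes)",
                  title = "Spike-wave index by channel")
}

#' Plot the cohort slope change against the SWI
#'
#' @param object a `cohort_result`.
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.cohort_result <- function(object, ...) {
  df <- object$table[is.finite(object$table$somnidex), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$swi_percent, y = .data$somnidex)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4, colour = "firebrick") +
    ggplot2::labs(x = "SWI (%)", y = "overnight slope change (LH-FH)/FH",
                  title = "Synaptic renormalization vs spike burden")
}
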