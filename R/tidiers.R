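#' @exportS3Method generics::tidy
tidy.somnidex_report <- function(x, ...) {
  tidy_report_row(x)
}

#' @exportS3Method generics::glance
glance.somnidex_report <- function(x, ...) {
  tibble(somnidex = x$somnidex, category = x$category,
         n_matched = x$n_matched, excluded = length(x$exclusion_flags) > 0)
}

#' @exportS3Method generics::tidy
tidy.swi_result <- function(x, ...) {
  dplyr::mutate(x$per_channel, focus = .data$channel == x$focus_channel)
}

#' @exportS3Method generics::tidy
tidy.kappa_result <- function(x, ...) {
  tibble(kappa = x$kappa, landis_koch_label = x$landis_koch_label,
         p_observed = x$p_o, p_expected = x$p_e)
}

#' @exportS3Method generics::tidy
tidy.lstm_net <- function(x, ...) x$history

#' @exportS3Method generics::glance
glance.lstm_net <- function(x, ...) {
  tibble(task = x$task %||% NA_character_,
         layers = paste(x$layer_sizes, collapse = "x"),
         epochs = x$epochs,
         final_train_loss = tail(x$history$train_loss, 1),
         final_val_kappa = tail(x$history$val_kappa, 1),
         seed = x$seed)
}

#' @exportS3Method generics::tidy
tidy.matched_waves <- function(x, ...) {
  dplyr::bind_rows(fh = x$fh, lh = x$lh, .id = "hour")
}

#' @exportS3Method generics::glance
glance.cohort_result <- function(x, ...) {
  rho <- x$correlations$somnidex_vs_swi
  tibble(n = nrow(x$table),
         n_analyzed = sum(is.finite(x$table$somnidex)),
         rho_somnidex_swi = if (is.null(rho)) NA_real_ else rho$rho,
         p_somnidex_swi = if (is.null(rho)) NA_real_ else rho$p_value,
         prop_decrease = x$category_proportions$decrease,
         prop_no_change = x$category_proportions$no_change,
         prop_increase = x$category_proportions$increase)
}
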