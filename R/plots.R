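#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col
#'   geom_hline geom_errorbarh labs theme_minimal facet_wrap coord_flip
#'   scale_y_log10
NULL

#' @export
ggplot2::autoplot

#' Plot a cosinor fit over the observed diurnal profile
#'
#' Shows the subject's hourly mean activity profile with the fitted cosine
#' overlaid; the dashed line marks the MESOR.
#'
#' @param object A `cosinor_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cosinor_fit <- function(object, ...) {
  prof <- tibble::tibble(hour = 0:23 + 0.5, enmo = object$profile)
  tt <- seq(0, 24, by = 0.1)
  fit <- tibble::tibble(
    hour = tt,
    enmo = object$mesor + object$amplitude *
      cos(2 * pi * (tt - (object$acrophase %||% 0)) / object$period))
  ggplot(prof, aes(x = .data$hour, y = .data$enmo)) +
    geom_point(na.rm = TRUE) +
    geom_line(data = fit, colour = "#2166ac") +
    geom_hline(yintercept = object$mesor, linetype = "dashed",
               colour = "grey50") +
    labs(x = "Clock hour", y = "ENMO (mg)",
         title = sprintf("Cosinor fit: A = %.1f mg, acrophase %.1f h",
                         object$amplitude, object$acrophase %||% NA)) +
    theme_minimal()
}

#' Plot global Shapley importance
#'
#' Bars of mean |attribution| per feature, signed colouring by the
#' direction in which higher feature values push the prediction.
#'
#' @param object A `shap_result`.
#' @param top_n Features shown.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.shap_result <- function(object, top_n = 10, ...) {
  d <- utils::head(object$ranking, top_n)
  d$feature <- factor(d$feature, levels = rev(d$feature))
  d$effect <- ifelse(d$direction >= 0, "higher value -> higher risk",
                     "higher value -> lower risk")
  ggplot(d, aes(x = .data$mean_abs, y = .data$feature, fill = .data$effect)) +
    geom_col() +
    labs(x = "Mean |Shapley value|", y = NULL, fill = NULL) +
    theme_minimal()
}

#' Forest plot of sex-stratified mediation hazard ratios
#'
#' @param mediation_table Output of [sex_stratified_mediation()].
#' @return A ggplot (log-scaled HR axis, dashed null line).
#' @export
plot_mediation_forest <- function(mediation_table) {
  d <- mediation_table
  d$row <- paste(d$exposure, toupper(d$effect))
  ggplot(d, aes(x = .data$hr, y = .data$row)) +
    geom_point() +
    geom_errorbarh(aes(xmin = .data$ci_low, xmax = .data$ci_high),
                   height = 0.2, na.rm = TRUE) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    facet_wrap(~sex) +
    ggplot2::scale_x_log10() +
    labs(x = "Hazard ratio (log scale)", y = NULL) +
    theme_minimal()
}
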