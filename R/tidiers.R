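#' @importFrom generics tidy glance
#' @importFrom rlang :=
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a cosinor fit
#'
#' @param x A `cosinor_fit`.
#' @param ... Unused.
#' @return One row per rhythm parameter with `term` and `estimate`.
#' @export
tidy.cosinor_fit <- function(x, ...) {
  tibble::tibble(
    term = c("mesor", "amplitude", "acrophase", "up_mesor", "period"),
    estimate = c(x$mesor, x$amplitude, x$acrophase, x$up_mesor, x$period))
}

#' @rdname tidy.cosinor_fit
#' @return For `glance()`: one row with fit statistics.
#' @export
glance.cosinor_fit <- function(x, ...) {
  tibble::tibble(pseudo_f = x$pseudo_f, rss = x$rss, n = x$n,
                 acrophase_defined = x$acrophase_defined)
}

#' Tidy a Gompertz proportional-hazards fit
#'
#' @param x A `gompertz_ph`.
#' @param ... Unused.
#' @return Tibble of terms (`log_b`, `a` unless shape was fixed, and the
#'   covariate log-hazards) with standard errors where available.
#' @export
tidy.gompertz_ph <- function(x, ...) {
  est <- c(log_b = x$log_b, if (!x$shared_shape) c(a = x$a),
           x$coefficients)
  se <- sqrt(diag(x$vcov))[names(est)]
  tibble::tibble(term = names(est), estimate = unname(est),
                 std_error = unname(se))
}

#' @rdname tidy.gompertz_ph
#' @export
glance.gompertz_ph <- function(x, ...) {
  tibble::tibble(a = x$a, b = x$b, loglik = x$loglik, n = x$n,
                 n_events = x$n_events, horizon = x$horizon, sex = x$sex)
}

#' Tidy a trained aging classifier
#'
#' @param x An `aging_clf`.
#' @param ... Unused.
#' @return The held-out evaluation report (`glance()` returns the same
#'   single row).
#' @export
tidy.aging_clf <- function(x, ...) x$report

#' @rdname tidy.aging_clf
#' @export
glance.aging_clf <- function(x, ...) x$report

#' Tidy a Shapley attribution result
#'
#' @param x A `shap_result`.
#' @param ... Unused.
#' @return The global ranking tibble (feature, mean |attribution|,
#'   direction).
#' @export
tidy.shap_result <- function(x, ...) x$ranking
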