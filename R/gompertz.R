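# Stable Gompertz helpers: g0 = (e^(at)-1)/a (cumulative-hazard shape) and
# its derivative in a; both fall back to series near a = 0.
gomp_g0 <- function(a, t) {
  if (abs(a) < 1e-8) t * (1 + a * t / 2 + (a * t)^2 / 6) else expm1(a * t) / a
}
gomp_dg <- function(a, t) {
  if (abs(a) < 1e-8) t^2 / 2 + a * t^3 / 3 else
    (t * exp(a * t) - gomp_g0(a, t)) / a
}

#' Gompertz proportional-hazards log-likelihood
#'
#' Censored log-likelihood of hazard h(t) = b e^(at) e^(eta):
#' sum delta_i (ln b + a t_i + eta_i) - sum (b/a)(e^(a t_i) - 1) e^(eta_i),
#' with the exponential limit at a = 0.
#'
#' @param a,b Shape (1/year) and rate (1/year).
#' @param eta Linear predictor per subject.
#' @param time,event Follow-up years and 0/1 indicator.
#' @return The log-likelihood value.
#' @export
gompertz_loglik <- function(a, b, eta, time, event) {
  sum(event * (log(b) + a * time + eta)) -
    b * sum(gomp_g0(a, time) * exp(eta))
}

#' Fit a Gompertz proportional-hazards model
#'
#' Maximum likelihood in the unconstrained parameterization (ln b, a, beta)
#' by BFGS with analytic gradients, followed by Newton polishing until the
#' gradient infinity-norm drops below `tol`. Covariates are standardized
#' internally; returned coefficients are on the original scale. `a` is
#' unconstrained and |a| < 1e-8 is evaluated through the exponential-limit
#' series, so the exponential model is the smooth a = 0 special case.
#'
#' @param data Data frame holding time, event, and covariates.
#' @param covariates Character vector of covariate column names (may be
#'   empty for a baseline-only model).
#' @param time,event Column names of follow-up years and the 0/1 indicator.
#' @param horizon Risk horizon in years carried by the model (used by
#'   [cosinor_age()]).
#' @param sex Optional label recording which stratum the model was fit on.
#' @param shape Fix the shape `a` at this value instead of estimating it
#'   (shared-shape mode); `NULL` estimates it.
#' @param weights Optional non-negative case weights (e.g. the expanded
#'   natural-effects weights); default all one.
#' @param tol Gradient infinity-norm convergence tolerance.
#' @return A `gompertz_ph` object with elements `a`, `b`, `log_b`,
#'   `coefficients`, `vcov`, `loglik`, `n`, `n_events`, `horizon`, `sex`.
#' @export
fit_gompertz_ph <- function(data, covariates = character(), time = "time",
                            event = "event", horizon = 5, sex = NA_character_,
                            shape = NULL, weights = NULL, tol = 1e-8) {
  assert_cols(data, c(time, event, covariates), "survival data")
  tt <- as.numeric(data[[time]]); dd <- as.integer(data[[event]])
  w <- if (is.null(weights)) rep(1, length(tt)) else as.numeric(weights)
  stopifnot(length(w) == length(tt), all(w >= 0))
  if (any(tt <= 0)) abort("all survival times must be > 0")
  if (!all(dd %in% c(0L, 1L))) abort("event must be 0/1")
  if (sum(dd) < 1) abort("no events in the data")
  # (weights enter the likelihood; the event check is on raw counts)
  p <- length(covariates)
  X <- if (p) as.matrix(data[, covariates, drop = FALSE]) else
    matrix(0, length(tt), 0)
  mu <- if (p) colMeans(X) else numeric(0)
  sdv <- if (p) apply(X, 2, sd) else numeric(0)
  if (p && any(sdv == 0)) abort("constant covariate(s) supplied")
  Z <- if (p) sweep(sweep(X, 2, mu), 2, sdv, "/") else X

  fixed_a <- !is.null(shape)
  # theta = (ln b, [a], beta_std)
  nll <- function(th) {
    lb <- th[1]; a <- if (fixed_a) shape else th[2]
    be <- th[(2 + !fixed_a):length(th)]
    if (p == 0) be <- numeric(0)
    eta <- if (p) as.numeric(Z %*% be) else rep(0, length(tt))
    -(sum(w * dd * (lb + a * tt + eta)) -
        exp(lb) * sum(w * gomp_g0(a, tt) * exp(eta)))
  }
  grd <- function(th) {
    lb <- th[1]; a <- if (fixed_a) shape else th[2]
    be <- th[(2 + !fixed_a):length(th)]
    if (p == 0) be <- numeric(0)
    eta <- if (p) as.numeric(Z %*% be) else rep(0, length(tt))
    g0 <- gomp_g0(a, tt)
    H <- exp(lb) * g0 * exp(eta)
    g_lb <- sum(w * dd) - sum(w * H)
    out <- g_lb
    if (!fixed_a) {
      dg <- gomp_dg(a, tt)
      out <- c(out, sum(w * dd * tt) - exp(lb) * sum(w * dg * exp(eta)))
    }
    if (p) out <- c(out, as.numeric(crossprod(Z, w * (dd - H))))
    -out
  }

  b0 <- sum(w * dd) / sum(w * tt)
  th <- c(log(b0), if (!fixed_a) 0.02, rep(0, p))
  opt <- optim(th, nll, grd, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
  th <- opt$par
  # Newton polish to hit the gradient tolerance
  for (it in 1:50) {
    g <- grd(th)
    if (max(abs(g)) < tol) break
    Hm <- stats::optimHess(th, nll, grd)
    step <- tryCatch(solve(Hm, g), error = function(e) g * 1e-4)
    th_new <- th - step
    if (!is.finite(nll(th_new)) || nll(th_new) > nll(th) + 1e-9) {
      th_new <- th - 0.5 * step
      if (!is.finite(nll(th_new)) || nll(th_new) > nll(th)) break
    }
    th <- th_new
  }
  g <- grd(th)
  if (max(abs(g)) > 1e-4)
    abort(sprintf("Gompertz fit did not converge (grad inf-norm %.2e)",
                  max(abs(g))))

  lb_s <- th[1]; a_hat <- if (fixed_a) shape else th[2]
  be_s <- if (p) th[(2 + !fixed_a):length(th)] else numeric(0)
  beta <- if (p) be_s / sdv else numeric(0)
  log_b <- lb_s - if (p) sum(be_s * mu / sdv) else 0
  names(beta) <- covariates

  Hm <- stats::optimHess(th, nll, grd)
  V_std <- tryCatch(solve(Hm), error = function(e) matrix(NA, length(th), length(th)))
  k <- length(th)
  J <- diag(k)
  if (p) {
    idx <- (2 + !fixed_a):k
    J[1, idx] <- -mu / sdv
    for (j in seq_len(p)) J[idx[j], idx[j]] <- 1 / sdv[j]
  }
  V <- J %*% V_std %*% t(J)
  nm <- c("log_b", if (!fixed_a) "a", covariates)
  dimnames(V) <- list(nm, nm)

  structure(list(a = a_hat, b = exp(log_b), log_b = log_b,
                 coefficients = beta, covariates = covariates,
                 vcov = V, loglik = -nll(th), n = length(tt),
                 n_events = sum(dd), horizon = horizon, sex = sex,
                 shared_shape = fixed_a,
                 grad_norm = max(abs(g)), iterations = opt$counts[1]),
            class = "gompertz_ph")
}

#' @export
print.gompertz_ph <- function(x, ...) {
  cat(sprintf("<gompertz_ph> a = %.4f /y, b = %.3e /y, %d covariate(s), %d/%d events\n",
              x$a, x$b, length(x$coefficients), x$n_events, x$n))
  if (length(x$coefficients)) print(round(x$coefficients, 4))
  invisible(x)
}

# Cumulative hazard H(t) = b g0(a, t) e^eta for a fitted model.
gompertz_cumhaz <- function(model, data, t) {
  eta <- gompertz_eta(model, data)
  model$b * gomp_g0(model$a, t) * exp(eta)
}

gompertz_eta <- function(model, data) {
  if (!length(model$coefficients)) return(rep(0, nrow(data)))
  assert_cols(data, model$covariates, "newdata")
  as.numeric(as.matrix(data[, model$covariates, drop = FALSE]) %*%
               model$coefficients)
}

#' Biological age by equating Gompertz mortality risks (CosinorAge)
#'
#' Biological age is the age at which the age-only Gompertz model predicts
#' the same cumulative mortality hazard over the risk horizon as the
#' rhythm-augmented model predicts for the subject:
#' H_full(t*; x_i) = H_only(t*; BA_i). On the log scale this is linear in
#' age, giving the closed form
#' BA = (ln(b_f g0(a_f, t*)) + eta_full - ln(b_o g0(a_o, t*))) / gamma_age,
#' where gamma_age is the age-only model's age coefficient. Age
#' acceleration is AA = BA - CA; positive AA is accelerated aging.
#'
#' @param full Rhythm-plus-age `gompertz_ph` model.
#' @param age_only Age-only `gompertz_ph` model (single covariate).
#' @param data Data frame with the full model's covariates, including the
#'   age column used by `age_only`.
#' @param horizon Risk horizon t* in years; defaults to the models' shared
#'   horizon.
#' @return Tibble: `subject_id` (when present), `ba`, `ca`, `aa`,
#'   `accelerated`.
#' @export
cosinor_age <- function(full, age_only, data, horizon = NULL) {
  if (length(age_only$coefficients) != 1)
    abort("age_only model must have exactly one covariate (age)")
  age_col <- age_only$covariates
  gamma <- unname(age_only$coefficients)
  if (gamma <= 0) abort("age coefficient of the age-only model must be > 0")
  tstar <- horizon %||% full$horizon %||% 5
  eta_f <- gompertz_eta(full, data)
  ba <- (log(full$b * gomp_g0(full$a, tstar)) + eta_f -
           log(age_only$b * gomp_g0(age_only$a, tstar))) / gamma
  ca <- as.numeric(data[[age_col]])
  out <- tibble::tibble(ba = ba, ca = ca, aa = ba - ca,
                        accelerated = ba - ca > 0)
  if ("subject_id" %in% names(data))
    out <- dplyr::bind_cols(tibble::tibble(subject_id = data$subject_id), out)
  out
}

#' Sex-specific CosinorAge
#'
#' Applies per-sex model pairs (the convention of the underlying biological
#' age metric, which carries sex-specific weights) and binds the results.
#'
#' @param models Named list: for each sex label, `list(full =, age_only =)`.
#' @param data Data frame including a `sex` column matching the names.
#' @param sex_col Name of the sex column.
#' @return Tibble as in [cosinor_age()].
#' @export
cosinor_age_by_sex <- function(models, data, sex_col = "sex") {
  assert_cols(data, sex_col, "data")
  parts <- lapply(names(models), function(sx) {
    d <- data[data[[sex_col]] == sx, , drop = FALSE]
    if (!nrow(d)) return(NULL)
    cosinor_age(models[[sx]]$full, models[[sx]]$age_only, d)
  })
  dplyr::bind_rows(parts)
}

#' Age-acceleration stratum labels
#'
#' Right-closed bins: (<= -5\], (-5, -3\], (-3, 0\], (0, 3\], (3, 5\], (> 5).
#'
#' @param aa Numeric age-acceleration values (BA - CA, years).
#' @return Ordered factor of stratum labels.
#' @export
aa_stratum <- function(aa) {
  cut(aa, breaks = c(-Inf, -5, -3, 0, 3, 5, Inf),
      labels = c("AA<=-5", "-5<AA<=-3", "-3<AA<=0", "0<AA<=3", "3<AA<=5",
                 "AA>5"),
      right = TRUE, ordered_result = TRUE)
}

#' Feature medians across age-acceleration strata
#'
#' The tabular analogue of stratified activity heatmaps: per age
#' acceleration stratum (and optional phenotype grouping), the median of
#' each requested feature.
#'
#' @param data Data frame with an age-acceleration column and features.
#' @param features Character vector of feature columns to summarize.
#' @param by Optional extra grouping column (e.g. a rhythm-regularity or
#'   MVPA phenotype, or sex).
#' @param aa_col Name of the age-acceleration column.
#' @return Tibble of per-stratum medians and group sizes.
#' @export
stratify_age_acceleration <- function(data, features, by = NULL,
                                      aa_col = "aa") {
  assert_cols(data, c(aa_col, features, by), "data")
  d <- dplyr::mutate(data, .stratum = aa_stratum(.data[[aa_col]]))
  grp <- c(".stratum", by)
  d |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(n = dplyr::n(),
                     dplyr::across(dplyr::all_of(features),
                                   ~ median(.x, na.rm = TRUE),
                                   .names = "median_{.col}"),
                     .groups = "drop")
}

#' Construct a Gompertz PH model from supplied coefficients
#'
#' Builds a `gompertz_ph` object from externally published weights (e.g. a
#' validated biological-age coefficient set) so that [cosinor_age()] can be
#' applied without refitting.
#'
#' @param a Shape (1/year).
#' @param b Rate (1/year, > 0).
#' @param coefficients Named log-hazard coefficients.
#' @param horizon Risk horizon in years.
#' @param sex Optional stratum label.
#' @return A `gompertz_ph` object.
#' @export
gompertz_model <- function(a, b, coefficients, horizon = 5,
                           sex = NA_character_) {
  stopifnot(is.numeric(a), length(a) == 1, b > 0,
            !is.null(names(coefficients)))
  structure(list(a = a, b = b, log_b = log(b),
                 coefficients = coefficients,
                 covariates = names(coefficients), vcov = NULL,
                 loglik = NA_real_, n = NA_integer_, n_events = NA_integer_,
                 horizon = horizon, sex = sex, shared_shape = FALSE,
                 grad_norm = NA_real_, iterations = NA_integer_),
            class = "gompertz_ph")
}
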