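#' Z-score a numeric vector
#'
#' Centers to mean 0 and scales to sample SD 1.
#'
#' @param values Numeric vector with positive variance.
#' @return Standardized vector.
#' @export
zscore <- function(values) {
  s <- sd(values)
  if (!is.finite(s) || s == 0) abort("cannot z-score: zero variance")
  (values - mean(values)) / s
}

#' Quartile groups with an adverse-exposure trend code
#'
#' Cuts a feature at its sample quartiles (linear-interpolation
#' percentiles; values equal to a cut fall in the lower group). Labels run
#' Q1..Q4 where Q1 is the adverse extreme (by default the lowest values:
#' low amplitude, poor regularity); Q4 is the favorable reference. The
#' numeric trend code runs 0 (Q4) to 3 (Q1), so a positive regression
#' coefficient means a per-quartile move toward the adverse extreme is
#' associated with higher outcome.
#'
#' @param feature Numeric vector (>= 8 observations).
#' @param direction `"low_is_adverse"` (default) or `"high_is_adverse"`.
#' @return Tibble: `quartile` (factor Q1..Q4, reference Q4), `trend`
#'   (0..3).
#' @export
quartile_groups <- function(feature,
                            direction = c("low_is_adverse", "high_is_adverse")) {
  direction <- match.arg(direction)
  if (length(feature) < 8) abort("need at least 8 observations")
  cuts <- pct(feature, c(0.25, 0.5, 0.75))
  # ties at a boundary go to the lower group: strict > moves you up
  grp_low <- findInterval(feature, cuts, left.open = TRUE) + 1L  # 1..4 by value
  if (any(tabulate(grp_low, 4) == 0)) {
    empty <- which(tabulate(grp_low, 4) == 0)
    abort(sprintf("quartile cut %s is empty (massive ties)",
                  paste(empty, collapse = ",")))
  }
  q_adverse <- if (direction == "low_is_adverse") grp_low else 5L - grp_low
  lab <- factor(paste0("Q", q_adverse), levels = c("Q4", "Q3", "Q2", "Q1"))
  tibble::tibble(quartile = lab, trend = 4 - q_adverse)
}

#' Gaussian GLM for z-scored SII on an exposure
#'
#' Identity-link Gaussian fit by least squares on complete cases, with
#' Wald 95% confidence intervals and p-values. Coefficients are in SD
#' units of the (z-scored) outcome. Factor covariates are expanded against
#' their reference levels; rank deficiency raises an error naming the
#' collinear terms.
#'
#' @param data Data frame.
#' @param outcome Name of the (already z-scored) outcome column.
#' @param exposure Name of the exposure column (factor, quartile trend, or
#'   continuous).
#' @param covariates Character vector of adjustment columns.
#' @param subset Optional logical vector for stratified fits (e.g. one
#'   sex).
#' @return A `sii_glm` tibble: `term`, `beta`, `ci_low`, `ci_high`, `p`,
#'   `n`; exposure rows flagged in `is_exposure`.
#' @export
fit_sii_glm <- function(data, outcome, exposure, covariates = character(),
                        subset = NULL) {
  assert_cols(data, c(outcome, exposure, covariates), "data")
  d <- data[, c(outcome, exposure, covariates)]
  if (!is.null(subset)) d <- d[subset, , drop = FALSE]
  d <- d[complete.cases(d), , drop = FALSE]
  # covariates that are constant in this (sub)sample carry no information
  # and would break the factor expansion
  const <- covariates[vapply(covariates,
                             function(v) length(unique(d[[v]])) < 2, TRUE)]
  covariates <- setdiff(covariates, const)
  f <- as.formula(paste(outcome, "~",
                        paste(c(exposure, covariates), collapse = " + ")))
  fit <- lm(f, data = d)
  if (any(is.na(coef(fit)))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    abort(sprintf("rank-deficient design; collinear term(s): %s",
                  paste(bad, collapse = ", ")))
  }
  sm <- suppressWarnings(summary(fit))$coefficients
  z <- qnorm(0.975)
  out <- tibble::tibble(
    term = rownames(sm),
    beta = sm[, 1],
    ci_low = sm[, 1] - z * sm[, 2],
    ci_high = sm[, 1] + z * sm[, 2],
    p = 2 * pnorm(-abs(sm[, 1] / sm[, 2])),
    n = nrow(d),
    is_exposure = startsWith(rownames(sm), exposure))
  class(out) <- c("sii_glm", class(out))
  out
}

#' Joint-exposure (interaction) GLM for z-scored SII
#'
#' Crosses two binary adverse-exposure factors into a four-level joint
#' factor whose reference is the doubly favorable cell, and fits the
#' Gaussian GLM with a reduced covariate set. Returns the three cell
#' contrasts against the reference.
#'
#' @param data Data frame.
#' @param outcome Z-scored outcome column name.
#' @param factor_a,factor_b Names of binary (0/1 or logical) adverse
#'   exposure columns; 1 = adverse.
#' @param covariates Adjustment columns.
#' @return A `sii_glm` tibble restricted to the joint-factor contrasts
#'   (plus covariates, flagged by `is_exposure`).
#' @export
fit_interaction_glm <- function(data, outcome, factor_a, factor_b,
                                covariates = character()) {
  assert_cols(data, c(outcome, factor_a, factor_b, covariates), "data")
  a <- as.integer(as.logical(data[[factor_a]]))
  b <- as.integer(as.logical(data[[factor_b]]))
  lev <- c("fav_fav", "fav_adv", "adv_fav", "adv_adv")
  joint <- factor(lev[1 + b + 2 * a], levels = lev)
  if (length(unique(b)) == 1) joint <- droplevels(joint)
  d <- dplyr::bind_cols(data, tibble::tibble(.joint = joint))
  cells <- table(joint)
  if (any(cells == 0))
    abort(sprintf("empty joint-exposure cell(s): %s",
                  paste(names(cells)[cells == 0], collapse = ", ")))
  fit_sii_glm(d, outcome, ".joint", covariates)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjustment with monotonicity enforcement (delegates to
#' [stats::p.adjust()]); order-preserving.
#'
#' @param pvalues Numeric p-values in (0, 1\].
#' @return Adjusted p-values.
#' @export
bh_fdr <- function(pvalues) p.adjust(pvalues, method = "BH")

#' Sensitivity filter: drop shift workers and/or sleep-disturbed subjects
#'
#' @param cohort Data frame with logical `shift_work` and/or
#'   `sleep_disturbance` columns.
#' @param exclude_shift_work,exclude_sleep_disturbance Which filters to
#'   apply.
#' @return Filtered tibble; removal counts in attribute `"removed"`.
#' @export
sensitivity_filter <- function(cohort, exclude_shift_work = FALSE,
                               exclude_sleep_disturbance = FALSE) {
  keep <- rep(TRUE, nrow(cohort))
  removed <- c(shift_work = 0L, sleep_disturbance = 0L)
  if (exclude_shift_work) {
    assert_cols(cohort, "shift_work", "cohort")
    removed["shift_work"] <- sum(cohort$shift_work & keep)
    keep <- keep & !cohort$shift_work
  }
  if (exclude_sleep_disturbance) {
    assert_cols(cohort, "sleep_disturbance", "cohort")
    removed["sleep_disturbance"] <- sum(cohort$sleep_disturbance & keep)
    keep <- keep & !cohort$sleep_disturbance
  }
  out <- dplyr::as_tibble(cohort[keep, , drop = FALSE])
  if (!any(keep)) warn("all rows removed by sensitivity filter")
  attr(out, "removed") <- removed
  out
}

#' Main-effects association table for SII
#'
#' Builds the standard association table: relative-amplitude and
#' interdaily-stability quartiles (Q4 reference) and their per-quartile
#' trends, plus sex-stratified insufficient-MVPA contrasts, with BH-FDR
#' across the family of exposure rows.
#'
#' @param data Cohort tibble containing `sii`, wearable features, and
#'   covariates.
#' @param covariates Adjustment set for the main effects.
#' @param ra_col,is_col,mvpa_col Feature column names.
#' @return Tibble of exposure rows: `exposure`, `term`, `beta`, `ci_low`,
#'   `ci_high`, `p`, `p_adj`.
#' @export
sii_association_table <- function(data, covariates,
                                  ra_col = "relative_amplitude",
                                  is_col = "interdaily_stability",
                                  mvpa_col = "mvpa_hours") {
  d <- dplyr::as_tibble(data)
  d$sii_z <- zscore(d$sii)
  qa <- quartile_groups(d[[ra_col]]); qi <- quartile_groups(d[[is_col]])
  d$ra_q <- qa$quartile; d$ra_trend <- qa$trend
  d$is_q <- qi$quartile; d$is_trend <- qi$trend
  d$insufficient <- as.integer(d[[mvpa_col]] * 60 * 7 < 150)

  cov_ra <- union(covariates, mvpa_col)
  cov_is <- union(covariates, mvpa_col)
  cov_mv <- setdiff(union(covariates, is_col), "sex")

  pick <- function(res, exposure)
    dplyr::mutate(dplyr::filter(res, .data$is_exposure), exposure = exposure,
                  .before = 1)
  rows <- dplyr::bind_rows(
    pick(fit_sii_glm(d, "sii_z", "ra_trend", cov_ra), "relative_amplitude_trend"),
    pick(fit_sii_glm(d, "sii_z", "ra_q", cov_ra), "relative_amplitude_quartile"),
    pick(fit_sii_glm(d, "sii_z", "is_trend", cov_is), "interdaily_stability_trend"),
    pick(fit_sii_glm(d, "sii_z", "is_q", cov_is), "interdaily_stability_quartile"),
    pick(fit_sii_glm(d, "sii_z", "insufficient", cov_mv,
                     subset = d$sex == "male"), "insufficient_mvpa_male"),
    pick(fit_sii_glm(d, "sii_z", "insufficient", cov_mv,
                     subset = d$sex == "female"), "insufficient_mvpa_female"))
  rows$p_adj <- bh_fdr(rows$p)
  dplyr::select(rows, -"is_exposure")
}
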