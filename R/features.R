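#' Functional PCA of averaged 24-h activity profiles
#'
#' Eigendecomposition (via [stats::prcomp()]) of the subjects-by-time matrix
#' of average 24-h profiles, column-centered. Components capture dominant
#' modes of diurnal shape; the first is typically an overall-level mode
#' highly correlated with cosinor amplitude, so downstream feature vectors
#' keep only components 2-4. Component signs are fixed so the loading of
#' largest magnitude in each component is positive.
#'
#' @param profiles Numeric matrix or data frame, subjects x time-of-day.
#' @param n_components Components to return.
#' @param smooth_min Optional circular rolling-mean smoothing of each
#'   profile before decomposition, minutes (0 = none), assuming 1440
#'   columns per day.
#' @return List with `scores` (tibble, `fpc1..fpck`), `components`
#'   (time x k loadings), `explained_variance` (fraction per component),
#'   `center` (mean profile).
#' @export
fpca_profiles <- function(profiles, n_components = 4, smooth_min = 0) {
  m <- as.matrix(profiles)
  if (nrow(m) < n_components + 1)
    abort("need more subjects than components")
  if (smooth_min > 0) {
    k <- max(1, round(smooth_min * ncol(m) / 1440))
    m <- t(apply(m, 1, roll_window_mean, k = k))
  }
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE, rank. = n_components)
  rot <- pc$rotation
  sc <- pc$x
  for (k in seq_len(ncol(rot))) {
    j <- which.max(abs(rot[, k]))
    if (rot[j, k] < 0) { rot[, k] <- -rot[, k]; sc[, k] <- -sc[, k] }
  }
  tot <- sum(pc$sdev^2)
  ev <- if (tot > 0) pc$sdev[seq_len(n_components)]^2 / tot else
    rep(0, n_components)
  scores <- tibble::as_tibble(sc, .name_repair = "minimal")
  names(scores) <- paste0("fpc", seq_len(ncol(scores)))
  list(scores = scores, components = rot, explained_variance = ev,
       center = pc$center)
}

#' Average 24-h activity profile of one subject
#'
#' @param series Epoch tibble.
#' @return Numeric vector (one value per epoch-of-day) of mean wear ENMO.
#' @export
mean_24h_profile <- function(series) {
  ck <- series_clock(series)
  wear <- series_wear(series) & is.finite(series$enmo_mg)
  per_day <- round(86400 / ck$epoch_s)
  slot <- floor(ck$tod[wear] / 24 * per_day) + 1L
  prof <- rep(NA_real_, per_day)
  agg <- grp_mean(series$enmo_mg[wear], slot)
  prof[as.integer(names(agg))] <- as.numeric(agg)
  prof
}

#' Extract the per-subject wearable feature vector
#'
#' Runs the cosinor fit, day-level variability, nonparametric metrics,
#' intensity features, DFA and the sleep detector on one epoch series and
#' returns a single feature row. fPCA scores are cohort-level and are added
#' by [cohort_features()].
#'
#' @param series Epoch tibble for one subject.
#' @param period_search Search for the best-fitting cosinor period.
#' @param mvpa_cut,sed_cut,rest_threshold Thresholds in mg.
#' @return One-row tibble of named features, with the subject's average
#'   24-h profile attached as attribute `"profile"`.
#' @export
extract_features <- function(series, period_search = FALSE,
                             mvpa_cut = 100, sed_cut = 40,
                             rest_threshold = 10) {
  fit <- fit_cosinor(series, period_search = period_search)
  cvs <- suppressWarnings(daily_cosinor_cv(series))
  np <- nonparametric_metrics(series)
  int <- intensity_features(series, mvpa_cut = mvpa_cut, sed_cut = sed_cut)
  dfa <- dfa_exponents(series)
  slp <- tryCatch(sleep_metrics(series, rest_threshold = rest_threshold),
                  error = function(e) tibble::tibble(
                    sleep_onset = NA_real_, sleep_duration = NA_real_,
                    sleep_efficiency = NA_real_, sleep_duration_sd = NA_real_,
                    irregular_sleep = NA_integer_))
  out <- dplyr::bind_cols(
    tibble::tibble(
      subject_id = series$subject_id[1] %||% NA_character_,
      mesor = fit$mesor,
      cosinor_amplitude = fit$amplitude,
      acrophase = fit$acrophase,
      up_mesor = fit$up_mesor,
      pseudo_f = fit$pseudo_f,
      cosinor_amplitude_cv = cvs$amplitude_cv,
      acrophase_cv = cvs$acrophase_cv,
      up_mesor_cv = cvs$up_mesor_cv,
      relative_amplitude_cv = cvs$relative_amplitude_cv),
    np[, c("interdaily_stability", "intradaily_variability",
           "relative_amplitude", "m10", "l5")],
    int[, c("mvpa_hours", "mvpa_cv", "weekly_mvpa_min", "insufficient_mvpa",
            "sedentary_hours", "sedentary_cv", "intensity_gradient")],
    dfa[, c("dfa1", "dfa2")],
    slp[, c("sleep_onset", "sleep_duration", "sleep_efficiency",
            "sleep_duration_sd", "irregular_sleep")])
  attr(out, "profile") <- mean_24h_profile(series)
  out
}

#' Extract features for a whole cohort, with regularity screen and fPCA
#'
#' Maps [extract_features()] over the cohort's subjects (regenerating epoch
#' series from the generator config when the bundle was built without
#' them), applies the IS/IV regularity screen, runs fPCA on the retained
#' subjects' average 24-h profiles, and appends the fpc2-fpc4 scores.
#'
#' @param cohort A `rar_cohort` bundle.
#' @param screen Apply [regularity_screen()] before fPCA.
#' @param ... Passed to [extract_features()].
#' @return Tibble of retained subjects' features; excluded subject ids in
#'   attribute `"excluded"`, the fPCA object in attribute `"fpca"`.
#' @export
cohort_features <- function(cohort, screen = TRUE, ...) {
  n <- cohort$config$n_subjects
  ids <- cohort$truth$subject_id
  rows <- vector("list", n)
  profs <- vector("list", n)
  for (i in seq_len(n)) {
    s <- subject_series(cohort, i)
    fr <- extract_features(s, ...)
    profs[[i]] <- attr(fr, "profile")
    rows[[i]] <- fr
  }
  feats <- dplyr::bind_rows(rows)
  keep <- if (screen) suppressWarnings(regularity_screen(feats)) else
    rep(TRUE, n)
  pm <- do.call(rbind, profs[keep])
  pm[is.na(pm)] <- 0
  fp <- fpca_profiles(pm, n_components = 4)
  out <- dplyr::bind_cols(feats[keep, ],
                          fp$scores[, c("fpc2", "fpc3", "fpc4")])
  attr(out, "excluded") <- ids[!keep]
  attr(out, "fpca") <- fp
  attr(out, "screen_thresholds") <- attr(keep, "thresholds")
  out
}

# One subject's epoch series from a bundle, regenerating when not stored.
subject_series <- function(cohort, i) {
  if (!is.null(cohort$epochs)) return(cohort$epochs[[i]])
  simulate_subject_series(cohort$config, cohort$truth[i, ],
                          derive_seed(cohort$config$seed, 10L + i))
}
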