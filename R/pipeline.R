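PIPELINE_STAGES <- c("simulate", "features", "cosinorage", "ml", "assoc",
                     "mediate", "report")

#' Configuration for the end-to-end pipeline
#'
#' @param n_subjects Cohort size of the demo run.
#' @param seed Master seed; every stochastic stage derives its stream from
#'   it.
#' @param out_dir Artifact directory.
#' @param stages Stages to run, in dependency order.
#' @param model Classifier family for the ml stage.
#' @param mrmr_k Features kept by MRMR.
#' @param n_boot Bootstrap replicates in the mediation stage.
#' @param n_shap_instances,n_shap_background,n_shap_perm Shapley sampling
#'   sizes.
#' @param generator Optional [generator_config()] override (its
#'   `n_subjects` and `seed` are replaced by the pipeline's).
#' @param log_level `"info"` or `"quiet"`.
#' @return A `rar_run_config` list.
#' @export
pipeline_config <- function(n_subjects = 2000, seed = 1L,
                            out_dir = tempfile("rhythmage_run_"),
                            stages = PIPELINE_STAGES,
                            model = "xgboost", mrmr_k = 25, n_boot = 200,
                            n_shap_instances = 60, n_shap_background = 40,
                            n_shap_perm = 30,
                            generator = NULL, log_level = "info") {
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad)) abort(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")))
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]
  gen <- generator %||% generator_config()
  gen$n_subjects <- n_subjects
  gen$seed <- as.integer(seed)
  structure(list(n_subjects = n_subjects, seed = as.integer(seed),
                 out_dir = out_dir, stages = stages, model = model,
                 mrmr_k = mrmr_k, n_boot = n_boot,
                 n_shap_instances = n_shap_instances,
                 n_shap_background = n_shap_background,
                 n_shap_perm = n_shap_perm,
                 generator = gen, log_level = log_level),
            class = "rar_run_config")
}

plog <- function(cfg, fmt, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  message(sprintf(paste0("[rhythmage] ", fmt), ...))
}

stage_inputs <- list(
  simulate = character(),
  features = c("ground_truth.csv", "config.json"),
  cosinorage = c("features.csv", "covariates.csv", "survival.csv"),
  ml = c("features.csv", "aging.csv"),
  assoc = c("features.csv", "covariates.csv", "blood_counts.csv"),
  mediate = c("features.csv", "covariates.csv", "blood_counts.csv",
              "survival.csv"),
  report = c("features.csv", "covariates.csv", "aging.csv"))

stage_of_artifact <- c(
  "ground_truth.csv" = "simulate", "config.json" = "simulate",
  "covariates.csv" = "simulate", "blood_counts.csv" = "simulate",
  "survival.csv" = "simulate", "features.csv" = "features",
  "aging.csv" = "cosinorage")

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Orchestrates simulate -> features -> cosinorage -> ml -> assoc ->
#' mediate -> report. Each stage writes CSV/JSON artifacts into the
#' config's output directory plus a manifest row (stage, artifacts, MD5
#' hashes, duration, n in/out); re-running with an identical config and
#' seed reproduces identical artifacts. Requesting a downstream stage
#' whose inputs are missing raises an error naming the stage that should
#' have produced them.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the manifest tibble (also written to
#'   `manifest.csv`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "rar_run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  art <- function(f) file.path(config$out_dir, f)
  for (st in config$stages) {
    need <- stage_inputs[[st]]
    missing <- need[!file.exists(art(need))]
    if (length(missing))
      abort(sprintf(
        "stage '%s' is missing upstream artifact(s) %s from stage '%s'",
        st, paste(missing, collapse = ", "),
        stage_of_artifact[[missing[1]]]))
    t0 <- proc.time()[3]
    written <- switch(st,
      simulate = stage_simulate(config),
      features = stage_features(config),
      cosinorage = stage_cosinorage(config),
      ml = stage_ml(config),
      assoc = stage_assoc(config),
      mediate = stage_mediate(config),
      report = stage_report(config))
    secs <- proc.time()[3] - t0
    rows <- tibble::tibble(
      stage = st, artifact = basename(written),
      md5 = unname(tools::md5sum(written)),
      seconds = round(secs, 2))
    mpath <- art("manifest.csv")
    prev <- if (file.exists(mpath))
      readr::read_csv(mpath, show_col_types = FALSE) else NULL
    manifest <- dplyr::bind_rows(
      dplyr::filter(prev %||% rows[0, ], !.data$stage %in% st), rows)
    readr::write_csv(manifest, mpath)
    plog(config, "stage %-10s done in %6.1fs (%d artifact(s))", st, secs,
         length(written))
  }
  invisible(readr::read_csv(art("manifest.csv"), show_col_types = FALSE))
}

stage_simulate <- function(cfg) {
  cohort <- simulate_cohort(cfg$generator, include_epochs = FALSE)
  paths <- write_cohort_csv(cohort, cfg$out_dir)
  cj <- file.path(cfg$out_dir, "config.json")
  jsonlite::write_json(unclass(cfg$generator), cj, auto_unbox = TRUE,
                       digits = NA)
  plog(cfg, "simulate: %d subjects, %d deaths (%.1f%%)",
       nrow(cohort$survival), sum(cohort$survival$event),
       100 * mean(cohort$survival$event))
  c(unname(paths), cj)
}

read_generator_config <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- generator_config()
  for (nm in names(g)) cfg[[nm]] <- if (is.list(cfg[[nm]]) && !is.list(g[[nm]]))
    as.list(g[[nm]]) else g[[nm]]
  cfg
}

# Rebuild the cohort bundle from the simulate artifacts (epoch traces are
# regenerated deterministically from the seeded config).
load_cohort <- function(cfg) {
  rd <- function(f) readr::read_csv(file.path(cfg$out_dir, f),
                                    show_col_types = FALSE)
  gen <- read_generator_config(file.path(cfg$out_dir, "config.json"))
  structure(list(epochs = NULL, covariates = rd("covariates.csv"),
                 blood = rd("blood_counts.csv"),
                 survival = rd("survival.csv"), truth = rd("ground_truth.csv"),
                 config = gen), class = "rar_cohort")
}

stage_features <- function(cfg) {
  cohort <- load_cohort(cfg)
  feats <- cohort_features(cohort)
  plog(cfg, "features: %d in, %d retained after regularity screen",
       cohort$config$n_subjects, nrow(feats))
  fp <- file.path(cfg$out_dir, "features.csv")
  readr::write_csv(feats, fp)
  ex <- file.path(cfg$out_dir, "excluded_subjects.csv")
  readr::write_csv(tibble::tibble(subject_id = attr(feats, "excluded")), ex)
  c(fp, ex)
}

stage_cosinorage <- function(cfg) {
  rd <- function(f) readr::read_csv(file.path(cfg$out_dir, f),
                                    show_col_types = FALSE)
  d <- rd("features.csv") |>
    dplyr::inner_join(rd("covariates.csv"), by = "subject_id") |>
    dplyr::inner_join(rd("survival.csv"), by = "subject_id")
  rhythm <- c("mesor", "cosinor_amplitude", "acrophase")
  # sex-specific weights need enough events per stratum; small demo
  # cohorts fall back to pooled models
  ev <- tapply(d$event, d$sex, sum)
  if (length(ev) == 2 && min(ev) >= 15) {
    models <- lapply(split(d, d$sex), function(ds) {
      list(full = fit_gompertz_ph(ds, c(rhythm, "age"), sex = ds$sex[1]),
           age_only = fit_gompertz_ph(ds, "age", sex = ds$sex[1]))
    })
    aging <- cosinor_age_by_sex(models, d)
  } else {
    plog(cfg, "cosinorage: < 15 events in a sex stratum; pooled models")
    pooled <- list(full = fit_gompertz_ph(d, c(rhythm, "age"), sex = "pooled"),
                   age_only = fit_gompertz_ph(d, "age", sex = "pooled"))
    models <- list(pooled = pooled)
    aging <- cosinor_age(pooled$full, pooled$age_only, d)
  }
  plog(cfg, "cosinorage: %d subjects, %.1f%% accelerated", nrow(aging),
       100 * mean(aging$accelerated))
  ap <- file.path(cfg$out_dir, "aging.csv")
  readr::write_csv(aging, ap)
  mj <- file.path(cfg$out_dir, "cosinorage_models.json")
  jsonlite::write_json(lapply(models, function(m) lapply(m, function(g)
    list(a = g$a, log_b = g$log_b, coefficients = as.list(g$coefficients),
         horizon = g$horizon, sex = g$sex, n = g$n, n_events = g$n_events))),
    mj, auto_unbox = TRUE, digits = NA)
  c(ap, mj)
}

ml_feature_cols <- function(feats) {
  drop <- c("subject_id", "weekly_mvpa_min", "m10", "l5")
  nm <- setdiff(names(feats), drop)
  nm[vapply(feats[nm], is.numeric, TRUE)]
}

stage_ml <- function(cfg) {
  rd <- function(f) readr::read_csv(file.path(cfg$out_dir, f),
                                    show_col_types = FALSE)
  feats <- rd("features.csv")
  aging <- rd("aging.csv")
  d <- dplyr::inner_join(feats, aging[, c("subject_id", "accelerated")],
                         by = "subject_id")
  xcols <- ml_feature_cols(feats)
  x <- d[, xcols]
  x <- x[, colSums(is.na(x)) == 0 & vapply(x, sd, 0) > 0]
  y <- as.integer(d$accelerated)

  pr <- spearman_prune(x, y)
  x2 <- x[, pr$feature[pr$retained]]
  k <- min(cfg$mrmr_k, ncol(x2))
  mr <- mrmr_select(x2, y, k = k)
  xsel <- x2[, mr$feature]

  clf <- train_and_evaluate(xsel, y, model = cfg$model, seed = cfg$seed)
  set.seed(derive_seed(cfg$seed, 77L))
  test_ix <- clf$split$test
  inst <- xsel[sample(test_ix, min(cfg$n_shap_instances, length(test_ix))), ]
  bg <- xsel[sample(seq_len(nrow(xsel)), cfg$n_shap_background), ]
  sh <- shapley_attributions(clf$predict, bg, inst, mode = "sampling",
                             n_permutations = cfg$n_shap_perm,
                             seed = derive_seed(cfg$seed, 78L))

  sel <- file.path(cfg$out_dir, "selection.json")
  jsonlite::write_json(list(pruned = pr, mrmr = mr), sel, auto_unbox = TRUE,
                       digits = NA)
  met <- file.path(cfg$out_dir, "metrics.json")
  jsonlite::write_json(as.list(clf$report), met, auto_unbox = TRUE,
                       digits = NA)
  att <- file.path(cfg$out_dir, "attributions.csv")
  readr::write_csv(tibble::as_tibble(sh$values), att)
  rk <- file.path(cfg$out_dir, "attribution_ranking.csv")
  readr::write_csv(sh$ranking, rk)
  plog(cfg, "ml (%s): AUC %.3f, MCC %.3f; top attribution: %s",
       cfg$model, clf$report$auc, clf$report$mcc, sh$ranking$feature[1])
  c(sel, met, att, rk)
}

assoc_covariates <- c("age", "sex", "ethnicity", "tdi", "bmi_class",
                      "employment", "shift_work", "smoking", "alcohol",
                      "sleep_duration", "hypertension", "diabetes", "cvd",
                      "cancer", "neurodegenerative", "respiratory")
interaction_covariates <- c("age", "sex", "ethnicity", "tdi", "bmi_class",
                            "employment", "shift_work")

stage_assoc <- function(cfg) {
  rd <- function(f) readr::read_csv(file.path(cfg$out_dir, f),
                                    show_col_types = FALSE)
  d <- rd("features.csv") |>
    dplyr::inner_join(rd("covariates.csv"), by = "subject_id") |>
    dplyr::inner_join(rd("blood_counts.csv"), by = "subject_id")
  main <- sii_association_table(d, assoc_covariates)
  d$sii_z <- zscore(d$sii)
  d$low_amp <- as.integer(quartile_groups(d$cosinor_amplitude)$quartile == "Q1")
  d$irreg <- as.integer(quartile_groups(d$interdaily_stability)$quartile == "Q1")
  d$insuff <- as.integer(d$mvpa_hours * 60 * 7 < 150)
  inter <- dplyr::bind_rows(
    dplyr::mutate(
      dplyr::filter(fit_interaction_glm(d, "sii_z", "low_amp", "irreg",
                                        interaction_covariates),
                    .data$is_exposure),
      pair = "amplitude_x_regularity", .before = 1),
    dplyr::mutate(
      dplyr::filter(fit_interaction_glm(d, "sii_z", "insuff", "irreg",
                                        interaction_covariates),
                    .data$is_exposure),
      pair = "mvpa_x_regularity", .before = 1),
    dplyr::mutate(
      dplyr::filter(fit_interaction_glm(d, "sii_z", "low_amp", "insuff",
                                        interaction_covariates),
                    .data$is_exposure),
      pair = "amplitude_x_mvpa", .before = 1))
  p1 <- file.path(cfg$out_dir, "sii_main_effects.csv")
  p2 <- file.path(cfg$out_dir, "sii_interactions.csv")
  readr::write_csv(main, p1)
  readr::write_csv(dplyr::select(inter, -"is_exposure"), p2)
  plog(cfg, "assoc: %d main-effect rows, %d interaction rows",
       nrow(main), nrow(inter))
  c(p1, p2)
}

mediation_covariates <- c("age", "tdi", "bmi_num", "employed01", "shift01")

stage_mediate <- function(cfg) {
  rd <- function(f) readr::read_csv(file.path(cfg$out_dir, f),
                                    show_col_types = FALSE)
  d <- rd("features.csv") |>
    dplyr::inner_join(rd("covariates.csv"), by = "subject_id") |>
    dplyr::inner_join(rd("blood_counts.csv"), by = "subject_id") |>
    dplyr::inner_join(rd("survival.csv"), by = "subject_id")
  d$sii_z <- zscore(d$sii)
  d$bmi_num <- match(d$bmi_class, c("normal", "overweight", "obese"))
  d$employed01 <- as.integer(d$employment == "paid")
  d$shift01 <- as.integer(d$shift_work)
  med <- suppressWarnings(sex_stratified_mediation(
    d, mediator = "sii_z", covariates = mediation_covariates,
    n_boot = cfg$n_boot, seed = derive_seed(cfg$seed, 99L)))
  mp <- file.path(cfg$out_dir, "mediation.csv")
  readr::write_csv(med, mp)
  plog(cfg, "mediate: %d rows (B=%d)", nrow(med), cfg$n_boot)
  mp
}

stage_report <- function(cfg) {
  rd <- function(f) readr::read_csv(file.path(cfg$out_dir, f),
                                    show_col_types = FALSE)
  d <- rd("features.csv") |>
    dplyr::inner_join(rd("covariates.csv"), by = "subject_id") |>
    dplyr::inner_join(rd("aging.csv"), by = "subject_id")
  # train+validation vs test style split for the descriptive table
  set.seed(derive_seed(cfg$seed, 55L))
  d$split <- ifelse(runif(nrow(d)) < 0.8, "train_val", "test")
  vars <- c("age", "sex", "bmi_class", "cosinor_amplitude", "acrophase",
            "relative_amplitude", "interdaily_stability", "mvpa_hours",
            "sedentary_hours", "sleep_duration", "dfa1", "dfa2")
  t1 <- descriptive_table(d, vars, by = "split")
  d$regularity_group <- ifelse(
    d$interdaily_stability < median(d$interdaily_stability), "irregular",
    "regular")
  f2 <- stratify_age_acceleration(d, features = "mvpa_hours",
                                  by = c("sex", "regularity_group"))
  p1 <- file.path(cfg$out_dir, "table1_descriptives.csv")
  p2 <- file.path(cfg$out_dir, "fig2_strata_medians.csv")
  readr::write_csv(t1, p1)
  readr::write_csv(f2, p2)
  plog(cfg, "report: %d descriptive rows, %d strata rows", nrow(t1), nrow(f2))
  c(p1, p2)
}

#' Descriptive summary table with group comparisons
#'
#' Continuous variables are summarized as median \[IQR\] per group and
#' compared by the Wilcoxon rank-sum test; categorical variables as
#' N (%) per level with a chi-square test (no continuity correction).
#'
#' @param data Data frame.
#' @param vars Columns to summarize.
#' @param by Two-level grouping column.
#' @return Tibble: `variable`, `level`, one summary column per group, `p`.
#' @export
descriptive_table <- function(data, vars, by) {
  assert_cols(data, c(vars, by), "data")
  g <- factor(data[[by]])
  stopifnot(nlevels(g) == 2)
  rows <- list()
  for (v in vars) {
    x <- data[[v]]
    if (is.numeric(x) && length(unique(x)) > 5) {
      s <- unname(vapply(levels(g), function(l) {
        q <- pct(x[g == l], c(0.25, 0.5, 0.75))
        sprintf("%.2f [%.2f, %.2f]", q[2], q[1], q[3])
      }, ""))
      p <- suppressWarnings(stats::wilcox.test(x ~ g)$p.value)
      rows[[length(rows) + 1]] <- tibble::tibble(
        variable = v, level = "median [IQR]",
        !!levels(g)[1] := s[1], !!levels(g)[2] := s[2], p = p)
    } else {
      x <- factor(x)
      tab <- table(x, g)
      p <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
      for (l in rownames(tab)) {
        s <- unname(vapply(levels(g), function(gl) {
          sprintf("%d (%.1f)", tab[l, gl], 100 * tab[l, gl] / sum(tab[, gl]))
        }, ""))
        rows[[length(rows) + 1]] <- tibble::tibble(
          variable = v, level = l,
          !!levels(g)[1] := s[1], !!levels(g)[2] := s[2], p = p)
      }
    }
  }
  dplyr::bind_rows(rows)
}
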