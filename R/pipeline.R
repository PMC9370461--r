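#' Subject-level train/test split
#'
#' Random partition of subjects (never of individual visits: both visits
#' of a subject land on the same side) into disjoint, exhaustive training
#' and testing sets. The forest is fit on the training half and intervals,
#' labels and the time-to-event analysis use the testing half.
#'
#' @param subject_ids vector of unique subject identifiers (at least 10).
#' @param fraction training fraction in (0, 1); default 0.5.
#' @param seed optional integer seed.
#' @return list with `train` and `test` id vectors.
#' @export
split_train_test <- function(subject_ids, fraction = 0.5, seed = NULL) {
  subject_ids <- unique(subject_ids)
  n <- length(subject_ids)
  if (n < 10) stop("need at least 10 subjects to split")
  if (fraction <= 0 || fraction >= 1) stop("fraction must lie in (0, 1)")
  if (!is.null(seed)) set.seed(as.integer(seed))
  n_train <- round(fraction * n)
  train <- sort(sample(subject_ids, n_train))
  list(train = train, test = sort(setdiff(subject_ids, train)))
}

z_center <- function(x) x - mean(x, na.rm = TRUE)

# design matrix for one visit's rows: filtered exposures + model covariates
pipeline_design <- function(rows, exposure_cols) {
  X <- as.matrix(rows[, exposure_cols, drop = FALSE])
  age_c <- z_center(rows$age)
  cbind(X, age = rows$age, age2 = age_c^2, sex = rows$sex,
        ffq_version = rows$ffq_version, fasting_status = rows$fasting_status,
        followup_time = rows$followup_time)
}

#' Run the full precision-prevention pipeline on one or more cohorts
#'
#' Executes, per cohort: implausible-energy-reporter exclusion (FIL),
#' inverse normal transformation of the continuous exposures, removal of
#' zero-variance and highly correlated predictors, optional
#' random-forest imputation of missing exposures, a subject-level 50/50
#' train/test split, a quantile regression forest per trait (exposures
#' plus age, centred-age squared, sex, questionnaire version, fasting
#' status and follow-up time as predictors, after VIF filtering), 90%
#' prediction intervals and sensitivity labels on the held-out half, and
#' a Cox model of the labels on time-to-event with covariate adjustment.
#' Per-cohort estimates are then pooled by sensitivity category with
#' DerSimonian-Laird random effects, subgroup differences are tested, and
#' the incremental AUC of the any-trait sensitivity flag over a baseline
#' age-sex risk score is computed per cohort.
#'
#' When a cohort carries ground-truth latent classes (synthetic cohorts
#' do), the same Cox model is additionally fit on the true classes,
#' giving the planted-parameter benchmark the pipeline estimates are
#' compared against.
#'
#' @param cohorts a [simulate_cohort()] object or list of them (each may
#'   also be a bare list with elements `visits`, `survival`, optionally
#'   `latent_class` and `config`).
#' @param alpha prediction-interval miscoverage (default 0.10).
#' @param split_fraction training fraction (default 0.50).
#' @param forest_params list: `n_trees`, `mtry`, `min_node_size`.
#' @param mode `"persistent"` (two-visit labels) or `"single_visit"`; may
#'   be a vector with one entry per cohort, emulating a design that pools
#'   a two-examination cohort with a baseline-only cohort.
#' @param persistence_rule see [persistence_label()].
#' @param adverse_direction named map trait -> `"high"`/`"low"`; defaults
#'   to each cohort's config, else `"high"`.
#' @param cox_covariates covariate columns for the Cox model.
#' @param impute list: `enabled` (default: impute when exposures contain
#'   missing values), `max_iter`, `n_trees`.
#' @param auc_horizon years defining the binary outcome for the AUC
#'   comparison (default 10).
#' @param seed integer seed governing split, forests and imputation.
#' @return list of class `"pipeline_result"` with `cohort_results` (per
#'   cohort: `labels`, `cox`, `cox_truth`, `auc`, `manifest`), `pooled`
#'   and `pooled_truth` (per trait x category [dl_pool()] results),
#'   `subgroup` (per trait) and the echoed settings.
#' @export
run_pipeline <- function(cohorts, alpha = 0.10, split_fraction = 0.5,
                         forest_params = list(n_trees = 200, mtry = NULL,
                                              min_node_size = 5),
                         mode = c("persistent", "single_visit"),
                         persistence_rule = "both",
                         adverse_direction = NULL,
                         cox_covariates = c("age", "sex", "tei"),
                         impute = list(enabled = NULL, max_iter = 5,
                                       n_trees = 50),
                         auc_horizon = 10, seed = 1) {
  mode <- match.arg(mode, several.ok = TRUE)
  if (inherits(cohorts, "synthetic_cohort") ||
      (!is.null(cohorts$visits) && is.data.frame(cohorts$visits))) {
    cohorts <- list(cohorts)
  }
  if (is.null(names(cohorts))) {
    names(cohorts) <- paste0("cohort", seq_along(cohorts))
  }
  seed <- as.integer(seed)
  cohort_results <- list()
  estimates <- list()
  estimates_truth <- list()
  traits_seen <- character(0)

  for (ci in seq_along(cohorts)) {
    co <- cohorts[[ci]]
    co_name <- names(cohorts)[ci]
    mode_i <- mode[[min(ci, length(mode))]]
    visits <- co$visits
    v1 <- visits[visits$visit == 1, , drop = FALSE]
    v2 <- visits[visits$visit == 2, , drop = FALSE]
    has_v2 <- nrow(v2) > 0 && mode_i == "persistent"
    cohort_mode <- if (has_v2) "persistent" else "single_visit"
    manifest <- list(n_subjects = nrow(v1))

    # --- exclusions -----------------------------------------------------
    keep <- fil_exclusion(v1$tei, v1$bmr)
    kept_ids <- v1$subject_id[keep]
    v1 <- v1[keep, , drop = FALSE]
    if (has_v2) v2 <- v2[v2$subject_id %in% kept_ids, , drop = FALSE]
    manifest$n_after_fil <- nrow(v1)

    # --- exposure columns, transforms, filters --------------------------
    cfg <- co$config
    expo_cols <- if (!is.null(cfg)) {
      paste0("e", seq_len(cfg$n_exposures))
    } else {
      grep("^e[0-9]+$", names(v1), value = TRUE)
    }
    trait_cols <- if (!is.null(cfg)) names(cfg$effects) else {
      setdiff(names(v1), c("subject_id", "visit", "age", "sex",
                           "fasting_status", "ffq_version", "tei", "bmr",
                           "on_bp_med", "on_lipid_med", "followup_time",
                           expo_cols))
    }
    traits_seen <- union(traits_seen, trait_cols)
    transform_expo <- function(vv) {
      for (cc in expo_cols) {
        x <- vv[[cc]]
        if (length(unique(x[!is.na(x)])) > 2) {
          vv[[cc]] <- inverse_normal_transform(x)
        }
      }
      vv
    }
    v1 <- transform_expo(v1)
    if (has_v2) v2 <- transform_expo(v2)

    do_impute <- impute$enabled
    if (is.null(do_impute)) do_impute <- anyNA(v1[, expo_cols])
    if (isTRUE(do_impute)) {
      imp1 <- rf_impute(v1[, expo_cols], n_trees = impute$n_trees %||% 50,
                        max_iter = impute$max_iter %||% 5, seed = seed + ci)
      v1[, expo_cols] <- imp1$data
      if (has_v2 && anyNA(v2[, expo_cols])) {
        imp2 <- rf_impute(v2[, expo_cols],
                          n_trees = impute$n_trees %||% 50,
                          max_iter = impute$max_iter %||% 5,
                          seed = seed + ci + 1000L)
        v2[, expo_cols] <- imp2$data
      }
      manifest$imputed <- TRUE
    }
    # rows with remaining missing exposures cannot enter the forest
    complete1 <- stats::complete.cases(v1[, expo_cols])
    v1 <- v1[complete1, , drop = FALSE]
    if (has_v2) v2 <- v2[v2$subject_id %in% v1$subject_id, , drop = FALSE]
    manifest$n_complete <- nrow(v1)

    kept_expo <- filter_predictors(v1[, expo_cols], corr_threshold = 0.80)
    manifest$n_exposures_kept <- length(kept_expo)

    # --- split ----------------------------------------------------------
    sp <- split_train_test(v1$subject_id, split_fraction,
                           seed = seed + 7L * ci)
    manifest$n_train <- length(sp$train)
    manifest$n_test <- length(sp$test)

    tr1 <- v1[v1$subject_id %in% sp$train, , drop = FALSE]
    te1 <- v1[v1$subject_id %in% sp$test, , drop = FALSE]
    tr2 <- if (has_v2) v2[v2$subject_id %in% sp$train, , drop = FALSE]
    te2 <- if (has_v2) v2[v2$subject_id %in% sp$test, , drop = FALSE]

    # --- per-trait forest, intervals, labels ----------------------------
    labels <- NULL
    for (tn in trait_cols) {
      dir <- if (!is.null(adverse_direction) &&
                 tn %in% names(adverse_direction)) {
        adverse_direction[[tn]]
      } else if (!is.null(cfg)) cfg$adverse_direction[[tn]] else "high"

      Xtr <- pipeline_design(tr1, kept_expo)
      ytr <- tr1[[tn]]
      if (has_v2) {
        Xtr <- rbind(Xtr, pipeline_design(tr2, kept_expo))
        ytr <- c(ytr, tr2[[tn]])
      }
      kept_design <- vif_filter(Xtr, threshold = 10)
      Xtr <- Xtr[, kept_design, drop = FALSE]
      fit <- qrf(Xtr, ytr, n_trees = forest_params$n_trees %||% 200,
                 mtry = forest_params$mtry,
                 min_node_size = forest_params$min_node_size %||% 5,
                 seed = seed + 13L * ci + match(tn, trait_cols))
      pi1 <- prediction_interval(
        fit, pipeline_design(te1, kept_expo)[, kept_design, drop = FALSE],
        alpha = alpha, trait = tn)
      if (has_v2) {
        pi2 <- prediction_interval(
          fit, pipeline_design(te2, kept_expo)[, kept_design, drop = FALSE],
          alpha = alpha, trait = tn)
        lab <- classify_cohort(te1$subject_id, tn, te1[[tn]], pi1,
                               te2[[tn]], pi2, adverse_direction = dir,
                               rule = persistence_rule)
      } else {
        lab <- classify_cohort(te1$subject_id, tn, te1[[tn]], pi1,
                               adverse_direction = dir)
      }
      labels <- rbind(labels, lab)
    }
    label_mode <- if (cohort_mode == "persistent") "persistent"
                  else "single_visit"

    # --- survival on the test half --------------------------------------
    surv <- co$survival
    cov_df <- te1[, intersect(cox_covariates, names(te1)), drop = FALSE]
    cox_fits <- list()
    truth_fits <- list()
    for (tn in trait_cols) {
      lab <- labels[labels$trait == tn & labels$mode == label_mode, ,
                    drop = FALSE]
      dat <- merge(lab[, c("subject_id", "label")],
                   surv[, c("subject_id", "time", "event")],
                   by = "subject_id")
      dat <- cbind(dat, cov_df[match(dat$subject_id, te1$subject_id), ,
                               drop = FALSE])
      fit <- tryCatch(cox_fit(dat, covariates = names(cov_df)),
                      error = function(e) e)
      cox_fits[[tn]] <- fit
      if (inherits(fit, "cox_fit")) {
        for (cat in c("sensitive", "resilient")) {
          e <- cox_study_estimate(fit, cat, cohort = co_name, trait = tn,
                                  outcome = "any")
          if (!is.null(e)) estimates[[length(estimates) + 1L]] <- e
        }
      }
      if (!is.null(co$latent_class)) {
        tdat <- merge(co$latent_class, surv[, c("subject_id", "time",
                                                "event")],
                      by = "subject_id")
        tdat <- tdat[tdat$subject_id %in% te1$subject_id, , drop = FALSE]
        names(tdat)[names(tdat) == "class"] <- "label"
        tdat <- cbind(tdat,
                      cov_df[match(tdat$subject_id, te1$subject_id), ,
                             drop = FALSE])
        tfit <- tryCatch(cox_fit(tdat, covariates = names(cov_df)),
                         error = function(e) e)
        truth_fits[[tn]] <- tfit
        if (inherits(tfit, "cox_fit")) {
          for (cat in c("sensitive", "resilient")) {
            e <- cox_study_estimate(tfit, cat, cohort = co_name,
                                    trait = tn, outcome = "any")
            if (!is.null(e)) {
              estimates_truth[[length(estimates_truth) + 1L]] <- e
            }
          }
        }
      }
    }
    manifest$n_events_test <-
      sum(surv$event[surv$subject_id %in% te1$subject_id])
    manifest$labels <- table(labels$label[labels$mode == label_mode],
                             useNA = "no")

    # --- incremental AUC over a baseline risk score ---------------------
    lab_any <- labels[labels$mode == label_mode, , drop = FALSE]
    sens_any <- tapply(lab_any$label == "sensitive", lab_any$subject_id,
                       any)
    sdat <- surv[surv$subject_id %in% te1$subject_id, , drop = FALSE]
    at_risk <- sdat$event == 1 | sdat$time >= auc_horizon
    sdat <- sdat[at_risk, , drop = FALSE]
    y10 <- as.integer(sdat$event == 1 & sdat$time <= auc_horizon)
    base <- 0.06 * (te1$age[match(sdat$subject_id, te1$subject_id)] - 50) +
      0.4 * te1$sex[match(sdat$subject_id, te1$subject_id)]
    flag <- as.integer(sens_any[as.character(sdat$subject_id)])
    auc <- tryCatch(compare_with_sensitivity(base, flag, y10),
                    error = function(e) e)

    cohort_results[[co_name]] <- list(labels = labels, cox = cox_fits,
                                      cox_truth = truth_fits, auc = auc,
                                      manifest = manifest,
                                      mode = cohort_mode)
  }

  pool_by <- function(ests) {
    out <- list()
    for (tn in traits_seen) {
      for (cat in c("sensitive", "resilient")) {
        sel <- Filter(function(e) e$trait == tn && e$category == cat, ests)
        out[[tn]][[cat]] <- if (length(sel)) dl_pool(sel) else NULL
      }
    }
    out
  }
  pooled <- pool_by(estimates)
  pooled_truth <- pool_by(estimates_truth)
  subgroup <- lapply(traits_seen, function(tn) {
    subgroup_difference_test(pooled[[tn]][["resilient"]],
                             pooled[[tn]][["sensitive"]])
  })
  names(subgroup) <- traits_seen

  structure(list(cohort_results = cohort_results,
                 estimates = estimates, estimates_truth = estimates_truth,
                 pooled = pooled, pooled_truth = pooled_truth,
                 subgroup = subgroup,
                 settings = list(alpha = alpha,
                                 split_fraction = split_fraction,
                                 forest_params = forest_params,
                                 mode = mode, seed = seed)),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("Pipeline result: %d cohort(s), mode = %s\n",
              length(x$cohort_results),
              paste(x$settings$mode, collapse = "+")))
  for (tn in names(x$pooled)) {
    for (cat in names(x$pooled[[tn]])) {
      m <- x$pooled[[tn]][[cat]]
      if (!is.null(m)) {
        cat(sprintf("  %s / %s: pooled HR %.3f [%.3f, %.3f]\n", tn, cat,
                    m$hr, m$ci_lower, m$ci_upper))
      }
    }
  }
  invisible(x)
}

#' Export pooled results as a trait-by-category table
#'
#' Flattens a [run_pipeline()] result into the familiar meta-analysis
#' table: one row per trait and sensitivity category with pooled HR, CI,
#' heterogeneity Q and subgroup-difference p.
#'
#' @param result a [run_pipeline()] result.
#' @param truth use the ground-truth-label pooling instead.
#' @return data frame.
#' @export
pooled_table <- function(result, truth = FALSE) {
  pooled <- if (truth) result$pooled_truth else result$pooled
  rows <- list()
  for (tn in names(pooled)) {
    for (cat in names(pooled[[tn]])) {
      m <- pooled[[tn]][[cat]]
      sg <- result$subgroup[[tn]]
      rows[[length(rows) + 1L]] <- data.frame(
        trait = tn, category = cat,
        hr = if (is.null(m)) NA_real_ else m$hr,
        ci_lower = if (is.null(m)) NA_real_ else m$ci_lower,
        ci_upper = if (is.null(m)) NA_real_ else m$ci_upper,
        k = if (is.null(m)) 0L else m$k,
        tau2 = if (is.null(m)) NA_real_ else m$tau2,
        Q = if (is.null(m)) NA_real_ else m$Q,
        Q_p = if (is.null(m)) NA_real_ else m$Q_p,
        subgroup_p = if (is.null(sg)) NA_real_ else sg$p)
    }
  }
  do.call(rbind, rows)
}
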