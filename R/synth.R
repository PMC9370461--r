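#' Configuration for the synthetic cohort generator
#'
#' Bundles and validates all knobs of the generator. The generated cohorts
#' have the statistical structure the downstream analysis assumes:
#' block-correlated lifestyle exposures (a configurable fraction
#' dichotomized to emulate dummy variables), traits that are linear in the
#' exposures plus Gaussian noise, a latent persistent sensitivity class
#' that shifts traits beyond their conditional quantiles in the adverse
#' direction, two visits with AR(1)-drifting exposures, and exponential
#' survival with a planted hazard multiplier for the sensitive class plus
#' administrative censoring.
#'
#' @param n_subjects number of subjects (two visits each).
#' @param n_exposures number of exposure columns.
#' @param block_size exposures per correlated block.
#' @param block_correlation within-block correlation, in \[0, 1).
#' @param dichotomize_frac fraction of exposure columns (the trailing ones)
#'   thresholded at zero into 0/1 dummies.
#' @param effects named list of exposure-to-trait coefficient vectors, one
#'   per trait (each of length `n_exposures`); the names name the traits.
#' @param adverse_direction named character vector, `"high"` or `"low"` per
#'   trait: the direction in which the sensitive class is shifted.
#' @param noise_sd residual SD of the traits.
#' @param prop_sensitive,prop_resilient latent class proportions; their sum
#'   must be below 1.
#' @param shift_multiplier latent-class trait shift in units of `noise_sd`.
#' @param hazard_log_hr planted log hazard ratio of the sensitive class.
#' @param baseline_hazard events per person-year in the neutral class.
#' @param censor_horizon administrative censoring horizon in years.
#' @param visit_gap years between the two visits.
#' @param ar_coef AR(1) coefficient linking visit-2 exposures to visit-1.
#' @param covariate_log_hr named log-HRs for the survival covariates
#'   (centred age in years, sex).
#' @param event_type_probs probabilities of CVD / T2D / death given an event.
#' @param seed integer seed; all generator randomness derives from it.
#' @return a validated list of class `"synth_config"`.
#' @export
synth_config <- function(n_subjects = 4000, n_exposures = 30, block_size = 5,
                         block_correlation = 0.35, dichotomize_frac = 0.2,
                         effects = NULL, adverse_direction = NULL,
                         noise_sd = 1, prop_sensitive = 0.08,
                         prop_resilient = 0.08, shift_multiplier = 2.5,
                         hazard_log_hr = log(2), baseline_hazard = 0.015,
                         censor_horizon = 20, visit_gap = 10, ar_coef = 0.8,
                         covariate_log_hr = c(age = 0.02, sex = 0.1),
                         event_type_probs = c(CVD = 0.5, T2D = 0.3,
                                              death = 0.2),
                         seed = NULL) {
  if (is.null(effects)) {
    beta <- numeric(n_exposures)
    beta[seq_len(min(10, n_exposures))] <- 0.3
    effects <- list(sbp = beta)
  }
  if (is.null(names(effects)) || any(names(effects) == "")) {
    stop("effects must be a named list (one coefficient vector per trait)")
  }
  if (is.null(adverse_direction)) {
    adverse_direction <- stats::setNames(rep("high", length(effects)),
                                         names(effects))
  }
  cfg <- list(n_subjects = n_subjects, n_exposures = n_exposures,
              block_size = block_size, block_correlation = block_correlation,
              dichotomize_frac = dichotomize_frac, effects = effects,
              adverse_direction = adverse_direction, noise_sd = noise_sd,
              prop_sensitive = prop_sensitive,
              prop_resilient = prop_resilient,
              shift_multiplier = shift_multiplier,
              hazard_log_hr = hazard_log_hr,
              baseline_hazard = baseline_hazard,
              censor_horizon = censor_horizon, visit_gap = visit_gap,
              ar_coef = ar_coef, covariate_log_hr = covariate_log_hr,
              event_type_probs = event_type_probs, seed = seed)
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  stopifnot(cfg$n_subjects >= 1, cfg$n_exposures >= 1, cfg$block_size >= 1)
  if (cfg$block_correlation < 0 || cfg$block_correlation >= 1) {
    stop("block_correlation must lie in [0, 1)")
  }
  if (cfg$dichotomize_frac < 0 || cfg$dichotomize_frac > 1) {
    stop("dichotomize_frac must lie in [0, 1]")
  }
  if (cfg$noise_sd <= 0) stop("noise_sd must be positive")
  if (cfg$prop_sensitive < 0 || cfg$prop_resilient < 0 ||
      cfg$prop_sensitive + cfg$prop_resilient >= 1) {
    stop("prop_sensitive + prop_resilient must be below 1")
  }
  if (cfg$shift_multiplier < 0) stop("shift_multiplier must be non-negative")
  if (cfg$baseline_hazard <= 0) stop("baseline_hazard must be positive")
  if (cfg$censor_horizon <= 0) stop("censor_horizon must be positive")
  if (cfg$ar_coef < 0 || cfg$ar_coef > 1) stop("ar_coef must lie in [0, 1]")
  bad <- vapply(cfg$effects, length, 1L) != cfg$n_exposures
  if (any(bad)) stop("every effect vector must have length n_exposures")
  if (!all(cfg$adverse_direction %in% c("high", "low"))) {
    stop("adverse_direction entries must be 'high' or 'low'")
  }
  invisible(cfg)
}

seed_offset <- function(cfg, k) {
  if (!is.null(cfg$seed)) set.seed((as.integer(cfg$seed) + k) %% 2147483647L)
  invisible(NULL)
}

block_gaussian <- function(n, p, block_size, rho) {
  X <- matrix(stats::rnorm(n * p), n, p)
  if (rho > 0) {
    blocks <- split(seq_len(p), ceiling(seq_len(p) / block_size))
    for (b in blocks) {
      k <- length(b)
      if (k > 1) {
        S <- matrix(rho, k, k)
        diag(S) <- 1
        X[, b] <- X[, b, drop = FALSE] %*% chol(S)
      }
    }
  }
  X
}

#' Generate correlated exposures for two visits
#'
#' Visit-1 exposures are multivariate Gaussian with block-diagonal
#' correlation (`block_correlation` within blocks of `block_size`); visit-2
#' values follow an AR(1) drift `ar_coef * visit1 + sqrt(1 - ar_coef^2) *
#' fresh`, which keeps the marginal distribution stationary. The trailing
#' `dichotomize_frac` fraction of columns is thresholded at zero into 0/1
#' dummies, after the drift step, emulating dichotomized categorical items.
#'
#' @param cfg a [synth_config()].
#' @return list with matrices `visit1` and `visit2`
#'   (`n_subjects` by `n_exposures`, columns `e1..ep`).
#' @export
generate_exposures <- function(cfg) {
  validate_synth_config(cfg)
  seed_offset(cfg, 1L)
  n <- cfg$n_subjects
  p <- cfg$n_exposures
  v1 <- block_gaussian(n, p, cfg$block_size, cfg$block_correlation)
  fresh <- block_gaussian(n, p, cfg$block_size, cfg$block_correlation)
  v2 <- cfg$ar_coef * v1 + sqrt(1 - cfg$ar_coef^2) * fresh
  n_dich <- round(cfg$dichotomize_frac * p)
  if (n_dich > 0) {
    cols <- seq.int(p - n_dich + 1L, p)
    v1[, cols] <- (v1[, cols, drop = FALSE] > 0) + 0
    v2[, cols] <- (v2[, cols, drop = FALSE] > 0) + 0
  }
  colnames(v1) <- colnames(v2) <- paste0("e", seq_len(p))
  list(visit1 = v1, visit2 = v2)
}

#' Assign the latent persistent sensitivity class
#'
#' One draw per subject with the configured proportions; the class is a
#' subject-level (not visit-level) attribute, so persistence over the two
#' visits is recoverable by construction.
#'
#' @param cfg a [synth_config()].
#' @return factor with levels `neutral`, `sensitive`, `resilient`.
#' @export
assign_latent_class <- function(cfg) {
  validate_synth_config(cfg)
  seed_offset(cfg, 2L)
  factor(sample(c("neutral", "sensitive", "resilient"), cfg$n_subjects,
                replace = TRUE,
                prob = c(1 - cfg$prop_sensitive - cfg$prop_resilient,
                         cfg$prop_sensitive, cfg$prop_resilient)),
         levels = c("neutral", "sensitive", "resilient"))
}

#' Generate trait values for one visit
#'
#' `trait = X beta + class shift + N(0, noise_sd)`. For a trait whose
#' adverse direction is `"high"` the sensitive class is shifted by
#' `+shift_multiplier * noise_sd` and the resilient class by the negative;
#' for `"low"` traits (e.g. HDL-C) the signs are mirrored.
#'
#' @param exposures exposure matrix for the visit.
#' @param latent_class factor from [assign_latent_class()].
#' @param cfg a [synth_config()].
#' @return numeric matrix, one column per trait in `cfg$effects`.
#' @export
generate_traits <- function(exposures, latent_class, cfg) {
  validate_synth_config(cfg)
  exposures <- as.matrix(exposures)
  if (ncol(exposures) != cfg$n_exposures) {
    stop("exposure matrix has ", ncol(exposures),
         " columns but cfg expects ", cfg$n_exposures)
  }
  if (nrow(exposures) != length(latent_class)) {
    stop("latent_class length must match nrow(exposures)")
  }
  n <- nrow(exposures)
  delta <- cfg$shift_multiplier * cfg$noise_sd
  out <- vapply(names(cfg$effects), function(tr) {
    sgn <- if (cfg$adverse_direction[[tr]] == "high") 1 else -1
    shift <- sgn * delta * ((latent_class == "sensitive") -
                            (latent_class == "resilient"))
    drop(exposures %*% cfg$effects[[tr]]) + shift +
      stats::rnorm(n, sd = cfg$noise_sd)
  }, numeric(n))
  colnames(out) <- names(cfg$effects)
  out
}

#' Generate survival records with a planted sensitive-class hazard
#'
#' Event times are exponential with rate `baseline_hazard *
#' exp(hazard_log_hr * 1[sensitive] + gamma' covariates)`; censoring is
#' administrative at `min(censor_horizon, U)` with `U` uniform on the upper
#' half of the horizon (staggered study exit). The uncensored `true_time`
#' is retained so tests can check the planted rate ratio before censoring.
#'
#' @param latent_class factor from [assign_latent_class()].
#' @param covariates optional data frame / matrix with columns matching
#'   `names(cfg$covariate_log_hr)` (e.g. centred age, sex).
#' @param cfg a [synth_config()].
#' @return data frame with `time`, `event` (0/1), `event_type`
#'   (`CVD`/`T2D`/`death`, `NA` when censored), `true_time` and
#'   `admin_time` (the scheduled administrative follow-up, which is known
#'   at baseline and therefore usable as a model covariate without
#'   leaking the outcome).
#' @export
generate_survival <- function(latent_class, covariates = NULL, cfg) {
  validate_synth_config(cfg)
  seed_offset(cfg, 4L)
  n <- length(latent_class)
  lp <- cfg$hazard_log_hr * (latent_class == "sensitive")
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    nm <- names(cfg$covariate_log_hr)
    missing_cov <- setdiff(nm, colnames(covariates))
    if (length(missing_cov)) {
      stop("covariates lack columns: ", paste(missing_cov, collapse = ", "))
    }
    lp <- lp + drop(covariates[, nm, drop = FALSE] %*% cfg$covariate_log_hr)
  }
  rate <- cfg$baseline_hazard * exp(lp)
  true_time <- stats::rexp(n, rate = rate)
  cens <- stats::runif(n, cfg$censor_horizon / 2, cfg$censor_horizon)
  time <- pmin(true_time, cens)
  event <- as.integer(true_time <= cens)
  event_type <- rep(NA_character_, n)
  idx <- which(event == 1L)
  if (length(idx)) {
    event_type[idx] <- sample(names(cfg$event_type_probs), length(idx),
                              replace = TRUE, prob = cfg$event_type_probs)
  }
  data.frame(time = time, event = event, event_type = event_type,
             true_time = true_time, admin_time = cens)
}

#' Set cells missing completely at random
#'
#' Each cell of the selected columns is independently set missing with the
#' given probability. The original table and the missingness mask are
#' returned alongside, so imputation error can be scored on the masked
#' ground truth.
#'
#' @param table data frame or matrix.
#' @param rate missingness probability in \[0, 1).
#' @param seed optional integer seed.
#' @param columns columns to degrade (default: all).
#' @return list of class `"missingness_injection"` with elements `data`
#'   (degraded copy), `mask` (logical matrix, `TRUE` where set missing) and
#'   `original`.
#' @export
inject_missingness <- function(table, rate, seed = NULL,
                               columns = seq_len(ncol(table))) {
  if (rate < 0 || rate >= 1) stop("rate must lie in [0, 1)")
  if (!is.null(seed)) set.seed(as.integer(seed))
  out <- table
  mask <- matrix(FALSE, nrow(table), ncol(table),
                 dimnames = dimnames(table))
  if (rate > 0) {
    for (j in columns) {
      hit <- stats::runif(nrow(table)) < rate
      mask[hit, j] <- TRUE
      out[hit, j] <- NA
    }
  }
  structure(list(data = out, mask = mask, original = table),
            class = "missingness_injection")
}

#' Simulate a complete two-visit cohort
#'
#' Assembles exposures, traits, covariates and survival into the long
#' subject-visit table the pipeline consumes, together with the
#' ground-truth latent classes. Baseline age is uniform on 35-60 years,
#' sex is balanced, total energy intake (TEI, kcal/day) and basal
#' metabolic rate are plausibly scaled, fasting status and questionnaire
#' version are binary; medication flags are off (the correction step is a
#' preprocessing utility exercised on its own inputs).
#'
#' @param cfg a [synth_config()].
#' @return object of class `"synthetic_cohort"`: list with `visits` (long
#'   data frame, two rows per subject), `latent_class`, `survival` and
#'   `config`.
#' @export
simulate_cohort <- function(cfg) {
  validate_synth_config(cfg)
  expo <- generate_exposures(cfg)
  latent <- assign_latent_class(cfg)
  seed_offset(cfg, 3L)
  n <- cfg$n_subjects
  age1 <- stats::runif(n, 35, 60)
  sex <- stats::rbinom(n, 1, 0.5)
  tei <- stats::rnorm(n, 2200, 450)
  tei <- pmax(tei, 800)
  bmr <- 1400 + 8 * (age1 - 45) + 250 * sex + stats::rnorm(n, 0, 120)
  fasting <- stats::rbinom(n, 1, 0.9)
  ffq_version <- stats::rbinom(n, 1, 0.5)
  traits1 <- generate_traits(expo$visit1, latent, cfg)
  traits2 <- generate_traits(expo$visit2, latent, cfg)
  surv <- generate_survival(
    latent, data.frame(age = age1 - mean(age1), sex = sex), cfg)
  surv <- cbind(subject_id = seq_len(n), surv)
  mk_visit <- function(v, expo_v, traits_v, age_v) {
    data.frame(subject_id = seq_len(n), visit = v, age = age_v, sex = sex,
               fasting_status = fasting, ffq_version = ffq_version,
               tei = tei, bmr = bmr, on_bp_med = FALSE, on_lipid_med = FALSE,
               followup_time = surv$admin_time, expo_v, traits_v,
               check.names = FALSE)
  }
  visits <- rbind(mk_visit(1L, expo$visit1, traits1, age1),
                  mk_visit(2L, expo$visit2, traits2, age1 + cfg$visit_gap))
  structure(list(
    visits = visits,
    latent_class = data.frame(subject_id = seq_len(n), class = latent),
    survival = surv,
    config = cfg
  ), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(paste0("Synthetic cohort: %d subjects x 2 visits, ",
                     "%d exposures, traits: %s\n"),
              x$config$n_subjects, x$config$n_exposures,
              paste(names(x$config$effects), collapse = ", ")))
  print(table(x$latent_class$class))
  invisible(x)
}

#' Write a synthetic cohort to delimited text plus a truth sidecar
#'
#' One CSV per visit plus `truth.json` holding the ground-truth latent
#' classes, the survival records and the generating configuration.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (v in 1:2) {
    utils::write.csv(cohort$visits[cohort$visits$visit == v, , drop = FALSE],
                     file.path(dir, sprintf("visit%d.csv", v)),
                     row.names = FALSE)
  }
  truth <- list(
    latent_class = cohort$latent_class,
    survival = cohort$survival,
    config = cohort$config[setdiff(names(cohort$config), "effects")],
    effects = cohort$config$effects
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
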