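#' Medication correction constants
#'
#' Published additive constants used to restore untreated biomarker levels
#' in subjects on lipid-lowering or blood-pressure-lowering medication:
#' +0.208 mmol/L triglycerides, +1.347 mmol/L total cholesterol,
#' -0.060 mmol/L HDL-C, +1.290 mmol/L LDL-C, +15 mm Hg systolic and
#' +10 mm Hg diastolic blood pressure.
#'
#' @param tg_add,tc_add,hdl_add,ldl_add lipid corrections, mmol/L.
#' @param sbp_add,dbp_add blood pressure corrections, mm Hg.
#' @return named list of class `"medication_constants"`.
#' @export
medication_constants <- function(tg_add = 0.208, tc_add = 1.347,
                                 hdl_add = -0.060, ldl_add = 1.290,
                                 sbp_add = 15, dbp_add = 10) {
  structure(list(tg_add = tg_add, tc_add = tc_add, hdl_add = hdl_add,
                 ldl_add = ldl_add, sbp_add = sbp_add, dbp_add = dbp_add),
            class = "medication_constants")
}

#' Correct treated biomarkers by adding published constants
#'
#' Adds the medication constants to SBP/DBP for subjects flagged on
#' blood-pressure medication and to TG/TC/HDL-C/LDL-C for subjects on
#' lipid-lowering medication. Untreated subjects are unchanged. Missing
#' medication flags are treated as untreated (with a message). The
#' correction must be applied exactly once per table: a provenance flag is
#' set on the result and re-application errors.
#'
#' @param data data frame with (any of) trait columns `sbp`, `dbp`, `tg`,
#'   `tc`, `hdl`, `ldl` and logical flag columns `on_bp_med`,
#'   `on_lipid_med`.
#' @param constants a [medication_constants()] list.
#' @return `data` with corrected traits and attribute
#'   `med_corrected = TRUE`.
#' @export
medication_correction <- function(data, constants = medication_constants()) {
  if (isTRUE(attr(data, "med_corrected"))) {
    stop("medication correction already applied to this table")
  }
  flag <- function(nm) {
    if (!nm %in% names(data)) {
      message("flag '", nm, "' absent; subjects treated as untreated")
      return(rep(FALSE, nrow(data)))
    }
    f <- data[[nm]]
    if (anyNA(f)) {
      message(sum(is.na(f)), " missing '", nm,
              "' flags treated as untreated")
      f[is.na(f)] <- FALSE
    }
    as.logical(f)
  }
  bp <- flag("on_bp_med")
  lipid <- flag("on_lipid_med")
  add <- function(col, amount, sel) {
    if (col %in% names(data)) {
      data[[col]][sel] <<- data[[col]][sel] + amount
    }
  }
  add("sbp", constants$sbp_add, bp)
  add("dbp", constants$dbp_add, bp)
  add("tg", constants$tg_add, lipid)
  add("tc", constants$tc_add, lipid)
  add("hdl", constants$hdl_add, lipid)
  add("ldl", constants$ldl_add, lipid)
  attr(data, "med_corrected") <- TRUE
  data
}

#' Friedewald estimate of LDL cholesterol
#'
#' `ldl = tc - hdl - tg / 2.2` (all in mmol/L). The estimate is invalid at
#' high triglycerides; values with `tg >= 4.52` mmol/L (400 mg/dL) return
#' `NA`.
#'
#' @param tc,hdl,tg total cholesterol, HDL-C and triglycerides, mmol/L.
#' @return LDL-C in mmol/L; `NA` where inputs are missing or `tg` exceeds
#'   the validity bound.
#' @export
friedewald_ldl <- function(tc, hdl, tg) {
  if (any(tc < 0, na.rm = TRUE) || any(hdl < 0, na.rm = TRUE) ||
      any(tg < 0, na.rm = TRUE)) {
    stop("lipid concentrations must be non-negative")
  }
  ldl <- tc - hdl - tg / 2.2
  ldl[!is.na(tg) & tg >= 4.52] <- NA_real_
  ldl
}

#' Rank-based inverse normal transformation
#'
#' Maps values to normal quantiles of their Blom-offset fractional ranks,
#' `qnorm((r - 3/8) / (n + 1/4))`, with ties sharing averaged ranks and
#' missing values passed through. The result is symmetric around zero and
#' preserves rank order, so any strictly monotone transform of the input
#' yields the identical output.
#'
#' @param x numeric vector with at least 3 non-missing, non-constant values.
#' @return transformed vector of the same length.
#' @export
inverse_normal_transform <- function(x) {
  ok <- !is.na(x)
  n <- sum(ok)
  if (n < 3) stop("need at least 3 non-missing values")
  v <- x[ok]
  if (max(v) == min(v)) stop("constant vector: transform undefined")
  r <- rank(v, ties.method = "average")
  out <- rep(NA_real_, length(x))
  out[ok] <- stats::qnorm((r - 3 / 8) / (n + 1 / 4))
  out
}

#' Residual-method adjustment of a nutrient for total energy intake
#'
#' Regresses the nutrient on TEI by least squares and returns the residual
#' plus the nutrient mean, removing confounding by overall energy intake
#' while preserving the original scale. The adjusted values are exactly
#' uncorrelated with TEI.
#'
#' @param nutrient numeric vector.
#' @param tei total energy intake, same length, non-constant.
#' @return adjusted nutrient vector (missing where either input is).
#' @export
energy_adjust_residual <- function(nutrient, tei) {
  if (length(nutrient) != length(tei)) stop("inputs must have equal length")
  ok <- !is.na(nutrient) & !is.na(tei)
  if (stats::var(tei[ok]) < 1e-12) stop("tei is constant: cannot adjust")
  fit <- stats::lm.fit(cbind(1, tei[ok]), nutrient[ok])
  out <- rep(NA_real_, length(nutrient))
  out[ok] <- fit$residuals + mean(nutrient[ok])
  out
}

#' Exclude implausible energy reporters by food intake level
#'
#' FIL = TEI / BMR. Subjects with FIL strictly below the cohort's 5th
#' percentile or strictly above its 97.5th percentile are flagged for
#' exclusion.
#'
#' @param tei total energy intake, kcal/day.
#' @param bmr basal metabolic rate, kcal/day, positive.
#' @return logical keep-mask (`TRUE` = keep); attribute `fil` carries the
#'   computed ratios.
#' @export
fil_exclusion <- function(tei, bmr) {
  if (any(bmr <= 0, na.rm = TRUE)) stop("bmr must be positive")
  if (length(tei) != length(bmr)) stop("inputs must have equal length")
  if (sum(!is.na(tei) & !is.na(bmr)) < 40) {
    warning("fewer than 40 subjects: FIL percentile estimates are unstable")
  }
  fil <- tei / bmr
  lo <- stats::quantile(fil, 0.05, na.rm = TRUE, names = FALSE)
  hi <- stats::quantile(fil, 0.975, na.rm = TRUE, names = FALSE)
  keep <- !(fil < lo | fil > hi)
  keep[is.na(keep)] <- FALSE
  attr(keep, "fil") <- fil
  keep
}

#' Set out-of-bounds trait values missing
#'
#' Values outside the configured closed plausibility interval
#' `[low, high]` are set missing; boundary values are kept. The number of
#' removals per trait is recorded in the `n_removed` attribute.
#'
#' @param data data frame of subject-visit rows.
#' @param bounds named list, one `c(low, high)` pair per trait column.
#' @return `data` with out-of-bounds entries set `NA`.
#' @export
outlier_removal <- function(data, bounds) {
  removed <- integer(0)
  for (trait in names(bounds)) {
    b <- bounds[[trait]]
    if (length(b) != 2 || b[1] >= b[2]) {
      stop("bounds for '", trait, "' must be c(low, high) with low < high")
    }
    if (!trait %in% names(data)) next
    bad <- !is.na(data[[trait]]) & (data[[trait]] < b[1] | data[[trait]] > b[2])
    data[[trait]][bad] <- NA
    removed[trait] <- sum(bad)
  }
  attr(data, "n_removed") <- removed
  data
}
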