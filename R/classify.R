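#' Classify observations against their prediction intervals
#'
#' A subject whose observed trait value falls beyond their personal 90%
#' prediction interval in the adverse direction is `sensitive`; beyond the
#' interval in the protective direction, `resilient`; inside the interval,
#' `neutral`. For a trait whose adverse direction is `"high"` (blood
#' pressure, lipids, glucose, BMI), above the upper bound is sensitive and
#' below the lower bound resilient; for `"low"` traits (HDL-C) the mapping
#' is mirrored. The interval is treated as closed: values exactly on a
#' bound are neutral. Missing observations return `NA` (unlabeled,
#' excluded downstream).
#'
#' @param observed numeric vector of observed trait values.
#' @param pi a [prediction_interval()] data frame (or any data frame with
#'   `lower` and `upper` columns) aligned with `observed`.
#' @param adverse_direction `"high"` or `"low"`.
#' @return factor with levels `neutral`, `sensitive`, `resilient`.
#' @export
classify_observation <- function(observed, pi,
                                 adverse_direction = c("high", "low")) {
  adverse_direction <- match.arg(adverse_direction)
  if (length(observed) != nrow(pi)) {
    stop("observed and pi must have equal length")
  }
  if (any(pi$lower > pi$upper, na.rm = TRUE)) {
    stop("invalid intervals: lower > upper")
  }
  above <- observed > pi$upper
  below <- observed < pi$lower
  lab <- rep("neutral", length(observed))
  if (adverse_direction == "high") {
    lab[above] <- "sensitive"
    lab[below] <- "resilient"
  } else {
    lab[below] <- "sensitive"
    lab[above] <- "resilient"
  }
  lab[is.na(observed) | is.na(pi$lower) | is.na(pi$upper)] <- NA
  factor(lab, levels = c("neutral", "sensitive", "resilient"))
}

#' Combine two visit labels into a persistence label
#'
#' With the default `"both"` rule a subject is persistently sensitive
#' (resilient) only when classified the same way at both health
#' examinations; discordant pairs are neutral. The `"either"` rule instead
#' promotes a subject to sensitive (resilient) if classified so at either
#' visit, with sensitive taking precedence over resilient in the (rare)
#' discordant sensitive/resilient case. Either visit unlabeled gives `NA`.
#'
#' @param label_visit1,label_visit2 factors from [classify_observation()].
#' @param rule `"both"` (default) or `"either"`.
#' @return factor with levels `neutral`, `sensitive`, `resilient`.
#' @export
persistence_label <- function(label_visit1, label_visit2,
                              rule = c("both", "either")) {
  rule <- match.arg(rule)
  l1 <- as.character(label_visit1)
  l2 <- as.character(label_visit2)
  if (length(l1) != length(l2)) stop("visit labels must have equal length")
  out <- if (rule == "both") {
    ifelse(l1 == l2, l1, "neutral")
  } else {
    ifelse(l1 == "sensitive" | l2 == "sensitive", "sensitive",
           ifelse(l1 == "resilient" | l2 == "resilient", "resilient",
                  "neutral"))
  }
  out[is.na(l1) | is.na(l2)] <- NA
  factor(out, levels = c("neutral", "sensitive", "resilient"))
}

#' Build a subject-level label table for one trait
#'
#' Convenience wrapper producing the delimited-text-ready label table:
#' one row per subject with the single-visit label(s) and, when two
#' visits are supplied, the persistence label.
#'
#' @param subject_id vector of subject identifiers.
#' @param trait trait name.
#' @param observed1,pi1 visit-1 observations and intervals.
#' @param observed2,pi2 optional visit-2 observations and intervals.
#' @param adverse_direction `"high"` or `"low"`.
#' @param rule persistence rule, see [persistence_label()].
#' @return data frame with columns `subject_id`, `trait`, `mode`
#'   (`single_visit` or `persistent`) and `label`.
#' @export
classify_cohort <- function(subject_id, trait, observed1, pi1,
                            observed2 = NULL, pi2 = NULL,
                            adverse_direction = "high", rule = "both") {
  l1 <- classify_observation(observed1, pi1, adverse_direction)
  out <- data.frame(subject_id = subject_id, trait = trait,
                    mode = "single_visit", label = l1)
  if (!is.null(observed2)) {
    l2 <- classify_observation(observed2, pi2, adverse_direction)
    pers <- persistence_label(l1, l2, rule)
    out <- rbind(out, data.frame(subject_id = subject_id, trait = trait,
                                 mode = "persistent", label = pers))
  }
  out
}
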