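#' Iterative random-forest imputation of mixed-type data
#'
#' Nonparametric single imputation in the missForest style: missing cells
#' are initialized with the column mean (continuous) or mode (categorical);
#' columns are then revisited in order of increasing missingness, each
#' regressed on all other (currently completed) columns with a random
#' forest and its missing cells replaced by the forest's predictions. The
#' sweep repeats until the change in the imputed values increases for the
#' first time — measured as the normalized sum of squared differences for
#' continuous columns and the proportion of changed categories for
#' categorical ones — and the previous iterate is returned.
#'
#' Columns with 50% or more missingness are excluded from imputation (left
#' as-is, with a warning); an all-missing column is an error. Per-column
#' error diagnostics are taken from each column's final forest:
#' out-of-bag mean squared error (MSE) for continuous columns and
#' out-of-bag proportion falsely classified (PFC) for categorical ones.
#'
#' @param table data frame with numeric and/or factor columns.
#' @param n_trees trees per column forest (default 100).
#' @param max_iter maximum number of full sweeps (default 10).
#' @param seed integer seed; imputation is deterministic given it.
#' @return object of class `"imputation_result"`: list with `data`
#'   (completed table), `n_iterations`, `mse` (named, continuous columns),
#'   `pfc` (named, categorical columns) and `excluded` (columns skipped
#'   for >= 50% missingness).
#' @export
rf_impute <- function(table, n_trees = 100, max_iter = 10, seed = NULL) {
  if (!is.data.frame(table)) table <- as.data.frame(table)
  if (ncol(table) < 2) stop("need at least 2 columns to impute")
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- nrow(table)
  miss <- vapply(table, function(col) sum(is.na(col)), integer(1))
  if (any(miss == n)) {
    stop("column(s) entirely missing: ",
         paste(names(table)[miss == n], collapse = ", "))
  }
  excluded <- names(table)[miss / n >= 0.5]
  if (length(excluded)) {
    warning("excluded from imputation (>= 50% missing): ",
            paste(excluded, collapse = ", "))
  }
  targets <- setdiff(names(table)[miss > 0], excluded)
  is_cat <- vapply(table, function(col) is.factor(col) ||
                     is.character(col) || is.logical(col), logical(1))
  out <- table
  for (nm in names(out)) {
    if (is_cat[[nm]]) out[[nm]] <- factor(out[[nm]])
  }
  if (length(targets) == 0) {
    return(structure(list(data = out, n_iterations = 0L,
                          mse = numeric(0), pfc = numeric(0),
                          excluded = excluded),
                     class = "imputation_result"))
  }
  # mean/mode initialization of every missing cell (incl. excluded columns
  # so they can still serve as predictors without leaking NA)
  for (nm in names(out)) {
    na_idx <- which(is.na(out[[nm]]))
    if (!length(na_idx)) next
    if (is_cat[[nm]]) {
      tab <- table(out[[nm]])
      out[[nm]][na_idx] <- names(tab)[which.max(tab)]
    } else {
      out[[nm]][na_idx] <- mean(out[[nm]], na.rm = TRUE)
    }
  }
  targets <- targets[order(miss[targets])]
  na_map <- lapply(targets, function(nm) which(is.na(table[[nm]])))
  names(na_map) <- targets

  diff_cont <- Inf
  diff_cat <- Inf
  best <- out
  errs <- stats::setNames(rep(NA_real_, length(targets)), targets)
  iter <- 0L
  fit_seed <- if (is.null(seed)) NULL else as.integer(seed)
  while (iter < max_iter) {
    iter <- iter + 1L
    prev <- out
    for (nm in targets) {
      idx <- na_map[[nm]]
      obs <- setdiff(seq_len(n), idx)
      df <- out[setdiff(names(out), nm)]
      df$.response <- out[[nm]]
      fit <- ranger::ranger(
        dependent.variable.name = ".response",
        data = df[obs, , drop = FALSE],
        num.trees = n_trees, num.threads = 1,
        seed = if (is.null(fit_seed)) NULL else fit_seed + iter,
        respect.unordered.factors = "order")
      pred <- stats::predict(fit, df[idx, , drop = FALSE],
                             num.threads = 1)$predictions
      out[[nm]][idx] <- pred
      errs[nm] <- fit$prediction.error
    }
    # mixed-type stopping rule: stop at the first increase for the types
    # present, returning the previous iterate
    cont_t <- targets[!is_cat[targets]]
    cat_t <- targets[is_cat[targets]]
    new_cont <- if (length(cont_t)) {
      num <- sum(vapply(cont_t, function(nm)
        sum((out[[nm]][na_map[[nm]]] -
               as.numeric(prev[[nm]][na_map[[nm]]]))^2), numeric(1)))
      den <- sum(vapply(cont_t, function(nm)
        sum(out[[nm]][na_map[[nm]]]^2), numeric(1)))
      if (den > 0) num / den else 0
    } else NA_real_
    new_cat <- if (length(cat_t)) {
      changed <- sum(vapply(cat_t, function(nm)
        sum(out[[nm]][na_map[[nm]]] != prev[[nm]][na_map[[nm]]]),
        numeric(1)))
      total <- sum(vapply(cat_t, function(nm) length(na_map[[nm]]),
                          numeric(1)))
      changed / max(total, 1)
    } else NA_real_
    worse_cont <- is.na(new_cont) || new_cont >= diff_cont
    worse_cat <- is.na(new_cat) || new_cat >= diff_cat
    if (iter > 1 && worse_cont && worse_cat) {
      out <- prev
      iter <- iter - 1L
      break
    }
    best <- out
    diff_cont <- if (is.na(new_cont)) diff_cont else new_cont
    diff_cat <- if (is.na(new_cat)) diff_cat else new_cat
  }
  # excluded columns served as mean/mode-filled predictors during the
  # sweeps but are not themselves imputed: restore their missing cells
  for (nm in excluded) out[[nm]][is.na(table[[nm]])] <- NA
  structure(list(
    data = out,
    n_iterations = iter,
    mse = errs[targets[!is_cat[targets]]],
    pfc = errs[targets[is_cat[targets]]],
    excluded = excluded
  ), class = "imputation_result")
}

#' @export
print.imputation_result <- function(x, ...) {
  cat(sprintf("Random-forest imputation: %d iteration(s)\n", x$n_iterations))
  if (length(x$mse)) {
    cat("  OOB MSE:", paste(sprintf("%s=%.4g", names(x$mse), x$mse),
                            collapse = ", "), "\n")
  }
  if (length(x$pfc)) {
    cat("  OOB PFC:", paste(sprintf("%s=%.4g", names(x$pfc), x$pfc),
                            collapse = ", "), "\n")
  }
  if (length(x$excluded)) {
    cat("  excluded (>=50% missing):",
        paste(x$excluded, collapse = ", "), "\n")
  }
  invisible(x)
}
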