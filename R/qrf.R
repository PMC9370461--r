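#' Fit a quantile regression forest
#'
#' Grows an ensemble of CART regression trees on bootstrap resamples of the
#' training data and stores, for every tree, the terminal-node membership of
#' the training observations together with the bootstrap multiplicities.
#' These leaf memberships define the conditional response distribution
#' used by [predict.qrf()] and [prediction_interval()]: the weight of
#' training observation \eqn{i} at a query point \eqn{x} is the average over
#' trees of its bootstrap multiplicity divided by the total bootstrap count
#' of the leaf containing \eqn{x}, and conditional quantiles are inf-type
#' inverses of the resulting weighted empirical CDF.
#'
#' Splits minimize the weighted child variance (equivalently, maximize the
#' between-child sum-of-squares gain); at each node `mtry` features are
#' sampled without replacement and ties between candidate splits are broken
#' towards the lowest feature index and then the lowest split point, so
#' forests are exactly reproducible under a fixed seed. `min_node_size` is
#' a minimum leaf size: only splits leaving at least `min_node_size`
#' observations in each child are admissible, so terminal nodes hold
#' between `min_node_size` and `2 * min_node_size - 1` bootstrap
#' observations (singleton leaves, which would let single extreme
#' responses dominate the conditional distribution estimate, cannot
#' occur). Nodes with zero response variance also become leaves.
#'
#' @param X numeric matrix or data frame of predictors (no missing values).
#' @param y numeric response vector.
#' @param n_trees number of trees (default 500).
#' @param mtry features sampled per split; default `ceiling(p/3)`.
#' @param min_node_size minimum leaf size (default 5).
#' @param seed optional integer seed; when supplied, `set.seed(seed)` is
#'   called so the fit is reproducible.
#' @param bootstrap logical; `FALSE` grows every tree on the full sample
#'   (useful for the single-tree oracle equivalence with empirical
#'   quantiles).
#' @return an object of class `"qrf"`: a list with the fitted `trees`,
#'   `train_nodes` (terminal node of each training row per tree), `inbag`
#'   (bootstrap count matrix), `oob` (per-tree out-of-bag index sets),
#'   `node_purity`, the training `X` and `y`, `feature_names`, and `params`.
#' @seealso [predict.qrf()], [prediction_interval()], [variable_importance()]
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(600), ncol = 3)
#' y <- X[, 1] + rnorm(200, sd = 0.5)
#' fit <- qrf(X, y, n_trees = 50, seed = 1)
#' predict(fit, X[1:5, ], tau = c(0.05, 0.5, 0.95))
#' @export
qrf <- function(X, y, n_trees = 500, mtry = NULL, min_node_size = 5,
                seed = NULL, bootstrap = TRUE) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  n <- nrow(X)
  p <- ncol(X)
  if (n < 20) stop("need at least 20 training observations")
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (anyNA(X) || anyNA(y)) stop("missing values in X or y; impute first")
  if (is.null(mtry)) mtry <- ceiling(p / 3)
  if (!is.null(seed)) set.seed(seed)
  if (stats::var(y) < 1e-12) {
    warning("constant response: trees collapse to single leaves")
  }
  inbag <- if (bootstrap) {
    vapply(seq_len(n_trees),
           function(t) tabulate(sample.int(n, n, replace = TRUE), n),
           integer(n))
  } else {
    matrix(1L, n, n_trees)
  }
  grown <- grow_forest_cpp(X, y, inbag, as.integer(mtry),
                           as.integer(min_node_size))
  structure(list(
    trees = grown$trees,
    train_nodes = grown$train_nodes,
    inbag = inbag,
    oob = apply(inbag, 2, function(cnt) which(cnt == 0L), simplify = FALSE),
    node_purity = as.numeric(grown$node_purity),
    X = X, y = y,
    feature_names = if (is.null(colnames(X))) paste0("x", seq_len(p))
                    else colnames(X),
    params = list(n_trees = n_trees, mtry = mtry,
                  min_node_size = min_node_size, seed = seed,
                  bootstrap = bootstrap)
  ), class = "qrf")
}

qrf_newdata <- function(object, newdata) {
  newdata <- as.matrix(newdata)
  storage.mode(newdata) <- "double"
  if (ncol(newdata) != ncol(object$X)) {
    stop("newdata has ", ncol(newdata), " columns; model expects ",
         ncol(object$X))
  }
  if (anyNA(newdata)) stop("missing values in newdata")
  newdata
}

#' Predict conditional quantiles or means from a quantile regression forest
#'
#' @param object a fitted [qrf()] model.
#' @param newdata matrix or data frame of predictors.
#' @param tau quantile levels in (0, 1); may be a vector.
#' @param what `"quantile"` (default) or `"mean"` for the usual bagged
#'   point prediction.
#' @param ... unused.
#' @return for `"quantile"`, a numeric matrix with one column per `tau`
#'   (a vector if a single `tau`); for `"mean"`, a numeric vector.
#' @export
predict.qrf <- function(object, newdata, tau = c(0.05, 0.95),
                        what = c("quantile", "mean"), ...) {
  what <- match.arg(what)
  newdata <- qrf_newdata(object, newdata)
  nodes <- forest_nodes_cpp(object$trees, newdata)
  if (what == "mean") return(qrf_mean_cpp(object$trees, nodes))
  if (any(tau <= 0) || any(tau >= 1)) stop("tau must lie strictly in (0, 1)")
  q <- qrf_quantiles_cpp(object$trees, object$train_nodes, object$inbag,
                         object$y, nodes, as.numeric(tau))
  colnames(q) <- paste0("q", tau)
  if (length(tau) == 1L) q[, 1L] else q
}

#' Leaf-membership weights at query points
#'
#' Returns the Meinshausen weight of each training observation at each row
#' of `newdata`. Rows sum to one; mainly useful for diagnostics and tests.
#'
#' @inheritParams predict.qrf
#' @return numeric matrix, `nrow(newdata)` by `length(object$y)`.
#' @export
qrf_weights <- function(object, newdata) {
  newdata <- qrf_newdata(object, newdata)
  nodes <- forest_nodes_cpp(object$trees, newdata)
  qrf_weights_cpp(object$trees, object$train_nodes, object$inbag, nodes)
}

#' Conditional prediction interval for a trait
#'
#' The two-sided interval \eqn{[q_{\alpha/2}(Y|X=x),\; q_{1-\alpha/2}(Y|X=x)]}
#' of conditional quantiles; at the default `alpha = 0.10` this is the 90%
#' interval (fifth and 95th conditional quantiles) used to classify
#' observations as sensitive, resilient or neutral.
#'
#' @param object a fitted [qrf()] model.
#' @param newdata matrix or data frame of predictors.
#' @param alpha miscoverage level in (0, 1); default 0.10.
#' @param trait optional trait name carried through to the result.
#' @return data frame of class `"prediction_interval"` with columns
#'   `lower`, `upper` and attributes `alpha`, `trait`.
#' @export
prediction_interval <- function(object, newdata, alpha = 0.10,
                                trait = NULL) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  q <- predict(object, newdata, tau = c(alpha / 2, 1 - alpha / 2))
  out <- data.frame(lower = q[, 1L], upper = q[, 2L])
  stopifnot(all(out$lower <= out$upper))
  attr(out, "alpha") <- alpha
  attr(out, "trait") <- trait
  class(out) <- c("prediction_interval", "data.frame")
  out
}

#' Variable importance for a quantile regression forest
#'
#' Two measures, as conventional for regression forests:
#' `inc_mse_pct` (%IncMSE) is the relative increase in out-of-bag mean
#' squared error when the feature is permuted among a tree's out-of-bag
#' rows, averaged over trees and expressed in percent; `inc_node_purity`
#' is the total between-child sum-of-squares gain attributed to splits on
#' the feature, averaged over trees. Features never used in any split have
#' zero node purity.
#'
#' @param object a fitted [qrf()] model.
#' @param seed optional seed for the permutations.
#' @return data frame with columns `feature`, `inc_mse_pct`,
#'   `inc_node_purity` and `rank` (1 = largest %IncMSE).
#' @export
variable_importance <- function(object, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  inc <- qrf_perm_importance_cpp(object$trees, object$X, object$y,
                                 object$inbag)
  out <- data.frame(feature = object$feature_names,
                    inc_mse_pct = as.numeric(inc),
                    inc_node_purity = object$node_purity)
  out$rank <- rank(-out$inc_mse_pct, ties.method = "first")
  out[order(out$rank), , drop = FALSE]
}

#' @export
print.qrf <- function(x, ...) {
  cat("Quantile regression forest\n")
  cat(sprintf("  n = %d, p = %d, trees = %d, mtry = %d, min_node_size = %d\n",
              nrow(x$X), ncol(x$X), x$params$n_trees, x$params$mtry,
              x$params$min_node_size))
  invisible(x)
}

#' Serialize a quantile regression forest to JSON
#'
#' Writes the complete model state (flat per-tree node arrays, bootstrap
#' counts, training response) so that quantile prediction can be
#' reconstructed with [qrf_from_json()]. Node arrays use 0-based child and
#' feature indices with `split_var = -1` marking leaves.
#'
#' @param object a fitted [qrf()] model.
#' @param path file path to write.
#' @return `path`, invisibly.
#' @export
qrf_to_json <- function(object, path) {
  payload <- list(
    format = "cardiosens-qrf-1",
    params = object$params,
    feature_names = object$feature_names,
    y = object$y,
    inbag = object$inbag,
    train_nodes = object$train_nodes,
    trees = lapply(object$trees, function(tr) {
      lapply(tr, as.vector)
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname qrf_to_json
#' @return `qrf_from_json()` returns a `"qrf"` object able to predict
#'   quantiles (the training predictor matrix is not serialized, so
#'   permutation importance is unavailable on a deserialized model).
#' @export
qrf_from_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "cardiosens-qrf-1")) {
    stop("unrecognized model format")
  }
  # jsonlite simplifies the tree list to a data frame of list columns when
  # shapes allow; normalize back to per-tree lists of typed vectors
  raw <- payload$trees
  if (is.data.frame(raw)) {
    trees <- lapply(seq_len(nrow(raw)), function(i) {
      list(split_var = as.integer(raw$split_var[[i]]),
           split_val = as.numeric(raw$split_val[[i]]),
           left = as.integer(raw$left[[i]]),
           right = as.integer(raw$right[[i]]),
           pred = as.numeric(raw$pred[[i]]),
           node_n = as.integer(raw$node_n[[i]]))
    })
  } else {
    trees <- lapply(raw, function(tr) {
      list(split_var = as.integer(tr$split_var),
           split_val = as.numeric(tr$split_val),
           left = as.integer(tr$left), right = as.integer(tr$right),
           pred = as.numeric(tr$pred), node_n = as.integer(tr$node_n))
    })
  }
  inbag <- matrix(as.integer(payload$inbag), nrow = length(payload$y))
  structure(list(
    trees = trees,
    train_nodes = matrix(as.integer(payload$train_nodes),
                         nrow = length(payload$y)),
    inbag = inbag,
    oob = apply(inbag, 2, function(cnt) which(cnt == 0L), simplify = FALSE),
    node_purity = NULL,
    X = matrix(NA_real_, 0, length(payload$feature_names),
               dimnames = list(NULL, payload$feature_names)),
    y = as.numeric(payload$y),
    feature_names = payload$feature_names,
    params = payload$params
  ), class = "qrf")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
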