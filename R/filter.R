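#' Remove zero-variance and highly correlated predictors
#'
#' Zero-variance columns are dropped first. Then, as long as any pair of
#' remaining columns has absolute Pearson correlation above the threshold,
#' the pair with the largest absolute correlation is located (ties towards
#' the lowest column indices) and the member with the larger mean absolute
#' correlation to all other remaining columns is dropped (ties towards the
#' later column). The procedure is deterministic and the surviving set has
#' all pairwise absolute correlations at or below the threshold.
#'
#' @param X numeric matrix or data frame of predictors.
#' @param corr_threshold absolute correlation above which one of a pair is
#'   dropped (default 0.80).
#' @return character vector of kept column names (attribute `dropped`
#'   records removals and reasons).
#' @export
filter_predictors <- function(X, corr_threshold = 0.80) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  v <- apply(X, 2, stats::var)
  dropped <- data.frame(column = character(0), reason = character(0))
  zv <- colnames(X)[v < 1e-12 | is.na(v)]
  if (length(zv)) {
    dropped <- rbind(dropped, data.frame(column = zv,
                                         reason = "zero variance"))
    X <- X[, setdiff(colnames(X), zv), drop = FALSE]
  }
  if (ncol(X) == 0) stop("no predictors remain after filtering")
  keep <- colnames(X)
  cm <- abs(stats::cor(X))
  diag(cm) <- 0
  while (length(keep) > 1 && max(cm) > corr_threshold) {
    idx <- which(cm == max(cm), arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    i <- idx[1, 1]; j <- idx[1, 2]
    mac <- rowMeans(cm)
    drop_i <- if (mac[i] > mac[j]) i else if (mac[j] > mac[i]) j else max(i, j)
    dropped <- rbind(dropped,
                     data.frame(column = keep[drop_i],
                                reason = sprintf("corr %.3f with %s",
                                                 max(cm),
                                                 keep[setdiff(c(i, j),
                                                              drop_i)])))
    keep <- keep[-drop_i]
    cm <- cm[-drop_i, -drop_i, drop = FALSE]
  }
  if (length(keep) == 0) stop("no predictors remain after filtering")
  attr(keep, "dropped") <- dropped
  keep
}

vif_one <- function(X, j) {
  fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
  ssr <- sum(fit$residuals^2)
  sst <- sum((X[, j] - mean(X[, j]))^2)
  if (ssr / sst < 1e-12) Inf else sst / ssr   # 1 / (1 - R^2)
}

#' Iterative variance-inflation-factor filtering
#'
#' Computes `VIF_j = 1 / (1 - R^2_j)` from regressing each column on the
#' others and repeatedly removes the column with the largest VIF (exact
#' collinearity counts as infinite; ties go to the column with the largest
#' mean absolute correlation to the rest) until all VIFs are at or below
#' the threshold.
#'
#' @param X numeric matrix or data frame with more rows than columns.
#' @param threshold maximum tolerated VIF (default 10).
#' @return character vector of kept column names; attribute `vif` holds
#'   the final VIF of each kept column, attribute `dropped` the removals.
#' @export
vif_filter <- function(X, threshold = 10) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (nrow(X) <= ncol(X)) stop("need more rows than columns")
  keep <- colnames(X)
  dropped <- character(0)
  repeat {
    if (length(keep) < 2) break
    Xk <- X[, keep, drop = FALSE]
    vifs <- vapply(seq_along(keep), function(j) vif_one(Xk, j), numeric(1))
    if (max(vifs) <= threshold) break
    worst <- which(vifs == max(vifs))
    if (length(worst) > 1) {
      # several columns share the top VIF (e.g. an exactly collinear set):
      # drop the one most correlated on average with the rest
      cm <- abs(stats::cor(Xk))
      diag(cm) <- 0
      mac <- rowMeans(cm)[worst]
      worst <- worst[order(-mac, -worst)][1]
    }
    dropped <- c(dropped, keep[worst])
    keep <- keep[-worst]
  }
  Xk <- X[, keep, drop = FALSE]
  final_vif <- if (length(keep) > 1) {
    vapply(seq_along(keep), function(j) vif_one(Xk, j), numeric(1))
  } else rep(1, length(keep))
  attr(keep, "vif") <- stats::setNames(final_vif, keep)
  attr(keep, "dropped") <- dropped
  keep
}
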