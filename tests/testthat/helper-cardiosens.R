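# shared fixtures built in code

# equicorrelated Gaussian columns (plus iid noise columns if p_noise > 0)
make_correlated_data <- function(n, p, rho, seed = 1) {
  set.seed(seed)
  z <- rnorm(n)
  X <- sapply(seq_len(p), function(j) sqrt(rho) * z +
                sqrt(1 - rho) * rnorm(n))
  colnames(X) <- paste0("x", seq_len(p))
  X
}

# small cohort configuration used by pipeline-level tests
quick_config <- function(seed, n = 800, ...) {
  synth_config(n_subjects = n, n_exposures = 10, block_size = 5,
               effects = list(sbp = c(rep(0.4, 5), rep(0, 5))),
               dichotomize_frac = 0, seed = seed, ...)
}

# hand-written Cox partial likelihood for tie-free data, one binary
# covariate; independent oracle for the cox_fit wrapper
neg_log_partial_lik <- function(beta, time, event, x) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; x <- x[ord]
  ll <- 0
  for (i in seq_along(time)) {
    if (event[i] == 1) {
      risk <- which(time >= time[i])
      ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
    }
  }
  -ll
}
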