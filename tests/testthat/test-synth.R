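test_that("exposure generation honours the block correlation structure", {
  cfg0 <- synth_config(n_subjects = 5000, n_exposures = 10, block_size = 5,
                       block_correlation = 0, dichotomize_frac = 0,
                       effects = list(t = rep(0, 10)), seed = 71)
  e0 <- generate_exposures(cfg0)$visit1
  cm0 <- cor(e0)
  diag(cm0) <- 0
  expect_lt(max(abs(cm0)), 0.06)   # independence within Monte-Carlo error

  cfg9 <- synth_config(n_subjects = 5000, n_exposures = 10, block_size = 5,
                       block_correlation = 0.9, dichotomize_frac = 0,
                       effects = list(t = rep(0, 10)), seed = 71)
  e9 <- generate_exposures(cfg9)$visit1
  within <- cor(e9[, 1:5])[upper.tri(diag(5))]
  expect_true(all(within > 0.85 & within < 0.95))
  between <- cor(e9[, 1:5], e9[, 6:10])
  expect_lt(max(abs(between)), 0.06)
})

test_that("exposures are reproducible under a fixed seed and drift across visits", {
  cfg <- quick_config(72)
  a <- generate_exposures(cfg)
  b <- generate_exposures(cfg)
  expect_identical(a, b)
  # AR(1) drift: visits correlated at about ar_coef, stationary marginals
  r <- diag(cor(a$visit1, a$visit2))
  expect_true(all(abs(r - cfg$ar_coef) < 0.1))
  expect_error(synth_config(block_correlation = 1), "\\[0, 1\\)")
})

test_that("trait generation plants the class shift with the configured geometry", {
  # delta = 0: classes indistinguishable
  cfg0 <- synth_config(n_subjects = 2000, n_exposures = 4, block_size = 2,
                       effects = list(t = rep(0.3, 4)), dichotomize_frac = 0,
                       shift_multiplier = 0, prop_sensitive = 0.3,
                       prop_resilient = 0.3, seed = 73)
  e <- generate_exposures(cfg0)$visit1
  cls <- assign_latent_class(cfg0)
  tr <- generate_traits(e, cls, cfg0)[, "t"]
  p <- t.test(tr[cls == "sensitive"], tr[cls == "neutral"])$p.value
  expect_gt(p, 0.01)

  # delta = 3 with null effects: mean difference is 3 * noise_sd
  cfg3 <- synth_config(n_subjects = 20000, n_exposures = 4, block_size = 2,
                       effects = list(t = rep(0, 4)), dichotomize_frac = 0,
                       shift_multiplier = 3, noise_sd = 1.5,
                       prop_sensitive = 0.2, prop_resilient = 0.2,
                       seed = 74)
  e3 <- generate_exposures(cfg3)$visit1
  cls3 <- assign_latent_class(cfg3)
  tr3 <- generate_traits(e3, cls3, cfg3)[, "t"]
  d <- mean(tr3[cls3 == "sensitive"]) - mean(tr3[cls3 == "neutral"])
  expect_lt(abs(d - 3 * 1.5), 0.15)
  # resilient is mirrored
  dr <- mean(tr3[cls3 == "resilient"]) - mean(tr3[cls3 == "neutral"])
  expect_lt(abs(dr + 3 * 1.5), 0.15)

  # adverse-direction low flips the shift sign
  cfg_lo <- synth_config(n_subjects = 20000, n_exposures = 4,
                         block_size = 2, effects = list(hdl = rep(0, 4)),
                         adverse_direction = c(hdl = "low"),
                         dichotomize_frac = 0, shift_multiplier = 3,
                         prop_sensitive = 0.2, prop_resilient = 0.2,
                         seed = 74)
  trl <- generate_traits(e3, cls3, cfg_lo)[, "hdl"]
  dl <- mean(trl[cls3 == "sensitive"]) - mean(trl[cls3 == "neutral"])
  expect_lt(abs(dl + 3), 0.15)   # shift_multiplier * noise_sd = 3, negated

  # degenerate: vanishing noise, zero effects, zero shift
  cfg_degen <- synth_config(n_subjects = 100, n_exposures = 4,
                            block_size = 2, effects = list(t = rep(0, 4)),
                            dichotomize_frac = 0, shift_multiplier = 0,
                            noise_sd = 1e-9, seed = 75)
  trd <- generate_traits(generate_exposures(cfg_degen)$visit1,
                         assign_latent_class(cfg_degen), cfg_degen)
  expect_lt(max(abs(trd)), 1e-6)
  # dimension mismatch rejected
  expect_error(generate_traits(e3[, 1:3], cls3, cfg3), "columns")
})

test_that("survival generation plants the hazard ratio and censors at the horizon", {
  cfg <- synth_config(n_subjects = 10000, n_exposures = 2, block_size = 1,
                      effects = list(t = rep(0, 2)), dichotomize_frac = 0,
                      prop_sensitive = 0.3, prop_resilient = 0.1,
                      hazard_log_hr = log(2), seed = 76)
  cls <- assign_latent_class(cfg)
  sv <- generate_survival(cls, covariates = NULL, cfg = cfg)
  # crude rate ratio before censoring from the uncensored times
  rr <- (1 / mean(sv$true_time[cls == "sensitive"])) /
    (1 / mean(sv$true_time[cls == "neutral"]))
  expect_lt(abs(rr - 2), 0.2)
  expect_true(all(sv$time > 0))
  expect_true(all(sv$time <= cfg$censor_horizon))

  # null hazard: event curves coincide
  cfg0 <- synth_config(n_subjects = 10000, n_exposures = 2, block_size = 1,
                       effects = list(t = rep(0, 2)), dichotomize_frac = 0,
                       prop_sensitive = 0.3, hazard_log_hr = 0, seed = 77)
  cls0 <- assign_latent_class(cfg0)
  sv0 <- generate_survival(cls0, covariates = NULL, cfg = cfg0)
  lr <- survival::survdiff(survival::Surv(time, event) ~ cls0, data = sv0)
  expect_gt(1 - pchisq(lr$chisq, 2), 0.01)

  # tiny horizon: almost everything censored
  cfg_h <- synth_config(n_subjects = 2000, n_exposures = 2, block_size = 1,
                        effects = list(t = rep(0, 2)), dichotomize_frac = 0,
                        censor_horizon = 0.001, seed = 78)
  sv_h <- generate_survival(assign_latent_class(cfg_h), NULL, cfg_h)
  expect_lt(mean(sv_h$event), 0.005)
  expect_error(synth_config(baseline_hazard = 0), "positive")
})

test_that("missingness injection is binomial, masked, and reproducible", {
  set.seed(79)
  tab <- matrix(rnorm(1000 * 10), 1000, 10,
                dimnames = list(NULL, paste0("e", 1:10)))
  inj0 <- inject_missingness(tab, rate = 0)
  expect_identical(inj0$data, tab)
  expect_false(any(inj0$mask))

  inj <- inject_missingness(tab, rate = 0.2, seed = 80)
  frac <- mean(inj$mask)
  expect_gt(frac, 0.19)
  expect_lt(frac, 0.21)
  expect_true(all(is.na(inj$data[inj$mask])))
  expect_identical(inj$original, tab)
  inj_b <- inject_missingness(tab, rate = 0.2, seed = 80)
  expect_identical(inj$mask, inj_b$mask)
  expect_error(inject_missingness(tab, rate = 1), "\\[0, 1\\)")
})

test_that("simulated cohorts respect class proportions, persistence and variance structure", {
  cfg <- synth_config(n_subjects = 6000, n_exposures = 10, block_size = 5,
                      block_correlation = 0.3, dichotomize_frac = 0,
                      effects = list(sbp = c(rep(0.3, 5), rep(0, 5))),
                      seed = 81)
  co <- simulate_cohort(cfg)
  # proportions within binomial error (3 sd ~ 0.011 at n = 6000)
  p_hat <- mean(co$latent_class$class == "sensitive")
  expect_lt(abs(p_hat - cfg$prop_sensitive), 0.012)
  # class constant across visits by construction (stored per subject)
  expect_equal(nrow(co$latent_class), cfg$n_subjects)
  expect_equal(nrow(co$visits), 2L * cfg$n_subjects)
  # marginal trait variance = var(lp) + noise^2 + shift contribution
  Sigma_block <- matrix(0.3, 5, 5); diag(Sigma_block) <- 1
  beta <- rep(0.3, 5)
  var_lp <- drop(t(beta) %*% Sigma_block %*% beta)
  p_s <- cfg$prop_sensitive; p_r <- cfg$prop_resilient
  d <- cfg$shift_multiplier * cfg$noise_sd
  var_shift <- (p_s + p_r) * d^2 - ((p_s - p_r) * d)^2
  v1 <- co$visits[co$visits$visit == 1, ]
  expect_lt(abs(var(v1$sbp) - (var_lp + cfg$noise_sd^2 + var_shift)), 0.25)
  expect_error(synth_config(prop_sensitive = 0.6, prop_resilient = 0.5),
               "below 1")
})

test_that("cohorts round-trip to delimited text with a truth sidecar", {
  co <- simulate_cohort(quick_config(82, n = 60))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "visit1.csv")))
  expect_true(file.exists(file.path(dir, "visit2.csv")))
  v1 <- read.csv(file.path(dir, "visit1.csv"))
  expect_equal(nrow(v1), 60)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(nrow(truth$latent_class), 60)
  expect_equal(truth$config$seed, 82)
})
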