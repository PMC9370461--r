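test_that("medication correction adds the published constants to treated subjects only", {
  d <- data.frame(sbp = c(120, 130), dbp = c(80, 85), tg = c(1.0, 1.5),
                  tc = c(5.0, 6.0), hdl = c(1.2, 1.4), ldl = c(3.0, 3.5),
                  on_bp_med = c(TRUE, FALSE), on_lipid_med = c(TRUE, FALSE))
  out <- medication_correction(d)
  expect_equal(out$sbp[1] - d$sbp[1], 15)
  expect_equal(out$dbp[1] - d$dbp[1], 10)
  expect_equal(out$tg[1] - d$tg[1], 0.208)
  expect_equal(out$tc[1] - d$tc[1], 1.347)
  expect_equal(out$hdl[1] - d$hdl[1], -0.060)
  expect_equal(out$ldl[1] - d$ldl[1], 1.290)
  # untreated row untouched
  expect_equal(unlist(out[2, 1:6]), unlist(d[2, 1:6]))
})

test_that("medication correction is applied exactly once and tolerates missing flags", {
  d <- data.frame(sbp = 120, on_bp_med = TRUE)
  once <- medication_correction(d)
  expect_true(attr(once, "med_corrected"))
  expect_error(medication_correction(once), "already applied")
  # missing flag column: treated as untreated, with a message
  d2 <- data.frame(sbp = 120, on_bp_med = NA)
  expect_message(out <- medication_correction(d2), "untreated")
  expect_equal(out$sbp, 120)
})

test_that("Friedewald LDL-C matches direct arithmetic and respects the validity bound", {
  expect_equal(friedewald_ldl(5.2, 1.0, 2.2), 3.2)
  expect_equal(friedewald_ldl(5.2, 1.0, 0), 4.2)       # zero-TG limit
  expect_true(is.na(friedewald_ldl(5.2, 1.0, 5.0)))    # tg >= 4.52
  expect_true(is.na(friedewald_ldl(5.2, 1.0, 4.52)))
  expect_error(friedewald_ldl(-1, 1, 1), "non-negative")
})

test_that("inverse normal transform reproduces Blom-offset normal quantiles", {
  got <- inverse_normal_transform(c(5, 1, 3))
  want <- qnorm((c(3, 1, 2) - 3 / 8) / (3 + 1 / 4))
  expect_equal(got, want, tolerance = 1e-12)
  expect_equal(round(got, 4), c(0.8694, -0.8694, 0))
  # middle value of an odd-length tie-free vector maps to 0
  x <- c(10, 2, 7, 99, -3)
  expect_equal(inverse_normal_transform(x)[order(x)[3]], 0)
})

test_that("inverse normal transform is rank-invariant, centred, and guards degenerate input", {
  set.seed(42)
  x <- rexp(500)
  t1 <- inverse_normal_transform(x)
  expect_equal(t1, inverse_normal_transform(log(x)))   # monotone invariance
  expect_lt(abs(mean(t1)), 1e-6)
  expect_gt(shapiro.test(t1)$p.value, 0.01)
  expect_error(inverse_normal_transform(rep(1, 10)), "constant")
  expect_error(inverse_normal_transform(c(1, 2)), "at least 3")
  # missing values pass through
  x[3] <- NA
  expect_true(is.na(inverse_normal_transform(x)[3]))
})

test_that("residual-method energy adjustment removes TEI correlation and preserves the mean", {
  set.seed(7)
  tei <- rnorm(300, 2200, 400)
  nutrient <- 0.02 * tei + rnorm(300, sd = 5)
  adj <- energy_adjust_residual(nutrient, tei)
  expect_lt(abs(cor(adj, tei)), 1e-10)
  expect_equal(mean(adj), mean(nutrient))
  # perfect collinearity collapses to the mean
  prop <- 0.01 * tei
  expect_equal(energy_adjust_residual(prop, tei),
               rep(mean(prop), 300), tolerance = 1e-8)
  # independence: adjustment leaves the nutrient nearly unchanged
  indep <- rnorm(300)
  expect_gt(cor(energy_adjust_residual(indep, tei), indep), 0.99)
  expect_error(energy_adjust_residual(indep, rep(2000, 300)), "constant")
})

test_that("FIL exclusion flags the expected tail fractions", {
  set.seed(11)
  bmr <- runif(1000, 1200, 1900)
  tei <- bmr * rnorm(1000, 1.5, 0.3)
  keep <- fil_exclusion(tei, bmr)
  n_excl <- sum(!keep)
  expect_gt(n_excl, 65)   # ~5% + 2.5% of 1000
  expect_lt(n_excl, 85)
  fil <- attr(keep, "fil")
  expect_true(keep[which.min(abs(fil - median(fil)))])  # median kept
  # identical FILs: nothing excluded
  expect_true(all(fil_exclusion(rep(3000, 50), rep(1500, 50))))
  expect_warning(fil_exclusion(rep(3000, 10) + 1:10, rep(1500, 10)),
                 "fewer than 40")
})

test_that("outlier removal blanks out-of-bounds values and keeps boundary values", {
  d <- data.frame(sbp = c(400, 120, 250, 70), dbp = c(80, 80, 80, 80))
  out <- outlier_removal(d, list(sbp = c(70, 250)))
  expect_true(is.na(out$sbp[1]))
  expect_equal(out$sbp[2], 120)
  expect_equal(out$sbp[3], 250)   # closed interval
  expect_equal(out$sbp[4], 70)
  expect_equal(out$dbp, d$dbp)
  expect_equal(attr(out, "n_removed")[["sbp"]], 1L)
  expect_error(outlier_removal(d, list(sbp = c(250, 70))), "low < high")
})
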