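test_that("first-timepoint clearance is A_baso * V_baso / A_stock in every mode", {
  geom <- make_geom()
  w <- make_series(baso = c(100, 80, 60, 40), stock = 1000)
  for (mode in c("per_interval", "literal", "donor_corrected")) {
    cc <- interval_clearance(w, geom, mode)
    expect_equal(cc$clearance[1], 100 * 900 / 1000, info = mode)  # 90 uL
  }
  zero <- interval_clearance(make_series(baso = rep(0, 4)), geom)
  expect_equal(zero$clearance, rep(0, 4))
  expect_equal(zero$cumulative, rep(0, 4))
})

test_that("correction modes behave as specified on later timepoints", {
  geom <- make_geom()
  set.seed(11)
  for (i in 1:20) {
    A <- runif(4, 5, 150)
    As <- runif(1, 500, 2000)
    w <- make_series(baso = A, stock = As)
    per <- interval_clearance(w, geom, "per_interval")$clearance
    lit <- interval_clearance(w, geom, "literal")$clearance
    don <- interval_clearance(w, geom, "donor_corrected")$clearance
    base <- A * 900 / As
    expect_equal(per, base)
    # literal subtracts the volume-factor-scaled excess of previous
    # clearances over the first one
    expect_equal(lit[1], base[1])
    expect_equal(lit[3], base[3] - 3 * sum(base[1:2] - base[1]))
    # donor-corrected divides by the depleted donor signal
    expect_equal(don[2], A[2] * 900 / (As - 3 * A[1]))
    expect_equal(don[4], A[4] * 900 / (As - 3 * sum(A[1:3])))
  }
  expect_error(interval_clearance(
    make_series(baso = c(400, 400, 400, 400), stock = 1000),
    geom, "donor_corrected"), "depleted")
})

test_that("noise-free sink-regime clearances match the closed-form solution", {
  geom <- make_geom()
  ps_all <- 0.05  # slow transport: < 4% total depletion
  p <- sim_params(ps_cell_passive = 1, ps_blank = 1e9, noise_cv = 0,
                  donor_concentration = 100, signal_per_concentration = 1)
  # force exact ps_all by using a single barrier: ps_cell = ps_all, huge blank
  p$ps_cell_passive <- ps_all * 1e9 / (1e9 - ps_all)
  sw <- simulate_well(p, geom, list(well_id = "w", role = "cells",
                                    compound = "x", inhibitor = "none",
                                    treatment = "n/a", channel = "mAU_min"),
                      seed = 1)
  cc <- interval_clearance(sw$series, geom, "per_interval")
  # oracle: receiver amount per interval from the analytic solution
  ca <- 100
  for (i in 1:4) {
    cb <- oracle_interval_cb(ca, ps_all, 300, 900, 60)
    expect_equal(cc$clearance[i], cb * 900 / 100, tolerance = 1e-9)
    ca <- ca - cb * 900 / 300
    # each interval's clearance approximates PS * dt in the sink regime
    expect_equal(cc$clearance[i], ps_all * 60, tolerance = 0.05)
  }
})

test_that("slope fit is OLS through the cumulative curve with origin included", {
  fit <- fit_ps(c(60, 120, 180, 240), c(60, 120, 180, 240))
  expect_equal(fit$ps, 1)
  expect_equal(fit$intercept, 0)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$n_points, 5)
  expect_identical(fit$flag, "ok")

  flat <- fit_ps(c(0, 0, 0, 0), c(60, 120, 180, 240))
  expect_equal(flat$ps, 0)
  expect_identical(flat$flag, "excluded")

  # free intercept: lm oracle on the same augmented points
  y <- c(10, 25, 33, 49)
  x <- c(60, 120, 180, 240)
  o <- lm(c(0, y) ~ c(0, x))
  f <- fit_ps(y, x)
  expect_equal(f$ps, unname(coef(o)[2]), tolerance = 1e-12)
  expect_equal(f$intercept, unname(coef(o)[1]), tolerance = 1e-12)
  expect_error(fit_ps(5, 60), "at least 2")
})

test_that("blank correction follows the series-resistance identity", {
  expect_equal(correct_blank(1, 2), 2)
  expect_equal(correct_blank(1, 1e12), 1, tolerance = 1e-9)
  expect_true(is.na(correct_blank(2, 2)))    # blank-dominated
  expect_true(is.na(correct_blank(3, 2)))
  expect_error(correct_blank(-1, 2), "positive")

  # monotonicity: PS_cell >= PS_all, increasing as the blank gets faster
  set.seed(4)
  ps_all <- runif(50, 0.01, 2)
  ps_blank <- ps_all * runif(50, 1.01, 10)
  ps_cell <- correct_blank(ps_all, ps_blank)
  expect_true(all(ps_cell >= ps_all))
  expect_true(all(correct_blank(ps_all, ps_blank * 0.9 + ps_all * 0.1) >=
                    ps_cell))
})

test_that("Papp conversion is the 10x dimensional factor", {
  expect_equal(papp(0.336, 0.336), 10)  # 1 uL/min/cm^2 = 10 um/min
  expect_equal(papp(0, 0.336), 0)
  expect_equal(papp(c(0.0336, 0.336), 0.336), c(1, 10))
  expect_error(papp(1, 0), "positive")
  expect_error(papp(-1, 0.336), "non-negative")
})

test_that("CF normalisation supports per-insert and group-mean modes", {
  expect_equal(normalize_to_cf(5, 5), 1)
  expect_equal(normalize_to_cf(c(4, 6), c(4, 6)), c(1, 1))
  # group-mean mode on the published group means
  expect_equal(normalize_to_cf(11.90, 4.63, mode = "group_mean"),
               2.570194, tolerance = 1e-6)
  expect_error(normalize_to_cf(5, numeric(0)), "CF")
})

test_that("fold change is the ratio of group means", {
  expect_equal(fold_change(6.66, 3.64)$fold, 1.83, tolerance = 0.005)
  expect_equal(fold_change(7.87, 5.77)$fold, 1.36, tolerance = 0.005)
  expect_equal(fold_change(c(2, 4, 6), c(2, 4, 6))$fold, 1)
  expect_equal(fold_change(c(8, 12), 5)$ratios, c(1.6, 2.4))
  expect_error(fold_change(1, 0), "non-zero")
})

test_that("derived quantities are invariant to overall signal scale", {
  geom <- make_geom()
  A <- c(40, 45, 50, 42)
  for (mode in c("per_interval", "literal", "donor_corrected")) {
    f1 <- fit_ps(interval_clearance(make_series(baso = A, stock = 800),
                                    geom, mode))
    f2 <- fit_ps(interval_clearance(make_series(baso = A * 7.3,
                                                stock = 800 * 7.3),
                                    geom, mode))
    expect_equal(f1$ps, f2$ps, tolerance = 1e-12, info = mode)
  }
})

test_that("cumulated amount performs the unit arithmetic", {
  geom <- make_geom()
  expect_equal(cumulated_amount(make_series(baso = rep(0, 4)), geom, 100), 0)
  # one interval at 1 uM receiver concentration, 900 uL, 33.6 mm^2
  w <- make_series(baso = c(10, 0, 0, 0), stock = 1000)  # 10/1000 * 100 uM = 1 uM
  expect_equal(cumulated_amount(w, geom, 100), 0.9 / 33.6, tolerance = 1e-12)
  expect_error(cumulated_amount(w, geom, 0), "positive")
})
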