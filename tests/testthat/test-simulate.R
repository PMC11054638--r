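test_that("series composition and blank correction are exact inverses", {
  expect_equal(series_ps(2, 2), 1)
  expect_equal(series_ps(0.5, 1e12), 0.5, tolerance = 1e-9)
  set.seed(99)
  a <- runif(1000, 1e-3, 20)
  b <- runif(1000, 1e-3, 20)
  expect_equal(correct_blank(series_ps(a, b), b), a, tolerance = 1e-12)
  expect_error(series_ps(0, 1), "positive")
})

test_that("one-interval solution matches limits and a numerical integrator", {
  geom <- make_geom()
  expect_equal(simulate_interval(100, 0, 0, geom, 60),
               c(Ca = 100, Cb = 0))
  # infinite-time limit: equilibrium partition Ca0 * Va / (Va + Vb)
  eq <- simulate_interval(100, 0, 0.5, geom, 1e9)
  expect_equal(unname(eq["Ca"]), 100 * 300 / 1200, tolerance = 1e-12)
  expect_equal(unname(eq["Cb"]), unname(eq["Ca"]), tolerance = 1e-12)
  # sink/first-order regime: Cb * Vb ~ PS * Ca0 * dt
  s <- simulate_interval(100, 0, 0.02, geom, 5)
  expect_equal(unname(s["Cb"]) * 900, 0.02 * 100 * 5, tolerance = 1e-3)

  skip_if_not_installed("deSolve")
  rhs <- function(t, y, p) {
    flux <- p$ps * (y[1] - y[2])
    list(c(-flux / 300, flux / 900))
  }
  for (ps in c(0.05, 0.3, 1.5)) {
    num <- deSolve::lsoda(c(100, 0), c(0, 60), rhs, list(ps = ps),
                          rtol = 1e-12, atol = 1e-12)
    cf <- simulate_interval(100, 0, ps, geom, 60)
    expect_equal(unname(cf["Ca"]), unname(num[2, 2]), tolerance = 1e-9)
    expect_equal(unname(cf["Cb"]), unname(num[2, 3]), tolerance = 1e-9)
  }
})

test_that("simulated wells conserve mass and expose correct ground truth", {
  geom <- make_geom()
  set.seed(2)
  for (i in 1:10) {
    p <- sim_params(ps_cell_passive = runif(1, 0.02, 0.5),
                    ps_blank = runif(1, 0.5, 2), noise_cv = 0.05)
    sw <- simulate_well(p, geom, list(well_id = "w", role = "cells",
                                      compound = "x", inhibitor = "none",
                                      treatment = "n/a", channel = "mAU_min"),
                        seed = i)
    expect_lt(sw$truth$mass_error, 1e-9)
    expect_equal(sw$truth$ps_all,
                 series_ps(p$ps_cell_passive, p$ps_blank))
    expect_equal(sw$truth$papp_true, 10 * p$ps_cell_passive / 0.336)
  }
  # blank role transports with ps_blank alone; noise-free pipeline recovers it
  pb <- sim_params(ps_cell_passive = 1, ps_blank = 0.1, noise_cv = 0)
  swb <- simulate_well(pb, geom, list(well_id = "b", role = "blank",
                                      compound = "x", inhibitor = "none",
                                      treatment = "n/a", channel = "mAU_min"),
                       seed = 1)
  fit <- fit_ps(interval_clearance(swb$series, geom))
  expect_equal(fit$ps, 0.1, tolerance = 0.05)  # small depletion bias only
  expect_true(is.na(swb$truth$papp_true))
})

test_that("a zero-efficacy inhibitor is a no-op at the same seed", {
  geom <- make_geom()
  p <- sim_params(ps_cell_passive = 0.2, ps_active = -0.05,
                  inhibitor_efficacy = 0, ps_blank = 0.6, noise_cv = 0.03)
  lab <- list(well_id = "w", role = "cells", compound = "x",
              treatment = "n/a", channel = "mAU_min")
  a <- simulate_well(p, geom, c(lab, inhibitor = "none"), seed = 5)
  b <- simulate_well(p, geom, c(lab, inhibitor = "verapamil"), seed = 5)
  expect_identical(a$series$baso_signal, b$series$baso_signal)

  # with full efficacy the inhibitor removes the efflux term
  p$inhibitor_efficacy <- 1
  d <- simulate_well(p, geom, c(lab, inhibitor = "verapamil"), seed = 5)
  expect_equal(d$truth$ps_cell_effective, 0.2)
  expect_equal(b$truth$ps_cell_effective, 0.15)
})

test_that("study generation is deterministic and order-independent", {
  des <- paper_mimic_design(n_cells = 2, n_blank = 1)
  s1 <- generate_study(des, seed = 10)
  s2 <- generate_study(des, seed = 10)
  expect_identical(s1$replicates, s2$replicates)
  expect_identical(s1$truth, s2$truth)
  s3 <- generate_study(des, seed = 11)
  expect_false(identical(s1$replicates$signal, s3$replicates$signal))

  # permuting the design rows leaves every individual well unchanged
  sp <- generate_study(des[rev(seq_len(nrow(des))), ], seed = 10)
  for (nm in names(s1$study$wells)) {
    expect_identical(sp$study$wells[[nm]], s1$study$wells[[nm]])
  }
})

test_that("the study-mimicking design has the published structure", {
  des <- paper_mimic_design(n_cells = 4, n_blank = 2)
  expect_equal(nrow(des), 14)  # 4 NSAIDs x 3 inhibitor arms + CF + diazepam
  sim <- generate_study(des, seed = 1)
  tr <- sim$truth
  native <- tr[!(tr$channel == "RFU" & tr$compound != "CF") |
                 (tr$compound == "CF" & tr$inhibitor == "none" &
                    grepl("^CF_", tr$well_id)), ]
  expect_equal(sum(tr$role == "cells" & !(tr$channel == "RFU")) +
                 sum(tr$role == "cells" & tr$compound == "CF" &
                       grepl("^CF_", tr$well_id)),
               14 * 4)  # 56 native cells series
  # every cells group has a matched blank group (study_table validated it)
  expect_s3_class(sim$study, "study_table")
})

test_that("receiver amount increases strictly with the cell PS", {
  geom <- make_geom()
  amounts <- vapply(c(0.05, 0.1, 0.2, 0.4), function(ps) {
    p <- sim_params(ps_cell_passive = ps, ps_blank = 1.5, noise_cv = 0)
    sw <- simulate_well(p, geom, list(well_id = "w", role = "cells",
                                      compound = "x", inhibitor = "none",
                                      treatment = "n/a", channel = "mAU_min"),
                        seed = 1)
    cumulated_amount(sw$series, geom, 100)
  }, numeric(1))
  expect_true(all(diff(amounts) > 0))
})

test_that("noise-free recovery is within 2% of truth under sink conditions", {
  geom <- make_geom()
  grid <- expand.grid(papp = c(0.5, 2, 5, 12), factor = c(2, 3, 5))
  bias <- mapply(function(pa, fac) {
    ps_cell <- pa * geom$insert_area / 10
    des <- data.frame(compound = "x", inhibitor = "none",
                      ps_cell_passive = ps_cell, ps_blank = fac * ps_cell,
                      n_cells = 1, n_blank = 1, noise_cv = 0)
    sim <- generate_study(des, geom, seed = 1)
    rep <- run_permeability(sim$study)
    est <- rep$groups$papp_mean[1]
    # depletion from the true trajectory: amount left in the donor
    ps_all <- series_ps(ps_cell, fac * ps_cell)
    ca <- 100
    for (i in 1:4) {
      cb <- oracle_interval_cb(ca, ps_all, 300, 900, 60)
      ca <- ca - cb * 900 / 300
    }
    depletion <- 1 - ca / 100
    err <- (est - pa) / pa
    if (depletion < 0.10) expect_lt(abs(err), 0.02)
    abs(err)
  }, grid$papp, grid$factor)
  # bias grows with donor depletion: the fastest case is the worst
  expect_gt(bias[grid$papp == 12 & grid$factor == 5],
            bias[grid$papp == 0.5 & grid$factor == 2])
})
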