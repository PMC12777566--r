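test_that("scaling is the identity within species and allometric across", {
  p <- base_params()
  mouse <- mouse_phys()
  expect_equal(scale_parameters(p, mouse, reference_mass = mouse$body_mass),
               p)
  human <- get_physiology("human")
  # per-kg parameterization (b = 1): per-kg value unchanged, total scales
  # linearly with mass
  ph <- scale_parameters(p, human)
  expect_equal(ph$CL_active, p$CL_active)
  expect_equal(ph$CL_active * human$body_mass, 0.0129 * 70, tolerance = 1e-9)
  # b = 0.75 shrinks the per-kg value for larger bodies
  ph2 <- scale_parameters(p, human, exponent = 0.75, reference_mass = 0.025)
  expect_lt(ph2$CL_active, p$CL_active)
})

test_that("single doses are linear at the bottom of the ladder", {
  p <- base_params()
  tt <- seq(0, 12, 0.5)
  lo <- simulate_regimen(regimen_scenario("human", daily_dose = 1e7,
                                          schedule = "x1", duration = 1),
                         p, times = tt)
  hi <- simulate_regimen(regimen_scenario("human", daily_dose = 2e7,
                                          schedule = "x1", duration = 1),
                         p, times = tt)
  sel <- lo$blood_pfu_ml > 1e-3  # above numerical noise
  ratio <- hi$blood_pfu_ml[sel] / lo$blood_pfu_ml[sel]
  expect_true(all(abs(ratio - 2) < 0.01))
})

test_that("dose-normalized exposure is non-decreasing up the PFU ladder", {
  p <- base_params(); io <- iodine_parameters()
  tt <- seq(0, 24, 0.2)
  auc_per_dose <- vapply(10^c(7, 9, 11, 12), function(d) {
    out <- simulate_regimen(regimen_scenario("human", daily_dose = d,
                                             schedule = "x1", duration = 1),
                            p, io, times = tt)
    auc_trapezoid(tt, pmax(out$blood_pfu_ml, 0)) / d
  }, numeric(1))
  expect_true(all(diff(auc_per_dose) > -1e-9))
})

test_that("repeated dosing approaches a periodic steady state", {
  p <- base_params()
  tt <- seq(0, 24 * 7, 0.25)
  out <- simulate_regimen(regimen_scenario("human", daily_dose = 1e11,
                                           schedule = "Q12H", duration = 7),
                          p, times = tt)
  cyc <- function(start) {
    idx <- tt >= start & tt < start + 12
    max(out$blood_pfu_ml[idx])
  }
  # peaks of the two final dosing intervals agree within 1%
  expect_rel_equal(cyc(24 * 6), cyc(24 * 6 + 12), 0.01)
})

test_that("Monte Carlo bands collapse without uncertainty and repeat with the seed", {
  p <- base_params()
  scen <- regimen_scenario("human", daily_dose = 1e10, schedule = "x1",
                           duration = 1, n_mc = 20, seed = 17)
  tt <- seq(0, 24, 1)
  rse0 <- c(CL_active = 0)
  mc0 <- monte_carlo(scen, p, rse = rse0, times = tt)
  det <- simulate_regimen(scen, p, times = tt)$blood_pfu_ml
  expect_equal(unname(mc0$bands["p50", ]), det, tolerance = 1e-9)
  expect_equal(unname(mc0$bands["p5", ]), unname(mc0$bands["p95", ]),
               tolerance = 1e-9)

  rse <- c(CL_active = 10, Ps = 14.3)
  mc1 <- monte_carlo(scen, p, rse = rse, times = tt)
  mc2 <- monte_carlo(scen, p, rse = rse, times = tt)
  expect_identical(mc1$bands, mc2$bands)
  expect_true(all(mc1$bands["p5", ] <= mc1$bands["p95", ] + 1e-12))
})

test_that("the median band tracks the deterministic curve in the linear regime", {
  p <- base_params()
  scen <- regimen_scenario("human", daily_dose = 1e9, schedule = "x1",
                           duration = 1, n_mc = 200, seed = 23)
  tt <- seq(0.5, 8, 0.5)
  mc <- monte_carlo(scen, p, rse = c(CL_active = 5.10), times = tt)
  det <- simulate_regimen(scen, p, times = tt)$blood_pfu_ml
  expect_lt(max(abs(mc$bands["p50", ] - det) / det), 0.05)
})
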