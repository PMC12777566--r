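test_that("the pooled likelihood matches closed-form contributions", {
  design <- small_design(1)
  truth <- base_params()
  truth$sigma[] <- 1e-12
  d <- generate_study(design, truth, NULL, seed = 4)
  phys <- get_physiology("mouse", design$nominal_mass)
  pred <- predict_dataset(truth, d, phys = phys)

  # single observation, obs = pred, sigma = 1 -> contribution log(2*pi)
  one <- d[1, , drop = FALSE]
  one$value <- pred[1]
  p1 <- truth; p1$sigma[] <- 1
  expect_equal(neg2_log_likelihood(p1, one, phys = phys), log(2 * pi),
               tolerance = 1e-9)

  # three observations with hand-set residuals (1, -2, 0.5), sigma = 2
  three <- d[1:3, , drop = FALSE]
  three$value <- pred[1:3] + c(1, -2, 0.5)
  p2 <- truth; p2$sigma[] <- 2
  hand <- 3 * log(2 * pi * 4) + (1 + 4 + 0.25) / 4
  expect_equal(neg2_log_likelihood(p2, three, phys = phys), hand,
               tolerance = 1e-9)

  # noise-free data at the truth: residual sum of squares is zero, so the
  # objective equals the pure normalization term
  pfull <- truth; pfull$sigma[] <- 1
  expect_equal(neg2_log_likelihood(pfull, transform(d, value = pred),
                                   phys = phys),
               nrow(d) * log(2 * pi), tolerance = 1e-6)
})

test_that("the likelihood is invariant to record order", {
  design <- small_design(1)
  d <- generate_study(design, base_params(), NULL, seed = 6)
  phys <- get_physiology("mouse", design$nominal_mass)
  set.seed(1)
  perm <- sample.int(nrow(d))
  expect_equal(neg2_log_likelihood(base_params(), d, phys = phys),
               neg2_log_likelihood(base_params(), d[perm, ], phys = phys),
               tolerance = 1e-9)
})

test_that("refitting from the optimum is a fixed point", {
  design <- small_design(1)
  truth <- base_params()
  d <- generate_study(design, truth, NULL, seed = 7)
  phys <- get_physiology("mouse", design$nominal_mass)
  fit1 <- fit_pooled(d, init = truth, free = "CL_active", n_starts = 1,
                     phys = phys, compute_rse = FALSE,
                     control = list(rel.tol = 1e-10))
  fit2 <- fit_pooled(d, init = fit1$estimates, free = "CL_active",
                     n_starts = 1, phys = phys, compute_rse = FALSE,
                     control = list(rel.tol = 1e-10))
  expect_lt(abs(fit1$objective - fit2$objective), 1e-6)
})

test_that("reduced noise improves recovery of the permeability coefficient", {
  design <- small_design(1)
  phys <- get_physiology("mouse", design$nominal_mass)
  err <- function(noise_scale, seed) {
    truth <- base_params()
    truth$sigma <- truth$sigma * noise_scale
    d <- generate_study(design, truth, NULL, seed = seed)
    init <- truth; init$Ps <- truth$Ps * 2
    fit <- fit_pooled(d, init = init, free = "Ps", n_starts = 1, phys = phys,
                      compute_rse = FALSE)
    abs(fit$estimates$Ps - 0.0427) / 0.0427
  }
  seeds <- c(21, 22, 23)
  full <- vapply(seeds, function(s) err(1, s), numeric(1))
  tenth <- vapply(seeds, function(s) err(0.1, s), numeric(1))
  expect_lt(median(tenth), median(full))
})

test_that("the likelihood-ratio test has its chi-square boundary cases", {
  lrt <- likelihood_ratio_test(103.841, 100, df = 1)
  expect_equal(lrt$p_value, 0.05, tolerance = 1e-3)
  lrt0 <- likelihood_ratio_test(100, 100, df = 1)
  expect_equal(lrt0$p_value, 1)
  expect_false(lrt0$reject)
  expect_error(likelihood_ratio_test(100, 101, df = 1), "optimization-quality")
})

test_that("RSEs are finite and the information matrix is usable", {
  design <- small_design(1)
  truth <- base_params()
  d <- generate_study(design, truth, NULL, seed = 8)
  phys <- get_physiology("mouse", design$nominal_mass)
  fit <- fit_pooled(d, init = truth, free = c("Ps", "CL_active"),
                    n_starts = 1, phys = phys, compute_rse = TRUE,
                    control = list(rel.tol = 1e-8))
  expect_true(all(is.finite(fit$rse_pct)))
  expect_true(all(fit$ci95[, "lo"] < fit$ci95[, "hi"]))
  expect_true(all(fit$ci95[, "lo"] > 0))
})
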