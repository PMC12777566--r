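test_that("the generated dataset matches the destructive design combinatorics", {
  design <- small_design(n_per_group = 2)
  d <- generate_study(design, base_params(), default_effects(), seed = 5)
  # per strain: 6 groups x n x 12 measured quantities + 4 early-blood
  # groups x n x 1 blood value
  per_strain <- 6 * 2 * length(design$tissues) + 4 * 2
  expect_equal(nrow(d), 3 * per_strain)
  # destructive sampling: every animal contributes exactly one time point
  tp <- tapply(d$time_h, d$animal_id, function(x) length(unique(x)))
  expect_true(all(tp == 1))
  # body masses within the declared range
  expect_true(all(d$body_mass_kg >= 0.022 & d$body_mass_kg <= 0.030))
  expect_true(all(d$value >= 0))
})

test_that("generation is deterministic given the seed", {
  design <- small_design(1)
  a <- generate_study(design, base_params(), default_effects(), seed = 9)
  b <- generate_study(design, base_params(), default_effects(), seed = 9)
  expect_identical(a, b)
  c2 <- generate_study(design, base_params(), default_effects(), seed = 10)
  expect_false(isTRUE(all.equal(a$value, c2$value)))
})

test_that("noise-free generation reproduces the model exactly", {
  design <- small_design(1)
  truth <- base_params()
  truth$sigma[] <- 1e-12
  d <- generate_study(design, truth, default_effects(), seed = 2)
  pred <- predict_dataset(truth, d,
                          phys = get_physiology("mouse", design$nominal_mass),
                          use_covariate = TRUE)
  expect_lt(max(abs(d$value - pred)), 1e-8)
  # and the residual sum of squares vanishes at the truth
  expect_lt(sum((d$value - pred)^2), 1e-18)
})

test_that("a planted clearance reduction raises that strain's blood exposure", {
  design <- small_design(1)
  truth <- base_params()
  truth$sigma[] <- 1e-12
  blood_auc_of <- function(d, strain) {
    sub <- d[d$strain == strain & d$tissue == "blood", ]
    agg <- aggregate(value ~ time_h, sub, median)
    auc_trapezoid(agg$time_h, agg$value)
  }
  d_eff <- generate_study(design, truth,
                          plant_covariate(strain = "PAML-31-1",
                                          effect = exp(-1.94)), seed = 3)
  expect_gt(blood_auc_of(d_eff, "PAML-31-1"), blood_auc_of(d_eff, "Luz24"))
  expect_gt(blood_auc_of(d_eff, "PAML-31-1"), blood_auc_of(d_eff, "OMKO1"))
  # a unit effect is a no-op
  d_null <- generate_study(design, truth, NULL, seed = 3)
  d_one <- generate_study(design, truth,
                          plant_covariate(strain = "PAML-31-1", effect = 1),
                          seed = 3)
  expect_equal(d_null$value, d_one$value)
  # the effect follows the strain label
  d_omk <- generate_study(design, truth,
                          plant_covariate(strain = "OMKO1",
                                          effect = exp(-1.94)), seed = 3)
  expect_gt(blood_auc_of(d_omk, "OMKO1"), blood_auc_of(d_omk, "Luz24"))
})

test_that("designed tissues must carry a residual sigma", {
  design <- small_design(1)
  design$tissues <- c(design$tissues, "skin")
  expect_error(generate_study(design, base_params(), NULL, seed = 1),
               "without a residual sigma")
  expect_error(plant_covariate(strain = "PAML-31-1", effect = -2), "positive")
  expect_error(plant_covariate(strain = "nope", effect = 2), "unknown strain")
})
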