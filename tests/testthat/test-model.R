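test_that("derivatives vanish for the empty system and at exchange equilibrium", {
  p <- base_params(); io <- iodine_quiet(); phys <- mouse_phys()
  y0 <- initial_state(p, io, phys)
  d0 <- tissue_derivatives(y0, 0, p, io, phys)
  expect_equal(unname(d0), rep(0, length(d0)))

  # one tissue at vascular/interstitial equilibrium with arterial blood:
  # its exchange terms must vanish
  y <- y0
  m <- phagepbpk:::build_model(p, io, phys, dose_regimen())
  Ca <- 10
  y["blood.art"] <- Ca * m$V_art
  i <- which(m$organs$name == "brain")  # no active clearance, no portal role
  Vv <- m$organs$V_vas_L[i]; Vint <- m$organs$V_int_L[i]
  y[paste0("brain.vas")] <- Ca * Vv
  y[paste0("brain.int")] <- p$Kp_Crs * Ca * Vint
  d <- tissue_derivatives(y, 0, p, io, phys)
  # flow term zero (Cv = Ca) and permeation term zero (Cint = Kp * Cv);
  # only MPS uptake moves interstitial phage
  expect_equal(unname(d["brain.vas"]), 0, tolerance = 1e-12)
  kup <- log(2) / p$T_up
  expect_equal(unname(d["brain.int"]), -kup * y["brain.int"][[1]],
               tolerance = 1e-9)
})

test_that("vascular balance reproduces the hand-computed permeability-limited form", {
  # hand oracle: dCv*Vv = Q*(Ca - Cv) - P*Q*(Cv - Cint/Kp)
  #            = 0.1*(1 - 0.5) - 0.0427*0.1*(0.5 - 0.2/0.934) = 0.04877942...
  organs <- data.frame(
    name = c("blood", "lung", "muscle", "carcass"),
    weight_fraction = c(0.05, 0.01, 0.10, 0.84),
    flow_fraction = c(0, 1, 0.1, 0.9),
    vascular_fraction = c(1, 0.25, 0.1, 0.04),
    interstitial_fraction = c(0, 0.2, 0.2, 0.1),
    phagocyte_density = 0,
    stringsAsFactors = FALSE
  )
  phys <- physiology_table("mouse", 0.1, organs, cardiac_output = 1,
                           blood_volume = 0.005)
  expect_length(validate_physiology(phys), 0)
  p <- base_params(); io <- iodine_parameters(k_deconj = 1e-30)
  y <- initial_state(p, io, phys)
  m <- phagepbpk:::build_model(p, io, phys, dose_regimen())
  y["blood.art"] <- 1 * m$V_art          # C_a = 1
  y["muscle.vas"] <- 0.5 * 0.001         # C_v = 0.5, V_v = 0.001 L
  y["muscle.int"] <- 0.2 * 0.002         # C_int = 0.2, V_int = 0.002 L
  d <- tissue_derivatives(y, 0, p, io, phys)
  hand <- 0.1 * (1 - 0.5) - 0.0427 * 0.1 * (0.5 - 0.2 / 0.934)
  expect_equal(unname(d["muscle.vas"]), hand, tolerance = 1e-12)
  expect_equal(hand, 0.04877935, tolerance = 1e-6)
})

test_that("R and compiled right-hand sides agree on random states", {
  p <- base_params(); io <- iodine_parameters(); phys <- mouse_phys()
  m <- phagepbpk:::build_model(p, io, phys, dose_regimen())
  nst <- length(m$state_names)
  set.seed(42)
  for (rep in 1:5) {
    y <- runif(nst, 0, 2)
    names(y) <- m$state_names
    dR <- tissue_derivatives(y, 0, p, io, phys)
    dC <- deSolve::lsoda(
      y = unname(y), times = c(0, 1e-9), func = "phage_derivs",
      parms = m$parms, dllname = "phagepbpk", initfunc = "phage_init",
      nout = 1, rtol = 1e-10, atol = 1e-12
    )
    # forward-Euler consistency over an infinitesimal step
    dApprox <- (dC[2, 2:(nst + 1)] - y) / 1e-9
    expect_equal(unname(dApprox), unname(dR), tolerance = 1e-4)
  }
})

test_that("state dimension mismatches are a structural error", {
  p <- base_params(); io <- iodine_parameters(); phys <- mouse_phys()
  expect_error(tissue_derivatives(numeric(3), 0, p, io, phys),
               "compartments")
})

test_that("mass balance and nonnegativity hold across regimens", {
  p <- base_params(); io <- iodine_parameters(); phys <- mouse_phys()
  sims <- list(
    simulate_phage(p, io, phys, dose_regimen(), times = seq(0, 24, 0.5)),
    simulate_phage(p, io, phys,
                   dose_regimen(route = "infusion", infusion_duration = 5 / 60),
                   times = seq(0, 12, 0.25)),
    simulate_phage(p, io, phys,
                   dose_regimen(schedule = "Q12H", n_doses = 3),
                   times = seq(0, 36, 0.5))
  )
  for (sim in sims) {
    expect_lt(sim$mass_balance_residual, 0.1)
    expect_gt(min(sim$amounts), -1e-6)
  }
})

test_that("zero-like dose produces a zero-like result", {
  p <- base_params(); io <- iodine_parameters(); phys <- mouse_phys()
  # the homogeneous system stays at the origin; probe via the derivative
  y0 <- initial_state(p, io, phys)
  expect_equal(max(abs(tissue_derivatives(y0, 0, p, io, phys))), 0)
})

test_that("with elimination pathways disabled total phage is conserved", {
  p <- base_params(CL_active = 1e-15, T_deg = 1e12)
  io <- iodine_quiet()
  phys <- mouse_phys()
  sim <- simulate_phage(p, io, phys, dose_regimen(), times = seq(0, 24, 1))
  phage_cols <- grep("\\.(vas|int|mps)$|blood\\.(ven|art)", colnames(sim$amounts))
  total <- rowSums(sim$amounts[, phage_cols])
  expect_equal(total, rep(100, length(total)), tolerance = 1e-6)
  # and no free label is generated
  free_cols <- grep("fmp|free", colnames(sim$amounts))
  expect_lt(max(abs(sim$amounts[, free_cols])), 1e-6)
})

test_that("simulated blood matches the analytic linear-system solution", {
  # all organs collapsed into one generic tissue, MPS and active clearance
  # disabled: the system is linear; oracle = eigen-decomposition of the
  # independently assembled rate matrix
  phys <- tiny_phys()
  p <- base_params(CL_active = 1e-15)
  io <- iodine_parameters(k_deconj = 1e-30)
  m <- phagepbpk:::build_model(p, io, phys, dose_regimen())
  org <- m$organs
  CO <- phys$cardiac_output
  Qc <- org$flow_L_h[org$name == "carcass"]
  Vlv <- org$V_vas_L[org$name == "lung"]; Vli <- org$V_int_L[org$name == "lung"]
  Vcv <- org$V_vas_L[org$name == "carcass"]; Vci <- org$V_int_L[org$name == "carcass"]
  Kl <- p$Kp_LunKid; Kc <- p$Kp_Crs; P <- p$Ps
  # states: ven, art, lung.v, lung.i, carc.v, carc.i (amounts)
  A <- matrix(0, 6, 6)
  A[1, 1] <- -CO / m$V_ven;        A[1, 5] <- Qc / Vcv
  A[2, 3] <- CO / Vlv;             A[2, 2] <- -CO / m$V_art
  A[3, 1] <- CO / m$V_ven
  A[3, 3] <- -CO / Vlv - P * CO / Vlv
  A[3, 4] <- P * CO / (Kl * Vli)
  A[4, 3] <- P * CO / Vlv;         A[4, 4] <- -P * CO / (Kl * Vli)
  A[5, 2] <- Qc / m$V_art
  A[5, 5] <- -Qc / Vcv - P * Qc / Vcv
  A[5, 6] <- P * Qc / (Kc * Vci)
  A[6, 5] <- P * Qc / Vcv;         A[6, 6] <- -P * Qc / (Kc * Vci)
  y0 <- c(100, 0, 0, 0, 0, 0)
  eg <- eigen(A)
  coef0 <- solve(eg$vectors, y0)
  times <- seq(0, 24, 1)
  oracle <- t(sapply(times, function(t)
    Re(eg$vectors %*% (coef0 * exp(eg$values * t)))))
  sim <- simulate_phage(p, io, phys, dose_regimen(), times = times)
  blood_sim <- sim$amounts[, "blood.ven"] + sim$amounts[, "blood.art"]
  blood_oracle <- oracle[, 1] + oracle[, 2]
  expect_lt(max(abs(blood_sim - blood_oracle) / blood_oracle), 0.005)
})

test_that("raising the PFU dose lowers the early fraction degraded by the MPS", {
  p <- base_params(); io <- iodine_quiet(); phys <- mouse_phys()
  frac <- vapply(c(1e8, 1e9, 1e10, 1e11), function(d) {
    sim <- simulate_phage(p, io, phys, dose_regimen(dose_pfu = d),
                          times = c(0, 1, 2))
    am <- sim$amounts[3, ]
    deg <- sum(am[grep("fmp", names(am))]) + am["free.blood"] +
      am["free.thyroid"] + am["free.eliminated"]
    unname(deg) / 100
  }, numeric(1))
  expect_true(all(diff(frac) < 0))
})

test_that("observable concentrations conserve the dose and convert units", {
  p <- base_params(); io <- iodine_parameters(); phys <- mouse_phys()
  sim <- simulate_phage(p, io, phys, dose_regimen(), times = c(0, 2, 8))
  obs <- observable_concentrations(sim)
  org <- sim$model$organs
  for (tt in c(2, 8)) {
    snap <- obs[abs(obs$time_h - tt) < 1e-9, ]
    conc <- snap[snap$unit == "percentID_per_g", ]
    masses <- c(setNames(org$mass_kg * 1000, org$name),
                blood = phys$blood_volume * 1000)
    total <- sum(conc$value * masses[conc$tissue]) +
      sum(snap$value[snap$unit == "percentID"])
    # remaining label not in the snapshot: transit/elimination sinks
    am <- sim$amounts[abs(sim$times - tt) < 1e-9, ]
    sinks <- am["gi_sink"] + am["urine_sink"] + am["free.eliminated"]
    expect_equal(unname(total + sinks), 100, tolerance = 0.1)
  }
  expect_error(observable_series(sim, "plasmaX"), "no observable")
})

test_that("PFU/mL conversion matches the plasma-volume arithmetic", {
  p <- base_params(); io <- iodine_parameters()
  phys <- get_physiology("human")
  sim <- simulate_phage(p, io, phys,
                        dose_regimen(amount = 1e12, dose_unit = "PFU"),
                        times = c(0, 1))
  pfu <- blood_pfu_per_ml(sim)
  # the full dose in 5 L of blood: 1e12 / 5000 mL = 2e8 PFU/mL
  expect_equal(pfu[1], 2e8, tolerance = 1e-9)
  sim_pct <- simulate_phage(p, io, phys, dose_regimen(), times = c(0, 1))
  expect_error(blood_pfu_per_ml(sim_pct), "dose_unit")
})

test_that("simulation requires sorted nonnegative times", {
  p <- base_params(); io <- iodine_parameters(); phys <- mouse_phys()
  expect_error(simulate_phage(p, io, phys, times = c(2, 1)), "sorted")
})
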