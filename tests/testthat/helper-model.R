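# Shared fixtures, built in code at test time.

`%||%` <- function(a, b) if (is.null(a)) b else a

mouse_phys <- function(mass = 0.025) get_physiology("mouse", mass)

base_params <- function(...) phage_parameters(...)

# free-label constants with deconjugation effectively off, to isolate the
# labeled-phage system in structural tests
iodine_quiet <- function() iodine_parameters(k_deconj = 1e-15)

# minimal flow topology: blood pools, an in-series lung and a single
# perfused "carcass" tissue; used for analytic linear-system oracles
tiny_phys <- function(body_mass = 0.1, cardiac_output = 1,
                      lung_flow = 1, carcass_flow = 1) {
  organs <- data.frame(
    name = c("blood", "lung", "carcass"),
    weight_fraction = c(0.05, 0.01, 0.94),
    flow_fraction = c(0, lung_flow, carcass_flow),
    vascular_fraction = c(1, 0.25, 0.04),
    interstitial_fraction = c(0, 0.2, 0.1),
    phagocyte_density = c(0, 0, 0),
    stringsAsFactors = FALSE
  )
  phys <- physiology_table("mouse", body_mass, organs,
                           cardiac_output = cardiac_output,
                           blood_volume = 0.05 * body_mass)
  expect_length(validate_physiology(phys), 0)
  phys
}

# small three-strain study design for estimation tests (full tissue panel,
# fewer animals per group than the reference design)
small_design <- function(n_per_group = 2) {
  study_design(n_per_group = n_per_group)
}

default_effects <- function() {
  plant_covariate(strain = "PAML-31-1", effect = exp(-1.94))
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
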