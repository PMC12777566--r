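#' Biodistribution study design
#'
#' The destructive-sampling mouse design: per strain, six groups of
#' `n_per_group` animals each euthanized at one terminal time with all
#' measured quantities collected, plus four separate early-blood groups
#' (retro-orbital microsamples) contributing one blood value each. The
#' intermediate-size strain is followed to 72 h instead of 8 h.
#'
#' @param strains Named vector of phage diameters, nm.
#' @param terminal_times Named list of per-strain terminal times, h.
#' @param early_blood_times Early blood sampling times, h.
#' @param n_per_group Animals per group.
#' @param tissues Measured quantities (must each carry a residual sigma).
#' @param body_mass_range Per-animal body-mass sampling range, kg
#'   (metadata; the pooled generative model runs at `nominal_mass`).
#' @param nominal_mass Body mass of the generative simulation, kg.
#' @param dose_value,dose_unit,dose_pfu Administered dose description.
#' @param species Species label.
#' @return An object of class `study_design`.
#' @export
study_design <- function(strains = strain_sizes(),
                         terminal_times = list(
                           "Luz24" = c(0.5, 1, 2, 4, 8, 24),
                           "PAML-31-1" = c(0.5, 1, 2, 4, 24, 72),
                           "OMKO1" = c(0.5, 1, 2, 4, 8, 24)
                         ),
                         early_blood_times = c(1, 5, 15, 30) / 60,
                         n_per_group = 5,
                         tissues = MEASURED_TISSUES,
                         body_mass_range = c(0.022, 0.030),
                         nominal_mass = 0.026,
                         dose_value = 100,
                         dose_unit = "percentID",
                         dose_pfu = 1e10,
                         species = "mouse") {
  stopifnot(n_per_group >= 1)
  for (s in names(strains)) {
    tt <- terminal_times[[s]]
    if (is.null(tt) || any(tt <= 0) || is.unsorted(tt, strictly = TRUE)) {
      stop(sprintf("terminal times for %s must be positive and sorted", s),
           call. = FALSE)
    }
  }
  structure(
    list(strains = strains, terminal_times = terminal_times,
         early_blood_times = early_blood_times, n_per_group = n_per_group,
         tissues = tissues, body_mass_range = body_mass_range,
         nominal_mass = nominal_mass, dose_value = dose_value,
         dose_unit = dose_unit, dose_pfu = dose_pfu, species = species),
    class = "study_design"
  )
}

#' Plant a strain-specific clearance effect in a generation config
#'
#' Returns a covariate-effect vector for [generate_study()] in which the
#' named strain's active clearance is multiplied by `effect` during
#' simulation (e.g. `exp(-1.94)` for the reduced-clearance strain).
#'
#' @param effects Existing named effect vector (default none).
#' @param strain Strain label.
#' @param effect Positive multiplier on `CL_active`.
#' @return Named numeric vector of multipliers.
#' @export
plant_covariate <- function(effects = NULL, strain, effect) {
  if (!is.finite(effect) || effect <= 0) {
    stop("covariate effect must be positive", call. = FALSE)
  }
  norm <- normalize_strain(strain)
  if (is.na(norm)) stop(sprintf("unknown strain '%s'", strain), call. = FALSE)
  out <- effects %||% setNames(numeric(0), character(0))
  out[norm] <- effect
  out
}

#' Generate a synthetic biodistribution dataset
#'
#' Simulates the PBPK model for each strain (with any planted covariate
#' multipliers on `CL_active`), samples each terminal animal's measured
#' quantities at its single euthanasia time (destructive design: one time
#' point per animal), adds separate early-blood animals, and applies
#' independent additive Gaussian residual noise with the per-tissue sigmas,
#' truncated (floored) at zero.
#'
#' @param design A [study_design()].
#' @param truth True [phage_parameters()] (sigmas included).
#' @param covariate_effects Named multipliers on `CL_active` per strain,
#'   e.g. from [plant_covariate()]; `NULL` for none.
#' @param seed Integer RNG seed (required; generation is deterministic
#'   given the seed).
#' @param iodine [iodine_parameters()].
#' @param phys Physiology; defaults to the design species at
#'   `design$nominal_mass`.
#' @return Data frame in the exchange schema: `animal_id`, `strain`,
#'   `size_nm`, `species`, `body_mass_kg`, `dose_value`, `dose_unit`,
#'   `time_h`, `tissue`, `value`, `unit`.
#' @export
generate_study <- function(design, truth, covariate_effects = NULL, seed,
                           iodine = iodine_parameters(), phys = NULL) {
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  missing_sigma <- setdiff(design$tissues, names(truth$sigma))
  if (length(missing_sigma) > 0) {
    stop("designed tissues without a residual sigma: ",
         paste(missing_sigma, collapse = ", "), call. = FALSE)
  }
  if (is.null(phys)) {
    phys <- get_physiology(design$species, design$nominal_mass)
  }
  regimen <- dose_regimen(amount = design$dose_value,
                          dose_unit = design$dose_unit,
                          dose_pfu = design$dose_pfu)
  set.seed(as.integer(seed))
  rows <- list()
  animal <- 0L
  for (s in names(design$strains)) {
    pars <- truth
    eff <- covariate_effects[s]
    if (length(eff) == 1 && !is.na(eff)) pars$CL_active <- pars$CL_active * eff
    tgrid <- sort(unique(c(design$early_blood_times, design$terminal_times[[s]])))
    sim <- simulate_phage(pars, iodine, phys, regimen,
                          times = sort(unique(c(0, tgrid))))
    obs <- observable_concentrations(sim)
    pred <- function(tissue, t) {
      v <- obs$value[obs$tissue == tissue & abs(obs$time_h - t) < 1e-9]
      if (length(v) != 1) stop("internal: prediction lookup failed")
      v
    }
    for (t in design$terminal_times[[s]]) {
      for (k in seq_len(design$n_per_group)) {
        animal <- animal + 1L
        bm <- runif(1, design$body_mass_range[1], design$body_mass_range[2])
        for (tissue in design$tissues) {
          mu <- pred(tissue, t)
          val <- max(0, mu + rnorm(1, 0, truth$sigma[[tissue]]))
          rows[[length(rows) + 1L]] <- data.frame(
            animal_id = sprintf("A%04d", animal), strain = s,
            size_nm = unname(design$strains[s]), species = design$species,
            body_mass_kg = bm, dose_value = design$dose_value,
            dose_unit = design$dose_unit, time_h = t, tissue = tissue,
            value = val,
            unit = if (tissue %in% c("stomach_contents", "urine"))
              "percentID" else "percentID_per_g",
            stringsAsFactors = FALSE
          )
        }
      }
    }
    for (t in design$early_blood_times) {
      for (k in seq_len(design$n_per_group)) {
        animal <- animal + 1L
        bm <- runif(1, design$body_mass_range[1], design$body_mass_range[2])
        mu <- pred("blood", t)
        rows[[length(rows) + 1L]] <- data.frame(
          animal_id = sprintf("A%04d", animal), strain = s,
          size_nm = unname(design$strains[s]), species = design$species,
          body_mass_kg = bm, dose_value = design$dose_value,
          dose_unit = design$dose_unit, time_h = t, tissue = "blood",
          value = max(0, mu + rnorm(1, 0, truth$sigma[["blood"]])),
          unit = "percentID_per_g", stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
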