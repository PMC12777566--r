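#' @keywords internal
ORGAN_NAMES <- c(
  "blood", "lung", "muscle", "bone", "liver", "stomach", "spleen",
  "small_intestine", "large_intestine", "kidney", "skin", "brain",
  "thyroid", "carcass"
)

# organs whose venous outflow enters the liver via the hepatic portal vein
PORTAL_ORGANS <- c("stomach", "spleen", "small_intestine", "large_intestine")

# organs carrying first-order active surface-site clearance; the kidney
# portion is excreted to urine, the rest to the stomach-contents pool
ACTIVE_URINARY_ORGANS <- "kidney"
ACTIVE_GASTRIC_ORGANS <- c("liver", "stomach", "small_intestine", "large_intestine")

# tissues with a fitted residual error (the measured observables); skin,
# brain, thyroid and carcass are simulated but excluded from the likelihood
MEASURED_TISSUES <- c(
  "blood", "lung", "liver", "spleen", "small_intestine", "large_intestine",
  "muscle", "kidney", "stomach", "bone", "stomach_contents", "urine"
)

#' Load a species physiology table
#'
#' Reads the packaged anatomical/physiological reference table for a species
#' (organ weight fractions, blood-flow fractions, vascular and interstitial
#' sub-volume fractions, and tissue-resident phagocyte densities) and
#' evaluates it at a body mass. Absolute organ masses are
#' `weight_fraction * body_mass` (tissue density taken as 1 g/mL), organ
#' blood flows are `flow_fraction * cardiac_output`, and cardiac output
#' follows the packaged allometric rule `CO = a * BW^b` (defaults
#' a = 16.5 L/h, b = 0.75, BW in kg). The lung is perfused in series with
#' the full cardiac output; all other organs are perfused in parallel from
#' arterial blood, with the carcass balancing both mass and flow closure.
#'
#' @param species One of `"mouse"`, `"rat"`, `"human"`.
#' @param body_mass Body mass in kg; defaults to the species reference mass
#'   (0.025, 0.25 and 70 kg respectively).
#' @param config Optional path to a YAML physiology file overriding the
#'   packaged table (same schema).
#' @return An object of class `phage_physiology`: a list with `species`,
#'   `body_mass` (kg), `cardiac_output` (L/h), `blood_volume` (L),
#'   `venous_fraction`, and `organs`, a data frame with one row per organ
#'   carrying the configured fractions plus derived absolute quantities
#'   `mass_kg`, `volume_L`, `flow_L_h`, `V_vas_L`, `V_int_L`.
#' @export
#' @examples
#' phys <- get_physiology("mouse", 0.025)
#' phys$cardiac_output
get_physiology <- function(species, body_mass = NULL, config = NULL) {
  if (length(species) != 1L || !is.character(species)) {
    stop("`species` must be a single species label", call. = FALSE)
  }
  if (is.null(config)) {
    config <- system.file(
      "extdata", "physiology", paste0(species, ".yaml"),
      package = "phagepbpk"
    )
    if (!nzchar(config)) {
      stop(sprintf(
        "unsupported species '%s' (no packaged physiology; supported: mouse, rat, human)",
        species
      ), call. = FALSE)
    }
  }
  cfg <- yaml::read_yaml(config)
  if (!identical(cfg$species, species)) {
    stop(sprintf("physiology file is for species '%s', not '%s'",
                 cfg$species, species), call. = FALSE)
  }
  if (is.null(body_mass)) body_mass <- cfg$body_mass_default
  organs <- do.call(rbind, lapply(cfg$organs, function(o) {
    data.frame(
      name = o$name,
      weight_fraction = as.numeric(o$weight_fraction),
      flow_fraction = as.numeric(o$flow_fraction),
      vascular_fraction = as.numeric(o$vascular_fraction),
      interstitial_fraction = as.numeric(o$interstitial_fraction),
      phagocyte_density = as.numeric(o$phagocyte_density),
      stringsAsFactors = FALSE
    )
  }))
  co <- cfg$cardiac_output$coefficient_L_h * body_mass^cfg$cardiac_output$exponent
  phys <- physiology_table(
    species = species,
    body_mass = body_mass,
    organs = organs,
    cardiac_output = co,
    blood_volume = cfg$blood_volume_fraction * body_mass,
    venous_fraction = cfg$venous_fraction_of_blood
  )
  viol <- validate_physiology(phys)
  if (length(viol) > 0) {
    stop("invalid physiology table:\n  ", paste(viol, collapse = "\n  "),
         call. = FALSE)
  }
  phys
}

#' Construct a physiology table from explicit components
#'
#' Low-level constructor used by [get_physiology()] and by tests that need
#' reduced topologies (e.g. a single perfused tissue). Derived absolute
#' quantities are computed here; validation is the caller's responsibility
#' via [validate_physiology()].
#'
#' @param species Species label.
#' @param body_mass Body mass, kg (> 0).
#' @param organs Data frame with columns `name`, `weight_fraction`,
#'   `flow_fraction`, `vascular_fraction`, `interstitial_fraction`,
#'   `phagocyte_density`. Must contain `blood`, `lung` and `carcass` rows.
#' @param cardiac_output Cardiac output, L/h.
#' @param blood_volume Volume of the venous + arterial blood pools, L
#'   (organ vascular spaces are accounted within each organ volume).
#' @param venous_fraction Fraction of `blood_volume` in the venous pool.
#' @return A `phage_physiology` object; see [get_physiology()].
#' @export
physiology_table <- function(species, body_mass, organs, cardiac_output,
                             blood_volume, venous_fraction = 2 / 3) {
  if (!is.numeric(body_mass) || body_mass <= 0) {
    stop("`body_mass` must be a positive mass in kg", call. = FALSE)
  }
  organs$mass_kg <- organs$weight_fraction * body_mass
  organs$volume_L <- organs$mass_kg  # 1 kg/L tissue density
  organs$flow_L_h <- organs$flow_fraction * cardiac_output
  organs$V_vas_L <- organs$vascular_fraction * organs$volume_L
  organs$V_int_L <- organs$interstitial_fraction * organs$volume_L
  structure(
    list(
      species = species,
      body_mass = body_mass,
      cardiac_output = cardiac_output,
      blood_volume = blood_volume,
      venous_fraction = venous_fraction,
      organs = organs
    ),
    class = "phage_physiology"
  )
}

#' Validate a physiology table
#'
#' Checks the structural invariants of a [physiology_table()]: all fractions
#' in \[0, 1\] with vascular + interstitial not exceeding 1, nonnegative
#' phagocyte densities, mass closure (weight fractions summing to 1 with the
#' carcass as balancing term) and systemic flow closure (flow fractions over
#' parallel-perfused organs plus carcass summing to 1, the lung carrying the
#' full cardiac output in series).
#'
#' @param table A `phage_physiology` object.
#' @return Character vector of human-readable violations; empty if the table
#'   satisfies every invariant.
#' @export
validate_physiology <- function(table) {
  viol <- character(0)
  org <- table$organs
  req <- c("blood", "lung", "carcass")
  missing_req <- setdiff(req, org$name)
  if (length(missing_req) > 0) {
    viol <- c(viol, paste0("missing required organs: ",
                           paste(missing_req, collapse = ", ")))
    return(viol)
  }
  if (any(duplicated(org$name))) {
    viol <- c(viol, paste0("duplicated organ rows: ",
                           paste(unique(org$name[duplicated(org$name)]),
                                 collapse = ", ")))
  }
  for (i in seq_len(nrow(org))) {
    o <- org[i, ]
    for (f in c("weight_fraction", "flow_fraction", "vascular_fraction",
                "interstitial_fraction")) {
      v <- o[[f]]
      if (!is.finite(v) || v < 0 || v > 1) {
        viol <- c(viol, sprintf("%s/%s = %g outside [0, 1]", o$name, f, v))
      }
    }
    if (is.finite(o$vascular_fraction) && is.finite(o$interstitial_fraction) &&
        o$vascular_fraction + o$interstitial_fraction > 1 + 1e-9) {
      viol <- c(viol, sprintf(
        "%s: vascular_fraction + interstitial_fraction = %g exceeds 1",
        o$name, o$vascular_fraction + o$interstitial_fraction
      ))
    }
    if (!is.finite(o$phagocyte_density) || o$phagocyte_density < 0) {
      viol <- c(viol, sprintf("%s/phagocyte_density = %g negative",
                              o$name, o$phagocyte_density))
    }
  }
  wsum <- sum(org$weight_fraction)
  if (abs(wsum - 1) > 1e-6) {
    viol <- c(viol, sprintf(
      "mass closure: weight fractions sum to %.8f (carcass must balance to 1)",
      wsum
    ))
  }
  systemic <- !(org$name %in% c("blood", "lung"))
  fsum <- sum(org$flow_fraction[systemic])
  if (abs(fsum - 1) > 1e-6) {
    viol <- c(viol, sprintf(
      "flow closure: systemic flow fractions sum to %.8f (carcass must balance to 1)",
      fsum
    ))
  }
  lungf <- org$flow_fraction[org$name == "lung"]
  if (abs(lungf - 1) > 1e-6) {
    viol <- c(viol, sprintf(
      "lung/flow_fraction = %g (in-series lung must receive total cardiac output)",
      lungf
    ))
  }
  if (!is.finite(table$cardiac_output) || table$cardiac_output <= 0) {
    viol <- c(viol, sprintf("cardiac_output = %g not positive",
                            table$cardiac_output))
  }
  if (!is.finite(table$blood_volume) || table$blood_volume <= 0) {
    viol <- c(viol, sprintf("blood_volume = %g not positive",
                            table$blood_volume))
  }
  viol
}

#' @export
print.phage_physiology <- function(x, ...) {
  cat(sprintf(
    "<phage_physiology> %s, %.4g kg, CO %.4g L/h, blood %.4g L, %d organs\n",
    x$species, x$body_mass, x$cardiac_output, x$blood_volume, nrow(x$organs)
  ))
  invisible(x)
}
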