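#' PBPK model parameters for labeled phage
#'
#' Bundles the estimated and fixed parameters of the whole-body phage model:
#' tissue partition coefficients for the high-flow organs (lung, kidney),
#' the gastrointestinal organs (liver, spleen, stomach) and the rest of the
#' body; the whole-body permeability coefficient; the saturable
#' mononuclear-phagocyte-system (MPS) submodel (capacity per 1e5 phagocytes
#' on a log10 PFU scale, uptake and degradation half-lives, with the release
#' rate constant tied to uptake, `k_rel = ln2 / T_up`); the first-order
#' active surface-site clearance and its strain covariate effect; gastric
#' and urine transit half-lives; and the additive residual error SD per
#' measured tissue (%ID/g, or %ID for stomach contents and urine).
#'
#' Defaults are the canonical estimates of the fitted mouse model.
#' `alternative = TRUE` loads the variant set quoted in running text where
#' it differs from the canonical table (Ps 0.0227, CL_active 0.0145 L/h/kg,
#' T_deg 0.0301 h).
#'
#' @param Kp_LunKid Partition coefficient, lung and kidney (unitless).
#' @param Kp_LvrSpnSto Partition coefficient, liver/spleen/stomach (unitless).
#' @param Kp_Crs Partition coefficient, rest of body (unitless).
#' @param Ps Whole-body permeability coefficient (unitless multiplier on
#'   tissue blood flow).
#' @param A_mps_cap MPS capacity, log10(PFU per 1e5 phagocytes).
#' @param T_up MPS uptake half-life, h (fixed; endosomal degradation is
#'   rate-limiting).
#' @param T_deg MPS degradation half-life, h.
#' @param CL_active Active surface-site clearance, L/h/kg.
#' @param theta_PAML31 Covariate effect of the PAML-31-1 strain on
#'   `CL_active`, applied as `CL_active * exp(theta_PAML31)`.
#' @param T_sto_out Gastric transit half-life, h.
#' @param T_u_out Urine transit half-life, h.
#' @param sigma Named numeric vector of additive residual SDs for the
#'   measured tissues.
#' @param alternative Load the running-text variant estimates instead.
#' @return An object of class `phage_parameters` (a named list).
#' @export
phage_parameters <- function(Kp_LunKid = 0.395,
                             Kp_LvrSpnSto = 2.12e-4,
                             Kp_Crs = 0.934,
                             Ps = 0.0427,
                             A_mps_cap = 3.81,
                             T_up = 0.001,
                             T_deg = 0.0437,
                             CL_active = 0.0129,
                             theta_PAML31 = -1.94,
                             T_sto_out = 3.28,
                             T_u_out = 1.73,
                             sigma = default_sigma(),
                             alternative = FALSE) {
  if (isTRUE(alternative)) {
    Ps <- 0.0227
    CL_active <- 0.0145
    T_deg <- 0.0301
  }
  p <- structure(
    list(
      Kp_LunKid = Kp_LunKid, Kp_LvrSpnSto = Kp_LvrSpnSto, Kp_Crs = Kp_Crs,
      Ps = Ps, A_mps_cap = A_mps_cap, T_up = T_up, T_deg = T_deg,
      CL_active = CL_active, theta_PAML31 = theta_PAML31,
      T_sto_out = T_sto_out, T_u_out = T_u_out, sigma = sigma
    ),
    class = "phage_parameters"
  )
  validate_parameters(p)
  p
}

#' @keywords internal
validate_parameters <- function(p) {
  pos <- c("Kp_LunKid", "Kp_LvrSpnSto", "Kp_Crs", "Ps", "T_up", "T_deg",
           "CL_active", "T_sto_out", "T_u_out")
  for (nm in pos) {
    if (!is.finite(p[[nm]]) || p[[nm]] <= 0) {
      stop(sprintf("parameter %s = %g must be strictly positive", nm, p[[nm]]),
           call. = FALSE)
    }
  }
  if (any(!is.finite(p$sigma)) || any(p$sigma <= 0)) {
    stop("all residual sigmas must be positive", call. = FALSE)
  }
  invisible(p)
}

#' Default residual error SDs per measured tissue
#'
#' Additive residual SDs of the fitted error model, in %ID/g (%ID for the
#' stomach-contents and urine amounts).
#' @return Named numeric vector.
#' @export
default_sigma <- function() {
  c(
    blood = 4.28, lung = 0.721, liver = 1.23, spleen = 3.26,
    small_intestine = 1.18, large_intestine = 1.39, muscle = 0.902,
    kidney = 0.899, stomach = 4.15, bone = 1.14,
    stomach_contents = 6.53, urine = 6.12
  )
}

#' Fixed kinetic parameters of the twin free-radiolabel model
#'
#' Free label (iodide liberated from the phage capsid) is produced by slow
#' thermal deconjugation in every labeled-phage compartment and, much
#' faster, by MPS degradation of phage; MPS-liberated label exits the
#' phagocyte pool to blood at `k_mps_release`. Circulating free label is
#' eliminated first-order with half-life `T_free_elim` and taken up by the
#' thyroid with biological half-life `T_thyroid_up`. All rates are fixed
#' from published free-iodide kinetics, not estimated.
#'
#' @param k_deconj Thermal deconjugation rate, 1/h.
#' @param k_mps_release Release rate of MPS-liberated free label to blood, 1/h.
#' @param T_thyroid_up Thyroid biological uptake half-life, h.
#' @param T_free_elim Free-label elimination half-life, h.
#' @return An object of class `iodine_parameters`.
#' @export
iodine_parameters <- function(k_deconj = 0.000298,
                              k_mps_release = 0.05,
                              T_thyroid_up = 30,
                              T_free_elim = 7) {
  vals <- c(k_deconj = k_deconj, k_mps_release = k_mps_release,
            T_thyroid_up = T_thyroid_up, T_free_elim = T_free_elim)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all free-label parameters must be positive", call. = FALSE)
  }
  structure(as.list(vals), class = "iodine_parameters")
}

#' Dosing regimen
#'
#' @param amount Dose per administration. With `dose_unit = "percentID"` a
#'   single administration is 100 %ID; with `"PFU"` the amount is in
#'   plaque-forming units. For `schedule = "continuous"`, `amount` is the
#'   daily dose delivered uniformly over each 24 h.
#' @param dose_unit `"percentID"` or `"PFU"`.
#' @param route `"bolus"` (IV push as an instantaneous venous input) or
#'   `"infusion"` (zero-order over `infusion_duration`); a "rapid 5 min
#'   push" is an infusion with `infusion_duration = 5/60`.
#' @param infusion_duration Infusion length per administration, h.
#' @param schedule One of `"x1"`, `"Q24H"`, `"Q12H"`, `"continuous"`.
#' @param n_doses Number of administrations (days of infusion for
#'   `"continuous"`).
#' @param dose_pfu Physical dose in PFU used to convert the cellular MPS
#'   capacity into %ID units. Required context when `dose_unit =
#'   "percentID"`; defaults to 1e10 PFU, the nominal single-mouse dose of
#'   the biodistribution study design (50 uL of ~2e11 PFU/mL stock).
#' @return An object of class `dose_regimen`.
#' @export
dose_regimen <- function(amount = 100,
                         dose_unit = c("percentID", "PFU"),
                         route = c("bolus", "infusion"),
                         infusion_duration = 0,
                         schedule = c("x1", "Q24H", "Q12H", "continuous"),
                         n_doses = 1,
                         dose_pfu = NULL) {
  dose_unit <- match.arg(dose_unit)
  route <- match.arg(route)
  schedule <- match.arg(schedule)
  if (!is.finite(amount) || amount <= 0) {
    stop("dose amount must be positive", call. = FALSE)
  }
  if (route == "infusion" && infusion_duration <= 0 && schedule != "continuous") {
    stop("infusion route requires a positive infusion_duration", call. = FALSE)
  }
  if (is.null(dose_pfu)) {
    dose_pfu <- if (dose_unit == "PFU") amount else 1e10
  }
  structure(
    list(amount = amount, dose_unit = dose_unit, route = route,
         infusion_duration = infusion_duration, schedule = schedule,
         n_doses = as.integer(n_doses), dose_pfu = dose_pfu),
    class = "dose_regimen"
  )
}

#' Saturable MPS uptake rate constant
#'
#' The first-order uptake rate into the tissue MPS compartment declines
#' linearly with MPS filling, `k_up = k_up_max * (1 - A_mps / A_max)`,
#' floored at zero at and beyond capacity, with
#' `k_up_max = ln2 / T_up`.
#'
#' @param A_mps Current amount of phage in the MPS compartment (%ID).
#' @param A_max Tissue MPS capacity (%ID), > 0.
#' @param params A [phage_parameters()] object.
#' @return Uptake rate constant, 1/h.
#' @export
mps_uptake_rate <- function(A_mps, A_max, params) {
  if (any(A_max <= 0)) {
    stop("A_max must be positive (parameterization error)", call. = FALSE)
  }
  k_up_max <- log(2) / params$T_up
  pmax(0, k_up_max * (1 - A_mps / A_max))
}

#' Tissue MPS capacity
#'
#' Total phage capacity of a tissue's resident phagocyte pool:
#' `M_i * V_i * 10^A_mps_cap / 1e5` in PFU, where `M_i` is the phagocyte
#' density (cells/g) and `V_i` the tissue mass (g); divided by the
#' administered dose (PFU) and expressed as a percentage for %ID units.
#'
#' @param phagocyte_density Tissue-resident phagocytes per gram.
#' @param tissue_mass_g Tissue mass, g.
#' @param dose_pfu Administered dose, PFU (> 0); required for `unit = "percentID"`.
#' @param params A [phage_parameters()] object (uses `A_mps_cap`).
#' @param unit `"percentID"` (default) or `"PFU"`.
#' @return Capacity in the requested unit.
#' @export
mps_capacity <- function(phagocyte_density, tissue_mass_g, dose_pfu, params,
                         unit = c("percentID", "PFU")) {
  unit <- match.arg(unit)
  if (any(is.na(phagocyte_density))) {
    stop("missing phagocyte_density (configuration error)", call. = FALSE)
  }
  cap_pfu <- phagocyte_density * tissue_mass_g * 10^params$A_mps_cap / 1e5
  if (unit == "PFU") return(cap_pfu)
  if (!is.finite(dose_pfu) || dose_pfu <= 0) {
    stop("dose_pfu must be positive to express capacity in %ID", call. = FALSE)
  }
  cap_pfu / dose_pfu * 100
}

#' Apply the strain covariate to the active clearance
#'
#' The PAML-31-1 strain carries a log-scale covariate effect on the active
#' surface-site clearance: `CL_active <- CL_active * exp(theta_PAML31)`.
#' Other study strains pass through unchanged; unknown strain labels pass
#' through with a warning.
#'
#' @param params A [phage_parameters()] object.
#' @param strain Strain label (`"Luz24"`, `"PAML-31-1"`, `"OMKO1"`).
#' @return Parameters with the covariate applied.
#' @export
apply_covariate <- function(params, strain) {
  known <- c("Luz24", "PAML-31-1", "OMKO1")
  norm <- normalize_strain(strain)
  if (is.na(norm)) {
    warning(sprintf("unknown strain '%s'; no covariate applied", strain))
    return(params)
  }
  if (norm == "PAML-31-1") {
    params$CL_active <- params$CL_active * exp(params$theta_PAML31)
  }
  params
}

#' @keywords internal
normalize_strain <- function(strain) {
  key <- toupper(gsub("[^A-Za-z0-9]", "", strain))
  switch(key,
    "LUZ24" = "Luz24",
    "PAML311" = "PAML-31-1",
    "PAML31" = "PAML-31-1",
    "OMKO1" = "OMKO1",
    NA_character_
  )
}

#' Phage diameters of the study strains
#' @return Named vector of diameters in nm.
#' @export
strain_sizes <- function() {
  c("Luz24" = 63, "PAML-31-1" = 227, "OMKO1" = 400)
}

#' @export
print.phage_parameters <- function(x, ...) {
  cat("<phage_parameters>\n")
  for (nm in setdiff(names(x), "sigma")) {
    cat(sprintf("  %-14s %g\n", nm, x[[nm]]))
  }
  cat("  sigma:", paste(sprintf("%s=%g", names(x$sigma), x$sigma),
                        collapse = " "), "\n")
  invisible(x)
}
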