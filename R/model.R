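NGLOB <- 15L
MAXORG <- 32L
ORGAN_STRIDE <- 10L
NPARMS <- NGLOB + ORGAN_STRIDE * MAXORG

# Organs whose MPS uptake draws on the vascular space instead of the
# interstitium. Empty by default: the canonical MPS balance feeds from the
# interstitial space. Sinusoidal organs (liver, spleen) can be switched to
# vascular sampling via the `mps_vascular` argument of the simulation
# functions to explore intravascular (Kupffer / red-pulp) uptake.
SINUSOIDAL_MPS_ORGANS <- character(0)

#' Assemble the internal model structure
#'
#' Translates a physiology table, a parameter set, the free-label constants
#' and a dosing regimen into the flat state/parameter layout used by the
#' compiled ODE right-hand side. The blood row of the physiology table
#' becomes the venous/arterial pools; every other organ contributes
#' vascular, interstitial, MPS and MPS-resident free-label states.
#'
#' Active surface-site clearance totals `CL_active * body_mass` (L/h) and is
#' partitioned across the urinary-route organ (kidney) and the
#' gastric-route organs (liver, stomach, small and large intestine) in
#' proportion to their interstitial volumes (a surface-area proxy); the
#' clearance samples the organ's vascular-space concentration, as the
#' epithelial surface sites face the perfusing blood.
#'
#' @param params [phage_parameters()].
#' @param iodine [iodine_parameters()].
#' @param phys [get_physiology()] table.
#' @param regimen [dose_regimen()] (used for the MPS capacity dose scaling).
#' @param mps_vascular Organ names whose MPS uptake samples the vascular
#'   space (e.g. `c("liver", "spleen")` for sinusoidal macrophages);
#'   default none (interstitial uptake everywhere).
#' @return Internal list with `parms`, `state_names`, `organs`, volumes.
#' @keywords internal
build_model <- function(params, iodine, phys, regimen,
                        mps_vascular = character(0)) {
  org <- phys$organs[phys$organs$name != "blood", , drop = FALSE]
  n <- nrow(org)
  if (n > MAXORG) stop("too many organs (max ", MAXORG, ")", call. = FALSE)
  if (!"lung" %in% org$name) stop("physiology must include a lung", call. = FALSE)

  kp <- kp_for_organs(org$name, params)
  amax <- ifelse(
    org$phagocyte_density > 0,
    mps_capacity(org$phagocyte_density, org$mass_kg * 1000, regimen$dose_pfu,
                 params, unit = "percentID"),
    0
  )

  cl_organs <- c(ACTIVE_URINARY_ORGANS, ACTIVE_GASTRIC_ORGANS)
  in_cl <- org$name %in% cl_organs
  cl_total <- params$CL_active * phys$body_mass
  w <- ifelse(in_cl, org$V_int_L, 0)
  cl <- if (sum(w) > 0) cl_total * w / sum(w) else rep(0, n)

  route <- ifelse(org$name %in% ACTIVE_URINARY_ORGANS, 1,
                  ifelse(org$name %in% ACTIVE_GASTRIC_ORGANS, 2, 0))
  type <- ifelse(org$name == "lung", 1,
                 ifelse(org$name == "liver", 2,
                        ifelse(org$name %in% PORTAL_ORGANS, 3, 0)))
  if (any(type == 3) && !any(type == 2)) {
    stop("portal organs present but no liver", call. = FALSE)
  }

  V_ven <- phys$blood_volume * phys$venous_fraction
  V_art <- phys$blood_volume * (1 - phys$venous_fraction)

  parms <- numeric(NPARMS)
  parms[1] <- n
  parms[2] <- params$Ps
  parms[3] <- log(2) / params$T_up          # k_up_max
  parms[4] <- log(2) / params$T_up          # k_rel tied to uptake
  parms[5] <- log(2) / params$T_deg
  parms[6] <- iodine$k_deconj
  parms[7] <- iodine$k_mps_release
  parms[8] <- log(2) / iodine$T_thyroid_up
  parms[9] <- log(2) / iodine$T_free_elim
  parms[10] <- log(2) / params$T_sto_out
  parms[11] <- log(2) / params$T_u_out
  parms[12] <- V_ven
  parms[13] <- V_art
  parms[14] <- 0                            # infusion rate, set per segment
  parms[15] <- phys$cardiac_output
  mps_src <- as.integer(org$name %in% mps_vascular)
  for (i in seq_len(n)) {
    off <- NGLOB + ORGAN_STRIDE * (i - 1L)
    parms[off + 1L] <- org$flow_L_h[i]
    parms[off + 2L] <- org$V_vas_L[i]
    parms[off + 3L] <- org$V_int_L[i]
    parms[off + 4L] <- kp[i]
    parms[off + 5L] <- amax[i]
    parms[off + 6L] <- cl[i]
    parms[off + 7L] <- route[i]
    parms[off + 8L] <- type[i]
    parms[off + 9L] <- mps_src[i]
  }

  state_names <- c(
    as.vector(t(outer(org$name, c("vas", "int", "mps", "fmp"), paste, sep = "."))),
    "blood.ven", "blood.art", "stomach_contents", "gi_sink",
    "urine", "urine_sink", "free.blood", "free.thyroid", "free.eliminated"
  )
  list(parms = parms, state_names = state_names, organs = org,
       n = n, V_ven = V_ven, V_art = V_art, kp = kp, amax = amax, cl = cl,
       mps_src = mps_src)
}

#' @keywords internal
kp_for_organs <- function(names, params) {
  ifelse(names %in% c("lung", "kidney"), params$Kp_LunKid,
         ifelse(names %in% c("liver", "spleen", "stomach"), params$Kp_LvrSpnSto,
                params$Kp_Crs))
}

#' Model derivatives at a state (reference implementation)
#'
#' Pure-R evaluation of the coupled ODE right-hand side: the
#' permeability-limited vascular/interstitial exchange per tissue
#' (`dAv = flows - P*Q*(Cv - Cint/Kp)`,
#' `dAint = P*Q*(Cv - Cint/Kp) - k_up(t)*Aint + k_rel*Amps - CL*Cint`),
#' the saturable MPS balance, active surface clearance routed to the urine
#' and stomach-contents pools, and the twin free-label system. The compiled
#' solver uses an identical C implementation; this function exposes the
#' derivative computation for inspection and testing.
#'
#' @param state Named state vector (use [initial_state()] for the layout).
#' @param t Time, h (the system is autonomous; kept for the ODE signature).
#' @param params,iodine,phys,regimen Model inputs as in [simulate_phage()].
#' @param infusion_rate Zero-order venous input, %ID/h.
#' @param mps_vascular Organs with vascular-space MPS uptake; see
#'   [build_model()] internals (default none).
#' @return Named derivative vector, %ID/h.
#' @export
tissue_derivatives <- function(state, t, params, iodine, phys,
                               regimen = dose_regimen(), infusion_rate = 0,
                               mps_vascular = character(0)) {
  m <- build_model(params, iodine, phys, regimen, mps_vascular)
  if (length(state) != length(m$state_names)) {
    stop(sprintf("state has %d entries; model defines %d compartments",
                 length(state), length(m$state_names)), call. = FALSE)
  }
  y <- unname(state)
  org <- m$organs
  n <- m$n
  p <- params
  kup_max <- log(2) / p$T_up
  krel <- kup_max
  kdeg <- log(2) / p$T_deg
  kdec <- iodine$k_deconj
  base <- 4L * n
  Aven <- y[base + 1]; Aart <- y[base + 2]
  Cven <- Aven / m$V_ven; Cart <- Aart / m$V_art
  CO <- phys$cardiac_output

  dy <- numeric(length(y))
  ven_in <- 0; portal_in <- 0; Q_portal <- 0
  urine_in <- 0; gastric_in <- 0; free_to_blood <- 0; Clung_v <- 0
  liver_i <- NA_integer_
  for (i in seq_len(n)) {
    idx <- 4L * (i - 1L)
    Av <- y[idx + 1]; Ai <- y[idx + 2]; Am <- y[idx + 3]; Af <- y[idx + 4]
    Q <- org$flow_L_h[i]; Vv <- org$V_vas_L[i]; Vint <- org$V_int_L[i]
    Cv <- Av / Vv; Cint <- Ai / Vint
    J <- p$Ps * Q * (Cv - Cint / m$kp[i])
    kup <- if (m$amax[i] > 0) max(0, kup_max * (1 - Am / m$amax[i])) else 0
    clearance <- m$cl[i] * Cv
    uptake <- kup * (if (m$mps_src[i] == 1) Av else Ai)
    dAv <- -J - clearance - kdec * Av
    dAi <- J - kdec * Ai
    dAm <- uptake - (krel + kdeg + kdec) * Am
    dAf <- (kdeg + kdec) * Am - iodine$k_mps_release * Af
    if (m$mps_src[i] == 1) {
      dAv <- dAv - uptake + krel * Am
    } else {
      dAi <- dAi - uptake + krel * Am
    }
    nm <- org$name[i]
    if (nm == "lung") {
      dAv <- dAv + CO * (Cven - Cv); Clung_v <- Cv
    } else if (nm == "liver") {
      liver_i <- i
    } else {
      dAv <- dAv + Q * (Cart - Cv)
      if (nm %in% PORTAL_ORGANS) {
        portal_in <- portal_in + Q * Cv; Q_portal <- Q_portal + Q
      } else {
        ven_in <- ven_in + Q * Cv
      }
    }
    if (nm %in% ACTIVE_URINARY_ORGANS) urine_in <- urine_in + clearance
    if (nm %in% ACTIVE_GASTRIC_ORGANS) gastric_in <- gastric_in + clearance
    free_to_blood <- free_to_blood + iodine$k_mps_release * Af + kdec * (Av + Ai)
    dy[idx + 1] <- dAv; dy[idx + 2] <- dAi; dy[idx + 3] <- dAm; dy[idx + 4] <- dAf
  }
  if (!is.na(liver_i)) {
    idx <- 4L * (liver_i - 1L)
    Qha <- org$flow_L_h[liver_i]
    Cv <- y[idx + 1] / org$V_vas_L[liver_i]
    Qout <- Qha + Q_portal
    dy[idx + 1] <- dy[idx + 1] + Qha * Cart + portal_in - Qout * Cv
    ven_in <- ven_in + Qout * Cv
  }
  ksto <- log(2) / p$T_sto_out
  kuo <- log(2) / p$T_u_out
  dy[base + 1] <- ven_in - CO * Cven - kdec * Aven + infusion_rate
  dy[base + 2] <- CO * Clung_v - CO * Cart - kdec * Aart
  dy[base + 3] <- gastric_in - ksto * y[base + 3]
  dy[base + 4] <- ksto * y[base + 3]
  dy[base + 5] <- urine_in - kuo * y[base + 5]
  dy[base + 6] <- kuo * y[base + 5]
  free_to_blood <- free_to_blood + kdec * (Aven + Aart)
  kthy <- log(2) / iodine$T_thyroid_up
  kfel <- log(2) / iodine$T_free_elim
  dy[base + 7] <- free_to_blood - (kthy + kfel) * y[base + 7]
  dy[base + 8] <- kthy * y[base + 7]
  dy[base + 9] <- kfel * y[base + 7]
  names(dy) <- m$state_names
  dy
}

#' All-zero initial state for a model
#'
#' @inheritParams tissue_derivatives
#' @return Named zero vector over the model's compartments.
#' @export
initial_state <- function(params, iodine, phys, regimen = dose_regimen()) {
  m <- build_model(params, iodine, phys, regimen)
  stats::setNames(numeric(length(m$state_names)), m$state_names)
}

#' Simulate the whole-body phage model
#'
#' Integrates the coupled labeled-phage + free-label system with a
#' stiff-capable solver (lsoda, compiled right-hand side; relative
#' tolerance 1e-8, absolute 1e-10 by default). Dosing enters the venous
#' pool: boluses as instantaneous increments at each administration time,
#' infusions as zero-order input over the infusion window, and continuous
#' schedules as a uniform rate of the daily amount. Multi-dose schedules
#' are integrated piecewise through the full nonlinear system (no
#' superposition).
#'
#' @param params [phage_parameters()].
#' @param iodine [iodine_parameters()]; defaults to the fixed literature set.
#' @param phys [get_physiology()] table.
#' @param regimen [dose_regimen()].
#' @param times Sorted output time grid, h (first time >= 0).
#' @param solver_opts List with optional `rtol`, `atol`, `maxsteps`.
#' @param mps_vascular Organs whose MPS uptake samples the vascular space
#'   (structural option; default none).
#' @return Object of class `phage_sim`: `times`, matrix `amounts`
#'   (%ID per compartment), `observables` (per-tissue total-label
#'   concentrations, %ID/g, plus the %ID amount pools), the inputs, and
#'   `mass_balance_residual` (max |dosed - accounted| over the grid, %ID).
#' @export
simulate_phage <- function(params, iodine = iodine_parameters(), phys,
                           regimen = dose_regimen(),
                           times = seq(0, 24, by = 0.1),
                           solver_opts = list(),
                           mps_vascular = character(0)) {
  if (is.unsorted(times, strictly = FALSE) || times[1] < 0) {
    stop("`times` must be sorted and nonnegative", call. = FALSE)
  }
  rtol <- solver_opts$rtol %||% 1e-8
  atol <- solver_opts$atol %||% 1e-10
  maxsteps <- solver_opts$maxsteps %||% 50000

  m <- build_model(params, iodine, phys, regimen, mps_vascular)
  nstate <- length(m$state_names)

  # dose schedule in internal units: one administration == 100 %ID
  ev <- dose_events(regimen, t_end = max(times))
  seg_bounds <- sort(unique(c(0, ev$bolus_times, ev$windows$start,
                              ev$windows$end, max(times))))
  seg_bounds <- seg_bounds[seg_bounds <= max(times) + 1e-12]

  y <- numeric(nstate)
  out_times <- unique(times)
  res <- matrix(NA_real_, nrow = length(out_times), ncol = nstate)
  t_cursor <- 0
  dosed <- 0
  record <- function(tt, yy) {
    hit <- which(abs(out_times - tt) < 1e-12)
    for (h in hit) res[h, ] <<- yy
  }
  # apply any bolus at t = 0 before recording
  b0 <- ev$bolus_times[abs(ev$bolus_times - 0) < 1e-12]
  if (length(b0)) { y[nstate - 8L] <- y[nstate - 8L] + 100 * length(b0); dosed <- dosed + 100 * length(b0) }
  record(0, y)

  for (k in seq_len(length(seg_bounds) - 1L)) {
    t0 <- seg_bounds[k]; t1 <- seg_bounds[k + 1L]
    if (t1 - t0 < 1e-12) next
    rate <- infusion_rate_at(ev, (t0 + t1) / 2)
    parms <- m$parms
    parms[14] <- rate
    dosed <- dosed + rate * (t1 - t0)
    seg_out <- sort(unique(c(t0, out_times[out_times > t0 + 1e-12 & out_times < t1 - 1e-12], t1)))
    sol <- deSolve::lsoda(
      y = y, times = seg_out, func = "phage_derivs", parms = parms,
      dllname = "phagepbpk", initfunc = "phage_init",
      nout = 1, outnames = "total",
      rtol = rtol, atol = atol, maxsteps = maxsteps
    )
    if (attr(sol, "istate")[1] < 0) {
      stop(sprintf("ODE integration failed in [%g, %g] (istate %d)",
                   t0, t1, attr(sol, "istate")[1]), call. = FALSE)
    }
    for (r in seq_len(nrow(sol))) record(sol[r, 1], sol[r, 2:(nstate + 1)])
    y <- sol[nrow(sol), 2:(nstate + 1)]
    # boluses scheduled exactly at t1
    nb <- sum(abs(ev$bolus_times - t1) < 1e-12 & ev$bolus_times > 0)
    if (nb > 0) {
      y[nstate - 8L] <- y[nstate - 8L] + 100 * nb
      dosed <- dosed + 100 * nb
      record(t1, y)  # record post-dose state
    }
  }

  colnames(res) <- m$state_names
  neg <- min(res, na.rm = TRUE)
  if (neg < -1e-6) {
    warning(sprintf("negative compartment amount %.3g beyond solver tolerance", neg))
  }
  dosed_at <- vapply(out_times, function(tt) dose_delivered(ev, tt), numeric(1))
  residual <- max(abs(rowSums(res) - dosed_at))
  structure(
    list(times = out_times, amounts = res, model = m, params = params,
         iodine = iodine, phys = phys, regimen = regimen,
         mass_balance_residual = residual),
    class = "phage_sim"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
dose_events <- function(regimen, t_end) {
  starts <- switch(regimen$schedule,
    x1 = 0,
    Q24H = 24 * (seq_len(regimen$n_doses) - 1),
    Q12H = 12 * (seq_len(regimen$n_doses) - 1),
    continuous = 0
  )
  if (regimen$schedule == "continuous") {
    dur <- 24 * regimen$n_doses
    return(list(bolus_times = numeric(0),
                windows = data.frame(start = 0, end = dur, rate = 100 / 24)))
  }
  if (regimen$route == "bolus") {
    list(bolus_times = starts,
         windows = data.frame(start = numeric(0), end = numeric(0),
                              rate = numeric(0)))
  } else {
    list(bolus_times = numeric(0),
         windows = data.frame(start = starts,
                              end = starts + regimen$infusion_duration,
                              rate = 100 / regimen$infusion_duration))
  }
}

#' @keywords internal
infusion_rate_at <- function(ev, t) {
  w <- ev$windows
  if (nrow(w) == 0) return(0)
  sum(w$rate[t >= w$start & t < w$end])
}

#' @keywords internal
dose_delivered <- function(ev, t) {
  amt <- 100 * sum(ev$bolus_times <= t + 1e-12)
  w <- ev$windows
  if (nrow(w) > 0) {
    amt <- amt + sum(w$rate * pmax(0, pmin(t, w$end) - w$start))
  }
  amt
}

#' @export
print.phage_sim <- function(x, ...) {
  cat(sprintf(
    "<phage_sim> %s, %d compartments, t in [%g, %g] h (%d points), mass-balance residual %.2g %%ID\n",
    x$phys$species, ncol(x$amounts), min(x$times), max(x$times),
    length(x$times), x$mass_balance_residual
  ))
  invisible(x)
}

#' Observable tissue concentrations from a simulation
#'
#' Per tissue, the observable is the total label in the organ — labeled
#' phage in vascular, interstitial and MPS spaces, the MPS-resident free
#' label, plus the organ's share of circulating free label (which
#' distributes instantaneously with unit partition across body water) —
#' divided by organ mass, in %ID/g. The blood observable uses the
#' venous + arterial pools over blood mass; thyroid adds its accumulated
#' free label; `stomach_contents` and `urine` are reported as %ID amounts.
#'
#' @param result A `phage_sim` from [simulate_phage()].
#' @param phys Physiology table (defaults to the one used in the simulation).
#' @return Data frame in long format: `time_h`, `tissue`, `value`, `unit`.
#' @export
observable_concentrations <- function(result, phys = result$phys) {
  am <- result$amounts
  org <- result$model$organs
  nm <- org$name
  # distribution volume for circulating free label: all organ volumes + blood
  V_dist <- sum(org$volume_L) + phys$blood_volume
  free_conc <- am[, "free.blood"] / V_dist  # %ID per L

  out <- list()
  for (i in seq_along(nm)) {
    tot <- am[, paste0(nm[i], ".vas")] + am[, paste0(nm[i], ".int")] +
      am[, paste0(nm[i], ".mps")] + am[, paste0(nm[i], ".fmp")] +
      free_conc * org$volume_L[i]
    if (nm[i] == "thyroid") tot <- tot + am[, "free.thyroid"]
    out[[nm[i]]] <- tot / (org$mass_kg[i] * 1000)  # %ID/g
  }
  blood_tot <- am[, "blood.ven"] + am[, "blood.art"] +
    free_conc * phys$blood_volume
  out[["blood"]] <- blood_tot / (phys$blood_volume * 1000)

  conc <- do.call(rbind, lapply(names(out), function(t) {
    data.frame(time_h = result$times, tissue = t, value = out[[t]],
               unit = "percentID_per_g", stringsAsFactors = FALSE)
  }))
  amounts <- do.call(rbind, lapply(c("stomach_contents", "urine"), function(t) {
    data.frame(time_h = result$times, tissue = t, value = am[, t],
               unit = "percentID", stringsAsFactors = FALSE)
  }))
  rbind(conc, amounts)
}

#' Extract one observable time course
#'
#' @param result A `phage_sim`.
#' @param tissue Tissue label (organ, `"blood"`, `"stomach_contents"`,
#'   `"urine"`).
#' @return Numeric vector over `result$times` (%ID/g, or %ID for the
#'   amount pools).
#' @export
observable_series <- function(result, tissue) {
  obs <- observable_concentrations(result)
  v <- obs$value[obs$tissue == tissue]
  if (length(v) == 0) stop(sprintf("no observable for tissue '%s'", tissue),
                           call. = FALSE)
  v
}

#' Convert a blood observable to PFU/mL
#'
#' Converts the labeled-phage blood pool (free label excluded: free iodide
#' is not phage) to plaque-forming units per mL, assuming phage remain in
#' the plasma-equivalent blood volume and do not enter red cells:
#' `PFU/mL = (amount %ID / 100) * dose_PFU / (V_blood_L * 1000)`.
#'
#' @param result A `phage_sim` with a PFU-denominated regimen.
#' @return Numeric vector of blood concentrations, PFU/mL, over
#'   `result$times`.
#' @export
blood_pfu_per_ml <- function(result) {
  if (result$regimen$dose_unit != "PFU") {
    stop("PFU/mL requested but dose_unit is not PFU", call. = FALSE)
  }
  frac <- (result$amounts[, "blood.ven"] + result$amounts[, "blood.art"]) / 100
  frac * result$regimen$dose_pfu / (result$phys$blood_volume * 1000)
}
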