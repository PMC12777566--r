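#' Model predictions for an observed dataset
#'
#' Runs one simulation per strain (at the pooled nominal physiology, with
#' the strain covariate applied when requested) and returns the predicted
#' value for every record of a long-format biodistribution dataset.
#'
#' @param params [phage_parameters()].
#' @param data Dataset in the exchange schema (see [generate_study()]).
#' @param phys Physiology table; defaults to the dataset's species at its
#'   median recorded body mass.
#' @param iodine [iodine_parameters()].
#' @param use_covariate Apply `theta_PAML31` to the reduced-clearance
#'   strain (covariate model) or not (structural model).
#' @param dose_pfu Physical dose in PFU backing the %ID scale.
#' @return Numeric vector of predictions aligned with `data` rows.
#' @export
predict_dataset <- function(params, data, phys = NULL,
                            iodine = iodine_parameters(),
                            use_covariate = FALSE, dose_pfu = 1e10) {
  if (is.null(phys)) {
    phys <- get_physiology(data$species[1], median(data$body_mass_kg))
  }
  regimen <- dose_regimen(amount = data$dose_value[1],
                          dose_unit = data$dose_unit[1],
                          dose_pfu = dose_pfu)
  pred <- numeric(nrow(data))
  for (s in unique(data$strain)) {
    idx <- which(data$strain == s)
    pars <- if (use_covariate) apply_covariate(params, s) else params
    tgrid <- sort(unique(c(0, data$time_h[idx])))
    sim <- simulate_phage(pars, iodine, phys, regimen, times = tgrid)
    obs <- observable_concentrations(sim)
    key <- paste(obs$tissue, signif(obs$time_h, 12))
    lookup <- setNames(obs$value, key)
    pred[idx] <- lookup[paste(data$tissue[idx], signif(data$time_h[idx], 12))]
  }
  if (any(is.na(pred))) stop("prediction failed for some records", call. = FALSE)
  pred
}

#' Naive pooled -2 log-likelihood
#'
#' Gaussian additive residual error per measured tissue: each record
#' contributes `log(2 pi sigma_t^2) + (obs - pred)^2 / sigma_t^2`; one
#' simulation per strain supplies the predictions (no random effects).
#'
#' @inheritParams predict_dataset
#' @return Scalar -2 log-likelihood.
#' @export
neg2_log_likelihood <- function(params, data, phys = NULL,
                                iodine = iodine_parameters(),
                                use_covariate = FALSE, dose_pfu = 1e10) {
  missing_sigma <- setdiff(unique(data$tissue), names(params$sigma))
  if (length(missing_sigma) > 0) {
    stop("observed tissues without a sigma: ",
         paste(missing_sigma, collapse = ", "), call. = FALSE)
  }
  pred <- predict_dataset(params, data, phys, iodine, use_covariate, dose_pfu)
  sg <- params$sigma[data$tissue]
  sum(log(2 * pi * sg^2) + (data$value - pred)^2 / sg^2)
}

# parameters estimated on the log scale; theta_PAML31 stays untransformed
LOG_SCALE_PARAMS <- c("Kp_LunKid", "Kp_LvrSpnSto", "Kp_Crs", "Ps", "T_deg",
                      "T_up", "A_mps_cap", "CL_active", "T_sto_out", "T_u_out")

#' Fit the model to pooled biodistribution data
#'
#' Direct maximum likelihood for the naive pooled model: free structural
#' parameters are optimized on the log scale (the covariate effect, when
#' free, on its natural scale) with `nlminb`, multi-start (log-uniform
#' jitter within +/- 3-fold of the initial values). Residual sigmas are
#' profiled analytically (`sigma_t^2 = mean(res_t^2)`) by default.
#' Relative standard errors come from the observed information matrix via
#' central finite differences on the transformed scale.
#'
#' @param data Dataset in the exchange schema.
#' @param init Initial [phage_parameters()].
#' @param free Names of parameters to estimate; `"theta_PAML31"` is only
#'   meaningful with `use_covariate = TRUE`. Everything else stays fixed
#'   (the capacity and uptake half-life are fixed by convention).
#' @param use_covariate Fit the strain covariate model.
#' @param profile_sigma Profile the residual sigmas analytically (else the
#'   sigmas in `init` are treated as known).
#' @param n_starts Number of multi-start optimizations.
#' @param seed Seed for the start jitter.
#' @param phys,iodine,dose_pfu As in [predict_dataset()].
#' @param compute_rse Compute RSEs/CIs from the numerical information
#'   matrix (adds ~2 k^2 objective evaluations).
#' @param control Passed to [nlminb()].
#' @return Object of class `phage_fit`: `estimates` (full parameter set),
#'   `objective` (-2LL), `free`, `rse_pct`, `ci95`, `convergence`,
#'   `starts` (per-start objectives), `fixed` ledger.
#' @export
fit_pooled <- function(data, init = phage_parameters(),
                       free = c("Ps", "CL_active"),
                       use_covariate = FALSE,
                       profile_sigma = TRUE,
                       n_starts = 5, seed = 1,
                       phys = NULL, iodine = iodine_parameters(),
                       dose_pfu = 1e10, compute_rse = TRUE,
                       control = list(rel.tol = 1e-8)) {
  if (length(free) < 1) stop("need at least one free parameter", call. = FALSE)
  if (nrow(data) == 0) stop("empty dataset", call. = FALSE)
  if (length(unique(data$time_h)) < 2) {
    warning("single time point: parameters are likely unidentifiable")
  }
  if (is.null(phys)) {
    phys <- get_physiology(data$species[1], median(data$body_mass_kg))
  }

  to_vec <- function(p) {
    vapply(free, function(nm) {
      if (nm %in% LOG_SCALE_PARAMS) log(p[[nm]]) else p[[nm]]
    }, numeric(1))
  }
  from_vec <- function(x) {
    p <- init
    for (j in seq_along(free)) {
      nm <- free[j]
      p[[nm]] <- if (nm %in% LOG_SCALE_PARAMS) exp(x[j]) else x[j]
    }
    p
  }
  objective <- function(x) {
    p <- from_vec(x)
    out <- try({
      pred <- predict_dataset(p, data, phys, iodine, use_covariate, dose_pfu)
      if (profile_sigma) {
        res <- data$value - pred
        obj <- 0
        for (t in unique(data$tissue)) {
          r <- res[data$tissue == t]
          s2 <- max(mean(r^2), 1e-12)
          obj <- obj + length(r) * (log(2 * pi * s2) + 1)
        }
        obj
      } else {
        sg <- p$sigma[data$tissue]
        sum(log(2 * pi * sg^2) + (data$value - pred)^2 / sg^2)
      }
    }, silent = TRUE)
    if (inherits(out, "try-error") || !is.finite(out)) 1e10 else out
  }

  x0 <- to_vec(init)
  set.seed(as.integer(seed))
  starts <- list(x0)
  if (n_starts > 1) {
    for (k in seq_len(n_starts - 1)) {
      jitter <- runif(length(x0), -log(3), log(3))
      # natural-scale free parameters jitter additively by up to 1
      jitter[!(free %in% LOG_SCALE_PARAMS)] <-
        runif(sum(!(free %in% LOG_SCALE_PARAMS)), -1, 1)
      starts[[k + 1]] <- x0 + jitter
    }
  }
  fits <- lapply(starts, function(s) {
    nlminb(s, objective, control = control)
  })
  objs <- vapply(fits, function(f) f$objective, numeric(1))
  best <- fits[[which.min(objs)]]
  est <- from_vec(best$par)
  if (profile_sigma) {
    pred <- predict_dataset(est, data, phys, iodine, use_covariate, dose_pfu)
    res <- data$value - pred
    for (t in intersect(names(est$sigma), unique(data$tissue))) {
      est$sigma[[t]] <- sqrt(max(mean(res[data$tissue == t]^2), 1e-12))
    }
  }

  rse <- ci <- NULL
  if (compute_rse) {
    H <- numeric_hessian(objective, best$par, h = 1e-4)
    cov <- try(2 * solve(H), silent = TRUE)
    if (!inherits(cov, "try-error") && all(diag(cov) > 0)) {
      se <- sqrt(diag(cov))
      rse <- setNames(100 * se, free)   # SE on log scale ~ CV of estimate
      ci <- do.call(rbind, lapply(seq_along(free), function(j) {
        nm <- free[j]
        b <- unname(best$par[j])
        if (nm %in% LOG_SCALE_PARAMS) {
          c(lo = exp(b - 1.96 * se[j]), hi = exp(b + 1.96 * se[j]))
        } else {
          c(lo = b - 1.96 * se[j], hi = b + 1.96 * se[j])
        }
      }))
      rownames(ci) <- free
    }
  }

  structure(
    list(
      estimates = est, objective = best$objective, free = free,
      use_covariate = use_covariate, rse_pct = rse, ci95 = ci,
      convergence = best$convergence, message = best$message,
      starts = objs,
      fixed = setdiff(c(names(init)[names(init) != "sigma"]), free),
      data_n = nrow(data), phys = phys, iodine = iodine, dose_pfu = dose_pfu,
      profile_sigma = profile_sigma
    ),
    class = "phage_fit"
  )
}

#' @keywords internal
numeric_hessian <- function(f, x, h = 1e-4) {
  k <- length(x)
  H <- matrix(NA_real_, k, k)
  f0 <- f(x)
  step <- function(i, s) { y <- x; y[i] <- y[i] + s; y }
  for (i in seq_len(k)) {
    H[i, i] <- (f(step(i, h)) - 2 * f0 + f(step(i, -h))) / h^2
    if (i < k) for (j in seq((i + 1), k)) {
      fpp <- f(step(j, h) + replace(numeric(k), i, h))
      fpm <- f(step(j, -h) + replace(numeric(k), i, h))
      fmp <- f(step(j, h) + replace(numeric(k), i, -h))
      fmm <- f(step(j, -h) + replace(numeric(k), i, -h))
      H[i, j] <- H[j, i] <- (fpp - fpm - fmp + fmm) / (4 * h^2)
    }
  }
  H
}

#' @export
print.phage_fit <- function(x, ...) {
  cat(sprintf("<phage_fit> -2LL = %.3f (%d records, %d free)\n",
              x$objective, x$data_n, length(x$free)))
  for (nm in x$free) {
    v <- if (nm == "theta_PAML31") x$estimates[[nm]] else x$estimates[[nm]]
    r <- if (!is.null(x$rse_pct)) sprintf(" (RSE %.1f%%)", x$rse_pct[[nm]]) else ""
    cat(sprintf("  %-14s %.4g%s\n", nm, v, r))
  }
  invisible(x)
}

#' Empirical-Bayes covariate screen
#'
#' For each animal with at least two observations, computes conditional-mode
#' (MAP) individual estimates of each parameter of interest under a
#' log-normal prior centered at the pooled estimates with standard
#' deviation `omega`, then correlates the individual estimates with phage
#' size (rank correlation) and with each strain indicator (point-biserial).
#' Correlations with absolute value above `threshold` are flagged; rows are
#' ordered by descending absolute correlation, which fixes the covariate
#' testing order.
#'
#' @param fit A `phage_fit`.
#' @param data The dataset used for the fit.
#' @param params_of_interest Parameters screened (1-D MAP per parameter).
#' @param omega Prior SD on the log scale.
#' @param threshold Flagging threshold on |correlation|.
#' @return List with `ebe` (animal-level estimates) and `correlations`
#'   (ranked data frame: parameter, covariate, correlation, flagged).
#' @export
covariate_screen <- function(fit, data,
                             params_of_interest = c("Ps", "T_deg", "CL_active"),
                             omega = 1, threshold = 0.3) {
  est <- fit$estimates
  phys <- fit$phys
  iodine <- fit$iodine
  counts <- table(data$animal_id)
  keep <- names(counts)[counts >= 2]
  dropped <- sum(counts < 2)
  if (dropped > 0) {
    warning(sprintf("%d animal(s) with < 2 observations excluded", dropped))
  }
  ebe <- list()
  for (id in keep) {
    sub <- data[data$animal_id == id, , drop = FALSE]
    row <- list(animal_id = id, strain = sub$strain[1],
                size_nm = sub$size_nm[1])
    for (nm in params_of_interest) {
      center <- log(est[[nm]])
      obj <- function(lx) {
        p <- est
        p[[nm]] <- exp(lx)
        val <- try(neg2_log_likelihood(p, sub, phys, iodine,
                                       fit$use_covariate, fit$dose_pfu),
                   silent = TRUE)
        if (inherits(val, "try-error") || !is.finite(val)) return(1e10)
        val + ((lx - center) / omega)^2
      }
      opt <- optimize(obj, interval = center + c(-3, 3) * omega)
      row[[nm]] <- exp(opt$minimum)
    }
    ebe[[length(ebe) + 1L]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  ebe <- do.call(rbind, ebe)

  rows <- list()
  for (nm in params_of_interest) {
    v <- log(ebe[[nm]])
    corr_size <- if (sd(v) == 0 || sd(ebe$size_nm) == 0) 0 else
      suppressWarnings(cor(v, ebe$size_nm, method = "spearman"))
    rows[[length(rows) + 1L]] <- data.frame(
      parameter = nm, covariate = "size_nm", correlation = corr_size,
      stringsAsFactors = FALSE
    )
    for (s in unique(ebe$strain)) {
      ind <- as.numeric(ebe$strain == s)
      cc <- if (sd(v) == 0 || sd(ind) == 0) 0 else cor(v, ind)
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = nm, covariate = paste0("strain:", s), correlation = cc,
        stringsAsFactors = FALSE
      )
    }
  }
  correlations <- do.call(rbind, rows)
  correlations$correlation[is.na(correlations$correlation)] <- 0
  correlations$flagged <- abs(correlations$correlation) > threshold
  correlations <- correlations[order(-abs(correlations$correlation)), ]
  rownames(correlations) <- NULL
  list(ebe = ebe, correlations = correlations)
}

#' Likelihood-ratio test between nested fits
#'
#' `Lambda = (-2LL)_null - (-2LL)_alt` referred to a chi-square with `df`
#' degrees of freedom; the null is rejected when `p < alpha`.
#'
#' @param fit_null,fit_alt `phage_fit` objects (or bare -2LL scalars).
#' @param df Extra free parameters in the alternative.
#' @param alpha Significance level.
#' @return List with `lambda`, `df`, `p_value`, `reject`.
#' @export
likelihood_ratio_test <- function(fit_null, fit_alt, df = 1, alpha = 0.05) {
  obj_null <- if (inherits(fit_null, "phage_fit")) fit_null$objective else fit_null
  obj_alt <- if (inherits(fit_alt, "phage_fit")) fit_alt$objective else fit_alt
  lambda <- obj_null - obj_alt
  if (lambda < -1e-6) {
    stop("alternative fits worse than null: optimization-quality error",
         call. = FALSE)
  }
  lambda <- max(lambda, 0)
  p <- pchisq(lambda, df = df, lower.tail = FALSE)
  list(lambda = lambda, df = df, p_value = p, reject = p < alpha)
}
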