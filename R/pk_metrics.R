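#' Linear-trapezoid area under the curve
#'
#' @param times Strictly increasing sampling times, h.
#' @param conc Nonnegative concentrations at `times`.
#' @return AUC from the first to the last observation (concentration
#'   units x h).
#' @export
auc_trapezoid <- function(times, conc) {
  if (length(times) < 2 || length(times) != length(conc)) {
    stop("need >= 2 matching time/concentration points", call. = FALSE)
  }
  if (is.unsorted(times, strictly = TRUE)) {
    stop("`times` must be strictly increasing", call. = FALSE)
  }
  if (any(conc < 0)) stop("concentrations must be nonnegative", call. = FALSE)
  sum(diff(times) * (conc[-length(conc)] + conc[-1]) / 2)
}

#' Terminal half-life by log-linear regression
#'
#' Fits ordinary least squares to `log(conc)` over the last `n_terminal`
#' points; the terminal rate constant is the negated slope and the
#' half-life `ln2 / lambda_z`.
#'
#' @param times Sampling times, h.
#' @param conc Concentrations (last `n_terminal` must be positive).
#' @param n_terminal Number of terminal points to regress on (>= 3).
#' @return List with `half_life` (h), `lambda_z` (1/h), `n_points`,
#'   `r_squared`.
#' @export
terminal_halflife <- function(times, conc, n_terminal = 3) {
  if (n_terminal < 3) stop("n_terminal must be >= 3", call. = FALSE)
  if (length(times) < n_terminal) {
    stop("fewer observations than n_terminal", call. = FALSE)
  }
  idx <- seq(length(times) - n_terminal + 1, length(times))
  tt <- times[idx]; cc <- conc[idx]
  if (any(cc <= 0)) {
    stop("terminal concentrations must be positive for log regression",
         call. = FALSE)
  }
  fit <- lm(log(cc) ~ tt)
  slope <- unname(coef(fit)[2])
  if (slope >= 0) {
    stop("no terminal phase: log-linear slope is nonnegative", call. = FALSE)
  }
  sst <- sum((log(cc) - mean(log(cc)))^2)
  list(
    half_life = log(2) / (-slope),
    lambda_z = -slope,
    n_points = n_terminal,
    r_squared = if (sst > 0) 1 - sum(residuals(fit)^2) / sst else 1
  )
}

#' Mean residence time from a simulation
#'
#' `MRT = AUMC / AUC`: the ratio of the first to the zeroth moment of the
#' tissue observable over `[0, t_end]`, both by linear trapezoid on the
#' simulation's own grid (use a dense grid, e.g. 0.01 h, for moment
#' accuracy).
#'
#' @param result A `phage_sim` spanning `[0, t_end]`.
#' @param tissue Observable label.
#' @param t_end Upper integration horizon, h (default: end of simulation).
#' @return MRT in hours.
#' @export
mean_residence_time <- function(result, tissue, t_end = max(result$times)) {
  keep <- result$times <= t_end + 1e-12
  mrt_curve(result$times[keep], observable_series(result, tissue)[keep])
}

#' Mean residence time of a sampled curve
#'
#' `AUMC / AUC` by linear trapezoid on the given grid.
#'
#' @param times Strictly increasing times, h.
#' @param values Nonnegative curve values.
#' @return MRT in hours.
#' @export
mrt_curve <- function(times, values) {
  auc <- auc_trapezoid(times, values)
  if (auc <= 0) stop("zero AUC: MRT undefined", call. = FALSE)
  auc_trapezoid(times, times * values) / auc
}

#' Normalized change between two exposures
#'
#' `(AUC_test - AUC_ref) / AUC_ref`, the dimensionless exposure shift used
#' to express sensitivity-analysis perturbations.
#'
#' @param auc_test,auc_ref Exposure metrics; `auc_ref > 0`.
#' @return Dimensionless normalized change.
#' @export
normalized_change <- function(auc_test, auc_ref) {
  if (any(auc_ref <= 0)) stop("auc_ref must be positive", call. = FALSE)
  (auc_test - auc_ref) / auc_ref
}

#' Relative bias and relative RMSE of predictions
#'
#' On the linear scale, `rBias = 100 * mean((pred - obs)/obs)` and
#' `rRMSE = 100 * sqrt(mean(((pred - obs)/obs)^2))`; on the log10 scale the
#' elementwise error is `log10(pred) - log10(obs)` instead (both must then
#' be positive). Zero observations are excluded with a warning.
#'
#' @param observed,predicted Equal-length numeric vectors.
#' @param scale `"linear"` (default) or `"log10"`.
#' @return List with `rbias` and `rrmse`, percent.
#' @export
rbias_rrmse <- function(observed, predicted, scale = c("linear", "log10")) {
  scale <- match.arg(scale)
  if (length(observed) != length(predicted)) {
    stop("observed and predicted must have equal length", call. = FALSE)
  }
  drop <- observed == 0
  if (any(drop)) {
    warning(sprintf("%d zero observation(s) excluded", sum(drop)))
    observed <- observed[!drop]; predicted <- predicted[!drop]
  }
  err <- if (scale == "linear") {
    (predicted - observed) / observed
  } else {
    if (any(observed <= 0) || any(predicted <= 0)) {
      stop("log10 scale requires positive values", call. = FALSE)
    }
    log10(predicted) - log10(observed)
  }
  list(rbias = 100 * mean(err), rrmse = 100 * sqrt(mean(err^2)))
}
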