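#' Five-parameter development-rate curve
#'
#' Constructs and validates the parameter set of the unimodal
#' development-rate curve used throughout the package:
#' \deqn{r(T) = b_1 \, 2^{-u^2 (1 + (b_4 u_+)^{5 b_5})}, \quad
#'       u = (T - b_3)/b_2, \; u_+ = \max(u, 0).}
#' The curve is a base-2 Gaussian below the optimum (the rate halves
#' \eqn{b_2} degrees below \eqn{b_3}) with a sharp, \eqn{b_4}-controlled
#' cutoff above it, the asymmetry typical of ectotherm thermal performance.
#' By construction the rate peaks at exactly \eqn{T = b_3} (the thermal
#' optimum) with peak value \eqn{b_1}.
#'
#' @param b1 Peak development rate (percent development per day), > 0.
#' @param b2 Sub-optimal thermal spread (degrees C): the rate is `b1/2` at
#'   `b3 - b2`. Must satisfy `0 < b2 < b3`, so `b3 - b2` is the lower
#'   reference temperature of the curve.
#' @param b3 Temperature of peak rate, the thermal optimum (degrees C).
#' @param b4 Supra-optimal cutoff steepness (dimensionless, > 0). Weakly
#'   identified when few observations lie above the optimum; fit with
#'   multiple starts.
#' @param b5 Cutoff shape exponent (dimensionless, > 0); `5*b5` is the power
#'   of the supra-optimal term, so the conventional fixed value `b5 = 0.4`
#'   gives a quadratic-in-\eqn{u^2} (overall quartic) cutoff.
#' @param se Optional named numeric vector of standard errors for the free
#'   parameters (fixed parameters carry no SE).
#' @param rss Optional residual sum of squares of the fit that produced the
#'   parameters (days^2 on the default duration residual scale).
#' @param species_label Free-text label.
#'
#' @return An object of class `rate_curve_params`.
#' @seealso [dev_rate()], [fit_rate_curve()], [estimate_ctmax()]
#' @export
#' @examples
#' p <- rate_curve_params(3.02, 8.94, 23.33, 4.9, 0.4, species_label = "G. alba")
#' dev_rate(23.33, p)  # equals b1
rate_curve_params <- function(b1, b2, b3, b4, b5 = 0.4,
                              se = NULL, rss = NULL, species_label = "") {
  vals <- c(b1 = b1, b2 = b2, b3 = b3, b4 = b4, b5 = b5)
  if (any(!is.finite(vals)))
    stop("rate curve parameters must be finite numbers", call. = FALSE)
  if (b1 <= 0) stop("b1 (peak rate) must be > 0", call. = FALSE)
  if (b2 <= 0) stop("b2 (thermal spread) must be > 0", call. = FALSE)
  if (b2 >= b3) stop("b2 must be smaller than b3", call. = FALSE)
  if (b4 <= 0 || b5 <= 0) stop("b4 and b5 must be > 0", call. = FALSE)
  structure(list(b1 = unname(b1), b2 = unname(b2), b3 = unname(b3),
                 b4 = unname(b4), b5 = unname(b5),
                 se = se, rss = unname(rss), species_label = species_label),
            class = "rate_curve_params")
}

#' @export
print.rate_curve_params <- function(x, ...) {
  cat("Development-rate curve", if (nzchar(x$species_label))
    paste0("(", x$species_label, ")") else "", "\n")
  b <- unlist(x[c("b1", "b2", "b3", "b4", "b5")])
  se <- rep(NA_real_, 5); names(se) <- names(b)
  if (!is.null(x$se)) se[names(x$se)] <- x$se
  out <- data.frame(estimate = round(b, 4), se = round(se, 4))
  print(out)
  if (!is.null(x$rss)) cat("RSS:", format(x$rss, digits = 6), "\n")
  invisible(x)
}

#' Reference parameter sets for two Geocrinia species
#'
#' Published development-rate parameter sets for *Geocrinia alba* and
#' *G. vitellina* (stage 19-39 larval window), used as defaults by the
#' synthetic-data generators so that recovery tests double as parity checks
#' against the published thermal thresholds.
#'
#' @return A named list of two [rate_curve_params()] objects
#'   (`alba`, `vitellina`).
#' @export
#' @examples
#' default_rate_curves()$alba
default_rate_curves <- function() {
  list(
    alba = rate_curve_params(3.02, 8.94, 23.33, 4.90, 0.4,
                             se = c(b1 = 0.11, b2 = 0.72, b3 = 0.70, b4 = 5.50),
                             rss = 18.91, species_label = "Geocrinia alba"),
    vitellina = rate_curve_params(3.10, 8.76, 23.80, 5.37, 0.4,
                                  se = c(b1 = 0.43, b2 = 3.60, b3 = 2.40, b4 = 23.60),
                                  rss = 43.28, species_label = "Geocrinia vitellina")
  )
}

#' Evaluate the development-rate curve
#'
#' @param temp Temperature(s), degrees C. Vectorised.
#' @param params A [rate_curve_params()] object.
#' @return Development rate(s), percent development per day (non-negative).
#' @export
#' @examples
#' p <- default_rate_curves()$alba
#' dev_rate(c(15, 20, 23.33, 28), p)
dev_rate <- function(temp, params) {
  stopifnot(inherits(params, "rate_curve_params"))
  if (length(temp) == 0L) return(numeric(0))
  if (any(!is.finite(temp)))
    stop("temperatures must be finite", call. = FALSE)
  u <- (temp - params$b3) / params$b2
  up <- pmax(u, 0)
  params$b1 * 2^(-u^2 * (1 + (params$b4 * up)^(5 * params$b5)))
}

#' Incubation temperature regime
#'
#' A constant temperature or an hourly temperature series (recycled
#' periodically when development outlasts the recorded series, as for a
#' programmed diel sine cycle).
#'
#' @param regime_id Identifier.
#' @param kind `"constant"` or `"fluctuating"`.
#' @param constant_temp Temperature, degrees C (constant regimes).
#' @param hourly_temps Numeric vector of degrees C at 1-h cadence
#'   (fluctuating regimes); non-empty.
#' @param nominal_label Display label, e.g. `"25 +/- 5"`.
#' @return An object of class `incubation_regime`.
#' @export
incubation_regime <- function(regime_id, kind = c("constant", "fluctuating"),
                              constant_temp = NULL, hourly_temps = NULL,
                              nominal_label = "") {
  kind <- match.arg(kind)
  if (kind == "constant") {
    if (is.null(constant_temp) || !is.finite(constant_temp))
      stop("constant regime needs a finite constant_temp", call. = FALSE)
    temps <- constant_temp
  } else {
    if (is.null(hourly_temps) || length(hourly_temps) == 0L)
      stop("fluctuating regime needs a non-empty hourly series", call. = FALSE)
    temps <- hourly_temps
  }
  if (any(!is.finite(temps)) || any(temps < -10) || any(temps > 50))
    stop("regime temperatures must be finite and within -10..50 C", call. = FALSE)
  structure(list(regime_id = as.character(regime_id), kind = kind,
                 constant_temp = constant_temp, hourly_temps = hourly_temps,
                 nominal_label = nominal_label),
            class = "incubation_regime")
}

regime_temps <- function(regime) {
  if (regime$kind == "constant") regime$constant_temp else regime$hourly_temps
}

#' Predict development duration under a temperature regime
#'
#' Rate summation: the instantaneous rate `dev_rate(T_t)` is accumulated in
#' steps of `step_hours` (the hourly series is recycled periodically) until
#' cumulative development reaches 100 percent; the final step is linearly
#' interpolated. For a constant regime this converges to `100 / dev_rate(T)`.
#'
#' @param regime An [incubation_regime()].
#' @param params A [rate_curve_params()] object.
#' @param step_hours Integration step, hours (default 1).
#' @param max_days Give up (with an error) if development has not completed
#'   after this many days; guards against regimes entirely outside the
#'   viable temperature range.
#' @return Duration in days.
#' @export
#' @examples
#' p <- default_rate_curves()$alba
#' r <- incubation_regime("c21", "constant", constant_temp = 21)
#' predict_duration(r, p)  # ~ 100 / dev_rate(21, p)
predict_duration <- function(regime, params, step_hours = 1, max_days = 2000) {
  stopifnot(inherits(regime, "incubation_regime"))
  if (!is.numeric(step_hours) || step_hours <= 0)
    stop("step_hours must be a positive number", call. = FALSE)
  temps <- regime_temps(regime)
  n_steps <- ceiling(max_days * 24 / step_hours)
  # hourly series sampled at the step grid (nearest recorded hour)
  if (length(temps) == 1L) {
    rates <- rep(dev_rate(temps, params), n_steps)
  } else {
    idx <- (floor((seq_len(n_steps) - 1) * step_hours) %% length(temps)) + 1L
    rates <- dev_rate(temps, params)[idx]
  }
  inc <- rates * step_hours / 24          # % development per step
  if (sum(inc[seq_len(min(n_steps, ceiling(24 / step_hours)))]) <= 0 &&
      all(inc <= .Machine$double.eps))
    stop("regime entirely outside the viable temperature range: development cannot complete",
         call. = FALSE)
  cs <- cumsum(inc)
  i <- which(cs >= 100)[1L]
  if (is.na(i))
    stop("development did not complete within max_days = ", max_days,
         call. = FALSE)
  prev <- if (i == 1L) 0 else cs[i - 1L]
  frac <- (100 - prev) / inc[i]           # linear interpolation in final step
  (i - 1L + frac) * step_hours / 24
}

#' Fit the development-rate curve to observed durations
#'
#' Bounded Levenberg-Marquardt least squares (via [minpack.lm::nls.lm()]) of
#' observed stage-window durations against rate-summation predictions, with
#' multiple jittered starts to guard against the weakly identified
#' supra-optimal cutoff. Fluctuating regimes enter the objective through
#' their recorded hourly series, not their mean temperature.
#'
#' @param observations Data frame with columns `clutch_id`, `regime_id`,
#'   `duration_days`.
#' @param regimes List of [incubation_regime()] objects covering every
#'   `regime_id` in `observations`.
#' @param fixed Named numeric vector of parameters to hold fixed, e.g.
#'   `c(b5 = 0.4)` (the default). Use `numeric(0)` to free all five.
#' @param init Optional [rate_curve_params()] (or named vector) of starting
#'   values; a data-driven default is used otherwise.
#' @param bounds Optional list with named vectors `lower`, `upper`.
#' @param residual_scale `"duration"` (days, default) or `"rate"`
#'   (percent/day, using observed rate `100/duration`).
#' @param n_starts Number of optimisation starts (first start unjittered).
#' @param start_seed Seed for the start jitter (local RNG; does not disturb
#'   the global stream).
#' @param step_hours Rate-summation step passed to [predict_duration()].
#'
#' @return A [rate_curve_params()] object with `se` (Jacobian-based, free
#'   parameters only) and `rss` filled in, plus attributes `fitted`
#'   (per-observation predictions), `convergence` and `fixed`.
#' @export
fit_rate_curve <- function(observations, regimes, fixed = c(b5 = 0.4),
                           init = NULL, bounds = NULL,
                           residual_scale = c("duration", "rate"),
                           n_starts = 5, start_seed = 20, step_hours = 1) {
  residual_scale <- match.arg(residual_scale)
  stopifnot(is.data.frame(observations),
            all(c("regime_id", "duration_days") %in% names(observations)))
  if (any(observations$duration_days <= 0))
    stop("duration_days must be positive", call. = FALSE)
  names(regimes) <- vapply(regimes, function(r) r$regime_id, character(1))
  if (!all(observations$regime_id %in% names(regimes)))
    stop("observations reference unknown regime ids: ",
         paste(setdiff(observations$regime_id, names(regimes)), collapse = ", "),
         call. = FALSE)

  pnames <- c("b1", "b2", "b3", "b4", "b5")
  fixed <- fixed[names(fixed) %in% pnames]
  free <- setdiff(pnames, names(fixed))
  if (length(free) == 0L) stop("no free parameters to fit", call. = FALSE)
  n_obs <- nrow(observations)
  if (n_obs < length(free) + 1L)
    stop("need at least ", length(free) + 1L, " observations for ",
         length(free), " free parameters", call. = FALSE)
  if (length(unique(observations$regime_id)) < 3L)
    stop("need observations spanning at least 3 distinct regimes", call. = FALSE)

  # data-driven default start: peak near the fastest regime
  obs_rate <- 100 / observations$duration_days
  mean_temps <- vapply(regimes[observations$regime_id],
                       function(r) mean(regime_temps(r)), numeric(1))
  dflt <- c(b1 = max(obs_rate) * 1.05,
            b2 = max(diff(range(mean_temps)) * 0.8, 2),
            b3 = unname(mean_temps[which.max(obs_rate)]) + 1,
            b4 = 5, b5 = 0.4)
  start <- dflt
  if (!is.null(init)) {
    iv <- if (inherits(init, "rate_curve_params"))
      unlist(init[pnames]) else init
    start[names(iv)] <- iv
  }
  lower <- c(b1 = 0.05, b2 = 0.5, b3 = 5, b4 = 0.05, b5 = 0.05)
  upper <- c(b1 = 50, b2 = 40, b3 = 45, b4 = 100, b5 = 5)
  if (!is.null(bounds)) {
    if (!is.null(bounds$lower)) lower[names(bounds$lower)] <- bounds$lower
    if (!is.null(bounds$upper)) upper[names(bounds$upper)] <- bounds$upper
  }

  reg_list <- regimes[unique(observations$regime_id)]
  obs_idx <- match(observations$regime_id, names(reg_list))
  target <- if (residual_scale == "duration")
    observations$duration_days else obs_rate

  predict_all <- function(b) {
    p <- rate_curve_params(b["b1"], b["b2"], b["b3"], b["b4"], b["b5"])
    vapply(reg_list, function(r)
      tryCatch(predict_duration(r, p, step_hours = step_hours),
               error = function(e) NA_real_), numeric(1))
  }
  resid_fun <- function(theta) {
    b <- c(theta, fixed)[pnames]
    if (b["b2"] >= b["b3"]) return(rep(1e4, n_obs))
    pr <- tryCatch(predict_all(b), error = function(e) rep(NA_real_, length(reg_list)))
    pred <- pr[obs_idx]
    if (residual_scale == "rate") pred <- 100 / pred
    r <- target - pred
    r[!is.finite(r)] <- 1e4
    r
  }

  jitters <- local({
    rng <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(rng)) assign(".Random.seed", rng, globalenv()) else
      rm(".Random.seed", envir = globalenv()))
    set.seed(start_seed)
    lapply(seq_len(max(n_starts, 1L)), function(s)
      if (s == 1L) rep(1, length(free)) else 1 + stats::runif(length(free), -0.25, 0.25))
  })

  best <- NULL
  for (jit in jitters) {
    th0 <- pmin(pmax(start[free] * jit, lower[free] * 1.001), upper[free] * 0.999)
    f <- tryCatch(
      minpack.lm::nls.lm(par = th0, lower = lower[free], upper = upper[free],
                         fn = resid_fun,
                         control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (is.null(f) || !is.finite(f$deviance)) next
    if (is.null(best) || f$deviance < best$deviance) best <- f
  }
  if (is.null(best))
    stop("rate-curve fit failed to converge from any start", call. = FALSE)
  theta <- stats::coef(best)
  rss <- best$deviance
  if (rss >= 1e6)
    stop("rate-curve fit did not converge: objective ", format(rss),
         ", gradient norm ",
         format(sqrt(sum((2 * t(best$fvec) %*% jacobian_fd(resid_fun, theta))^2))),
         call. = FALSE)

  # Jacobian-based covariance at the optimum
  J <- jacobian_fd(resid_fun, theta)
  dof <- max(n_obs - length(free), 1L)
  sigma2 <- rss / dof
  covm <- tryCatch(sigma2 * solve(crossprod(J)), error = function(e) NULL)
  se <- if (is.null(covm)) rep(NA_real_, length(free)) else sqrt(pmax(diag(covm), 0))
  names(se) <- free

  b <- c(theta, fixed)[pnames]
  out <- rate_curve_params(b["b1"], b["b2"], b["b3"], b["b4"], b["b5"],
                           se = se, rss = rss)
  attr(out, "fitted") <- predict_all(b)[obs_idx]
  attr(out, "convergence") <- list(info = best$info,
                                   message = best$message,
                                   n_starts = n_starts,
                                   residual_scale = residual_scale)
  attr(out, "fixed") <- fixed
  out
}

# central-difference Jacobian of a vector-valued function
jacobian_fd <- function(fn, x, eps = 1e-6) {
  f0 <- fn(x)
  J <- matrix(0, length(f0), length(x))
  for (k in seq_along(x)) {
    h <- eps * max(abs(x[k]), 1)
    xp <- x; xp[k] <- x[k] + h
    xm <- x; xm[k] <- x[k] - h
    J[, k] <- (fn(xp) - fn(xm)) / (2 * h)
  }
  J
}

#' Extrapolate the critical thermal maximum from the fitted curve
#'
#' Scans upward from the thermal optimum on a fixed temperature grid and
#' returns the first temperature at which the predicted development rate has
#' fallen to (effectively) zero: at or below `epsilon * b1`, or exactly zero
#' if the curve reaches zero first. The rule (epsilon and grid step) is
#' recorded in the result.
#'
#' @param params A [rate_curve_params()] object.
#' @param epsilon Fall-to-zero criterion as a fraction of the peak rate
#'   (default 0.01).
#' @param grid_step Scan resolution, degrees C (default 0.01).
#' @param t_ceiling Highest temperature scanned; failure to meet the
#'   criterion below it is an error.
#' @return An object of class `thermal_thresholds`: list with `t_opt`,
#'   `ct_max` and `ct_max_rule`.
#' @export
#' @examples
#' estimate_ctmax(default_rate_curves()$alba)$ct_max  # 29.69
estimate_ctmax <- function(params, epsilon = 0.01, grid_step = 0.01,
                           t_ceiling = 60) {
  stopifnot(inherits(params, "rate_curve_params"))
  if (epsilon <= 0 || epsilon >= 1)
    stop("epsilon must be in (0, 1)", call. = FALSE)
  grid <- seq(params$b3, t_ceiling, by = grid_step)
  r <- dev_rate(grid, params)
  hit <- which(r <= epsilon * params$b1 | r == 0)[1L]
  if (is.na(hit))
    stop("development rate does not fall to ", epsilon, " * b1 below ",
         t_ceiling, " C", call. = FALSE)
  structure(list(t_opt = params$b3, ct_max = grid[hit],
                 ct_max_rule = list(epsilon = epsilon, grid_step = grid_step,
                                    t_ceiling = t_ceiling)),
            class = "thermal_thresholds")
}

#' @export
print.thermal_thresholds <- function(x, ...) {
  cat(sprintf("T_opt = %.2f C, CT_max = %.2f C (rate <= %.3g * peak, %.3g C grid)\n",
              x$t_opt, x$ct_max, x$ct_max_rule$epsilon, x$ct_max_rule$grid_step))
  invisible(x)
}

#' Warming tolerance
#'
#' The thermal buffer between a species' critical thermal maximum and the
#' maximum habitat (soil) temperature it experiences; negative values mean
#' the habitat already exceeds the tolerable maximum.
#'
#' @param ct_max Critical thermal maximum, degrees C.
#' @param t_hab_max Maximum habitat temperature, degrees C.
#' @return `ct_max - t_hab_max` (degrees C).
#' @export
warming_tolerance <- function(ct_max, t_hab_max) {
  if (any(!is.finite(ct_max)) || any(!is.finite(t_hab_max)))
    stop("inputs must be finite", call. = FALSE)
  ct_max - t_hab_max
}

#' Thermal safety margin
#'
#' Difference between the thermal optimum and the habitat temperature.
#'
#' @param t_opt Thermal optimum, degrees C.
#' @param t_hab Habitat temperature, degrees C.
#' @return `t_opt - t_hab` (degrees C).
#' @export
thermal_safety_margin <- function(t_opt, t_hab) {
  if (any(!is.finite(t_opt)) || any(!is.finite(t_hab)))
    stop("inputs must be finite", call. = FALSE)
  t_opt - t_hab
}
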