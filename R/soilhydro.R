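#' Soil water retention curve (van Genuchten)
#'
#' Monotone mapping between volumetric water content (VWC, percent) and
#' soil water potential (psi, kPa <= 0) in the van Genuchten form with
#' `m = 1 - 1/n`:
#' \deqn{S_e = \frac{\theta - \theta_r}{\theta_s - \theta_r}
#'       = \left[1 + (\alpha |\psi|)^n\right]^{-m}.}
#'
#' @param soil_class Label, e.g. `"sand"` or `"clay"`.
#' @param theta_r Residual VWC, percent.
#' @param theta_s Saturated VWC, percent (`0 <= theta_r < theta_s <= 100`).
#' @param alpha Inverse air-entry scale, kPa^-1 (> 0).
#' @param n Pore-size distribution index, dimensionless (> 1).
#' @return An object of class `retention_curve`.
#' @export
retention_curve <- function(soil_class, theta_r, theta_s, alpha, n) {
  if (!(theta_r >= 0 && theta_r < theta_s && theta_s <= 100))
    stop("need 0 <= theta_r < theta_s <= 100", call. = FALSE)
  if (alpha <= 0) stop("alpha must be > 0", call. = FALSE)
  if (n <= 1) stop("n must be > 1", call. = FALSE)
  structure(list(soil_class = as.character(soil_class), theta_r = theta_r,
                 theta_s = theta_s, alpha = alpha, n = n, m = 1 - 1 / n),
            class = "retention_curve")
}

#' @export
print.retention_curve <- function(x, ...) {
  cat(sprintf("Retention curve '%s': theta_r=%.3g%%, theta_s=%.3g%%, alpha=%.4g kPa^-1, n=%.3g\n",
              x$soil_class, x$theta_r, x$theta_s, x$alpha, x$n))
  invisible(x)
}

#' Packaged sand and clay retention curves (synthetic)
#'
#' Synthetic parameter sets for a sandy and a clayey soil. Residual and
#' saturated VWC and the shape index `n` are typical textbook values for
#' each texture class (chosen so the clay curve holds more water than the
#' sand curve at every water potential); `alpha` is then solved in closed
#' form so each curve passes exactly through its anchor point: 10.5 percent
#' VWC (sand) and 27.6 percent VWC (clay) at -50 kPa, the equivalents of
#' the frogs' absorption threshold in the two soil types.
#'
#' @return Named list of two [retention_curve()] objects (`sand`, `clay`).
#' @export
#' @examples
#' vwc_to_psi(10.5, default_retention_curves()$sand)  # -50
default_retention_curves <- function() {
  calib_alpha <- function(theta_anchor, psi_anchor, theta_r, theta_s, n) {
    m <- 1 - 1 / n
    se <- (theta_anchor - theta_r) / (theta_s - theta_r)
    (se^(-1 / m) - 1)^(1 / n) / abs(psi_anchor)
  }
  list(
    sand = retention_curve("sand", theta_r = 3, theta_s = 38,
                           alpha = calib_alpha(10.5, -50, 3, 38, 2.2), n = 2.2),
    clay = retention_curve("clay", theta_r = 10, theta_s = 45,
                           alpha = calib_alpha(27.6, -50, 10, 45, 1.25), n = 1.25)
  )
}

#' Convert volumetric water content to water potential
#'
#' Inverse van Genuchten: `|psi| = (Se^(-1/m) - 1)^(1/n) / alpha`.
#'
#' @param vwc VWC, percent; must lie in `(theta_r, theta_s]`. Vectorised.
#' @param curve A [retention_curve()].
#' @return Water potential, kPa (<= 0; 0 at saturation).
#' @export
vwc_to_psi <- function(vwc, curve) {
  stopifnot(inherits(curve, "retention_curve"))
  if (any(!is.finite(vwc)) || any(vwc <= curve$theta_r) || any(vwc > curve$theta_s))
    stop("vwc must lie in (theta_r, theta_s] = (", curve$theta_r, ", ",
         curve$theta_s, "]", call. = FALSE)
  se <- (vwc - curve$theta_r) / (curve$theta_s - curve$theta_r)
  -((se^(-1 / curve$m) - 1)^(1 / curve$n)) / curve$alpha
}

#' Convert water potential to volumetric water content
#'
#' @param psi Water potential, kPa (<= 0). Vectorised.
#' @param curve A [retention_curve()].
#' @return VWC, percent, in `(theta_r, theta_s]`.
#' @export
psi_to_vwc <- function(psi, curve) {
  stopifnot(inherits(curve, "retention_curve"))
  if (any(!is.finite(psi)) || any(psi > 0))
    stop("psi must be finite and <= 0 kPa", call. = FALSE)
  se <- (1 + (curve$alpha * abs(psi))^curve$n)^(-curve$m)
  curve$theta_r + se * (curve$theta_s - curve$theta_r)
}
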