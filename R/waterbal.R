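#' Ventral surface area from body mass
#'
#' Empirical anuran allometry `area = 9.9 * mass^0.56`.
#'
#' @param mass Body mass, g (>= 0). Vectorised.
#' @return Surface area, cm^2.
#' @export
#' @examples
#' surface_area(1)     # 9.9
#' surface_area(1.35)  # 11.71
surface_area <- function(mass) {
  if (any(!is.finite(mass)) || any(mass < 0))
    stop("mass must be finite and non-negative", call. = FALSE)
  9.9 * mass^0.56
}

#' Hydration level as a fraction of standard mass
#'
#' Standard mass is the mass of a fully hydrated animal with an empty
#' bladder; hydration experiments are expressed relative to it.
#'
#' @param mass Current mass, g.
#' @param standard_mass Standard (fully hydrated) mass, g (> 0).
#' @return `mass / standard_mass`.
#' @export
hydration_fraction <- function(mass, standard_mass) {
  if (any(standard_mass <= 0))
    stop("standard_mass must be > 0", call. = FALSE)
  mass / standard_mass
}

#' Area-normalised water flux
#'
#' Mass change over an exposure, normalised by the surface area implied by
#' the animal's standard mass (the single area the animal is credited with
#' throughout the experiment) and by duration. Positive = uptake.
#'
#' @param mass_start,mass_end Masses, g.
#' @param duration_h Exposure, hours (> 0).
#' @param standard_mass Standard mass, g, used for the area normalisation.
#' @return Flux in mg cm^-2 h^-1.
#' @export
#' @examples
#' flux_rate(1.000, 0.9766, 2, 1.000)  # -1.182
flux_rate <- function(mass_start, mass_end, duration_h, standard_mass) {
  if (any(!is.finite(duration_h)) || any(duration_h <= 0))
    stop("duration_h must be positive", call. = FALSE)
  1000 * (mass_end - mass_start) / surface_area(standard_mass) / duration_h
}

#' Estimate the water absorption threshold
#'
#' The absorption threshold is the substrate water potential at which net
#' cutaneous water flux is zero: on wetter substrates the animal gains
#' water, on drier ones it loses water. Per-treatment mean fluxes are
#' computed from the non-excluded measurements and the zero crossing is
#' located either by linear interpolation between the two adjacent
#' treatment means that bracket zero (`"bracket"`, the default: the design
#' localises the crossing between neighbouring treatments) or on a global
#' monotone (isotonic) fit of mean flux against water potential
#' (`"isotonic"`).
#'
#' @param measurements Data frame with columns `water_potential` (kPa,
#'   <= 0), `flux` (mg cm^-2 h^-1) and optionally `frog_id` and `excluded`
#'   (logical or 0/1; e.g. urination/defecation events).
#' @param method `"bracket"` or `"isotonic"`.
#' @return An object of class `absorption_threshold`: list with `threshold`
#'   (kPa), `method`, `n_frogs`, `bracketing` (kPa pair), and
#'   `treatment_means`.
#' @export
#' @examples
#' m <- data.frame(water_potential = c(-40, -40, -60, -60),
#'                 flux = c(0.4, 0.6, -0.4, -0.6))
#' estimate_absorption_threshold(m)$threshold  # -50
estimate_absorption_threshold <- function(measurements,
                                          method = c("bracket", "isotonic")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(measurements),
            all(c("water_potential", "flux") %in% names(measurements)))
  m <- measurements
  if (!is.null(m$excluded)) m <- m[!as.logical(m$excluded), , drop = FALSE]
  if (nrow(m) == 0L)
    stop("no usable measurements (all excluded or empty)", call. = FALSE)
  if (any(m$water_potential > 0))
    stop("water potentials must be <= 0 kPa", call. = FALSE)

  agg <- stats::aggregate(flux ~ water_potential, data = m, FUN = mean)
  agg <- agg[order(agg$water_potential, decreasing = TRUE), ]  # wet -> dry
  if (nrow(agg) < 2L)
    stop("need at least 2 water-potential treatments", call. = FALSE)

  psi <- agg$water_potential
  mf <- agg$flux
  n_frogs <- if (!is.null(m$frog_id)) length(unique(m$frog_id)) else NA_integer_

  if (method == "isotonic") {
    # flux is non-decreasing in psi (wetter -> more uptake); isoreg needs
    # increasing x, so fit on psi ascending (dry -> wet)
    ord <- order(psi)
    iso <- stats::isoreg(psi[ord], mf[ord])
    fit <- iso$yf[order(ord)]           # back to wet -> dry order
    mf <- fit
  }
  sgn <- sign(mf)
  cross <- which(sgn[-length(sgn)] >= 0 & sgn[-1] < 0)[1L]
  if (is.na(cross))
    stop("treatment mean fluxes do not change sign: no absorption threshold ",
         "within the tested range", call. = FALSE)
  p1 <- psi[cross]; p2 <- psi[cross + 1L]
  f1 <- mf[cross]; f2 <- mf[cross + 1L]
  thr <- if (f1 == f2) mean(c(p1, p2)) else p1 + (0 - f1) * (p2 - p1) / (f2 - f1)
  structure(list(threshold = thr, method = method, n_frogs = n_frogs,
                 bracketing = c(p1, p2),
                 treatment_means = agg),
            class = "absorption_threshold")
}

#' @export
print.absorption_threshold <- function(x, ...) {
  cat(sprintf("Absorption threshold: %.1f kPa (%s; bracketed by %g and %g kPa)\n",
              x$threshold, x$method, x$bracketing[1], x$bracketing[2]))
  invisible(x)
}

#' Dehydration (or rehydration) rate across a hydration window
#'
#' Average rate of mass change between two hydration fractions, with the
#' crossing times of both bounds obtained by linear interpolation of the
#' timestamped mass series. With the default bounds (1.0 to 0.9) this is a
#' dehydration rate; bounds (0.89, 1.0) give the mirrored rehydration rate.
#'
#' @param frog List with `standard_mass` (g) and `mass_series`, a data frame
#'   with columns `time_h` and `mass_g` ordered in time.
#' @param from_fraction,to_fraction Hydration fractions delimiting the
#'   window (fractions of standard mass).
#' @return List with `rate_g_h` (magnitude of the mass-change rate, g/h),
#'   `rate_pct_h` (percent of standard mass per hour), and the interpolated
#'   window times `t_from`, `t_to`.
#' @export
dehydration_rate <- function(frog, from_fraction = 1.0, to_fraction = 0.9) {
  stopifnot(is.list(frog), !is.null(frog$standard_mass),
            is.data.frame(frog$mass_series))
  ms <- frog$mass_series
  stopifnot(all(c("time_h", "mass_g") %in% names(ms)))
  if (frog$standard_mass <= 0 || any(ms$mass_g <= 0))
    stop("masses must be positive", call. = FALSE)
  frac <- ms$mass_g / frog$standard_mass
  drying <- from_fraction > to_fraction

  cross_time <- function(bound) {
    # first time the series reaches the bound (moving away from from_fraction)
    hit <- if (drying) which(frac <= bound) else which(frac >= bound)
    if (length(hit) == 0L)
      stop("mass series never reaches hydration fraction ", bound,
           call. = FALSE)
    i <- hit[1L]
    if (i == 1L || frac[i] == bound) return(ms$time_h[i])
    # interpolate between i-1 and i
    f0 <- frac[i - 1L]; f1 <- frac[i]
    ms$time_h[i - 1L] + (bound - f0) / (f1 - f0) * (ms$time_h[i] - ms$time_h[i - 1L])
  }
  t_from <- cross_time(from_fraction)
  t_to <- cross_time(to_fraction)
  if (t_to <= t_from)
    stop("hydration window not traversed in time order", call. = FALSE)
  dmass <- (to_fraction - from_fraction) * frog$standard_mass
  rate <- abs(dmass) / (t_to - t_from)
  list(rate_g_h = rate,
       rate_pct_h = 100 * rate / frog$standard_mass,
       t_from = t_from, t_to = t_to)
}
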