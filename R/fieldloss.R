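#' Percent mass loss per deployed hour of an agar model
#'
#' @param mass_out Pre-deployment mass, g.
#' @param mass_in Post-deployment mass, g (cannot exceed `mass_out`: agar
#'   only loses water).
#' @param exposure_h Hours deployed (>= 1). Vectorised.
#' @return Percent of initial mass lost per hour.
#' @export
#' @examples
#' percent_loss_per_hour(2.000, 1.820, 10)  # 0.9
percent_loss_per_hour <- function(mass_out, mass_in, exposure_h) {
  if (any(!is.finite(exposure_h)) || any(exposure_h < 1))
    stop("exposure_h must be >= 1 hour", call. = FALSE)
  if (any(mass_in > mass_out))
    stop("mass_in exceeds mass_out: agar models cannot gain water", call. = FALSE)
  100 * (mass_out - mass_in) / mass_out / exposure_h
}

#' Standardise water loss to a 9-hour daytime exposure
#'
#' Multiplies the hourly percent loss by 9 (the minimum daytime exposure
#' shared by all deployments). Values extrapolating past total water
#' content are capped at 100 percent and flagged rather than silently
#' truncated.
#'
#' @param loss_pct_per_h Percent loss per hour (from
#'   [percent_loss_per_hour()]). Vectorised.
#' @param hours Standard exposure (default 9).
#' @return Numeric vector of percent loss over `hours`, capped at 100, with
#'   attribute `capped` (logical vector marking capped entries).
#' @export
standardize_9h <- function(loss_pct_per_h, hours = 9) {
  raw <- loss_pct_per_h * hours
  capped <- raw > 100
  out <- pmin(raw, 100)
  attr(out, "capped") <- capped
  out
}

#' Grouped water-loss summary of agar-model deployments
#'
#' Reduces a deployment table to per-group mean, standard error and n of
#' the standardised 9-hour water loss. Under the habitat grouping,
#' deployments at 0 m (the habitat boundary) are excluded by default.
#' Empty groups are reported with `n = 0`, not dropped.
#'
#' @param deployments Data frame with columns `mass_out`, `mass_in`,
#'   `exposure_h`, plus the grouping columns (`habitat` and `distance_m`,
#'   or `cover` and `size_class`).
#' @param grouping `"habitat_distance"` (means per habitat, filtered to
#'   `distances`) or `"cover_size"` (means per cover type x size class).
#' @param distances Distances (m) retained under the habitat grouping
#'   (default `c(25, 50)`).
#' @return Data frame with one row per group: group labels, `mean_loss_9h`,
#'   `se`, `n`, `n_capped`.
#' @export
group_summary <- function(deployments,
                          grouping = c("habitat_distance", "cover_size"),
                          distances = c(25, 50)) {
  grouping <- match.arg(grouping)
  stopifnot(is.data.frame(deployments),
            all(c("mass_out", "mass_in", "exposure_h") %in% names(deployments)))
  d <- deployments
  if (grouping == "habitat_distance") {
    stopifnot(all(c("habitat", "distance_m") %in% names(d)))
    levels_all <- unique(d$habitat)
    d <- d[d$distance_m %in% distances, , drop = FALSE]
    key <- factor(d$habitat, levels = levels_all)
  } else {
    stopifnot(all(c("cover", "size_class") %in% names(d)))
    as_fct <- function(x) if (is.factor(x)) x else factor(x)
    key <- interaction(as_fct(d$cover), as_fct(d$size_class), sep = ":",
                       drop = FALSE)
  }
  loss <- standardize_9h(percent_loss_per_hour(d$mass_out, d$mass_in, d$exposure_h))
  capped <- attr(loss, "capped")
  groups <- split(seq_len(nrow(d)), key, drop = FALSE)
  out <- do.call(rbind, lapply(names(groups), function(g) {
    i <- groups[[g]]
    n <- length(i)
    data.frame(group = g,
               mean_loss_9h = if (n > 0) mean(loss[i]) else NA_real_,
               se = if (n > 1) stats::sd(loss[i]) / sqrt(n) else NA_real_,
               n = n,
               n_capped = sum(capped[i]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
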