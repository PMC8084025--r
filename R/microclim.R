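#' Soil sensor series
#'
#' A 30-minute soil water potential / soil temperature series for one
#' site-habitat, as recorded by buried matric-potential sensors. Missing
#' readings are `NA`; timestamps must be strictly increasing at a nominal
#' 30-minute cadence (longer gaps are treated as missing data, not errors).
#'
#' @param site_id Site identifier.
#' @param habitat `"riparian"` or `"terrestrial"`.
#' @param timestamps `POSIXct` vector (timezone-naive logger local time,
#'   stored as UTC), strictly increasing.
#' @param psi Soil water potential, kPa (<= 0 where present; `NA` allowed).
#' @param temp Soil temperature, degrees C (`NA` allowed).
#' @param cadence_min Nominal cadence in minutes (default 30).
#' @return An object of class `sensor_series`.
#' @export
sensor_series <- function(site_id, habitat = c("riparian", "terrestrial"),
                          timestamps, psi, temp, cadence_min = 30) {
  habitat <- match.arg(habitat)
  stopifnot(inherits(timestamps, "POSIXct"))
  n <- length(timestamps)
  if (length(psi) != n || length(temp) != n)
    stop("timestamps, psi and temp must have equal length", call. = FALSE)
  if (n > 1L) {
    d <- diff(as.numeric(timestamps))
    if (any(d <= 0))
      stop("timestamps must be strictly increasing", call. = FALSE)
    step <- stats::median(d) / 60
    if (abs(step - cadence_min) > cadence_min * 0.1)
      stop("median cadence ", round(step, 1), " min is not the nominal ",
           cadence_min, " min", call. = FALSE)
  }
  if (any(psi > 1e-9, na.rm = TRUE))
    stop("soil water potential must be <= 0 kPa where present", call. = FALSE)
  structure(list(site_id = as.character(site_id), habitat = habitat,
                 timestamps = timestamps, psi = psi, temp = temp,
                 gaps = is.na(psi) & is.na(temp)),
            class = "sensor_series")
}

#' Threshold exceedance summary for one site over a July-June year
#'
#' Counts, over a July 1 - June 30 window, the calendar days on which the
#' series breaches the absorption threshold (`psi < at` on any reading, by
#' default) and the thermal thresholds (`temp > t_opt`, `temp > ct_max`),
#' along with the habitat temperature maximum and warming tolerance.
#' Days with no readings drop out of the denominator; days with partial
#' readings count normally (no imputation).
#'
#' @param series A [sensor_series()].
#' @param at Absorption threshold, kPa (<= 0).
#' @param t_opt,ct_max Thermal thresholds, degrees C.
#' @param year_start Integer year Y: the window runs Y-07-01 to (Y+1)-06-30.
#' @param day_rule How a day is tested against a threshold: `"any"` (any
#'   30-min reading breaches; biologically conservative default),
#'   `"daily_extreme"` (daily minimum psi / daily maximum temperature
#'   breaches; identical to `"any"` for complete days) or `"daily_mean"`.
#' @return An object of class `site_year_summary`: list with `site_id`,
#'   `habitat`, `year_window`, day counts `days_exceeding_at`,
#'   `days_exceeding_topt`, `days_exceeding_ctmax`, proportions `prop_at`,
#'   `prop_topt`, `prop_ctmax`, `t_hab_max`, `wt`, `n_days_observed`,
#'   `day_rule`.
#' @export
summarize_site_year <- function(series, at, t_opt, ct_max, year_start,
                                day_rule = c("any", "daily_extreme", "daily_mean")) {
  stopifnot(inherits(series, "sensor_series"))
  day_rule <- match.arg(day_rule)
  if (at > 0) stop("absorption threshold must be <= 0 kPa", call. = FALSE)
  w0 <- as.POSIXct(sprintf("%d-07-01 00:00:00", year_start), tz = "UTC")
  w1 <- as.POSIXct(sprintf("%d-07-01 00:00:00", year_start + 1L), tz = "UTC")
  keep <- series$timestamps >= w0 & series$timestamps < w1
  if (!any(keep))
    stop("series does not overlap the window ", year_start, "-07-01 to ",
         year_start + 1L, "-06-30", call. = FALSE)
  day <- as.Date(series$timestamps[keep], tz = "UTC")
  psi <- series$psi[keep]
  temp <- series$temp[keep]

  observed <- tapply(!is.na(psi) | !is.na(temp), day, any)
  n_days <- sum(observed)

  day_breach <- function(x, breach) {
    # per-day breach indicator under the chosen rule; NA-only days -> FALSE
    if (day_rule == "daily_mean") {
      m <- tapply(x, day, function(v) mean(v, na.rm = TRUE))
      ifelse(is.finite(m), breach(m), FALSE)
    } else {
      # "any" and "daily_extreme" coincide: a day's extreme breaches iff
      # some reading does
      b <- tapply(x, day, function(v) any(breach(v), na.rm = TRUE))
      ifelse(is.na(b), FALSE, b)
    }
  }
  d_at <- sum(day_breach(psi, function(v) v < at))
  d_topt <- sum(day_breach(temp, function(v) v > t_opt))
  d_ctmax <- sum(day_breach(temp, function(v) v > ct_max))
  t_hab_max <- if (all(is.na(temp))) NA_real_ else max(temp, na.rm = TRUE)

  structure(list(site_id = series$site_id, habitat = series$habitat,
                 year_window = sprintf("%d-07-01/%d-06-30", year_start, year_start + 1L),
                 days_exceeding_at = d_at, days_exceeding_topt = d_topt,
                 days_exceeding_ctmax = d_ctmax,
                 prop_at = d_at / n_days, prop_topt = d_topt / n_days,
                 prop_ctmax = d_ctmax / n_days,
                 t_hab_max = t_hab_max,
                 wt = if (is.na(t_hab_max)) NA_real_ else warming_tolerance(ct_max, t_hab_max),
                 n_days_observed = n_days, day_rule = day_rule),
            class = "site_year_summary")
}

#' @export
print.site_year_summary <- function(x, ...) {
  cat(sprintf("Site %s (%s), %s [%s rule]\n", x$site_id, x$habitat,
              x$year_window, x$day_rule))
  cat(sprintf("  days > AT: %d, > T_opt: %d, > CT_max: %d (of %d observed)\n",
              x$days_exceeding_at, x$days_exceeding_topt,
              x$days_exceeding_ctmax, x$n_days_observed))
  cat(sprintf("  T_hab_max: %.1f C, WT: %.1f C\n", x$t_hab_max, x$wt))
  invisible(x)
}

#' Bind site-year summaries into a data frame
#'
#' @param summaries List of [summarize_site_year()] results.
#' @return Data frame with one row per summary.
#' @export
site_year_table <- function(summaries) {
  if (inherits(summaries, "site_year_summary")) summaries <- list(summaries)
  do.call(rbind, lapply(summaries, function(s)
    data.frame(site_id = s$site_id, habitat = s$habitat,
               year_window = s$year_window,
               days_exceeding_at = s$days_exceeding_at,
               days_exceeding_topt = s$days_exceeding_topt,
               days_exceeding_ctmax = s$days_exceeding_ctmax,
               prop_at = s$prop_at, prop_topt = s$prop_topt,
               prop_ctmax = s$prop_ctmax,
               t_hab_max = s$t_hab_max, wt = s$wt,
               n_days_observed = s$n_days_observed,
               stringsAsFactors = FALSE)))
}

#' Population estimate from calling-male counts
#'
#' Doubles the calling-male count, assuming a 50:50 sex ratio.
#'
#' @param site_id Site identifiers.
#' @param calling_males Counts of calling males.
#' @return Data frame with `site_id`, `calling_males`, `estimated_size`.
#' @export
population_estimate <- function(site_id, calling_males) {
  if (any(calling_males < 0)) stop("counts must be non-negative", call. = FALSE)
  data.frame(site_id = as.character(site_id),
             calling_males = calling_males,
             estimated_size = as.integer(2 * calling_males),
             stringsAsFactors = FALSE)
}

#' Rank correlation between threshold exceedance and population size
#'
#' Spearman rank-order correlation (average ranks for ties; the coefficient
#' is the Pearson correlation of the ranks) between a per-site exceedance
#' count and the estimated population size, paired by `site_id`. The
#' two-sided p-value uses the t approximation
#' `t = r * sqrt((n-2)/(1-r^2))` on `n - 2` degrees of freedom.
#'
#' @param summaries List of [summarize_site_year()] results or the data
#'   frame from [site_year_table()].
#' @param populations Data frame from [population_estimate()] (or any frame
#'   with `site_id` and `estimated_size`).
#' @param metric Which exceedance count to correlate
#'   (default `"days_exceeding_at"`).
#' @return List with `rs`, `p_value`, `n`, `metric`.
#' @export
exceedance_population_correlation <- function(summaries, populations,
                                              metric = "days_exceeding_at") {
  df <- if (is.data.frame(summaries)) summaries else site_year_table(summaries)
  stopifnot(metric %in% names(df), all(c("site_id", "estimated_size") %in% names(populations)))
  unmatched <- union(setdiff(df$site_id, populations$site_id),
                     setdiff(populations$site_id, df$site_id))
  if (length(unmatched) > 0L)
    stop("site ids not present in both tables: ",
         paste(unmatched, collapse = ", "), call. = FALSE)
  mg <- merge(df[, c("site_id", metric)], populations[, c("site_id", "estimated_size")],
              by = "site_id")
  n <- nrow(mg)
  if (n < 4L)
    stop("need at least 4 paired sites, got ", n, call. = FALSE)
  rx <- rank(mg[[metric]])          # average ranks for ties
  ry <- rank(mg$estimated_size)
  rs <- stats::cor(rx, ry)
  p <- if (abs(rs) >= 1) 0 else {
    tval <- rs * sqrt((n - 2) / (1 - rs^2))
    2 * stats::pt(-abs(tval), df = n - 2)
  }
  list(rs = rs, p_value = p, n = n, metric = metric)
}

#' Mean exceedance days across sites
#'
#' @param summaries List of summaries or [site_year_table()] data frame.
#' @param metric Which count to average (default `"days_exceeding_at"`).
#' @return Arithmetic mean number of exceedance days.
#' @export
mean_exceedance_days <- function(summaries, metric = "days_exceeding_at") {
  df <- if (is.data.frame(summaries)) summaries else site_year_table(summaries)
  if (nrow(df) == 0L) stop("no summaries supplied", call. = FALSE)
  stopifnot(metric %in% names(df))
  mean(df[[metric]])
}
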