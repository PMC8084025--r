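#' Annual climate series
#'
#' @param years Strictly increasing integer years (missing years allowed).
#' @param values Numeric values, one per year.
#' @param variable Label, e.g. `"rainfall_mm"`.
#' @param baseline Two-element year range used as the reference-period
#'   baseline for anomalies (default `c(1961, 1990)`, the standard
#'   climate-normal window).
#' @return An object of class `annual_series`.
#' @export
annual_series <- function(years, values, variable = "",
                          baseline = c(1961, 1990)) {
  if (length(years) != length(values))
    stop("years and values must have equal length", call. = FALSE)
  if (anyDuplicated(years) || is.unsorted(years, strictly = TRUE))
    stop("years must be strictly increasing with no duplicates", call. = FALSE)
  structure(list(years = as.integer(years), values = as.numeric(values),
                 variable = variable, baseline = baseline),
            class = "annual_series")
}

#' Subset an annual series to a closed year window
#'
#' @param series An [annual_series()].
#' @param from,to First and last year (inclusive).
#' @return An [annual_series()] restricted to the window.
#' @export
window_years <- function(series, from, to) {
  stopifnot(inherits(series, "annual_series"))
  keep <- series$years >= from & series$years <= to
  annual_series(series$years[keep], series$values[keep],
                series$variable, series$baseline)
}

#' Mann-Kendall trend test
#'
#' Rank-based nonparametric test for monotone trend:
#' `S = sum_{i<j} sign(x_j - x_i)` with the tie-corrected variance
#' `varS = [n(n-1)(2n+5) - sum_t t(t-1)(2t+5)] / 18` (sum over tie groups),
#' a continuity-corrected normal deviate `Z = (S -+ 1)/sqrt(varS)` and a
#' two-sided normal p-value. `tau = S / (n(n-1)/2)`.
#'
#' @param series An [annual_series()] (values may include `NA`, which are
#'   dropped pairwise with their years).
#' @return List with `S`, `varS`, `Z`, `p_two_sided`, `tau`, `n`.
#' @export
mann_kendall <- function(series) {
  stopifnot(inherits(series, "annual_series"))
  ok <- is.finite(series$values)
  x <- series$values[ok]
  n <- length(x)
  if (n < 4L) stop("need at least 4 observed years, got ", n, call. = FALSE)
  # S via sign of all pairwise differences (years are increasing, so order
  # in x is time order)
  d <- outer(x, x, "-")
  S <- sum(sign(d[lower.tri(d)]))  # d[j,i] = x_j - x_i for j > i
  tt <- table(x)
  tt <- tt[tt > 1L]
  varS <- (n * (n - 1) * (2 * n + 5) - sum(tt * (tt - 1) * (2 * tt + 5))) / 18
  Z <- if (S > 0) (S - 1) / sqrt(varS) else if (S < 0) (S + 1) / sqrt(varS) else 0
  list(S = S, varS = varS, Z = Z,
       p_two_sided = 2 * stats::pnorm(-abs(Z)),
       tau = S / (n * (n - 1) / 2), n = n)
}

#' Sen's slope estimate with rank-based confidence interval
#'
#' Median of all pairwise slopes `(x_j - x_i)/(year_j - year_i)`, reported
#' per year and per decade, with the distribution-free 95 percent interval
#' obtained by counting `1.96 * sqrt(varS)` pairwise slopes either side of
#' the median (ranks interpolated).
#'
#' @param series An [annual_series()] (`NA` values dropped with their years).
#' @param conf_level Confidence level (default 0.95).
#' @return List with `slope_per_year`, `slope_per_decade`, `ci_95`
#'   (per-year units), `n_pairs`.
#' @export
sens_slope <- function(series, conf_level = 0.95) {
  stopifnot(inherits(series, "annual_series"))
  ok <- is.finite(series$values)
  x <- series$values[ok]
  yr <- series$years[ok]
  n <- length(x)
  if (n < 2L) stop("need at least 2 observed years", call. = FALSE)
  ij <- utils::combn(n, 2)
  slopes <- (x[ij[2, ]] - x[ij[1, ]]) / (yr[ij[2, ]] - yr[ij[1, ]])
  slopes <- sort(slopes)
  N <- length(slopes)
  med <- stats::median(slopes)
  ci <- c(NA_real_, NA_real_)
  if (n >= 4L) {
    tt <- table(x); tt <- tt[tt > 1L]
    varS <- (n * (n - 1) * (2 * n + 5) - sum(tt * (tt - 1) * (2 * tt + 5))) / 18
    z <- stats::qnorm(1 - (1 - conf_level) / 2)
    C <- z * sqrt(varS)
    lo <- (N - C) / 2
    hi <- (N + C) / 2 + 1
    grab <- function(r) {
      if (r < 1) return(slopes[1L])
      if (r > N) return(slopes[N])
      f <- floor(r)
      if (f == r || f == N) slopes[f] else
        slopes[f] + (r - f) * (slopes[f + 1L] - slopes[f])
    }
    ci <- c(grab(lo), grab(hi))
  }
  list(slope_per_year = med, slope_per_decade = 10 * med,
       ci_95 = ci, n_pairs = N)
}

#' Anomaly relative to the baseline-period mean
#'
#' Deviation of one year's value from the mean over the series' baseline
#' window (by default 1961-1990).
#'
#' @param series An [annual_series()].
#' @param year Year to evaluate.
#' @param percent If `TRUE`, return `100 * (value - mean)/mean` instead of
#'   the absolute deviation.
#' @return Anomaly in the units of the series (or percent).
#' @export
anomaly <- function(series, year, percent = FALSE) {
  stopifnot(inherits(series, "annual_series"))
  i <- match(year, series$years)
  if (is.na(i) || !is.finite(series$values[i]))
    stop("year ", year, " not observed in the series", call. = FALSE)
  base <- series$years >= series$baseline[1] & series$years <= series$baseline[2] &
    is.finite(series$values)
  if (!any(base))
    stop("no observed years in the baseline window ",
         series$baseline[1], "-", series$baseline[2], call. = FALSE)
  m <- mean(series$values[base])
  if (percent) 100 * (series$values[i] - m) / m else series$values[i] - m
}

#' Empirical percentile rank of one year within the series
#'
#' Mid-rank convention: the mean of the "strictly less" and "less or equal"
#' proportions, times 100, so full ties sit at 50 and the maximum of n
#' distinct values sits at `100(n - 0.5)/n`.
#'
#' @param series An [annual_series()].
#' @param year Year to evaluate.
#' @return Percentile in 0-100.
#' @export
percentile_rank <- function(series, year) {
  stopifnot(inherits(series, "annual_series"))
  i <- match(year, series$years)
  if (is.na(i) || !is.finite(series$values[i]))
    stop("year ", year, " not observed in the series", call. = FALSE)
  x <- series$values[is.finite(series$values)]
  v <- series$values[i]
  100 * (sum(x < v) + sum(x <= v)) / (2 * length(x))
}

#' Lag-k sample autocorrelation with significance bounds
#'
#' Convenience check for serial correlation before trend testing; the
#' white-noise significance bounds are `+-1.96/sqrt(n)`.
#'
#' @param series An [annual_series()].
#' @param lag_max Largest lag (default `10*log10(n)` as in [stats::acf()]).
#' @return List with `lag`, `acf`, `bound`, and `significant` (logical,
#'   per lag, excluding lag 0).
#' @export
autocorrelation <- function(series, lag_max = NULL) {
  stopifnot(inherits(series, "annual_series"))
  x <- series$values
  n <- sum(is.finite(x))
  a <- stats::acf(x, lag.max = lag_max, plot = FALSE, na.action = stats::na.pass)
  lag <- drop(a$lag)
  val <- drop(a$acf)
  bound <- 1.96 / sqrt(n)
  list(lag = lag, acf = val, bound = bound,
       significant = abs(val) > bound & lag > 0)
}
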