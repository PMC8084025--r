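# Readers and writers for the delimited formats the analysis consumes.

autodetect_delim <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L) return(",")
  if (lengths(regmatches(first, gregexpr("\t", first))) >=
      lengths(regmatches(first, gregexpr(",", first)))) "\t" else ","
}

#' Read a soil sensor logger export
#'
#' Normalises delimited logger exports (iButton/HOBO/Em50-style) to a
#' [sensor_series()]. Column names and the timestamp format are
#' configurable; malformed rows (unparseable timestamp or non-numeric
#' reading) are counted and reported via a warning, and become a hard
#' error above a tolerated fraction.
#'
#' @param path File path.
#' @param site_id,habitat Passed to [sensor_series()].
#' @param column_map Named character vector mapping roles to file columns;
#'   must cover `timestamp` and at least one of `psi`, `temp`. Default
#'   `c(timestamp = "timestamp", psi = "psi_kPa", temp = "temp_C")`.
#' @param timestamp_format `strptime` format (default `"%Y-%m-%d %H:%M:%S"`).
#' @param delim Field delimiter; autodetected (comma/tab) when `NULL`.
#' @param tolerance Maximum tolerated fraction of malformed rows
#'   (default 0.2).
#' @return A [sensor_series()]; attribute `n_malformed` counts dropped rows.
#' @export
read_sensor_export <- function(path, site_id, habitat = "riparian",
                               column_map = c(timestamp = "timestamp",
                                              psi = "psi_kPa",
                                              temp = "temp_C"),
                               timestamp_format = "%Y-%m-%d %H:%M:%S",
                               delim = NULL, tolerance = 0.2) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(delim)) delim <- autodetect_delim(path)
  raw <- utils::read.table(path, header = TRUE, sep = delim,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  if (nrow(raw) == 0L) stop("empty sensor export: ", path, call. = FALSE)
  if (!("timestamp" %in% names(column_map)) ||
      !any(c("psi", "temp") %in% names(column_map)))
    stop("column_map must cover 'timestamp' and at least one of 'psi'/'temp'",
         call. = FALSE)
  missing_cols <- setdiff(unname(column_map), names(raw))
  if (length(missing_cols) > 0L)
    stop("columns not in file: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)

  ts <- as.POSIXct(raw[[column_map["timestamp"]]], format = timestamp_format,
                   tz = "UTC")
  num_or_na <- function(role)
    if (role %in% names(column_map))
      suppressWarnings(as.numeric(raw[[column_map[role]]]))
    else rep(NA_real_, nrow(raw))
  psi <- num_or_na("psi")
  temp <- num_or_na("temp")

  has_data <- (if ("psi" %in% names(column_map)) !is.na(psi) else FALSE) |
    (if ("temp" %in% names(column_map)) !is.na(temp) else FALSE)
  bad <- is.na(ts) | !has_data
  n_bad <- sum(bad)
  if (n_bad / nrow(raw) > tolerance)
    stop(n_bad, " of ", nrow(raw), " rows malformed (lines ",
         paste(utils::head(which(bad) + 1L, 10), collapse = ", "),
         if (n_bad > 10) ", ..." else "", ") in ", path, call. = FALSE)
  if (n_bad > 0L)
    warning(n_bad, " malformed row(s) dropped from ", path, call. = FALSE)
  keep <- !bad
  if (!any(keep)) stop("no parseable rows in ", path, call. = FALSE)
  out <- sensor_series(site_id, habitat, ts[keep], psi[keep], temp[keep])
  attr(out, "n_malformed") <- n_bad
  out
}

#' Write / read fitted rate-curve parameters as plain text
#'
#' Round-trippable key-value text representation (full precision) of a
#' [rate_curve_params()] object.
#'
#' @param params A [rate_curve_params()] object.
#' @param path Output file.
#' @return `write_rate_params()` returns `path` invisibly;
#'   `read_rate_params()` returns the reconstructed object.
#' @export
write_rate_params <- function(params, path) {
  stopifnot(inherits(params, "rate_curve_params"))
  num <- function(x) formatC(x, digits = 17, format = "g")
  lines <- c(
    sprintf("species_label: %s", params$species_label),
    vapply(c("b1", "b2", "b3", "b4", "b5"), function(k)
      sprintf("%s: %s", k, num(params[[k]])), character(1)),
    if (!is.null(params$rss)) sprintf("rss: %s", num(params$rss)),
    if (!is.null(params$se))
      sprintf("se_%s: %s", names(params$se), num(params$se)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_rate_params
#' @export
read_rate_params <- function(path) {
  lines <- readLines(path, warn = FALSE)
  kv <- regmatches(lines, regexec("^([^:]+): ?(.*)$", lines))
  keys <- vapply(kv, `[`, character(1), 2)
  vals <- vapply(kv, `[`, character(1), 3)
  getv <- function(k) as.numeric(vals[keys == k][1])
  se_keys <- keys[startsWith(keys, "se_")]
  se <- if (length(se_keys) > 0) {
    s <- vapply(se_keys, function(k) as.numeric(vals[keys == k][1]), numeric(1))
    names(s) <- sub("^se_", "", se_keys)
    s
  } else NULL
  rate_curve_params(getv("b1"), getv("b2"), getv("b3"), getv("b4"), getv("b5"),
                    se = se,
                    rss = if ("rss" %in% keys) getv("rss") else NULL,
                    species_label = vals[keys == "species_label"][1])
}
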