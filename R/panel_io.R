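#' Construct a city panel
#'
#' A city panel is the package's central container: one row per areal unit
#' (optionally per time period) with planar centroid coordinates in km, a
#' response concentration (\eqn{\mu g/m^3}), and named covariate columns.
#'
#' @param data data.frame with columns `unit_id`, `x`, `y`, `y_resp`,
#'   optionally `group` and `time`, plus one column per covariate.
#' @param covariates character vector naming the covariate columns.
#' @param validate if `TRUE` (default), enforce the panel invariants:
#'   unit ids unique within each time slice, finite coordinates and response,
#'   unique covariate names.
#' @return a `city_panel` (a data.frame subclass carrying a `covariates`
#'   attribute).
#' @export
city_panel <- function(data, covariates = character(), validate = TRUE) {
  stopifnot(is.data.frame(data))
  need <- c("unit_id", "x", "y", "y_resp")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop2("panel is missing mandatory column(s): ", paste(miss, collapse = ", "))
  covariates <- as.character(covariates)
  if (anyDuplicated(covariates))
    stop2("covariate names must be unique")
  miss <- setdiff(covariates, names(data))
  if (length(miss))
    stop2("covariate column(s) not in data: ", paste(miss, collapse = ", "))
  data$unit_id <- as.character(data$unit_id)
  if (validate) {
    key <- if ("time" %in% names(data))
      paste(data$unit_id, data$time, sep = "\r") else data$unit_id
    if (anyDuplicated(key))
      stop2("duplicate (unit_id, time) rows in panel")
    bad <- !is.finite(data$x) | !is.finite(data$y) | !is.finite(data$y_resp)
    if (any(bad))
      stop2(sum(bad), " row(s) with non-finite response or coordinates; ",
            "clean before constructing (read_panel drops them)")
  }
  structure(data, covariates = covariates,
            class = c("city_panel", "data.frame"))
}

#' @export
print.city_panel <- function(x, ...) {
  cat(sprintf("<city_panel> %d rows, %d unit(s), %d covariate(s)%s\n",
              nrow(x), length(unique(x$unit_id)),
              length(attr(x, "covariates")),
              if ("time" %in% names(x))
                sprintf(", %d time label(s)", length(unique(x$time))) else ""))
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

#' Covariate names of a panel
#' @param panel a `city_panel`.
#' @return character vector of covariate column names.
#' @export
panel_covariates <- function(panel) attr(panel, "covariates")

#' Subset a panel to one time slice
#' @param panel a `city_panel` with a `time` column.
#' @param time the time label to keep.
#' @return a `city_panel` with the `time` filter applied.
#' @export
panel_slice <- function(panel, time) {
  if (!"time" %in% names(panel)) return(panel)
  out <- panel[panel$time == time, , drop = FALSE]
  rownames(out) <- NULL
  city_panel(as.data.frame(out), panel_covariates(panel))
}

#' Read a city panel from CSV
#'
#' Reads a long-format CSV (one row per unit x period) and maps its columns
#' onto the canonical panel fields. Rows with a missing response or missing
#' coordinates are dropped with a warning that reports the count.
#'
#' @param path CSV file path. Lines starting with `#` are ignored.
#' @param schema named list mapping canonical fields to file columns:
#'   `unit_id`, `x`, `y`, `y_resp` (mandatory), `group`, `time` (optional),
#'   and `covariates`, a character vector of covariate column names kept as-is.
#' @return a validated [city_panel()].
#' @export
read_panel <- function(path,
                       schema = list(unit_id = "unit_id", x = "x", y = "y",
                                     y_resp = "y_resp",
                                     covariates = character())) {
  if (!file.exists(path)) stop2("no such file: ", path)
  raw <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  mandatory <- c("unit_id", "x", "y", "y_resp")
  for (f in mandatory)
    if (is.null(schema[[f]]))
      stop2("schema must map the mandatory field `", f, "`")
  cols <- unlist(schema[mandatory])
  opt <- intersect(c("group", "time"), names(schema))
  cols <- c(cols, unlist(schema[opt]))
  covs <- as.character(schema$covariates %||% character())
  miss <- setdiff(c(cols, covs), names(raw))
  if (length(miss))
    stop2("mapped column(s) absent from file: ", paste(miss, collapse = ", "))
  df <- data.frame(unit_id = as.character(raw[[schema$unit_id]]),
                   x = as.numeric(raw[[schema$x]]),
                   y = as.numeric(raw[[schema$y]]),
                   y_resp = as.numeric(raw[[schema$y_resp]]),
                   stringsAsFactors = FALSE, check.names = FALSE)
  for (f in opt) df[[f]] <- raw[[schema[[f]]]]
  for (cv in covs) df[[cv]] <- as.numeric(raw[[cv]])
  bad <- !is.finite(df$x) | !is.finite(df$y) | !is.finite(df$y_resp)
  if (any(bad)) {
    warn2("dropped ", sum(bad), " row(s) with missing response or coordinates")
    df <- df[!bad, , drop = FALSE]
    rownames(df) <- NULL
  }
  city_panel(df, covs)
}

#' Write a city panel to CSV
#'
#' Numeric content survives a read/write round trip to better than 1e-9
#' (values are printed with 15 significant digits).
#'
#' @param panel a `city_panel`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  df <- as.data.frame(panel)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) formatC(v, digits = 15, format = "g"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Meteorological season of a (year, month) pair
#'
#' Seasons are spring = Mar/Apr/May, summer = Jun/Jul/Aug,
#' autumn = Sep/Oct/Nov, winter = Dec plus Jan/Feb of the following calendar
#' year; December is therefore labelled with the following year's winter
#' (Dec 2015, Jan 2016 and Feb 2016 all belong to winter 2016).
#'
#' @param year integer calendar year(s).
#' @param month integer month(s) 1..12.
#' @return data.frame with columns `season_year` and `season`.
#' @export
season_of <- function(year, month) {
  stopifnot(all(month %in% 1:12))
  season <- c("winter", "winter", "spring", "spring", "spring",
              "summer", "summer", "summer", "autumn", "autumn",
              "autumn", "winter")[month]
  season_year <- ifelse(month == 12L, year + 1L, year)
  data.frame(season_year = as.integer(season_year), season = season,
             stringsAsFactors = FALSE)
}

period_expectations <- function(level, key) {
  # expected number of sub-periods feeding each period, for completeness checks
  switch(level,
         daily = 24,
         monthly = {
           y <- as.integer(substr(key, 1, 4)); m <- as.integer(substr(key, 6, 7))
           first <- as.Date(sprintf("%04d-%02d-01", y, m))
           as.integer(format(seq(first, by = "month", length.out = 2)[2] - 1, "%d"))
         },
         seasonal = 3,
         annual = 12)
}

agg_level <- function(values, keys, level, completeness) {
  means <- tapply(values, keys, mean, na.rm = TRUE)
  keep <- vapply(names(means), function(k) {
    exp_n <- period_expectations(level, k)
    n_ok <- sum(!is.na(values[keys == k]))
    n_ok / exp_n >= completeness
  }, logical(1))
  means[keep & is.finite(means)]
}

#' Aggregate station records to daily/monthly/seasonal/annual unit means
#'
#' Hourly station concentrations are aggregated stepwise (hours to days,
#' days to months, months to seasons or years), at every step keeping a
#' period only if the fraction of non-missing sub-periods reaches
#' `completeness`. Annual means average the 12 monthly means (months weigh
#' equally), and seasonal means average 3 monthly means, with December
#' assigned to the following year's winter (see [season_of()]). The unit
#' value for a period is the unweighted mean of its stations' period means.
#'
#' @param stations data.frame with columns `station_id`, `unit_id`,
#'   `timestamp` (POSIXct or `"YYYY-MM-DD HH:MM:SS"` strings, naive local
#'   time) and `value` (concentration, \eqn{\ge 0} or `NA`).
#' @param level one of `"daily"`, `"monthly"`, `"seasonal"`, `"annual"`.
#' @param completeness minimum fraction of non-missing sub-periods required
#'   to report a period; default 0.75 at every level.
#' @return data.frame with columns `unit_id`, `time`, `y_resp`.
#' @export
aggregate_series <- function(stations, level = c("annual", "seasonal",
                                                 "monthly", "daily"),
                             completeness = 0.75) {
  level <- match.arg(level)
  assert_scalar_number(completeness, "completeness", lower = 1e-12, upper = 1)
  if (nrow(stations) == 0L) {
    warn2("empty station input; returning empty panel slices")
    return(data.frame(unit_id = character(), time = character(),
                      y_resp = numeric()))
  }
  need <- c("station_id", "unit_id", "timestamp", "value")
  miss <- setdiff(need, names(stations))
  if (length(miss)) stop2("stations missing column(s): ",
                          paste(miss, collapse = ", "))
  if (any(is.na(stations$unit_id)))
    stop2("station record(s) with unknown unit mapping")
  ts <- stations$timestamp
  if (!inherits(ts, "POSIXt"))
    ts <- as.POSIXct(as.character(ts), tz = "UTC")
  if (any(is.na(ts))) stop2("unparseable timestamp(s)")
  v <- as.numeric(stations$value)
  if (any(v < 0, na.rm = TRUE)) stop2("negative concentration value(s)")
  sid <- as.character(stations$station_id)
  day <- format(ts, "%Y-%m-%d")

  per_station <- function(fun) {
    sp <- split(seq_along(v), sid)
    do.call(rbind, lapply(names(sp), function(s) {
      i <- sp[[s]]
      res <- fun(v[i], i)
      if (is.null(res) || nrow(res) == 0L) return(NULL)
      res$station_id <- s
      res$unit_id <- stations$unit_id[i][1L]
      res
    }))
  }

  station_daily <- per_station(function(vals, idx) {
    m <- agg_level(vals, day[idx], "daily", completeness)
    if (!length(m)) return(NULL)
    data.frame(time = names(m), value = as.numeric(m),
               stringsAsFactors = FALSE)
  })
  if (is.null(station_daily) || nrow(station_daily) == 0L) {
    warn2("no period met the completeness threshold")
    return(data.frame(unit_id = character(), time = character(),
                      y_resp = numeric()))
  }
  up <- function(df, keys, lev) {
    sp <- split(seq_len(nrow(df)), df$station_id)
    out <- do.call(rbind, lapply(names(sp), function(s) {
      i <- sp[[s]]
      m <- agg_level(df$value[i], keys[i], lev, completeness)
      if (!length(m)) return(NULL)
      data.frame(time = names(m), value = as.numeric(m),
                 station_id = s, unit_id = df$unit_id[i][1L],
                 stringsAsFactors = FALSE)
    }))
    out
  }
  res <- station_daily
  if (level != "daily") {
    res <- up(res, substr(res$time, 1, 7), "monthly")
    if (!is.null(res) && level == "seasonal") {
      yr <- as.integer(substr(res$time, 1, 4))
      mo <- as.integer(substr(res$time, 6, 7))
      se <- season_of(yr, mo)
      res <- up(res, paste(se$season_year, se$season, sep = "-"), "seasonal")
    } else if (!is.null(res) && level == "annual") {
      res <- up(res, substr(res$time, 1, 4), "annual")
    }
  }
  if (is.null(res) || nrow(res) == 0L) {
    warn2("no period met the completeness threshold")
    return(data.frame(unit_id = character(), time = character(),
                      y_resp = numeric()))
  }
  agg <- stats::aggregate(value ~ unit_id + time, data = res, FUN = mean)
  out <- data.frame(unit_id = agg$unit_id, time = agg$time,
                    y_resp = agg$value, stringsAsFactors = FALSE)
  out[order(out$unit_id, out$time), , drop = FALSE]
}
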