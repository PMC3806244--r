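#' Read a station monthly-temperature table
#'
#' Reads delimited text with header
#' \code{station_id,division,year,month,temp_c}: one row per station, year and
#' month, temperatures in degrees Celsius.
#'
#' @param path Path to a delimited text file (comma-separated by default).
#' @param sep Field separator.
#' @return A data frame with columns \code{station_id}, \code{division},
#'   \code{year}, \code{month}, \code{temp_c}.
#' @export
read_station_table <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  required <- c("station_id", "division", "year", "month", "temp_c")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("station table is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  df$division <- as.integer(df$division)
  df$year <- as.integer(df$year)
  df$month <- as.integer(df$month)
  df$temp_c <- as.numeric(df$temp_c)
  df
}

#' Read USHCN-style fixed-width monthly temperature records
#'
#' Adapter for the fixed-width monthly layout used by the U.S. Historical
#' Climatology Network: an 11-character station identifier, a 4-digit year,
#' then twelve 9-character value groups whose first 6 characters hold the
#' monthly mean in hundredths of a degree Celsius (-9999 = missing).
#'
#' @param path Path to the fixed-width file.
#' @param station_divisions Named integer vector mapping station identifiers to
#'   climate-division codes; stations absent from the map are dropped with a
#'   message.
#' @return A station table as from [read_station_table()].
#' @export
read_ushcn_fixed <- function(path, station_divisions) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    sid <- trimws(substr(ln, 1, 11))
    yr <- as.integer(substr(ln, 13, 16))
    vals <- vapply(0:11, function(m) {
      start <- 18 + m * 9
      as.numeric(substr(ln, start, start + 5))
    }, numeric(1))
    keep <- !is.na(vals) & vals != -9999
    if (!any(keep)) next
    out[[i]] <- data.frame(station_id = sid, year = yr,
                           month = which(keep),
                           temp_c = vals[keep] / 100,
                           stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, out)
  if (is.null(df)) stop("no parsable records in ", path)
  known <- df$station_id %in% names(station_divisions)
  if (any(!known)) {
    message(sum(!known), " record(s) dropped: station not in division map")
    df <- df[known, , drop = FALSE]
  }
  df$division <- as.integer(station_divisions[df$station_id])
  df[, c("station_id", "division", "year", "month", "temp_c")]
}

#' Aggregate station temperatures to climate-division monthly means
#'
#' For every (division, year, month) the division mean is the arithmetic mean
#' of all reporting stations in that division, with the contributing station
#' count retained. Divisions average over whichever stations report in a given
#' month, so \code{n_stations} may vary through the record.
#'
#' @param stations Station table (see [read_station_table()]).
#' @return A data frame of class \code{division_monthly} with columns
#'   \code{division}, \code{year}, \code{month}, \code{mean_temp_c},
#'   \code{n_stations}.
#' @export
aggregate_division_monthly <- function(stations) {
  required <- c("station_id", "division", "year", "month", "temp_c")
  missing <- setdiff(required, names(stations))
  if (length(missing) > 0) {
    stop("station table is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  if (nrow(stations) == 0) stop("station table is empty")
  if (any(!is.finite(stations$temp_c))) {
    stop("non-finite temperature value(s) in station table")
  }
  if (any(stations$month < 1 | stations$month > 12)) {
    stop("month outside 1..12 in station table")
  }
  key <- paste(stations$station_id, stations$year, stations$month, sep = "|")
  dup <- duplicated(key)
  if (any(dup)) {
    stop("duplicate station-month record(s), e.g. ",
         paste(utils::head(key[dup], 3), collapse = "; "))
  }
  gkey <- interaction(stations$division, stations$year, stations$month,
                      drop = TRUE)
  mean_temp <- tapply(stations$temp_c, gkey, mean)
  n_stat <- tapply(stations$temp_c, gkey, length)
  parts <- strsplit(names(mean_temp), ".", fixed = TRUE)
  out <- data.frame(
    division = as.integer(vapply(parts, `[[`, "", 1L)),
    year = as.integer(vapply(parts, `[[`, "", 2L)),
    month = as.integer(vapply(parts, `[[`, "", 3L)),
    mean_temp_c = as.numeric(mean_temp),
    n_stations = as.integer(n_stat)
  )
  out <- out[order(out$division, out$year, out$month), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("division_monthly", "data.frame")
  out
}

# Dense (division x month-index) lookup used for fast repeated window means.
# Month index counts months from January of the first year in the series.
.division_temp_matrix <- function(series) {
  divisions <- sort(unique(series$division))
  y0 <- min(series$year)
  idx <- (series$year - y0) * 12L + series$month  # 1-based within grid
  n_col <- max(idx)
  mat <- matrix(NA_real_, nrow = length(divisions), ncol = n_col)
  mat[cbind(match(series$division, divisions), idx)] <- series$mean_temp_c
  list(mat = mat, divisions = divisions, first_year = y0)
}

#' Windowed mean of division monthly temperature
#'
#' Mean temperature over \code{n_months} consecutive months ending at
#' (\code{end_year}, \code{end_month}); the window wraps into the previous
#' calendar year when it extends before January. A May ending with
#' \code{n_months = 4} averages February through May of \code{end_year}.
#' Any missing month is an error; nothing is imputed.
#'
#' @param series A \code{division_monthly} table.
#' @param end_year,end_month Calendar position of the final month.
#' @param n_months Window length in months (>= 1).
#' @param division Division code; may be omitted when the series holds a
#'   single division.
#' @return Mean temperature in degrees Celsius.
#' @export
window_mean <- function(series, end_year, end_month, n_months, division = NULL) {
  if (n_months < 1) stop("n_months must be >= 1")
  if (end_month < 1 || end_month > 12) stop("end_month outside 1..12")
  if (is.null(division)) {
    division <- unique(series$division)
    if (length(division) != 1) {
      stop("series holds multiple divisions; supply `division`")
    }
  }
  sub <- series[series$division == division, , drop = FALSE]
  if (nrow(sub) == 0) stop("no records for division ", division)
  end_idx <- end_year * 12L + end_month
  want_idx <- (end_idx - n_months + 1L):end_idx
  want_year <- (want_idx - 1L) %/% 12L
  want_month <- want_idx - want_year * 12L
  pos <- match(paste(want_year, want_month), paste(sub$year, sub$month))
  if (anyNA(pos)) {
    gap <- which(is.na(pos))[1]
    stop(sprintf("missing month %d-%02d for division %s",
                 want_year[gap], want_month[gap], division))
  }
  mean(sub$mean_temp_c[pos])
}

#' Statewide series as the unweighted mean of division means
#'
#' @param series A \code{division_monthly} table covering one or more
#'   divisions.
#' @return A \code{division_monthly} table with a single pseudo-division 0,
#'   each month the unweighted mean over divisions reporting that month;
#'   \code{n_stations} holds the number of contributing divisions.
#' @export
statewide_series <- function(series) {
  gkey <- interaction(series$year, series$month, drop = TRUE)
  mean_temp <- tapply(series$mean_temp_c, gkey, mean)
  n_div <- tapply(series$mean_temp_c, gkey, length)
  parts <- strsplit(names(mean_temp), ".", fixed = TRUE)
  out <- data.frame(
    division = 0L,
    year = as.integer(vapply(parts, `[[`, "", 1L)),
    month = as.integer(vapply(parts, `[[`, "", 2L)),
    mean_temp_c = as.numeric(mean_temp),
    n_stations = as.integer(n_div)
  )
  out <- out[order(out$year, out$month), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("division_monthly", "data.frame")
  out
}

#' Seasonal temperature anomalies and linear warming trend
#'
#' For every year with complete coverage of \code{season_months}, the seasonal
#' mean is computed; anomalies subtract the all-years seasonal mean (full
#' record baseline). The warming trend is the ordinary least-squares slope of
#' anomaly on year, with the two-sided t-test p-value, and the total change is
#' slope times the year span. Years with incomplete seasonal coverage are
#' excluded with a warning.
#'
#' @param series A \code{division_monthly} table (one division, or a statewide
#'   series from [statewide_series()]).
#' @param season_months Integer months defining the season (e.g. \code{2:5}
#'   for February--May spring).
#' @param first_year,last_year Analysis span; defaults to the series range.
#' @param division Division code when the series holds several divisions.
#' @return An object of class \code{seasonal_trend}: list with
#'   \code{slope_c_per_year}, \code{total_change_c}, \code{p_value},
#'   \code{anomalies} (named by year), \code{season_months}, \code{years}.
#' @export
seasonal_trend <- function(series, season_months = 2:5,
                           first_year = NULL, last_year = NULL,
                           division = NULL) {
  if (!is.null(division)) {
    series <- series[series$division == division, , drop = FALSE]
  } else if (length(unique(series$division)) != 1) {
    stop("series holds multiple divisions; supply `division` or use statewide_series()")
  }
  if (is.null(first_year)) first_year <- min(series$year)
  if (is.null(last_year)) last_year <- max(series$year)
  sub <- series[series$year >= first_year & series$year <= last_year &
                  series$month %in% season_months, , drop = FALSE]
  cnt <- tapply(sub$month, sub$year, function(m) length(unique(m)))
  complete <- names(cnt)[cnt == length(season_months)]
  if (length(complete) < length(cnt)) {
    warning(length(cnt) - length(complete),
            " year(s) excluded for incomplete seasonal coverage")
  }
  if (length(complete) < 3) stop("fewer than 3 years with complete season coverage")
  sub <- sub[sub$year %in% as.integer(complete), , drop = FALSE]
  yearly <- tapply(sub$mean_temp_c, sub$year, mean)
  years <- as.integer(names(yearly))
  anomalies <- as.numeric(yearly) - mean(yearly)
  names(anomalies) <- years
  fit <- stats::lm(anomalies ~ years)
  sm <- summary(fit)$coefficients
  slope <- unname(sm["years", "Estimate"])
  structure(list(
    season_months = season_months,
    slope_c_per_year = slope,
    total_change_c = slope * (last_year - first_year),
    p_value = unname(sm["years", "Pr(>|t|)"]),
    anomalies = anomalies,
    years = years,
    first_year = first_year,
    last_year = last_year
  ), class = "seasonal_trend")
}

#' @export
#' @method print seasonal_trend
print.seasonal_trend <- function(x, ...) {
  cat(sprintf("Seasonal trend (months %s), %d-%d\n",
              paste(x$season_months, collapse = ","),
              x$first_year, x$last_year))
  cat(sprintf("  slope: %.4f degC/yr   total change: %.2f degC   p = %.3g\n",
              x$slope_c_per_year, x$total_change_c, x$p_value))
  invisible(x)
}

#' @export
plot.seasonal_trend <- function(x, ...) {
  graphics::plot(x$years, x$anomalies, pch = 16,
                 xlab = "Year", ylab = "Temperature anomaly (degC)", ...)
  graphics::abline(stats::lm(x$anomalies ~ x$years), col = "red")
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}
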