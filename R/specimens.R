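#' Day of year for calendar dates
#'
#' 1-based ordinal date (January 1 = 1), honouring leap years.
#'
#' @param dates A \code{Date} vector or ISO date strings.
#' @return Integer day-of-year vector.
#' @export
day_of_year <- function(dates) {
  dates <- as.Date(dates)
  as.POSIXlt(dates)$yday + 1L
}

#' Read a herbarium specimen table
#'
#' Delimited text with header
#' \code{species,date,division,collector,peak_flowering[,locality]}; dates are
#' ISO (\code{YYYY-MM-DD}), \code{peak_flowering} is logical (at least 50\% of
#' flower buds in anthesis).
#'
#' @param path Path to the delimited file.
#' @param sep Field separator.
#' @return Raw specimen data frame (unvalidated; see [filter_specimens()]).
#' @export
read_specimen_table <- function(path, sep = ",") {
  utils::read.table(path, header = TRUE, sep = sep,
                    stringsAsFactors = FALSE, quote = "\"")
}

#' Validate and filter specimen records
#'
#' Retains only peak-flowering records (specimens with more than half of their
#' flower buds in anthesis), parses dates and computes day of year, and drops
#' rows with unparseable dates or unrecognised climate divisions. Dropped
#' counts are reported in a message and attached as the \code{"dropped"}
#' attribute.
#'
#' @param specimens Raw specimen data frame with columns \code{species},
#'   \code{date}, \code{division}, \code{collector}, \code{peak_flowering}
#'   (and optionally \code{locality}).
#' @param divisions Integer vector of recognised division codes; \code{NULL}
#'   accepts any non-missing code.
#' @return Validated specimen records: columns \code{species}, \code{date}
#'   (Date), \code{year}, \code{month}, \code{doy}, \code{division},
#'   \code{collector} (and \code{locality} if present).
#' @export
filter_specimens <- function(specimens, divisions = NULL) {
  required <- c("species", "date", "division", "collector", "peak_flowering")
  missing <- setdiff(required, names(specimens))
  if (length(missing) > 0) {
    stop("specimen table is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  pf <- specimens$peak_flowering
  if (!is.logical(pf)) pf <- as.logical(toupper(as.character(pf)))
  n_nonpeak <- sum(!pf | is.na(pf))
  df <- specimens[!is.na(pf) & pf, , drop = FALSE]

  dt <- suppressWarnings(as.Date(as.character(df$date), format = "%Y-%m-%d"))
  n_baddate <- sum(is.na(dt))
  df <- df[!is.na(dt), , drop = FALSE]
  dt <- dt[!is.na(dt)]

  div <- suppressWarnings(as.integer(df$division))
  bad_div <- is.na(div)
  if (!is.null(divisions)) bad_div <- bad_div | !(div %in% divisions)
  n_baddiv <- sum(bad_div)
  df <- df[!bad_div, , drop = FALSE]
  dt <- dt[!bad_div]
  div <- div[!bad_div]

  out <- data.frame(
    species = as.character(df$species),
    date = dt,
    year = as.integer(format(dt, "%Y")),
    month = as.integer(format(dt, "%m")),
    doy = day_of_year(dt),
    division = div,
    collector = as.character(df$collector),
    stringsAsFactors = FALSE
  )
  if ("locality" %in% names(df)) out$locality <- as.character(df$locality)
  dropped <- c(non_peak = n_nonpeak, bad_date = n_baddate,
               unknown_division = n_baddiv)
  if (sum(dropped) > 0) {
    message("filter_specimens: dropped ", n_nonpeak, " non-peak, ",
            n_baddate, " unparseable-date, ", n_baddiv,
            " unknown-division record(s)")
  }
  attr(out, "dropped") <- dropped
  out
}

#' Collapse duplicate specimen records to a single datum
#'
#' Specimens of the same species with identical collection date, location and
#' collector represent a single sampling event; only the first such record in
#' input order is kept. Location is the free-text locality when present and
#' the climate-division code otherwise.
#'
#' @param records Validated specimen records from [filter_specimens()].
#' @return Deduplicated records; the number removed is attached as the
#'   \code{"n_removed"} attribute and reported in a message.
#' @export
dedupe_specimens <- function(records) {
  if (nrow(records) == 0) {
    attr(records, "n_removed") <- 0L
    return(records)
  }
  loc <- if ("locality" %in% names(records) && !all(is.na(records$locality))) {
    ifelse(is.na(records$locality) | records$locality == "",
           as.character(records$division), records$locality)
  } else {
    as.character(records$division)
  }
  key <- paste(records$species, records$date, loc, records$collector,
               sep = "\r")
  dup <- duplicated(key)
  out <- records[!dup, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(dup)
  if (any(dup)) message("dedupe_specimens: removed ", sum(dup), " duplicate(s)")
  out
}

#' Restrict to species with enough specimens
#'
#' Per-species regression needs a minimum number of specimens (10 by default);
#' species below the threshold are excluded.
#'
#' @param records Deduplicated specimen records.
#' @param min_n Minimum specimens per species.
#' @return Records of eligible species only, with a named per-species count
#'   vector (all species, pre-filter) attached as attribute \code{"counts"}.
#' @export
species_eligible <- function(records, min_n = 10) {
  counts <- table(records$species)
  keep <- names(counts)[counts >= min_n]
  out <- records[records$species %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "counts") <- stats::setNames(as.integer(counts), names(counts))
  out
}

#' Reference flowering month per species
#'
#' The modal calendar month across a species' retained specimens, ties broken
#' toward the earlier month. This reference month drives the window policy
#' (April-flowering species get the fixed February--April window).
#'
#' @param records Specimen records with \code{species} and \code{month}.
#' @return Named integer vector, species -> month.
#' @export
reference_month <- function(records) {
  vapply(split(records$month, records$species), function(m) {
    tab <- table(factor(m, levels = 1:12))
    as.integer(which.max(tab))  # which.max takes the first (earliest) tie
  }, integer(1))
}

#' Read a species trait table
#'
#' Delimited text with header
#' \code{species,season,growth_form,pollination,origin}. Levels follow the
#' functional-group scheme: season in \{spring (April--May), early_summer
#' (June--July), late_summer (August on)\}; growth form in \{woody_perennial,
#' herbaceous_perennial, herbaceous_annual, perennial_vine\} (biennials and
#' annual/perennial intermediates are coded as annuals); pollination in
#' \{wind, insect_facultative, insect_obligate, unknown\}; origin in
#' \{native, introduced\}.
#'
#' @param path Path to the delimited file.
#' @param sep Field separator.
#' @return Trait data frame with validated factor levels.
#' @export
read_trait_table <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  required <- c("species", "season", "growth_form", "pollination", "origin")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("trait table is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  levels <- list(
    season = c("spring", "early_summer", "late_summer"),
    growth_form = c("woody_perennial", "herbaceous_perennial",
                    "herbaceous_annual", "perennial_vine"),
    pollination = c("wind", "insect_facultative", "insect_obligate", "unknown"),
    origin = c("native", "introduced")
  )
  for (col in names(levels)) {
    bad <- !(df[[col]] %in% levels[[col]])
    if (any(bad)) {
      stop("invalid ", col, " value(s): ",
           paste(unique(df[[col]][bad]), collapse = ", "))
    }
  }
  df
}
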