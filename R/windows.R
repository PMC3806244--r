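# Per-specimen windowed temperatures, vectorised over records.
# anchor = "specimen": the window ends at each specimen's own collection month
# in its own year and division. anchor = "fixed": the window ends at calendar
# month `end_month` of each specimen's collection year (it may wrap into the
# prior year).
.specimen_window_temps <- function(records, series, n_months,
                                   anchor = c("specimen", "fixed"),
                                   end_month = NULL) {
  anchor <- match.arg(anchor)
  lk <- .division_temp_matrix(series)
  row <- match(records$division, lk$divisions)
  if (anyNA(row)) {
    stop("no climate series for division(s): ",
         paste(unique(records$division[is.na(row)]), collapse = ", "))
  }
  if (anchor == "fixed") {
    stopifnot(!is.null(end_month), end_month >= 1, end_month <= 12)
    end_idx <- (records$year - lk$first_year) * 12L + as.integer(end_month)
  } else {
    end_idx <- (records$year - lk$first_year) * 12L + records$month
  }
  acc <- numeric(nrow(records))
  for (off in 0:(n_months - 1L)) {
    j <- end_idx - off
    bad <- j < 1L | j > ncol(lk$mat)
    v <- rep(NA_real_, length(j))
    v[!bad] <- lk$mat[cbind(row[!bad], j[!bad])]
    if (anyNA(v)) {
      i <- which(is.na(v))[1]
      gy <- lk$first_year + (j[i] - 1L) %/% 12L
      gm <- j[i] - ((j[i] - 1L) %/% 12L) * 12L
      stop(sprintf(
        "specimen %d (%s, %s, division %s): climate series missing %d-%02d",
        i, records$species[i], format(records$date[i]), records$division[i],
        gy, gm))
    }
    acc <- acc + v
  }
  acc / n_months
}

#' Lagged-window correlation screen for one species
#'
#' For each candidate window length w = 1..\code{max_lag} months, computes the
#' mean division temperature over the w months ending at each specimen's own
#' flowering month (in its own year and climate division) and the Pearson
#' correlation of flowering day-of-year with that windowed temperature. The
#' same specimen set is used at every window length.
#'
#' The window can end at each specimen's own collection month (the default)
#' or, with \code{anchor = "fixed"}, at the species' reference flowering
#' month in every specimen's collection year. The fixed anchor keeps the
#' covariate independent of each specimen's realised collection month, which
#' otherwise leaks the seasonal cycle into the screen (a specimen collected a
#' few days into the next month drags its whole window onto climatologically
#' warmer or colder months).
#'
#' @param records Specimen records of a single species (validated,
#'   deduplicated).
#' @param series \code{division_monthly} temperature table covering every
#'   month any window needs.
#' @param max_lag Longest window length screened, in months.
#' @param anchor \code{"specimen"} or \code{"fixed"}.
#' @param end_month Anchor month for \code{anchor = "fixed"} (typically the
#'   species' reference flowering month).
#' @return Object of class \code{lag_profile}: list with \code{species},
#'   \code{corr_by_window} (length \code{max_lag}), \code{n}, \code{anchor}.
#' @export
lag_correlation_profile <- function(records, series, max_lag = 12,
                                    anchor = c("specimen", "fixed"),
                                    end_month = NULL) {
  anchor <- match.arg(anchor)
  sp <- unique(records$species)
  if (length(sp) != 1) stop("records must belong to a single species")
  if (stats::sd(records$doy) == 0) {
    stop("flowering day-of-year is constant across specimens of ", sp,
         "; correlation undefined")
  }
  corr <- vapply(seq_len(max_lag), function(w) {
    tw <- .specimen_window_temps(records, series, n_months = w,
                                 anchor = anchor, end_month = end_month)
    if (stats::sd(tw) == 0) return(NA_real_)
    stats::cor(records$doy, tw)
  }, numeric(1))
  structure(list(species = sp, corr_by_window = corr, n = nrow(records),
                 anchor = anchor),
            class = "lag_profile")
}

#' @export
#' @method print lag_profile
print.lag_profile <- function(x, ...) {
  cat("Lagged-window correlation profile:", x$species,
      sprintf("(n = %d)\n", x$n))
  print(round(stats::setNames(x$corr_by_window,
                              paste0("w", seq_along(x$corr_by_window))), 3))
  invisible(x)
}

#' Choose the temperature-averaging window for a species
#'
#' Under \code{policy = "standard"} every species gets the 4-month window
#' ending at each specimen's own flowering month, except species whose
#' reference flowering month is April, which get the fixed February--April
#' calendar window (January temperatures correlate poorly with April
#' flowering). Under \code{policy = "empirical_max"} the window length is the
#' argmax of |correlation| over the screened lengths, ties broken toward the
#' shorter window. \code{policy = "fixed_reference"} anchors every species'
#' window at its reference flowering month as a fixed calendar window (the
#' same lengths as \code{standard}); this variant removes the dependence
#' of the covariate on each specimen's realised collection month.
#'
#' @param profile A \code{lag_profile} (may be \code{NULL} except for
#'   \code{empirical_max}).
#' @param ref_month The species' reference flowering month (see
#'   [reference_month()]).
#' @param policy Window policy.
#' @param species Species name (defaults to the profile's).
#' @return Object of class \code{window_spec}: list with \code{species},
#'   \code{n_months}, \code{anchor} ("specimen" or "fixed") and, for fixed
#'   anchors, \code{end_month} and the calendar \code{months}.
#' @export
select_window <- function(profile = NULL, ref_month,
                          policy = c("standard", "empirical_max",
                                     "fixed_reference"),
                          species = profile$species) {
  policy <- match.arg(policy)
  fixed_spec <- function(end_month, n_months) {
    list(species = species, n_months = as.integer(n_months),
         anchor = "fixed", end_month = as.integer(end_month),
         months = (end_month - n_months + 1):end_month)
  }
  if (policy == "standard") {
    spec <- if (ref_month == 4L) fixed_spec(4L, 3L) else {
      list(species = species, n_months = 4L, anchor = "specimen",
           end_month = NULL, months = NULL)
    }
  } else if (policy == "fixed_reference") {
    spec <- if (ref_month == 4L) fixed_spec(4L, 3L) else
      fixed_spec(ref_month, 4L)
  } else {
    if (is.null(profile)) stop("empirical_max policy needs a lag profile")
    ac <- abs(profile$corr_by_window)
    if (all(is.na(ac))) stop("no defined correlations in profile")
    w <- which.max(ac)  # which.max returns the first (smallest w) tie
    spec <- list(species = species, n_months = as.integer(w),
                 anchor = "specimen", end_month = NULL, months = NULL)
  }
  structure(spec, class = "window_spec")
}

#' @export
#' @method print window_spec
print.window_spec <- function(x, ...) {
  if (x$anchor == "fixed") {
    m <- (x$months - 1) %% 12 + 1
    cat(sprintf("Window for %s: fixed calendar months %s\n", x$species,
                paste(month.abb[m], collapse = "-")))
  } else {
    cat(sprintf("Window for %s: %d months ending at each specimen's month\n",
                x$species, x$n_months))
  }
  invisible(x)
}

#' Cohort-level window screen
#'
#' Mirrors a study-level window decision: the screened window length is the
#' argmax over lengths of the mean absolute correlation across all species'
#' lag profiles (ties toward the shorter window). Single-species argmax
#' selection is noisy because adjacent window lengths share most of their
#' months; pooling the screen across species is how a single averaging period
#' is chosen for a whole analysis.
#'
#' @param profiles List of \code{lag_profile} objects.
#' @return List with \code{n_months} (the selected length) and
#'   \code{mean_abs_corr} (by window length).
#' @export
select_window_cohort <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  cm <- vapply(profiles, function(p) abs(p$corr_by_window),
               numeric(length(profiles[[1]]$corr_by_window)))
  mac <- rowMeans(cm, na.rm = TRUE)
  list(n_months = as.integer(which.max(mac)), mean_abs_corr = mac)
}
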