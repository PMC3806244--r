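#' Fit a species' phenological responsiveness
#'
#' Ordinary least squares of peak-flowering day-of-year on the windowed mean
#' temperature, each specimen paired with the temperature for its own year and
#' climate division of collection. The slope is the phenological
#' responsiveness rho, in days per degree Celsius; negative values mean
#' earlier flowering in warmer conditions.
#'
#' @param records Specimen records of one species (deduplicated).
#' @param series \code{division_monthly} temperature table.
#' @param window A \code{window_spec} from [select_window()].
#' @param min_n Minimum specimens required for the regression.
#' @return Object of class \code{species_responsiveness}: list with
#'   \code{species}, \code{rho}, \code{se}, \code{p_value}, \code{intercept},
#'   \code{r_squared}, \code{n}, \code{window}, and \code{data} (a data frame
#'   with per-specimen \code{temp_c} and \code{doy}).
#' @export
fit_species <- function(records, series, window, min_n = 10) {
  sp <- unique(records$species)
  if (length(sp) != 1) stop("records must belong to a single species")
  if (nrow(records) < min_n) {
    stop(sp, ": ", nrow(records), " specimens; at least ", min_n, " required")
  }
  tw <- .specimen_window_temps(records, series,
                               n_months = window$n_months,
                               anchor = window$anchor,
                               end_month = window$end_month)
  if (stats::sd(tw) == 0) {
    stop(sp, ": windowed temperature has zero variance ",
         "(all specimens share one temperature value)")
  }
  fit <- stats::lm(doy ~ temp_c, data = data.frame(doy = records$doy,
                                                   temp_c = tw))
  sm <- summary(fit)
  co <- sm$coefficients
  structure(list(
    species = sp,
    rho = unname(co["temp_c", "Estimate"]),
    se = unname(co["temp_c", "Std. Error"]),
    p_value = unname(co["temp_c", "Pr(>|t|)"]),
    intercept = unname(co["(Intercept)", "Estimate"]),
    r_squared = sm$r.squared,
    n = nrow(records),
    window = window,
    data = data.frame(species = sp, temp_c = tw, doy = records$doy,
                      year = records$year, division = records$division,
                      stringsAsFactors = FALSE)
  ), class = "species_responsiveness")
}

#' @export
#' @method print species_responsiveness
print.species_responsiveness <- function(x, ...) {
  cat(sprintf("%s: rho = %.2f days/degC (SE %.2f, p = %.3g, n = %d, R2 = %.2f)\n",
              x$species, x$rho, x$se, x$p_value, x$n, x$r_squared))
  invisible(x)
}

#' @export
coef.species_responsiveness <- function(object, ...) {
  c(intercept = object$intercept, rho = object$rho)
}

#' Classify a species' response at a significance level
#'
#' @param resp A \code{species_responsiveness}.
#' @param alpha Two-sided significance level (default 0.05, uncorrected
#'   across species).
#' @return One of \code{"sig_negative"}, \code{"sig_positive"},
#'   \code{"nonsignificant"}.
#' @export
classify_response <- function(resp, alpha = 0.05) {
  if (resp$p_value <= alpha && resp$rho < 0) "sig_negative"
  else if (resp$p_value <= alpha && resp$rho > 0) "sig_positive"
  else "nonsignificant"
}

#' Fit responsiveness for every eligible species
#'
#' Runs the window policy and the per-species regression across a whole
#' specimen set. With the default policy no correlation screen is needed;
#' under \code{"empirical_max"} the 12-lag screen is run per species first.
#'
#' @param records Validated, deduplicated, eligibility-filtered specimen
#'   records (several species).
#' @param series \code{division_monthly} temperature table.
#' @param policy Window policy (see [select_window()]).
#' @param alpha Significance level for classification.
#' @param min_n Minimum specimens per species.
#' @param fdr Apply Benjamini-Hochberg adjustment to the per-species p-values
#'   before classification (off by default; per-species significance is
#'   conventionally reported uncorrected).
#' @return Object of class \code{responsiveness_set}: data frame with one row
#'   per species (\code{species}, \code{rho}, \code{se}, \code{p},
#'   \code{intercept}, \code{r_squared}, \code{n}, \code{window_len},
#'   \code{anchor}, \code{class}); the individual fits are attached as the
#'   \code{"fits"} attribute.
#' @export
fit_all_species <- function(records, series,
                            policy = c("standard", "empirical_max",
                                       "fixed_reference"),
                            alpha = 0.05, min_n = 10, fdr = FALSE) {
  policy <- match.arg(policy)
  ref <- reference_month(records)
  by_sp <- split(records, records$species)
  fits <- lapply(names(by_sp), function(sp) {
    prof <- if (policy == "empirical_max") {
      lag_correlation_profile(by_sp[[sp]], series)
    } else NULL
    win <- select_window(prof, ref_month = ref[[sp]], policy = policy,
                         species = sp)
    fit_species(by_sp[[sp]], series, win, min_n = min_n)
  })
  names(fits) <- names(by_sp)
  out <- data.frame(
    species = names(by_sp),
    rho = vapply(fits, `[[`, 0, "rho"),
    se = vapply(fits, `[[`, 0, "se"),
    p = vapply(fits, `[[`, 0, "p_value"),
    intercept = vapply(fits, `[[`, 0, "intercept"),
    r_squared = vapply(fits, `[[`, 0, "r_squared"),
    n = vapply(fits, function(f) as.integer(f$n), 0L),
    window_len = vapply(fits, function(f) f$window$n_months, 0L),
    anchor = vapply(fits, function(f) f$window$anchor, ""),
    stringsAsFactors = FALSE
  )
  p_cls <- if (fdr) stats::p.adjust(out$p, method = "BH") else out$p
  out$class <- ifelse(p_cls <= alpha & out$rho < 0, "sig_negative",
               ifelse(p_cls <= alpha & out$rho > 0, "sig_positive",
                      "nonsignificant"))
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  class(out) <- c("responsiveness_set", "data.frame")
  out
}

#' Summarise responsiveness across species
#'
#' @param set A \code{responsiveness_set} from [fit_all_species()].
#' @param alpha Significance level.
#' @return Object of class \code{responsiveness_summary}: list with
#'   \code{n_species}, \code{n_sig_negative}, \code{n_sig_positive},
#'   \code{mean_rho_all}, \code{mean_rho_sig_negative} (NA when no species is
#'   significantly negative), and \code{rank_order} (species sorted by rho
#'   ascending, ties by name).
#' @export
summarise_responsiveness <- function(set, alpha = 0.05) {
  sig_neg <- set$p <= alpha & set$rho < 0
  sig_pos <- set$p <= alpha & set$rho > 0
  ord <- order(set$rho, set$species)
  structure(list(
    n_species = nrow(set),
    n_sig_negative = sum(sig_neg),
    n_sig_positive = sum(sig_pos),
    mean_rho_all = mean(set$rho),
    mean_rho_sig_negative = if (any(sig_neg)) mean(set$rho[sig_neg]) else NA_real_,
    rank_order = set$species[ord],
    alpha = alpha
  ), class = "responsiveness_summary")
}

#' @export
#' @method print responsiveness_summary
print.responsiveness_summary <- function(x, ...) {
  cat(sprintf("Phenological responsiveness, %d species\n", x$n_species))
  cat(sprintf("  significant negative (p <= %.2f): %d (%.0f%%)\n", x$alpha,
              x$n_sig_negative, 100 * x$n_sig_negative / x$n_species))
  cat(sprintf("  significant positive: %d\n", x$n_sig_positive))
  cat(sprintf("  mean rho, all species: %.2f days/degC\n", x$mean_rho_all))
  if (!is.na(x$mean_rho_sig_negative)) {
    cat(sprintf("  mean rho, significant negative: %.2f days/degC\n",
                x$mean_rho_sig_negative))
  }
  invisible(x)
}

#' Rank-order plot of species responsiveness
#'
#' Species ordered by rho with standard-error bars; filled points mark
#' responses significant at \code{alpha}.
#'
#' @param x A \code{responsiveness_set}.
#' @param alpha Significance level for point fill.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.responsiveness_set <- function(x, alpha = 0.05, ...) {
  ord <- order(x$rho, x$species)
  rho <- x$rho[ord]; se <- x$se[ord]; sig <- x$p[ord] <= alpha
  idx <- seq_along(rho)
  graphics::plot(idx, rho, pch = ifelse(sig, 16, 1),
                 ylim = range(rho - se, rho + se),
                 xlab = "Species rank", ylab = "rho (days/degC)", ...)
  graphics::segments(idx, rho - se, idx, rho + se)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}

#' @export
#' @method summary responsiveness_set
summary.responsiveness_set <- function(object, alpha = 0.05, ...) {
  summarise_responsiveness(object, alpha = alpha)
}

#' Predicted flowering day of year at given temperatures
#'
#' @param object A \code{species_responsiveness}.
#' @param newdata Optional data frame with a \code{temp_c} column; defaults
#'   to the fitted temperatures.
#' @param ... Unused.
#' @return Numeric vector of predicted days of year.
#' @export
predict.species_responsiveness <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$data$temp_c else newdata$temp_c
  object$intercept + object$rho * t
}

#' @export
#' @method residuals species_responsiveness
residuals.species_responsiveness <- function(object, ...) {
  object$data$doy - predict(object)
}

#' @export
#' @method plot species_responsiveness
plot.species_responsiveness <- function(x, ...) {
  graphics::plot(x$data$temp_c, x$data$doy,
                 xlab = "Windowed mean temperature (degC)",
                 ylab = "Flowering day of year", main = x$species, ...)
  graphics::abline(x$intercept, x$rho, col = "red")
  invisible(x)
}
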