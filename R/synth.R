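#' Scenario configuration for the synthetic-data generator
#'
#' Defaults mirror the study design the analysis targets: 10 climate
#' divisions observed 1895--2009 with a handful of stations each (one
#' division single-station), a temperate-continental monthly climatology with
#' a 0.9 degC warming over the record, 141 species totalling roughly 5000
#' specimens (10--235 per species), flowering day-of-year driven by the
#' 4-month windowed division temperature with a 7-day residual, and
#' season-level mean responsiveness of -2.5 (spring), -1.4 (early summer) and
#' -0.6 (late summer) days per degC.
#'
#' @param n_divisions Number of climate divisions.
#' @param stations_per_division Integer vector of station counts per division
#'   (recycled); default gives one single-station division and 2--4 elsewhere.
#' @param years Calendar years covered by the station record.
#' @param climatology Twelve monthly mean temperatures, degC (Jan--Dec).
#' @param warming_total_c Total linear warming over the record span, degC;
#'   scalar or per-division vector.
#' @param monthly_anomaly_sd SD of the shared per-division month anomaly,
#'   degC.
#' @param station_noise_sd SD of independent per-station noise, degC.
#' @param n_species Number of species.
#' @param mean_extra_specimens Mean of the (exponential) surplus above the
#'   10-specimen floor; default tuned so the default scenario totals about
#'   5000 specimens with a 10--235 range.
#' @param max_specimens Cap on specimens per species.
#' @param season_probs Probabilities of spring / early summer / late summer.
#' @param group_means Named true mean responsiveness per season, days/degC.
#' @param between_species_sd SD of species deviations around their season
#'   mean, days/degC.
#' @param residual_doy_sd Residual SD of flowering day-of-year, days.
#' @param true_window_months Window length generating the signal (the
#'   standard-policy April special case is honoured).
#' @param duplicate_rate Fraction of specimen records duplicated verbatim.
#' @param nonpeak_rate Fraction of extra non-peak-flowering rows injected.
#' @param lambda_true Phylogenetic signal of the species deviations (0 = iid).
#' @param tree Optional user-supplied \code{phylo} tree (tips must be the
#'   generated species names); by default a birth--death tree is simulated.
#' @param birth,death Birth--death rates for the simulated tree.
#' @param division_slope_sd SD of division-level random slopes, days/degC
#'   (0 = no division heterogeneity, the default).
#' @param seed Integer seed; everything is reproducible from it.
#' @return A list of class \code{scenario_config}.
#' @export
scenario_config <- function(n_divisions = 10,
                            stations_per_division = NULL,
                            years = 1895:2009,
                            climatology = c(-3.1, -1.9, 3.4, 9.4, 15.3, 20.2,
                                            22.3, 21.5, 18.0, 11.6, 5.3, -0.6),
                            warming_total_c = 0.9,
                            monthly_anomaly_sd = 2.0,
                            station_noise_sd = 0.5,
                            n_species = 141,
                            mean_extra_specimens = 26,
                            max_specimens = 235,
                            season_probs = c(spring = 0.40,
                                             early_summer = 0.32,
                                             late_summer = 0.28),
                            group_means = c(spring = -2.5,
                                            early_summer = -1.4,
                                            late_summer = -0.6),
                            between_species_sd = 1.5,
                            residual_doy_sd = 7,
                            true_window_months = 4,
                            duplicate_rate = 0.05,
                            nonpeak_rate = 0.05,
                            lambda_true = 0,
                            tree = NULL,
                            birth = 1, death = 0,
                            division_slope_sd = 0,
                            seed = 1) {
  stopifnot(length(climatology) == 12,
            monthly_anomaly_sd >= 0, station_noise_sd >= 0,
            residual_doy_sd >= 0, between_species_sd >= 0,
            duplicate_rate >= 0, duplicate_rate <= 1,
            nonpeak_rate >= 0, nonpeak_rate <= 1,
            lambda_true >= 0, lambda_true <= 1,
            true_window_months >= 1, n_species >= 1)
  if (!all(names(group_means) %in% names(season_probs))) {
    stop("group_means must be named by the season levels in season_probs")
  }
  structure(as.list(environment()), class = "scenario_config")
}

# season -> candidate reference flowering months
.season_months_map <- list(spring = 4:5, early_summer = 6:7, late_summer = 8:9)

#' Generate a complete synthetic scenario with known ground truth
#'
#' Produces station temperatures, specimen and trait tables, a phylogeny, and
#' the ground truth behind them. Station temperatures are climatology plus a
#' linear warming trend plus a shared division-month anomaly plus independent
#' station noise. Each species gets a season, a reference flowering month, a
#' true responsiveness (its season mean plus a deviation, optionally
#' phylogenetically correlated via a lambda-scaled Brownian covariance of the
#' generated tree), and an intercept anchoring mean flowering at mid
#' reference month. Each specimen's flowering day-of-year is
#' intercept + rho * (windowed division mean temperature for its year and
#' division) + Normal(0, residual SD); its record date realises that day.
#' Duplicate rows and non-peak rows are then injected at the configured
#' rates.
#'
#' @param config A [scenario_config()].
#' @return List of class \code{scenario}: \code{stations}, \code{specimens},
#'   \code{traits}, \code{tree}, \code{truth} (list: species-level truth data
#'   frame, injected-row counts, true warming, lambda, window policy),
#'   \code{config}.
#' @export
generate_scenario <- function(config = scenario_config()) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  cf <- config

  ## stations
  n_div <- cf$n_divisions
  spd <- cf$stations_per_division
  if (is.null(spd)) {
    spd <- c(1L, sample(2:4, n_div - 1L, replace = TRUE))
  } else {
    spd <- rep_len(as.integer(spd), n_div)
  }
  warming <- rep_len(cf$warming_total_c, n_div)
  yrs <- cf$years
  span <- max(yrs) - min(yrs)
  n_y <- length(yrs)
  st_list <- vector("list", n_div)
  truth_div_anom <- vector("list", n_div)
  for (d in seq_len(n_div)) {
    anom <- matrix(stats::rnorm(n_y * 12, 0, cf$monthly_anomaly_sd),
                   nrow = n_y)  # shared across the division's stations
    truth_div_anom[[d]] <- anom
    base <- outer(yrs - min(yrs), rep(1, 12)) / span * warming[d] +
      outer(rep(1, n_y), cf$climatology) + anom
    st <- lapply(seq_len(spd[d]), function(s) {
      data.frame(
        station_id = sprintf("ST%02d%02d", d, s),
        division = d,
        year = rep(yrs, each = 12),
        month = rep(1:12, times = n_y),
        temp_c = as.vector(t(base)) +
          stats::rnorm(n_y * 12, 0, cf$station_noise_sd)
      )
    })
    st_list[[d]] <- do.call(rbind, st)
  }
  stations <- do.call(rbind, st_list)
  rownames(stations) <- NULL

  ## species, traits, tree
  n_sp <- cf$n_species
  species <- sprintf("Species_%03d", seq_len(n_sp))
  season <- sample(names(cf$season_probs), n_sp, replace = TRUE,
                   prob = cf$season_probs)
  # every season level used by group_means must be realised
  if (n_sp >= length(cf$group_means)) {
    for (sl in names(cf$group_means)) {
      if (!sl %in% season) season[sample.int(n_sp, 1)] <- sl
    }
  }
  ref_month <- vapply(season, function(s) {
    ms <- .season_months_map[[s]]
    ms[sample.int(length(ms), 1)]
  }, integer(1))
  growth_form <- sample(c("woody_perennial", "herbaceous_perennial",
                          "herbaceous_annual", "perennial_vine"),
                        n_sp, replace = TRUE,
                        prob = c(0.25, 0.45, 0.25, 0.05))
  pollination <- sample(c("wind", "insect_facultative", "insect_obligate",
                          "unknown"),
                        n_sp, replace = TRUE, prob = c(0.2, 0.3, 0.3, 0.2))
  origin <- sample(c("native", "introduced"), n_sp, replace = TRUE,
                   prob = c(0.7, 0.3))
  traits <- data.frame(species = species, season = season,
                       growth_form = growth_form, pollination = pollination,
                       origin = origin, stringsAsFactors = FALSE)

  tree <- cf$tree
  if (is.null(tree)) {
    tree <- ape::rphylo(n_sp, birth = cf$birth, death = cf$death)
    tree$tip.label <- sample(species)  # random tip assignment
    depth <- max(ape::node.depth.edgelength(tree))
    tree$edge.length <- tree$edge.length / depth  # unit depth
  } else if (!all(species %in% tree$tip.label)) {
    stop("user tree must contain every generated species as a tip")
  }

  group_mean_x <- unname(cf$group_means[season])
  if (anyNA(group_mean_x)) {
    stop("season level(s) missing from group_means: ",
         paste(setdiff(unique(season), names(cf$group_means)), collapse = ", "))
  }
  if (cf$lambda_true > 0) {
    C <- brownian_covariance(tree, species_order = species)
    C <- C / mean(diag(C))
    Vl <- lambda_transform(C, cf$lambda_true)
    dev <- unname(drop(crossprod(chol(Vl), stats::rnorm(n_sp)))) *
      cf$between_species_sd
  } else {
    dev <- stats::rnorm(n_sp, 0, cf$between_species_sd)
  }
  rho_true <- group_mean_x + dev

  ## per-division true slope deviations (spatial heterogeneity; default off)
  div_slope_dev <- stats::rnorm(n_div, 0, cf$division_slope_sd)

  ## specimens
  divser <- aggregate_division_monthly(stations)
  lk <- .division_temp_matrix(divser)
  n_extra <- pmin(cf$max_specimens - 10L,
                  round(stats::rexp(n_sp, 1 / cf$mean_extra_specimens)))
  n_i <- 10L + as.integer(n_extra)
  w <- cf$true_window_months
  # expected window temperature from climatology, for intercept anchoring
  clim_window <- function(end_m, n_m) {
    mean(cf$climatology[((end_m - n_m + 1):end_m - 1) %% 12 + 1])
  }
  mid_doy <- function(m) day_of_year(as.Date(sprintf("2001-%02d-15", m)))

  rows <- vector("list", n_sp)
  for (x in seq_len(n_sp)) {
    n_x <- n_i[x]
    yr <- sample(yrs[-1], n_x, replace = TRUE)  # leave room for window wrap
    dv <- sample.int(n_div, n_x, replace = TRUE)
    m_ref <- ref_month[x]
    if (m_ref == 4L) {                 # fixed Feb--Apr window, April species
      end_idx <- (yr - lk$first_year) * 12L + 4L
      n_m <- 3L
    } else {
      end_idx <- (yr - lk$first_year) * 12L + m_ref
      n_m <- w
    }
    tw <- numeric(n_x)
    for (off in 0:(n_m - 1L)) {
      tw <- tw + lk$mat[cbind(dv, end_idx - off)]
    }
    tw <- tw / n_m
    a_x <- mid_doy(m_ref) - (rho_true[x]) *
      clim_window(if (m_ref == 4L) 4L else m_ref, n_m)
    rho_eff <- rho_true[x] + div_slope_dev[dv]
    doy <- a_x + rho_eff * tw + stats::rnorm(n_x, 0, cf$residual_doy_sd)
    doy <- pmax(1, pmin(364, round(doy)))
    date <- as.Date(sprintf("%d-01-01", yr)) + (doy - 1)
    rows[[x]] <- data.frame(
      species = species[x],
      date = format(date, "%Y-%m-%d"),
      division = dv,
      collector = sprintf("collector_%02d", sample.int(40, n_x, replace = TRUE)),
      peak_flowering = TRUE,
      intercept_true = a_x,
      stringsAsFactors = FALSE
    )
  }
  specimens <- do.call(rbind, rows)
  intercepts <- vapply(rows, function(r) r$intercept_true[1], 0)
  specimens$intercept_true <- NULL
  rownames(specimens) <- NULL

  # keep original (species, date, division, collector) keys unique so the
  # dedupe stage removes exactly the injected duplicates
  key <- paste(specimens$species, specimens$date, specimens$division,
               specimens$collector)
  while (any(dup <- duplicated(key))) {
    i <- which(dup)
    cur <- as.integer(sub("collector_", "", specimens$collector[i]))
    specimens$collector[i] <- sprintf("collector_%02d", cur %% 40 + 1)
    key <- paste(specimens$species, specimens$date, specimens$division,
                 specimens$collector)
  }
  n_original <- nrow(specimens)

  n_dup <- floor(cf$duplicate_rate * n_original)
  if (n_dup > 0) {
    di <- sample.int(n_original, n_dup)
    specimens <- rbind(specimens, specimens[di, , drop = FALSE])
  }
  n_nonpeak <- floor(cf$nonpeak_rate * n_original)
  if (n_nonpeak > 0) {
    ni <- sample.int(n_original, n_nonpeak)
    np <- specimens[ni, , drop = FALSE]
    np$date <- format(as.Date(np$date) +
                        sample(c(-14:-7, 7:14), n_nonpeak, replace = TRUE),
                      "%Y-%m-%d")
    np$peak_flowering <- FALSE
    specimens <- rbind(specimens, np)
  }
  specimens <- specimens[sample.int(nrow(specimens)), , drop = FALSE]
  rownames(specimens) <- NULL

  truth <- list(
    species = data.frame(species = species, season = season,
                         ref_month = as.integer(unname(ref_month)),
                         rho_true = rho_true, intercept_true = intercepts,
                         growth_form = growth_form, pollination = pollination,
                         origin = origin, n_specimens = n_i,
                         stringsAsFactors = FALSE),
    group_means = cf$group_means,
    warming_total_c = warming,
    division_slope_dev = div_slope_dev,
    lambda_true = cf$lambda_true,
    true_window_months = cf$true_window_months,
    n_original = n_original,
    n_duplicates_injected = n_dup,
    n_nonpeak_injected = n_nonpeak
  )
  structure(list(stations = stations, specimens = specimens, traits = traits,
                 tree = tree, truth = truth, config = config),
            class = "scenario")
}

#' @export
#' @method print scenario
print.scenario <- function(x, ...) {
  cat(sprintf(
    "Synthetic scenario: %d species, %d specimen rows (%d original, %d dup, %d non-peak),\n  %d divisions x %d years, seed %d\n",
    nrow(x$truth$species), nrow(x$specimens), x$truth$n_original,
    x$truth$n_duplicates_injected, x$truth$n_nonpeak_injected,
    x$config$n_divisions, length(x$config$years), x$config$seed))
  invisible(x)
}

#' Write a scenario to disk in the formats the analysis reads
#'
#' @param scenario A \code{scenario} from [generate_scenario()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the named vector of written paths.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(stations = file.path(dir, "stations.csv"),
             specimens = file.path(dir, "specimens.csv"),
             traits = file.path(dir, "traits.csv"),
             tree = file.path(dir, "tree.nwk"),
             truth = file.path(dir, "truth_species.csv"))
  utils::write.csv(scenario$stations, paths["stations"], row.names = FALSE)
  utils::write.csv(scenario$specimens, paths["specimens"], row.names = FALSE)
  utils::write.csv(scenario$traits, paths["traits"], row.names = FALSE)
  ape::write.tree(scenario$tree, paths["tree"])
  utils::write.csv(scenario$truth$species, paths["truth"], row.names = FALSE)
  invisible(paths)
}

#' Recovery metrics of a pipeline run against generator ground truth
#'
#' @param truth The \code{truth} element of a \code{scenario}.
#' @param set A \code{responsiveness_set} fitted on the scenario's data.
#' @param group_fit Optional \code{pheno_group_model} fitted by season.
#' @param lambda_prof Optional \code{lambda_profile}.
#' @return List of class \code{truth_report}: per-species \code{bias},
#'   \code{rmse}, \code{ci_coverage} (nominal 95\%), \code{window_recovery}
#'   (fraction of species fitted at the true window length), and, when
#'   supplied, \code{group_slope_error} and \code{lambda_error}.
#' @export
truth_report <- function(truth, set, group_fit = NULL, lambda_prof = NULL) {
  m <- merge(set, truth$species[, c("species", "rho_true", "season",
                                    "ref_month")], by = "species")
  if (nrow(m) == 0) stop("no species in common between truth and fits")
  err <- m$rho - m$rho_true
  tq <- stats::qt(0.975, df = m$n - 2)
  out <- list(
    n_species = nrow(m),
    bias = mean(err),
    rmse = sqrt(mean(err^2)),
    ci_coverage = mean(abs(err) <= tq * m$se),
    window_recovery = mean(m$window_len ==
                             ifelse(m$ref_month == 4, 3,
                                    truth$true_window_months))
  )
  if (!is.null(group_fit)) {
    gs <- group_fit$group_slopes
    tr <- truth$group_means[gs$group]
    out$group_slope_error <- stats::setNames(gs$slope - unname(tr), gs$group)
  }
  if (!is.null(lambda_prof)) {
    out$lambda_error <- lambda_prof$lambda_ml - truth$lambda_true
  }
  structure(out, class = "truth_report")
}

#' @export
#' @method print truth_report
print.truth_report <- function(x, ...) {
  cat(sprintf("Recovery report, %d species\n", x$n_species))
  cat(sprintf("  rho bias %.3f, RMSE %.3f days/degC; 95%% CI coverage %.3f\n",
              x$bias, x$rmse, x$ci_coverage))
  cat(sprintf("  window recovery: %.2f\n", x$window_recovery))
  if (!is.null(x$group_slope_error)) {
    cat("  group slope errors:",
        paste(sprintf("%s %.2f", names(x$group_slope_error),
                      x$group_slope_error), collapse = ", "), "\n")
  }
  if (!is.null(x$lambda_error)) {
    cat(sprintf("  lambda error: %.3f\n", x$lambda_error))
  }
  invisible(x)
}
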