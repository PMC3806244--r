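test_that("generation is deterministic given the seed", {
  a <- small_scenario(seed = 5)
  b <- small_scenario(seed = 5)
  expect_identical(a$stations, b$stations)
  expect_identical(a$specimens, b$specimens)
  expect_identical(a$traits, b$traits)
  expect_identical(ape::write.tree(a$tree), ape::write.tree(b$tree))
  expect_identical(a$truth$species, b$truth$species)

  c <- small_scenario(seed = 6)
  expect_false(identical(a$specimens, c$specimens))
})

test_that("a written scenario round-trips losslessly through the readers", {
  scn <- small_scenario(seed = 12)
  dir <- withr::local_tempdir()
  paths <- write_scenario(scn, dir)
  st <- read_station_table(paths["stations"])
  expect_equal(st$temp_c, scn$stations$temp_c)
  expect_identical(st$division, as.integer(scn$stations$division))
  sp <- read_specimen_table(paths["specimens"])
  expect_equal(nrow(sp), nrow(scn$specimens))
  tr <- read_trait_table(paths["traits"])
  expect_identical(tr$species, scn$traits$species)
  tw <- ape::read.tree(paths["tree"])
  expect_identical(sort(tw$tip.label), sort(scn$tree$tip.label))
})

test_that("filtering and deduplication recover the pre-injection record count", {
  scn <- generate_scenario(scenario_config(
    n_species = 25, n_divisions = 4, stations_per_division = 2,
    years = 1970:2009, duplicate_rate = 0.08, nonpeak_rate = 0.06, seed = 13))
  recs <- suppressMessages(filter_specimens(scn$specimens))
  expect_equal(nrow(recs),
               scn$truth$n_original + scn$truth$n_duplicates_injected)
  dd <- suppressMessages(dedupe_specimens(recs))
  expect_equal(nrow(dd), scn$truth$n_original)
  expect_equal(attr(dd, "n_removed"), scn$truth$n_duplicates_injected)
})

test_that("the noise-free limit is recovered up to calendar-date rounding", {
  scn <- generate_scenario(scenario_config(
    n_species = 10, n_divisions = 3, stations_per_division = 2,
    years = 1990:2009, residual_doy_sd = 0, station_noise_sd = 0,
    duplicate_rate = 0, nonpeak_rate = 0, seed = 14))
  st <- run_specimen_stages(scn)
  set <- fit_all_species(st$records, st$divser, policy = "fixed_reference")
  m <- merge(set, scn$truth$species, by = "species")
  # the generated flowering day is rounded to a calendar date, so slopes
  # recover to the rounding scale rather than machine precision
  expect_lt(max(abs(m$rho - m$rho_true)), 0.15)

  # the date pathway is exact up to that rounding
  fits <- attr(set, "fits")
  for (sp in set$species) {
    tt <- scn$truth$species[scn$truth$species$species == sp, ]
    d <- fits[[sp]]$data
    exact <- tt$intercept_true + tt$rho_true * d$temp_c
    expect_lt(max(abs(d$doy - exact)), 0.5 + 1e-9)  # date rounding only
  }
})

test_that("the default scenario matches the target study dimensions", {
  scn <- generate_scenario(scenario_config(seed = 15))
  tt <- scn$truth$species
  expect_equal(nrow(tt), 141)
  expect_true(all(tt$n_specimens >= 10 & tt$n_specimens <= 235))
  # total specimen count lands near the ~5000-sheet study scale
  expect_gt(scn$truth$n_original, 3500)
  expect_lt(scn$truth$n_original, 6500)
  expect_equal(length(unique(scn$stations$division)), 10)
  expect_equal(sort(unique(scn$specimens$peak_flowering)),
               c(FALSE, TRUE))
})

test_that("species deviations converge to the configured group means", {
  scn <- generate_scenario(scenario_config(
    n_species = 1000, mean_extra_specimens = 0.01, n_divisions = 2,
    stations_per_division = 1, years = 2000:2009,
    duplicate_rate = 0, nonpeak_rate = 0, seed = 16))
  tt <- scn$truth$species
  for (s in names(scn$config$group_means)) {
    mu <- mean(tt$rho_true[tt$season == s])
    n_s <- sum(tt$season == s)
    expect_lt(abs(mu - scn$config$group_means[[s]]),
              4 * scn$config$between_species_sd / sqrt(n_s))
  }
})

test_that("phylogenetic deviations honour the requested lambda", {
  scn <- generate_scenario(scenario_config(
    n_species = 80, mean_extra_specimens = 0.01, n_divisions = 2,
    stations_per_division = 1, years = 2000:2009, lambda_true = 1,
    group_means = c(spring = 0, early_summer = 0, late_summer = 0),
    duplicate_rate = 0, nonpeak_rate = 0, seed = 17))
  rho <- stats::setNames(scn$truth$species$rho_true,
                         scn$truth$species$species)
  p <- profile_lambda(rho, scn$tree, grid_step = 0.01)
  expect_gt(p$lambda_ml, 0.6)
})

test_that("truth_report computes recovery metrics against ground truth", {
  scn <- small_scenario(seed = 18)
  st <- run_specimen_stages(scn)
  set <- fit_all_species(st$records, st$divser, policy = "fixed_reference")
  tr <- truth_report(scn$truth, set)
  expect_equal(tr$n_species, nrow(set))
  expect_lt(abs(tr$bias), 1.5)
  expect_equal(tr$window_recovery, 1)
  expect_true(tr$ci_coverage >= 0 && tr$ci_coverage <= 1)
})

test_that("inconsistent configurations are rejected", {
  expect_error(scenario_config(duplicate_rate = 1.5))
  expect_error(scenario_config(residual_doy_sd = -1))
  expect_error(
    generate_scenario(scenario_config(
      n_species = 8, group_means = c(spring = -2),
      season_probs = c(spring = 1), seed = 1)),
    NA)  # single-season config is legitimate
  expect_error(scenario_config(group_means = c(winter = -2)),
               "named by the season levels")
})

test_that("per-specimen anchoring carries a positive month-crossing bias the fixed anchor removes", {
  scn <- generate_scenario(scenario_config(n_species = 30, seed = 7))
  st <- run_specimen_stages(scn)
  bias_of <- function(policy) {
    set <- fit_all_species(st$records, st$divser, policy = policy)
    truth_report(scn$truth, set)$bias
  }
  expect_gt(bias_of("standard"), 1)       # seasonal-cycle leakage
  expect_lt(abs(bias_of("fixed_reference")), 0.5)
})
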