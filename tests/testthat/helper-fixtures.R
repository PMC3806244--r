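# Shared builders for small in-code fixtures.

# Station table with one row per (station, year, month) from a function
# temp_fun(division, year, month) plus optional iid noise.
make_stations <- function(divisions = 1:2, stations_per_div = 2,
                          years = 2000:2004, months = 1:12,
                          temp_fun = function(d, y, m) 10, noise_sd = 0) {
  grid <- expand.grid(station = seq_len(stations_per_div),
                      division = divisions, year = years, month = months)
  data.frame(
    station_id = sprintf("S%d_%d", grid$division, grid$station),
    division = grid$division,
    year = grid$year,
    month = grid$month,
    temp_c = mapply(temp_fun, grid$division, grid$year, grid$month) +
      stats::rnorm(nrow(grid), 0, noise_sd)
  )
}

# Division series (bypassing stations) with an explicit temperature function.
make_division_series <- function(divisions = 1, years = 2000:2004,
                                 months = 1:12,
                                 temp_fun = function(d, y, m) 10) {
  grid <- expand.grid(division = divisions, year = years, month = months)
  out <- data.frame(
    division = grid$division, year = grid$year, month = grid$month,
    mean_temp_c = mapply(temp_fun, grid$division, grid$year, grid$month),
    n_stations = 1L
  )
  out <- out[order(out$division, out$year, out$month), ]
  rownames(out) <- NULL
  class(out) <- c("division_monthly", "data.frame")
  out
}

# Specimen records data frame in validated (post filter_specimens) form.
make_records <- function(species, year, month, day = 15, division = 1,
                         collector = "c1", doy = NULL) {
  date <- as.Date(sprintf("%d-%02d-%02d", year, month, day))
  n <- length(date)
  out <- data.frame(
    species = rep_len(species, n), date = date,
    year = as.integer(format(date, "%Y")),
    month = as.integer(format(date, "%m")),
    doy = if (is.null(doy)) day_of_year(date) else doy,
    division = rep_len(division, n),
    collector = rep_len(collector, n),
    stringsAsFactors = FALSE
  )
  out
}

# Small default scenario used by several test files.
small_scenario <- function(seed = 42, ...) {
  generate_scenario(scenario_config(
    n_species = 15, n_divisions = 3, stations_per_division = 2,
    years = 1980:2009, seed = seed, ...))
}

run_specimen_stages <- function(scn, min_n = 10) {
  divser <- aggregate_division_monthly(scn$stations)
  recs <- suppressMessages(filter_specimens(scn$specimens,
                                            divisions = unique(divser$division)))
  recs <- suppressMessages(dedupe_specimens(recs))
  list(divser = divser, records = species_eligible(recs, min_n = min_n))
}
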