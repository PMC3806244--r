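# Direct simulator for specimen-level mixed-model data: species intercepts
# and slopes drawn around group means, iid temperature covariate.
sim_group_data <- function(n_per_group = 15, n_i = 20,
                           group_slopes = c(A = -2.5, B = -0.6),
                           sd_int = 10, sd_slope = 1, sd_resid = 7,
                           temp_sd = 1.5, seed = 1) {
  set.seed(seed)
  n_sp <- n_per_group * length(group_slopes)
  grp <- rep(names(group_slopes), each = n_per_group)
  a <- rnorm(n_sp, 150, sd_int)
  b <- group_slopes[grp] + rnorm(n_sp, 0, sd_slope)
  sp <- rep(seq_len(n_sp), each = n_i)
  tc <- rnorm(n_sp * n_i, 10, temp_sd)
  data.frame(
    species = sprintf("sp%03d", sp),
    temp_c = tc,
    doy = a[sp] + b[sp] * tc + rnorm(n_sp * n_i, 0, sd_resid),
    year = 2000L,
    division = rep(rep(1:2, length.out = n_i), n_sp),
    season = grp[sp],
    stringsAsFactors = FALSE
  )
}

test_that("group slopes are recovered within two standard errors", {
  truth <- c(A = -2.5, B = -0.6)
  d <- sim_group_data(group_slopes = truth, seed = 101)
  gm <- suppressWarnings(fit_group_model(d, "season", ref_level = "A"))
  gs <- gm$group_slopes
  expect_equal(gs$group, c("A", "B"))
  for (i in 1:2) {
    expect_lt(abs(gs$slope[i] - truth[gs$group[i]]), 2 * gs$se[i])
  }
  # reference-level slope is the base temperature coefficient
  expect_equal(unname(gs$slope[1]), unname(lme4::fixef(gm$fit)["tc"]),
               tolerance = 1e-10)
  # a strong contrast is detected
  expect_lt(gm$lr_tests$slope_B_vs_ref$p, 0.01)
  expect_gte(gm$lr_tests$interaction$LR, 0)
})

test_that("a single-species group is rejected as unidentifiable", {
  d <- sim_group_data(n_per_group = 5, seed = 3)
  d$season[d$species == "sp006"] <- "C"
  d$season[d$species %in% sprintf("sp%03d", 7:10)] <- "B"
  expect_error(suppressWarnings(fit_group_model(d, "season")),
               "single species")
})

test_that("records with missing or unknown group labels are excluded", {
  d <- sim_group_data(seed = 4)
  d$pollination <- ifelse(d$season == "A", "wind", "unknown")
  d$pollination[d$species %in% c("sp016", "sp017")] <- "insect_obligate"
  expect_message(
    gm <- suppressWarnings(fit_group_model(d, "pollination",
                                           ref_level = "wind")),
    "excluding"
  )
  expect_equal(sort(gm$group_slopes$group), c("insect_obligate", "wind"))
})

test_that("likelihood-ratio testing validates nesting and handles identity", {
  d <- sim_group_data(seed = 5)
  d$tc <- d$temp_c - mean(d$temp_c)
  full <- suppressWarnings(
    lme4::lmer(doy ~ tc * season + (1 + tc | species), d, REML = FALSE))
  red <- suppressWarnings(
    lme4::lmer(doy ~ tc + season + (1 + tc | species), d, REML = FALSE))

  lt <- lr_test_term(full, red)
  expect_gte(lt$LR, 0)
  expect_equal(lt$df, 1L)
  expect_true(lt$p >= 0 && lt$p <= 1)

  same <- lr_test_term(full, full)
  expect_equal(same$LR, 0)
  expect_equal(same$p, 1)

  expect_error(lr_test_term(red, full), "not nested")
  # REML inputs are refitted under ML before comparison
  full_reml <- suppressWarnings(
    lme4::lmer(doy ~ tc * season + (1 + tc | species), d, REML = TRUE))
  expect_equal(lr_test_term(full_reml, red)$LR, lt$LR, tolerance = 1e-6)
})

test_that("the full-model ML likelihood dominates its nested reductions", {
  d <- sim_group_data(seed = 6, n_per_group = 10, n_i = 12)
  d$tc <- d$temp_c - mean(d$temp_c)
  full <- suppressWarnings(
    lme4::lmer(doy ~ tc * season + (1 + tc | species), d, REML = FALSE))
  for (f in list(doy ~ tc + season + (1 + tc | species),
                 doy ~ tc + (1 + tc | species),
                 doy ~ 1 + (1 + tc | species))) {
    red <- suppressWarnings(lme4::lmer(f, d, REML = FALSE))
    expect_gte(as.numeric(stats::logLik(full)) + 1e-6,
               as.numeric(stats::logLik(red)))
  }
})

test_that("with random-effect variances forced to zero fixed effects equal pooled OLS", {
  d <- sim_group_data(sd_int = 3, sd_slope = 0.5, sd_resid = 5,
                      n_per_group = 10, n_i = 15, seed = 7)
  md <- data.frame(doy = d$doy, tc = d$temp_c - mean(d$temp_c),
                   grp = factor(d$season, levels = c("A", "B")),
                   species = factor(d$species))
  lf <- lme4::lFormula(doy ~ tc * grp + (1 + tc | species), md, REML = FALSE)
  devfun <- do.call(lme4::mkLmerDevfun, lf)
  devfun(c(0, 0, 0))          # evaluate the profiled deviance at theta = 0
  beta_zero <- environment(devfun)$pp$beta(1)
  ols <- stats::lm(doy ~ tc * grp, md)
  expect_equal(unname(beta_zero), unname(stats::coef(ols)), tolerance = 1e-6)
})

test_that("division robustness flags heterogeneity only when present", {
  d0 <- sim_group_data(seed = 8)
  dr0 <- suppressWarnings(division_robustness(d0, "season", ref_level = "A"))
  expect_lt(dr0$max_abs_change, 0.5)
  expect_true(all(dr0$division_varcomp$sdcor[
    dr0$division_varcomp$var1 %in% c("(Intercept)", "tc") &
      is.na(dr0$division_varcomp$var2)] < 1))

  # inject strong division slope heterogeneity
  d1 <- sim_group_data(seed = 9, n_per_group = 12, n_i = 24)
  dev <- c(`1` = 2.0, `2` = -2.0)
  d1$doy <- d1$doy + dev[as.character(d1$division)] * (d1$temp_c - 10)
  dr1 <- suppressWarnings(division_robustness(d1, "season", ref_level = "A"))
  sl <- dr1$division_varcomp$sdcor[dr1$division_varcomp$var1 == "tc" &
                                     is.na(dr1$division_varcomp$var2)]
  expect_gt(max(sl), 0.5)

  one <- d0[d0$division == 1, ]
  expect_error(division_robustness(one, "season"), "at least 2 divisions")
})
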