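#' Assemble specimen-level data for hierarchical group models
#'
#' Collects the per-specimen windowed temperatures computed during the
#' species-level fits and joins the trait table, producing the long-format
#' table the mixed models consume.
#'
#' @param set A \code{responsiveness_set} from [fit_all_species()].
#' @param traits Trait table (see [read_trait_table()]).
#' @return Data frame with one row per specimen: \code{species},
#'   \code{temp_c}, \code{doy}, \code{year}, \code{division} and the trait
#'   columns.
#' @export
responsiveness_model_data <- function(set, traits) {
  fits <- attr(set, "fits")
  if (is.null(fits)) stop("set carries no per-species fits")
  df <- do.call(rbind, lapply(fits, `[[`, "data"))
  rownames(df) <- NULL
  merge(df, traits, by = "species", sort = FALSE)
}

.n_fixed <- function(model) {
  if (inherits(model, "merMod")) length(lme4::fixef(model))
  else length(stats::coef(model))
}

.as_ml <- function(model) {
  if (inherits(model, "merMod") && lme4::isREML(model)) {
    lme4::refitML(model)
  } else model
}

#' Likelihood-ratio test between nested models
#'
#' Both models are (re)fitted under maximum likelihood; the statistic is twice
#' the log-likelihood difference, referred to a chi-squared distribution with
#' degrees of freedom equal to the difference in fixed-effect parameter
#' counts.
#'
#' @param full,reduced Fitted models (\code{merMod} or \code{lm}), the reduced
#'   model nested in the full one and fitted to the same data.
#' @param tol Tolerance for declaring a negative statistic an optimizer
#'   failure.
#' @return List with \code{LR}, \code{df}, \code{p}.
#' @export
lr_test_term <- function(full, reduced, tol = 1e-4) {
  full <- .as_ml(full); reduced <- .as_ml(reduced)
  if (stats::nobs(full) != stats::nobs(reduced)) {
    stop("models fitted to different numbers of observations; not nested")
  }
  df <- .n_fixed(full) - .n_fixed(reduced)
  lr <- 2 * (as.numeric(stats::logLik(full)) -
               as.numeric(stats::logLik(reduced)))
  if (df < 0) stop("reduced model is not nested in the full model ",
                   "(more fixed-effect parameters than the full one)")
  if (df == 0) {
    if (abs(lr) <= tol) return(list(LR = 0, df = 0L, p = 1))
    stop("models have equally many fixed-effect parameters but different ",
         "likelihoods; not nested")
  }
  if (lr < -tol) {
    stop(sprintf(
      "full-model log-likelihood below reduced (LR = %.4g); optimizer failure",
      lr))
  }
  lr <- max(lr, 0)
  list(LR = lr, df = df, p = stats::pchisq(lr, df = df, lower.tail = FALSE))
}

# Build the lmer formula. `slope_factor` names the factor interacting with
# temperature (collapsed copies give single-df slope contrasts).
.group_formula <- function(slope_factor, division_random, independent_re) {
  re_sp <- if (independent_re) "(1 + tc || species)" else "(1 + tc | species)"
  rhs <- paste0("tc + grp + tc:", slope_factor, " + ", re_sp)
  if (division_random) {
    re_dv <- if (independent_re) "(1 + tc || division)" else "(1 + tc | division)"
    rhs <- paste0(rhs, " + ", re_dv)
  }
  stats::as.formula(paste("doy ~", rhs))
}

.fit_lmer <- function(formula, data, reml) {
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(formula, data = data, REML = reml)
  ))
  conv <- fit@optinfo$conv$opt
  if (!is.null(conv) && conv != 0) {
    stop("mixed-model optimizer failed to converge: ",
         paste(unlist(fit@optinfo$message), collapse = "; "))
  }
  fit
}

#' Hierarchical comparison of responsiveness among functional groups
#'
#' Fits a linear mixed model of flowering day-of-year on windowed temperature
#' with a functional-group covariate on the slope
#' (\code{doy ~ temp * group}), species-level random intercepts and random
#' temperature slopes (unstructured covariance, falling back to independent
#' effects upon singularity), and optionally division-level random intercepts
#' and slopes. Reported effects come from the REML fit; significance comes
#' from maximum-likelihood likelihood-ratio tests: the overall
#' temperature-by-group interaction, and a single-df contrast of each
#' non-reference group's slope against the reference group's. Temperature is
#' centred before fitting (slopes unaffected).
#'
#' @param data Specimen-level data from [responsiveness_model_data()].
#' @param group_by Name of the trait column defining the groups.
#' @param ref_level Reference group (defaults to the first level
#'   alphabetically); its marginal slope is the base temperature coefficient.
#' @param division_random Also give divisions random intercepts and slopes.
#' @param subset_season Restrict to one flowering season before fitting
#'   (season-stratified analyses).
#' @param reml Use REML for the reported effects (LR tests always refit ML).
#' @return Object of class \code{pheno_group_model}: list with
#'   \code{group_slopes} (data frame: group, slope, se, n_species, and Wald
#'   cross-check p), \code{lr_tests} (named list of LR/df/p), \code{varcomp},
#'   \code{fit} (the REML \code{merMod}), \code{singular}, \code{n_excluded}.
#' @export
fit_group_model <- function(data, group_by, ref_level = NULL,
                            division_random = FALSE, subset_season = NULL,
                            reml = TRUE) {
  if (!group_by %in% names(data)) stop("no column `", group_by, "` in data")
  if (!is.null(subset_season)) {
    data <- data[data$season == subset_season, , drop = FALSE]
  }
  g <- as.character(data[[group_by]])
  drop <- is.na(g) | g == "unknown"
  if (any(drop)) {
    message("fit_group_model: excluding ", sum(drop),
            " specimen(s) with missing/unknown ", group_by)
    data <- data[!drop, , drop = FALSE]
    g <- g[!drop]
  }
  sp_per_group <- tapply(data$species, g, function(s) length(unique(s)))
  if (length(sp_per_group) < 2) stop("need at least 2 groups with data")
  if (any(sp_per_group < 2)) {
    stop("group(s) with a single species (cannot separate the species ",
         "random effect from the group fixed effect): ",
         paste(names(sp_per_group)[sp_per_group < 2], collapse = ", "))
  }
  levels_g <- sort(unique(g))
  if (is.null(ref_level)) ref_level <- levels_g[1]
  if (!ref_level %in% levels_g) stop("ref_level `", ref_level, "` not present")
  levels_g <- c(ref_level, setdiff(levels_g, ref_level))

  md <- data.frame(doy = data$doy,
                   tc = data$temp_c - mean(data$temp_c),
                   grp = factor(g, levels = levels_g),
                   species = factor(data$species),
                   division = factor(data$division))

  fit <- .fit_lmer(.group_formula("grp", division_random, FALSE), md, reml)
  singular <- lme4::isSingular(fit)
  if (singular) {
    warning("singular random-effect covariance; refitting with independent ",
            "random intercepts and slopes (result flagged)")
    fit <- .fit_lmer(.group_formula("grp", division_random, TRUE), md, reml)
  }
  independent_re <- singular

  b <- lme4::fixef(fit)
  V <- as.matrix(stats::vcov(fit))
  slope_of <- function(lvl) {
    cvec <- stats::setNames(numeric(length(b)), names(b))
    cvec["tc"] <- 1
    if (lvl != ref_level) {
      nm <- paste0("tc:grp", lvl)
      if (!nm %in% names(b)) stop("missing interaction coefficient ", nm)
      cvec[nm] <- 1
    }
    est <- sum(cvec * b)
    se <- sqrt(drop(t(cvec) %*% V %*% cvec))
    c(est, se)
  }
  sl <- t(vapply(levels_g, slope_of, numeric(2)))
  group_slopes <- data.frame(
    group = levels_g,
    slope = sl[, 1],
    se = sl[, 2],
    n_species = as.integer(sp_per_group[levels_g]),
    wald_p = 2 * stats::pnorm(-abs(sl[, 1] / sl[, 2])),
    stringsAsFactors = FALSE
  )
  rownames(group_slopes) <- NULL

  # ML likelihood-ratio tests
  full_ml <- .fit_lmer(.group_formula("grp", division_random, independent_re),
                       md, reml = FALSE)
  no_int <- .fit_lmer(stats::as.formula(paste(
    "doy ~ tc + grp +",
    if (independent_re) "(1 + tc || species)" else "(1 + tc | species)",
    if (division_random) {
      if (independent_re) "+ (1 + tc || division)" else "+ (1 + tc | division)"
    } else "")), md, reml = FALSE)
  lr_tests <- list(interaction = lr_test_term(full_ml, no_int))
  for (lvl in setdiff(levels_g, ref_level)) {
    md$grp_c <- md$grp
    levels(md$grp_c)[levels(md$grp_c) == lvl] <- ref_level
    md$grp_c <- droplevels(md$grp_c)
    # with two groups the collapsed slope factor degenerates to one level:
    # the single-df contrast is then the interaction test itself
    red <- if (nlevels(md$grp_c) < 2) no_int else {
      .fit_lmer(.group_formula("grp_c", division_random, independent_re),
                md, reml = FALSE)
    }
    lr_tests[[paste0("slope_", lvl, "_vs_ref")]] <- lr_test_term(full_ml, red)
  }

  structure(list(
    group_by = group_by,
    ref_level = ref_level,
    group_slopes = group_slopes,
    lr_tests = lr_tests,
    varcomp = as.data.frame(lme4::VarCorr(fit)),
    fit = fit,
    singular = singular,
    n_species = length(unique(md$species)),
    n_specimens = nrow(md),
    n_excluded = sum(drop),
    note = paste("LR df = difference in fixed-effect parameter count;",
                 "p from the chi-squared upper tail")
  ), class = "pheno_group_model")
}

#' @export
#' @method print pheno_group_model
print.pheno_group_model <- function(x, ...) {
  cat(sprintf("Group model: doy ~ temp * %s + (1 + temp | species)%s\n",
              x$group_by, if (x$singular) "  [independent RE fallback]" else ""))
  cat(sprintf("  %d species, %d specimens; reference group: %s\n",
              x$n_species, x$n_specimens, x$ref_level))
  df <- x$group_slopes
  for (i in seq_len(nrow(df))) {
    cat(sprintf("  %-22s %6.2f days/degC (SE %.2f, %d species)\n",
                df$group[i], df$slope[i], df$se[i], df$n_species[i]))
  }
  for (nm in names(x$lr_tests)) {
    t <- x$lr_tests[[nm]]
    cat(sprintf("  LR[%s] = %.2f, df = %d, p = %.3g\n", nm, t$LR, t$df, t$p))
  }
  invisible(x)
}

#' @export
coef.pheno_group_model <- function(object, ...) {
  stats::setNames(object$group_slopes$slope, object$group_slopes$group)
}

#' Forest plot of group slopes
#'
#' @param x A \code{pheno_group_model}.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.pheno_group_model <- function(x, ...) {
  df <- x$group_slopes
  idx <- rev(seq_len(nrow(df)))
  graphics::plot(df$slope, idx, xlim = range(df$slope - df$se,
                                             df$slope + df$se, 0),
                 yaxt = "n", pch = 16, xlab = "Slope (days/degC)",
                 ylab = "", ...)
  graphics::segments(df$slope - df$se, idx, df$slope + df$se, idx)
  graphics::abline(v = 0, lty = 2)
  graphics::axis(2, at = idx, labels = df$group, las = 1)
  invisible(x)
}

#' Robustness of group slopes to division-level random effects
#'
#' Refits the group model with division-level random intercepts and
#' temperature slopes added alongside the species-level ones, and reports how
#' the group slopes move plus a likelihood-ratio comparison of the two models
#' (degrees of freedom counted as the difference in variance-covariance
#' parameters; the null lies on the parameter-space boundary, so the
#' chi-squared p-value is conservative).
#'
#' @param data Specimen-level data from [responsiveness_model_data()].
#' @param group_by Trait column defining the groups.
#' @param ... Passed to [fit_group_model()].
#' @return Object of class \code{division_robustness}: list with
#'   \code{base}, \code{with_division} (both \code{pheno_group_model}),
#'   \code{slope_changes}, \code{max_abs_change}, \code{division_varcomp},
#'   \code{lr}.
#' @export
division_robustness <- function(data, group_by, ...) {
  if (length(unique(data$division)) < 2) {
    stop("need at least 2 divisions for the robustness comparison")
  }
  base <- fit_group_model(data, group_by, division_random = FALSE, ...)
  withd <- fit_group_model(data, group_by, division_random = TRUE, ...)
  stopifnot(identical(base$group_slopes$group, withd$group_slopes$group))
  delta <- withd$group_slopes$slope - base$group_slopes$slope
  ml0 <- .as_ml(base$fit); ml1 <- .as_ml(withd$fit)
  lr <- 2 * (as.numeric(stats::logLik(ml1)) - as.numeric(stats::logLik(ml0)))
  df <- attr(stats::logLik(ml1), "df") - attr(stats::logLik(ml0), "df")
  vc <- withd$varcomp
  structure(list(
    base = base,
    with_division = withd,
    slope_changes = stats::setNames(delta, base$group_slopes$group),
    max_abs_change = max(abs(delta)),
    division_varcomp = vc[grepl("^division", vc$grp), , drop = FALSE],
    lr = list(LR = max(lr, 0), df = df,
              p = stats::pchisq(max(lr, 0), df = df, lower.tail = FALSE))
  ), class = "division_robustness")
}

#' @export
#' @method print division_robustness
print.division_robustness <- function(x, ...) {
  cat("Division-random-effect robustness check\n")
  cat(sprintf("  max |slope change|: %.3f days/degC\n", x$max_abs_change))
  cat(sprintf("  LR (division terms) = %.2f, df = %d, p = %.3g\n",
              x$lr$LR, x$lr$df, x$lr$p))
  invisible(x)
}
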