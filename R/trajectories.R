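# Adult BMI growth model: random-intercept/random-slope linear mixed model
# over the adult waves, centered so the intercept is the model-implied BMI
# at the centering age (default 17.5 years). Per-individual trajectories
# are fixed effects plus empirical-Bayes (BLUP) deviations.

#' Filter to individuals observed at every required wave
#'
#' @param long_table long-format phenotype table with `individual_id`,
#'   `wave`, `bmi`.
#' @param required_waves wave indices every retained individual must have a
#'   non-missing BMI for (default the three adult waves).
#' @return the filtered table; the number of removed individuals is
#'   reported via `message()`.
#' @export
select_complete_individuals <- function(long_table, required_waves = 3:5) {
  stopifnot(all(c("individual_id", "wave", "bmi") %in% names(long_table)))
  absent <- setdiff(required_waves, unique(long_table$wave))
  if (length(absent))
    stop("no eligible individuals: required wave(s) ",
         paste(absent, collapse = ", "), " absent from table")
  obs <- long_table[!is.na(long_table$bmi) &
                      long_table$wave %in% required_waves, ]
  counts <- table(factor(obs$individual_id))
  eligible <- names(counts)[counts >= length(required_waves)]
  # guard against duplicated waves inflating the count
  ok <- vapply(eligible, function(id) {
    w <- obs$wave[obs$individual_id == id]
    all(required_waves %in% w)
  }, logical(1))
  eligible <- eligible[ok]
  n_all <- length(unique(long_table$individual_id))
  if (!length(eligible))
    stop("no eligible individuals: none observed at all required waves")
  message(n_all - length(eligible), " of ", n_all,
          " individuals removed (incomplete required waves)")
  out <- long_table[long_table$individual_id %in% eligible, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fit the linear mixed-effects BMI growth model
#'
#' Fits `bmi ~ 1 + (age - center_age)` with correlated random intercepts
#' and slopes per individual, by REML (default) or ML, optionally
#' stratified by sex. With `random_effects = FALSE` an ordinary pooled
#' least-squares line is fit instead (all individuals share the fixed
#' trajectory), which is the zero-random-variance limit of the mixed model.
#'
#' @param long_table long-format phenotype table (see
#'   [select_complete_individuals()]); must also carry `sex` when
#'   `by_sex = TRUE`.
#' @param center_age centering age in years; the intercept is the model
#'   BMI at this age.
#' @param by_sex fit separate models per sex.
#' @param method `"REML"` or `"ML"`.
#' @param random_effects include the per-individual random intercept and
#'   slope.
#' @param min_obs minimum observations per individual (individuals below
#'   it are dropped with a message).
#' @return a `growth_model_fit` (or named list of them per sex) carrying
#'   fixed effects, the random-effects covariance, residual variance,
#'   log-likelihood and convergence flag.
#' @export
fit_growth_model <- function(long_table, center_age = 17.5, by_sex = TRUE,
                             method = c("REML", "ML"),
                             random_effects = TRUE, min_obs = 3L) {
  method <- match.arg(method)
  stopifnot(all(c("individual_id", "age", "bmi") %in% names(long_table)))
  d <- long_table[!is.na(long_table$bmi) & !is.na(long_table$age), ,
                  drop = FALSE]
  counts <- table(d$individual_id)
  low <- names(counts)[counts < min_obs]
  if (length(low)) {
    message(length(low), " individuals dropped with fewer than ", min_obs,
            " observations")
    d <- d[!d$individual_id %in% low, , drop = FALSE]
  }
  if (!nrow(d)) stop("no individuals with at least ", min_obs,
                     " observations")
  if (by_sex) {
    stopifnot("sex" %in% names(d))
    fits <- lapply(split(d, d$sex), fit_growth_model, center_age = center_age,
                   by_sex = FALSE, method = method,
                   random_effects = random_effects, min_obs = min_obs)
    class(fits) <- "growth_model_fit_list"
    return(fits)
  }
  d$age_c <- d$age - center_age
  if (random_effects) {
    fit <- lme4::lmer(bmi ~ age_c + (age_c | individual_id), data = d,
                      REML = method == "REML",
                      control = lme4::lmerControl(
                        check.conv.singular = "ignore",
                        calc.derivs = FALSE))
    vc <- lme4::VarCorr(fit)
    re_cov <- matrix(as.numeric(vc$individual_id[1:2, 1:2]), 2L, 2L)
    fixed <- lme4::fixef(fit)
    resid_var <- stats::sigma(fit)^2
    conv <- length(fit@optinfo$conv$lme4$messages) == 0L ||
      all(grepl("singular|Hessian", unlist(fit@optinfo$conv$lme4$messages)))
    ll <- as.numeric(stats::logLik(fit))
  } else {
    fit <- stats::lm(bmi ~ age_c, data = d)
    fixed <- stats::coef(fit)
    re_cov <- matrix(0, 2, 2)
    resid_var <- summary(fit)$sigma^2
    conv <- TRUE
    ll <- as.numeric(stats::logLik(fit))
  }
  dimnames(re_cov) <- list(c("intercept", "slope"), c("intercept", "slope"))
  structure(list(
    model = fit, random_effects = random_effects,
    fixed_intercept = unname(fixed[1L]), fixed_slope = unname(fixed[2L]),
    random_effects_cov = re_cov, residual_variance = resid_var,
    n_individuals = length(unique(d$individual_id)),
    n_observations = nrow(d),
    log_likelihood = ll, center_age = center_age, method = method,
    converged = conv, data = d
  ), class = "growth_model_fit")
}

#' @export
print.growth_model_fit <- function(x, ...) {
  cat("BMI growth model (", x$method, ", centered at ", x$center_age,
      " y): intercept ", round(x$fixed_intercept, 3), " kg/m2, slope ",
      round(x$fixed_slope, 4), " kg/m2 per year\n", sep = "")
  cat(x$n_individuals, "individuals,", x$n_observations, "observations;",
      "residual SD", round(sqrt(x$residual_variance), 3), "\n")
  invisible(x)
}

#' Per-individual trajectory estimates (intercept and slope)
#'
#' Extracts each individual's model-implied BMI at the centering age and
#' annual BMI change: fixed effect plus BLUP deviation (or the shared
#' fixed line when the model was fit without random effects).
#'
#' @param fit a `growth_model_fit` or the per-sex list returned by
#'   [fit_growth_model()].
#' @return data frame with `individual_id` (plus `sex` for stratified
#'   fits), `intercept` (kg/m2) and `slope` (kg/m2 per year); one row per
#'   individual in the fit.
#' @export
extract_individual_trajectories <- function(fit) {
  if (inherits(fit, "growth_model_fit_list")) {
    out <- do.call(rbind, lapply(names(fit), function(sx) {
      tr <- extract_individual_trajectories(fit[[sx]])
      tr$sex <- sx
      tr[, c("individual_id", "sex", "intercept", "slope")]
    }))
    rownames(out) <- NULL
    return(out)
  }
  stopifnot(inherits(fit, "growth_model_fit"))
  if (!fit$converged) stop("growth model did not converge")
  ids <- unique(fit$data$individual_id)
  if (fit$random_effects) {
    cf <- stats::coef(fit$model)$individual_id
    missing_ids <- setdiff(ids, rownames(cf))
    if (length(missing_ids))
      warning(length(missing_ids), " individuals absent from fit, skipped")
    out <- data.frame(individual_id = rownames(cf),
                      intercept = cf[, "(Intercept)"],
                      slope = cf[, "age_c"],
                      stringsAsFactors = FALSE)
  } else {
    out <- data.frame(individual_id = ids,
                      intercept = fit$fixed_intercept,
                      slope = fit$fixed_slope,
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
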