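# Univariate twin variance decomposition by full-information maximum
# likelihood over five zygosity-by-sex groups (MZM, MZF, DZM, DZF, DZOS).
# The expected within-group covariance of a twin pair is assembled from
# path coefficients with the classical cross-twin correlation constants:
# additive genetic A (1 in MZ, 0.5 in DZ), shared environment C (1, 1),
# dominance D (1, 0.25), unique environment E (0, 0).

KAPPA <- list(A = c(MZ = 1, DZ = 0.5),
              C = c(MZ = 1, DZ = 1),
              D = c(MZ = 1, DZ = 0.25),
              E = c(MZ = 0, DZ = 0))

#' Assemble zygosity-by-sex twin group data from an individual-level table
#'
#' Pivots a long per-individual trait table into per-group pair matrices
#' (twin 1, twin 2 ordered by birth order; opposite-sex pairs reordered so
#' the male twin is first). Incomplete pairs are retained with `NA` for the
#' missing co-twin and contribute through FIML.
#'
#' @param data data frame with columns `individual_id`, `pair_id`,
#'   `birth_order`, `sex`, `zygosity`, `opposite_sex`, and the trait column.
#' @param trait name of the trait column.
#' @return a list of `twin_group` objects (label, member sexes, pair matrix).
#' @export
build_twin_groups <- function(data, trait) {
  req <- c("pair_id", "birth_order", "sex", "zygosity", "opposite_sex", trait)
  miss <- setdiff(req, names(data))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "))
  data$group <- ifelse(data$opposite_sex, "DZOS",
                       paste0(data$zygosity, data$sex))
  groups <- list()
  for (g in intersect(GROUP_LABELS, unique(data$group))) {
    d <- data[data$group == g, ]
    d <- d[order(d$pair_id, d$birth_order), ]
    pair_ids <- unique(d$pair_id)
    X <- matrix(NA_real_, length(pair_ids), 2L,
                dimnames = list(pair_ids, c("twin1", "twin2")))
    slot <- if (g == "DZOS") ifelse(d$sex == "M", 1L, 2L)
            else pmin(d$birth_order, 2L)
    cell <- cbind(match(d$pair_id, pair_ids), slot)
    dup <- duplicated(cell)
    if (any(dup))
      stop("pair ", d$pair_id[which(dup)[1L]],
           " maps to more than two individuals (or duplicated birth order)")
    X[cell] <- d[[trait]]
    sexes <- switch(g, MZM = c("M", "M"), MZF = c("F", "F"),
                    DZM = c("M", "M"), DZF = c("F", "F"),
                    DZOS = c("M", "F"))
    X <- X[rowSums(!is.na(X)) > 0L, , drop = FALSE]
    if (nrow(X) == 0L) next
    groups[[g]] <- structure(
      list(label = g, zygosity = if (startsWith(g, "MZ")) "MZ" else "DZ",
           sexes = sexes, X = X, n_pairs = nrow(X), trait = trait),
      class = "twin_group")
  }
  if (!length(groups)) stop("no twin pairs found")
  groups
}

group_stats <- function(g) fiml_pattern_stats(g$X)

data_fingerprint <- function(groups) {
  v <- unlist(lapply(groups, function(g) c(g$n_pairs,
    sum(g$X, na.rm = TRUE), sum(g$X^2, na.rm = TRUE))))
  paste(signif(v, 12), collapse = "|")
}

#' Specify a univariate twin variance-components model
#'
#' @param components character subset of `A`, `C`, `D`, `E`. `E` is
#'   mandatory; `C` and `D` cannot be estimated simultaneously with twins
#'   reared together.
#' @param sex_mode `"full"` (separate paths and means per sex, opposite-sex
#'   DZ genetic correlation fixed at 0.5), `"no_sex_difference"` (all
#'   parameters equated across sexes) or `"no_sex_genetic"` (genetic paths
#'   equated, environmental paths and means free per sex).
#' @return an object of class `twin_model_spec`.
#' @export
twin_model_spec <- function(components = c("A", "E"),
                            sex_mode = c("full", "no_sex_difference",
                                         "no_sex_genetic")) {
  sex_mode <- match.arg(sex_mode)
  components <- unique(toupper(components))
  if (!all(components %in% c("A", "C", "D", "E")))
    stop("components must be a subset of A, C, D, E")
  if (!"E" %in% components) stop("the E component is mandatory")
  if (all(c("C", "D") %in% components))
    stop("C and D components cannot be estimated simultaneously")
  components <- intersect(c("A", "C", "D", "E"), components)
  structure(list(components = components, sex_mode = sex_mode),
            class = "twin_model_spec")
}

spec_label <- function(spec) {
  paste0(paste(spec$components, collapse = ""), "/", spec$sex_mode)
}

# Parameter template: data frame of (name, kind, component, sex).
uv_par_template <- function(spec) {
  comps <- spec$components
  rows <- list()
  add <- function(name, kind, component, sex)
    rows[[length(rows) + 1L]] <<- data.frame(name = name, kind = kind,
      component = component, sex = sex, stringsAsFactors = FALSE)
  if (spec$sex_mode == "no_sex_difference") {
    add("m", "mean", NA, "both")
    for (x in comps) add(tolower(x), "path", x, "both")
  } else {
    add("m_M", "mean", NA, "M"); add("m_F", "mean", NA, "F")
    for (x in comps) {
      shared <- spec$sex_mode == "no_sex_genetic" && x %in% c("A", "D")
      if (shared) add(tolower(x), "path", x, "both")
      else {
        add(paste0(tolower(x), "_M"), "path", x, "M")
        add(paste0(tolower(x), "_F"), "path", x, "F")
      }
    }
  }
  do.call(rbind, rows)
}

# par vector -> list(mean = c(M, F), path = matrix comps x sexes)
uv_assemble <- function(par, spec, tmpl) {
  mean_sex <- c(M = NA_real_, F = NA_real_)
  path <- matrix(0, length(spec$components), 2L,
                 dimnames = list(spec$components, c("M", "F")))
  for (i in seq_len(nrow(tmpl))) {
    v <- par[i]
    sx <- if (tmpl$sex[i] == "both") c("M", "F") else tmpl$sex[i]
    if (tmpl$kind[i] == "mean") mean_sex[sx] <- v
    else path[tmpl$component[i], sx] <- v
  }
  list(mean = mean_sex, path = path)
}

uv_group_moments <- function(model, g) {
  s1 <- g$sexes[1L]; s2 <- g$sexes[2L]
  p1 <- model$path[, s1]; p2 <- model$path[, s2]
  kap <- vapply(rownames(model$path), function(x) KAPPA[[x]][g$zygosity],
                numeric(1))
  v1 <- sum(p1^2); v2 <- sum(p2^2)
  cv <- sum(kap * p1 * p2)
  list(mu = c(model$mean[s1], model$mean[s2]),
       Sigma = matrix(c(v1, cv, cv, v2), 2L))
}

uv_m2ll <- function(par, spec, tmpl, groups, stats) {
  model <- uv_assemble(par, spec, tmpl)
  total <- 0
  for (i in seq_along(groups)) {
    mom <- uv_group_moments(model, groups[[i]])
    total <- total + fiml_m2ll(stats[[i]], mom$mu, mom$Sigma)
  }
  total
}

# Falconer-style moment start values (also exported as the oracle used in
# tests: a2 = 2(rMZ - rDZ), c2 = 2 rDZ - rMZ, projected onto the simplex).

#' Moment-based heritability estimate from twin correlations
#'
#' Falconer's formula: `a2 = 2 * (rMZ - rDZ)`, with the shared-environment
#' share `c2 = 2 * rDZ - rMZ`; both projected onto `[0, 1]`.
#'
#' @param r_mz,r_dz MZ and DZ intraclass/Pearson pair correlations.
#' @return named vector with `a2`, `c2`, `e2`.
#' @export
falconer_estimate <- function(r_mz, r_dz) {
  a2 <- min(max(2 * (r_mz - r_dz), 0), 1)
  c2 <- min(max(2 * r_dz - r_mz, 0), 1 - a2)
  c(a2 = a2, c2 = c2, e2 = 1 - a2 - c2)
}

uv_start_values <- function(spec, tmpl, groups) {
  all_vals <- unlist(lapply(groups, function(g) as.vector(g$X)))
  v_tot <- stats::var(all_vals, na.rm = TRUE)
  pair_cor <- function(zyg) {
    Xs <- do.call(rbind, lapply(groups, function(g)
      if (g$zygosity == zyg) g$X else NULL))
    if (is.null(Xs)) return(NA_real_)
    cc <- Xs[stats::complete.cases(Xs), , drop = FALSE]
    if (nrow(cc) < 3L) return(NA_real_)
    stats::cor(cc[, 1L], cc[, 2L])
  }
  r_mz <- pair_cor("MZ"); r_dz <- pair_cor("DZ")
  if (!is.finite(r_mz)) r_mz <- 0.6
  if (!is.finite(r_dz)) r_dz <- 0.3
  fal <- falconer_estimate(r_mz, r_dz)
  share <- c(A = max(fal["a2"], 0.1), C = max(fal["c2"], 0.05),
             D = 0.1, E = max(fal["e2"], 0.1))
  use <- share[spec$components]
  use <- use / sum(use)
  mean_sex <- vapply(c("M", "F"), function(s) {
    vals <- unlist(lapply(groups, function(g) {
      sel <- g$sexes == s
      as.vector(g$X[, sel, drop = FALSE])
    }))
    if (length(vals)) mean(vals, na.rm = TRUE) else mean(all_vals, na.rm = TRUE)
  }, numeric(1))
  par <- numeric(nrow(tmpl))
  for (i in seq_len(nrow(tmpl))) {
    if (tmpl$kind[i] == "mean") {
      par[i] <- if (tmpl$sex[i] == "both") mean(all_vals, na.rm = TRUE)
                else mean_sex[tmpl$sex[i]]
    } else {
      par[i] <- sqrt(use[tmpl$component[i]] * v_tot)
    }
  }
  par
}

#' Fit a univariate twin variance-components model by FIML
#'
#' Maximizes the multigroup Gaussian likelihood over missingness patterns.
#' Path coefficients are sign-unidentified, so absolute paths and
#' standardized variance shares are reported.
#'
#' @param groups list from [build_twin_groups()]; at least two zygosity
#'   groups are required to identify A against C or D.
#' @param spec a [twin_model_spec()].
#' @param ci `"none"` (default) or `"profile"`; profile CIs can also be
#'   obtained afterwards with [profile_ci()].
#' @param level confidence level for profile CIs.
#' @return object of class `twin_vc_fit`: absolute paths and means per sex,
#'   standardized shares (with CIs when requested), `minus2LL`,
#'   `n_free_params`, `AIC`, convergence flag.
#' @export
fit_variance_components <- function(groups, spec = twin_model_spec(),
                                    ci = c("none", "profile"), level = 0.95) {
  ci <- match.arg(ci)
  stopifnot(inherits(spec, "twin_model_spec"))
  zygs <- unique(vapply(groups, `[[`, "", "zygosity"))
  if (length(zygs) < 2L && length(setdiff(spec$components, "E")) > 1L)
    stop("need both MZ and DZ groups to identify more than one familial component")
  for (g in groups) if (all(is.na(g$X)))
    stop("group ", g$label, " has no observed values")
  tmpl <- uv_par_template(spec)
  stats_list <- lapply(groups, group_stats)
  fn <- function(par) uv_m2ll(par, spec, tmpl, groups, stats_list)
  start <- uv_start_values(spec, tmpl, groups)
  opt <- fiml_optimize(start, fn)
  model <- uv_assemble(opt$par, spec, tmpl)
  model$path <- abs(model$path)
  shares <- apply(model$path, 2L, function(p) {
    v <- sum(p^2)
    p^2 / v
  })
  if (is.null(dim(shares)))
    shares <- matrix(shares, nrow = 1L,
                     dimnames = list(spec$components, c("M", "F")))
  total_var <- colSums(model$path^2)
  fit <- structure(list(
    spec = spec, label = spec_label(spec),
    paths = model$path, means = model$mean,
    shares = shares, total_variance = total_var,
    minus2LL = opt$value, n_free_params = nrow(tmpl),
    AIC = opt$value + 2 * nrow(tmpl),
    converged = opt$convergence == 0L,
    par = opt$par, tmpl = tmpl, groups = groups, stats_list = stats_list,
    fingerprint = data_fingerprint(groups)
  ), class = "twin_vc_fit")
  if (ci == "profile") {
    sexes <- if (spec$sex_mode == "no_sex_difference") "both"
             else c("M", "F")
    fit$ci <- list()
    for (sx in sexes) for (x in spec$components) {
      fit$ci[[paste(x, sx, sep = "_")]] <-
        profile_ci(fit, component = x, sex = sx, level = level)
    }
  }
  fit
}

#' @export
print.twin_vc_fit <- function(x, ...) {
  cat("Twin variance-components fit:", x$label, "\n")
  cat("-2LL =", format(x$minus2LL), " free parameters =", x$n_free_params,
      " AIC =", format(x$AIC), "\n")
  cat("Standardized shares:\n")
  print(round(x$shares, 3))
  invisible(x)
}

# ---- saturated and constrained-saturated models ------------------------

sat_group_m2ll_analytic <- function(X) {
  cc <- X[stats::complete.cases(X), , drop = FALSE]
  n <- nrow(cc)
  m <- colMeans(cc)
  S <- crossprod(sweep(cc, 2L, m)) / n
  detS <- S[1, 1] * S[2, 2] - S[1, 2]^2
  if (detS <= 1e-12 * max(S[1, 1] * S[2, 2], 1e-300)) {
    return(list(mu = m, Sigma = S, m2ll = NA_real_, singular = TRUE))
  }
  list(mu = m, Sigma = S,
       m2ll = n * (2 * log(2 * pi) + log(detS) + 2), singular = FALSE)
}

#' Fit the saturated twin model
#'
#' Freely estimates the mean of each co-twin, both variances and the
#' within-pair covariance in every zygosity-by-sex group. For complete data
#' the maximum-likelihood solution is the closed-form sample-moment one;
#' with missing values each group is optimized by FIML. The `constrained`
#' variant equates means and variances across birth order within each group
#' (the classical twin-model assumption).
#'
#' @param groups list from [build_twin_groups()].
#' @param constrained logical; fit the equal-means/equal-variances variant.
#' @return object of class `twin_sat_fit` with per-group estimates,
#'   `minus2LL`, `n_free_params`, and singularity flags.
#' @export
fit_saturated <- function(groups, constrained = FALSE) {
  per_group <- list()
  total <- 0
  singular <- character(0)
  npar <- 0L
  for (g in groups) {
    X <- g$X
    st <- fiml_pattern_stats(X)
    complete <- !anyNA(X)
    if (!constrained && complete) {
      res <- sat_group_m2ll_analytic(X)
      if (res$singular) {
        singular <- c(singular, g$label)
        warning("group ", g$label,
                " has a singular within-pair covariance (correlation 1)")
        per_group[[g$label]] <- c(res, list(n_pairs = g$n_pairs))
        npar <- npar + 5L
        next
      }
      est <- res
    } else if (!constrained) {
      fn <- function(p) {
        v1 <- exp(p[3]); v2 <- exp(p[4]); rho <- tanh(p[5])
        Sigma <- matrix(c(v1, rho * sqrt(v1 * v2), rho * sqrt(v1 * v2), v2), 2)
        fiml_m2ll(st, p[1:2], Sigma)
      }
      m0 <- colMeans(X, na.rm = TRUE)
      v0 <- apply(X, 2L, stats::var, na.rm = TRUE)
      opt <- fiml_optimize(c(m0, log(pmax(v0, 1e-6)), 0.5), fn, restarts = 3L)
      p <- opt$par
      rho <- tanh(p[5]); v1 <- exp(p[3]); v2 <- exp(p[4])
      est <- list(mu = p[1:2],
                  Sigma = matrix(c(v1, rho * sqrt(v1 * v2),
                                   rho * sqrt(v1 * v2), v2), 2),
                  m2ll = opt$value, singular = FALSE)
    } else {
      fn <- function(p) {
        v <- exp(p[2]); rho <- tanh(p[3])
        Sigma <- matrix(c(v, rho * v, rho * v, v), 2)
        fiml_m2ll(st, rep(p[1], 2L), Sigma)
      }
      m0 <- mean(X, na.rm = TRUE)
      v0 <- stats::var(as.vector(X), na.rm = TRUE)
      opt <- fiml_optimize(c(m0, log(max(v0, 1e-6)), 0.5), fn, restarts = 3L)
      p <- opt$par; v <- exp(p[2]); rho <- tanh(p[3])
      est <- list(mu = rep(p[1], 2L),
                  Sigma = matrix(c(v, rho * v, rho * v, v), 2),
                  m2ll = opt$value, singular = FALSE)
    }
    per_group[[g$label]] <- c(est, list(n_pairs = g$n_pairs))
    npar <- npar + if (constrained) 3L else 5L
    total <- total + est$m2ll
  }
  structure(list(per_group = per_group,
                 minus2LL = if (length(singular)) NA_real_ else total,
                 n_free_params = npar,
                 AIC = if (length(singular)) NA_real_ else total + 2 * npar,
                 singular_groups = singular,
                 constrained = constrained,
                 label = if (constrained) "saturated_constrained" else "saturated",
                 converged = TRUE,
                 fingerprint = data_fingerprint(groups)),
            class = "twin_sat_fit")
}

#' @export
print.twin_sat_fit <- function(x, ...) {
  cat(if (x$constrained) "Constrained saturated" else "Saturated",
      "twin model: -2LL =", format(x$minus2LL),
      " free parameters =", x$n_free_params, "\n")
  if (length(x$singular_groups))
    cat("Singular groups:", paste(x$singular_groups, collapse = ", "), "\n")
  invisible(x)
}

#' Test the classical twin-model assumptions against the saturated model
#'
#' Compares (i) the birth-order equal-means/equal-variances constrained
#' saturated model and (ii) the full variance-components model to the
#' saturated model by likelihood-ratio tests. Violations are flagged at
#' `alpha` but are reported, not fatal: twin models are routinely fit and
#' interpreted even when these tests reject at large sample sizes.
#'
#' @param groups list from [build_twin_groups()].
#' @param spec variance-components model to test (default full-sex ACE).
#' @param alpha flag threshold for the violation column.
#' @return a `model_comparison` data frame with `minus2LL`, `df`,
#'   `delta_minus2LL`, `delta_df`, `p`, and `violation` columns.
#' @export
test_assumptions <- function(groups,
                             spec = twin_model_spec(c("A", "C", "E"), "full"),
                             alpha = 0.05) {
  sat <- fit_saturated(groups)
  con <- fit_saturated(groups, constrained = TRUE)
  vc <- fit_variance_components(groups, spec)
  cmp <- compare_models(list(con, vc), reference = sat)
  cmp$violation <- !is.na(cmp$p) & cmp$p < alpha
  cmp
}

#' Likelihood-ratio comparison of nested twin models
#'
#' Tabulates `-2LL` differences of each fit against a reference model and
#' selects the most parsimonious model not significantly worse than the
#' reference at `alpha` (AIC as tie-break). All fits must be on identical
#' data. With `boundary = TRUE` the conservative 50:50 chi-square mixture
#' p-value for a single variance component tested at its boundary is used.
#'
#' @param fits list of `twin_vc_fit` / `twin_sat_fit` objects nested in the
#'   reference.
#' @param reference the more general model.
#' @param alpha selection threshold.
#' @param boundary use the 0.5*chi2(df) + 0.5*chi2(0) mixture p-value.
#' @return a `model_comparison` data frame with attribute `selected`.
#' @export
compare_models <- function(fits, reference, alpha = 0.05, boundary = FALSE) {
  if (inherits(fits, c("twin_vc_fit", "twin_sat_fit"))) fits <- list(fits)
  fps <- vapply(c(fits, list(reference)), `[[`, "", "fingerprint")
  if (length(unique(fps)) != 1L)
    stop("model comparison requires fits on identical data (fingerprint mismatch)")
  row_of <- function(f, ref = NULL) {
    d <- if (is.null(ref)) NA_real_ else f$minus2LL - ref$minus2LL
    ddf <- if (is.null(ref)) NA_integer_ else
      ref$n_free_params - f$n_free_params
    if (!is.null(ref) && !is.na(ddf) && ddf < 0L)
      stop("model '", f$label, "' is not nested in the reference (more parameters)")
    p <- if (is.null(ref)) NA_real_ else {
      d0 <- max(d, 0)
      if (boundary) 0.5 * stats::pchisq(d0, max(ddf, 1L), lower.tail = FALSE) +
        0.5 * (d0 <= 0)
      else if (ddf == 0L) as.numeric(d0 <= 1e-8)
      else stats::pchisq(d0, ddf, lower.tail = FALSE)
    }
    data.frame(model = f$label, minus2LL = f$minus2LL, df = f$n_free_params,
               delta_minus2LL = d, delta_df = ddf, p = p,
               AIC = f$minus2LL + 2 * f$n_free_params,
               stringsAsFactors = FALSE)
  }
  tab <- rbind(row_of(reference),
               do.call(rbind, lapply(fits, row_of, ref = reference)))
  rownames(tab) <- NULL
  keep <- tab[is.na(tab$p) | tab$p >= alpha, , drop = FALSE]
  sel <- keep[order(keep$df, keep$AIC), , drop = FALSE]$model[1L]
  attr(tab, "selected") <- sel
  class(tab) <- c("model_comparison", class(tab))
  tab
}

# ---- profile-likelihood confidence intervals ---------------------------

# -2LL minimized subject to share of `component` (for `sex`) fixed at s.
# The constrained sex's paths are reparameterized as total variance V plus
# a stick-breaking split of the remaining share among the other components.
uv_profiled_m2ll <- function(fit, component, sex, s) {
  spec <- fit$spec; tmpl <- fit$tmpl
  groups <- fit$groups
  stats_list <- fit$stats_list
  if (is.null(stats_list)) stats_list <- lapply(groups, group_stats)
  target_sex <- if (sex == "both") c("M", "F") else sex
  is_target_path <- tmpl$kind == "path" &
    vapply(seq_len(nrow(tmpl)), function(i)
      any(target_sex %in% (if (tmpl$sex[i] == "both") c("M", "F")
                           else tmpl$sex[i])), logical(1))
  free_idx <- which(!is_target_path)
  other <- setdiff(spec$components[
    spec$components %in% tmpl$component[is_target_path]], component)
  if (!(component %in% tmpl$component[is_target_path]))
    stop("component ", component, " is not a free path for sex ", sex)
  V0 <- sum(fit$total_variance[target_sex]) / length(target_sex)
  sh0 <- rowMeans(fit$shares[, target_sex, drop = FALSE])
  extra0 <- log(max(V0, 1e-8))
  if (length(other) >= 2L) {
    rest <- pmax(sh0[other], 1e-6)
    extra0 <- c(extra0, stats::qlogis(rest[1L] / sum(rest)))
  }
  build_par <- function(theta) {
    par <- fit$par
    nfree <- length(free_idx)
    if (nfree) par[free_idx] <- theta[seq_len(nfree)]
    extra <- theta[-seq_len(nfree)]
    V <- exp(extra[1L])
    rem <- max(1 - s, 0)
    shares_t <- stats::setNames(numeric(length(other) + 1L),
                                c(component, other))
    shares_t[component] <- s
    if (length(other) == 1L) shares_t[other] <- rem
    else if (length(other) >= 2L) {
      w <- stats::plogis(extra[2L])
      shares_t[other[1L]] <- rem * w
      shares_t[other[2L]] <- rem * (1 - w)
    }
    for (i in which(is_target_path)) {
      par[i] <- sqrt(shares_t[tmpl$component[i]] * V)
    }
    par
  }
  fn <- function(theta) uv_m2ll(build_par(theta), spec, tmpl, groups,
                                stats_list)
  theta0 <- c(fit$par[free_idx], extra0)
  opt <- tryCatch(fiml_optimize(theta0, fn, restarts = 2L, maxit = 500L),
                  error = function(e) NULL)
  if (is.null(opt)) return(Inf)
  opt$value
}

#' Profile-likelihood confidence interval for a standardized variance share
#'
#' Finds the bounds where the profiled `-2LL` (nuisance parameters
#' re-optimized at each candidate value) rises by the chi-square(1) quantile
#' above its minimum, by bisection on the share scale. Bounds that are not
#' bracketed inside `[0, 1]` are reported at the boundary with a flag.
#'
#' @param fit a `twin_vc_fit`.
#' @param component which component's share (e.g. `"A"`).
#' @param sex `"M"`, `"F"`, or `"both"` for models without sex differences.
#' @param level confidence level.
#' @param tol bisection tolerance on the share scale.
#' @return list with `lower`, `upper`, `estimate`, `level` and
#'   `lower_at_boundary` / `upper_at_boundary` flags.
#' @export
profile_ci <- function(fit, component = "A", sex = "both", level = 0.95,
                       tol = 1e-3) {
  stopifnot(inherits(fit, "twin_vc_fit"))
  if (!fit$converged) stop("profile_ci requires a converged fit")
  if (sex == "both" && fit$spec$sex_mode != "no_sex_difference")
    sex <- "M"
  est_sex <- if (sex == "both") "M" else sex
  s_hat <- fit$shares[component, est_sex]
  crit <- stats::qchisq(level, 1L)
  m2ll_hat <- fit$minus2LL
  f <- function(s) {
    # shares 0 and 1 can make a group covariance exactly singular;
    # evaluate just inside the boundary instead
    s <- min(max(s, 1e-6), 1 - 1e-6)
    uv_profiled_m2ll(fit, component, sex, s) - m2ll_hat - crit
  }
  bisect <- function(lo, hi, flo) {
    # f(lo) and f(hi) have opposite signs; return the crossing point
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      fm <- f(mid)
      if (is.na(fm)) break
      if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
    }
    (lo + hi) / 2
  }
  f0 <- f(0)
  if (f0 <= 0) {
    lower <- 0; lower_boundary <- TRUE
  } else {
    lower <- bisect(0, s_hat, f0); lower_boundary <- FALSE
  }
  f1 <- f(1)
  if (f1 <= 0) {
    upper <- 1; upper_boundary <- TRUE
  } else {
    upper <- bisect(s_hat, 1, -crit); upper_boundary <- FALSE
  }
  list(lower = min(lower, s_hat), upper = max(upper, s_hat),
       estimate = s_hat, level = level,
       lower_at_boundary = lower_boundary,
       upper_at_boundary = upper_boundary)
}
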