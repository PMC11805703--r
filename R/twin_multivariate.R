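# Multivariate Cholesky twin model. Each component covariance is
# parameterized as T %*% t(T) with T lower-triangular, which keeps the
# implied component covariances positive semi-definite by construction.
# The expected 2k x 2k per-group covariance of a twin pair is
#   [[Sigma, kappa_A * Sigma_A + kappa_C * Sigma_C],
#    [  .  ,                 Sigma              ]]
# with Sigma = Sigma_A (+ Sigma_C) + Sigma_E and the same cross-twin
# constants as the univariate model.

#' Assemble multivariate twin pair data
#'
#' Builds, per zygosity group of one sex (or pooled), an
#' `n_pairs x 2k` matrix ordered (twin 1 traits, twin 2 traits) from a
#' per-individual table with one column per trait. Pairs missing some trait
#' values are retained and handled by FIML.
#'
#' @param data per-individual data frame with `pair_id`, `birth_order`,
#'   `sex`, `zygosity`, `opposite_sex` and the trait columns.
#' @param traits ordered character vector of trait column names (`k >= 1`).
#' @param sex restrict to same-sex pairs of this sex (`"M"` or `"F"`), the
#'   default for by-sex fits; `NULL` pools all same-sex pairs.
#' @param include_os include opposite-sex pairs (only meaningful when
#'   `sex` is `NULL`).
#' @return list of `multitrait_group` objects (label, matrix, trait labels).
#' @export
build_multitrait_groups <- function(data, traits, sex = NULL,
                                    include_os = FALSE) {
  if (length(traits) < 1L) stop("at least one trait required")
  miss <- setdiff(traits, names(data))
  if (length(miss)) stop("missing trait columns: ",
                         paste(miss, collapse = ", "))
  if (!include_os) data <- data[!data$opposite_sex, , drop = FALSE]
  if (!is.null(sex)) data <- data[data$sex == sex & !data$opposite_sex, ,
                                  drop = FALSE]
  if (!nrow(data)) stop("no individuals left after sex/zygosity filtering")
  k <- length(traits)
  groups <- list()
  for (zyg in c("MZ", "DZ")) {
    d <- data[data$zygosity == zyg, , drop = FALSE]
    if (!nrow(d)) next
    d <- d[order(d$pair_id, d$birth_order), ]
    pair_ids <- unique(d$pair_id)
    X <- matrix(NA_real_, length(pair_ids), 2L * k)
    colnames(X) <- c(paste0(traits, "_1"), paste0(traits, "_2"))
    slot <- pmin(d$birth_order, 2L)
    ri <- match(d$pair_id, pair_ids)
    for (j in seq_len(k)) {
      X[cbind(ri, (slot - 1L) * k + j)] <- d[[traits[j]]]
    }
    X <- X[rowSums(!is.na(X)) > 0L, , drop = FALSE]
    if (!nrow(X)) next
    groups[[zyg]] <- structure(
      list(label = paste0(zyg, if (!is.null(sex)) sex else ""),
           zygosity = zyg, traits = traits, k = k, X = X,
           n_pairs = nrow(X)),
      class = "multitrait_group")
  }
  if (length(groups) < 2L)
    stop("need both MZ and DZ groups for a Cholesky twin model")
  groups
}

vech_count <- function(k) k * (k + 1L) / 2L

vech_to_lower <- function(v, k) {
  Tm <- matrix(0, k, k)
  Tm[lower.tri(Tm, diag = TRUE)] <- v
  Tm
}

chol_assemble <- function(par, k, components) {
  nv <- vech_count(k)
  means <- par[seq_len(k)]
  Ts <- list()
  off <- k
  for (x in components) {
    Ts[[x]] <- vech_to_lower(par[off + seq_len(nv)], k)
    off <- off + nv
  }
  list(means = means, T = Ts)
}

chol_expected <- function(model, zygosity, components) {
  k <- length(model$means)
  Sig <- lapply(model$T, tcrossprod)
  within <- Reduce(`+`, Sig)
  cross <- matrix(0, k, k)
  for (x in components)
    cross <- cross + KAPPA[[x]][zygosity] * Sig[[x]]
  list(mu = rep(model$means, 2L),
       Sigma = rbind(cbind(within, cross), cbind(t(cross), within)),
       Sigma_comp = Sig, within = within)
}

#' Fit a multivariate Cholesky twin decomposition by FIML
#'
#' Decomposes the cross-trait covariance into additive-genetic and unique-
#' environmental (optionally shared-environmental) triangular factors using
#' MZ and DZ pair data of one sex (or pooled). With `k = 1` the model
#' reduces exactly to the univariate AE (or ACE) fit.
#'
#' @param groups list from [build_multitrait_groups()].
#' @param components character vector among `"A"`, `"C"`, `"E"`; `E` is
#'   mandatory. Default AE.
#' @return object of class `cholesky_fit` with triangular paths `T_A`
#'   (`T_C`) `T_E`, implied component covariances `Sigma_A` etc., total
#'   phenotypic covariance, `minus2LL`, and convergence flag.
#' @export
fit_cholesky <- function(groups, components = c("A", "E")) {
  components <- intersect(c("A", "C", "E"), unique(toupper(components)))
  if (!"E" %in% components) stop("the E component is mandatory")
  k <- groups[[1L]]$k
  traits <- groups[[1L]]$traits
  if (!all(vapply(groups, `[[`, 0L, "k") == k))
    stop("trait count differs between groups")
  stats_list <- lapply(groups, function(g) fiml_pattern_stats(g$X))
  fn <- function(par) {
    model <- chol_assemble(par, k, components)
    total <- 0
    for (i in seq_along(groups)) {
      exp_g <- chol_expected(model, groups[[i]]$zygosity, components)
      total <- total + fiml_m2ll(stats_list[[i]], exp_g$mu, exp_g$Sigma)
    }
    total
  }
  # start: split the pooled phenotypic covariance among the components
  pooled <- do.call(rbind, lapply(groups, function(g)
    rbind(g$X[, seq_len(k), drop = FALSE],
          g$X[, k + seq_len(k), drop = FALSE])))
  mu0 <- colMeans(pooled, na.rm = TRUE)
  S0 <- stats::cov(pooled, use = "pairwise.complete.obs")
  S0[!is.finite(S0)] <- 0
  S0 <- S0 + diag(1e-6 * max(diag(S0), 1), k)
  w <- c(A = 0.55, C = 0.15, E = 0.30)[components]
  w <- w / sum(w)
  par0 <- mu0
  for (x in components) {
    Tx <- t(chol(w[[x]] * S0))
    par0 <- c(par0, Tx[lower.tri(Tx, diag = TRUE)])
  }
  opt <- fiml_optimize(par0, fn, restarts = 3L, jitter_sd = 0.1)
  model <- chol_assemble(opt$par, k, components)
  Sig <- lapply(model$T, tcrossprod)
  within <- Reduce(`+`, Sig)
  for (x in components) dimnames(Sig[[x]]) <- list(traits, traits)
  dimnames(within) <- list(traits, traits)
  out <- list(components = components, traits = traits, k = k,
              means = stats::setNames(model$means, traits),
              T_A = model$T[["A"]], T_C = model$T[["C"]],
              T_E = model$T[["E"]],
              Sigma_A = Sig[["A"]], Sigma_C = Sig[["C"]],
              Sigma_E = Sig[["E"]], Sigma = within,
              minus2LL = opt$value,
              n_free_params = length(opt$par),
              converged = opt$convergence == 0L,
              par = opt$par, groups = groups, stats_list = stats_list,
              fingerprint = data_fingerprint(groups))
  class(out) <- "cholesky_fit"
  out
}

#' @export
print.cholesky_fit <- function(x, ...) {
  cat("Cholesky twin decomposition (", paste(x$components, collapse = ""),
      "), ", x$k, " traits: ", paste(x$traits, collapse = ", "), "\n",
      sep = "")
  cat("-2LL =", format(x$minus2LL), " free parameters =",
      x$n_free_params, "\n")
  cr <- derive_correlations(x, ci = FALSE)
  cat("Genetic correlations (r_A):\n"); print(round(cr$r_A, 3))
  cat("Unique-environment correlations (r_E):\n"); print(round(cr$r_E, 3))
  invisible(x)
}

#' Component and phenotypic correlation matrices from a Cholesky fit
#'
#' Standardizes each component covariance,
#' `r_X[i, j] = Sigma_X[i, j] / sqrt(Sigma_X[i, i] * Sigma_X[j, j])`, and
#' the total phenotypic covariance. Confidence intervals use the delta
#' method on the Fisher-z scale (numeric Jacobian of each correlation with
#' respect to the free parameters against the inverse -2LL Hessian) and are
#' labeled as such.
#'
#' @param fit a `cholesky_fit`.
#' @param ci compute delta-method CIs (slower; requires a Hessian solve).
#' @param level confidence level.
#' @return list with matrices `r_A` (`r_C`) `r_E`, phenotypic `r`, and —
#'   when requested — `ci` (per component, arrays lower/upper) and
#'   `ci_method = "delta"`. Correlations for traits with zero component
#'   variance are `NA`.
#' @export
derive_correlations <- function(fit, ci = FALSE, level = 0.95) {
  stopifnot(inherits(fit, "cholesky_fit"))
  if (!fit$converged) stop("derive_correlations requires a converged fit")
  safe_cor <- function(S) {
    d <- sqrt(diag(S))
    r <- S / outer(d, d)
    r[!is.finite(r)] <- NA_real_
    if (any(d <= 1e-10)) r[d <= 1e-10, ] <- r[, d <= 1e-10] <- NA_real_
    diag(r) <- ifelse(d > 1e-10, 1, NA_real_)
    r
  }
  out <- list(r = safe_cor(fit$Sigma))
  for (x in fit$components) {
    if (x == "E" || x == "A" || x == "C")
      out[[paste0("r_", x)]] <- safe_cor(fit[[paste0("Sigma_", x)]])
  }
  if (ci) {
    k <- fit$k
    comps <- fit$components
    stats_list <- fit$stats_list
    groups <- fit$groups
    fn <- function(par) {
      model <- chol_assemble(par, k, comps)
      total <- 0
      for (i in seq_along(groups)) {
        e <- chol_expected(model, groups[[i]]$zygosity, comps)
        total <- total + fiml_m2ll(stats_list[[i]], e$mu, e$Sigma)
      }
      total
    }
    H <- stats::optimHess(fit$par, fn)
    V <- tryCatch(2 * solve(H), error = function(e) NULL)
    out$ci <- list()
    out$ci_method <- "delta"
    if (!is.null(V)) {
      pairs_idx <- which(upper.tri(diag(k)), arr.ind = TRUE)
      for (x in comps) {
        lo <- hi <- matrix(NA_real_, k, k, dimnames = list(fit$traits,
                                                           fit$traits))
        diag(lo) <- diag(hi) <- 1
        for (q in seq_len(nrow(pairs_idx))) {
          i <- pairs_idx[q, 1L]; j <- pairs_idx[q, 2L]
          rf <- function(par) {
            m <- chol_assemble(par, k, comps)
            S <- tcrossprod(m$T[[x]])
            r <- S[i, j] / sqrt(S[i, i] * S[j, j])
            atanh(min(max(r, -0.999999), 0.999999))
          }
          gr <- drop(num_jacobian(rf, fit$par))
          se_z <- sqrt(max(drop(gr %*% V %*% gr), 0))
          z <- rf(fit$par)
          zq <- stats::qnorm(1 - (1 - level) / 2)
          lo[i, j] <- lo[j, i] <- tanh(z - zq * se_z)
          hi[i, j] <- hi[j, i] <- tanh(z + zq * se_z)
        }
        out$ci[[paste0("r_", x)]] <- list(lower = lo, upper = hi)
      }
    }
  }
  out
}

#' Decompose a phenotypic cross-trait covariance into component shares
#'
#' Returns the fraction of the phenotypic covariance between traits `i` and
#' `j` carried by each fitted component,
#' `share_X = Sigma_X[i, j] / Sigma[i, j]`; the shares sum to one.
#'
#' @param fit a `cholesky_fit`.
#' @param i,j trait indices or names, `i != j`.
#' @return named numeric vector of shares, or an error/flagged `NA` result
#'   when the phenotypic covariance is numerically zero.
#' @export
decompose_phenotypic_correlation <- function(fit, i, j) {
  stopifnot(inherits(fit, "cholesky_fit"))
  if (is.character(i)) i <- match(i, fit$traits)
  if (is.character(j)) j <- match(j, fit$traits)
  if (is.na(i) || is.na(j) || i == j)
    stop("i and j must name two distinct traits of the fit")
  tot <- fit$Sigma[i, j]
  shares <- vapply(fit$components, function(x)
    fit[[paste0("Sigma_", x)]][i, j] / tot, numeric(1))
  if (abs(tot) < 1e-10 * sqrt(fit$Sigma[i, i] * fit$Sigma[j, j])) {
    shares[] <- NA_real_
    attr(shares, "undefined") <- "phenotypic covariance is numerically zero"
  }
  shares
}
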