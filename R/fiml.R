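# Full-information maximum likelihood (FIML) machinery shared by the twin
# models. Rows of a (pairs x variables) matrix are grouped by missingness
# pattern; each pattern contributes its Gaussian -2 log-likelihood through
# sufficient statistics (pattern mean and ML scatter), so objective
# evaluations cost O(#patterns), not O(#rows).

#' @keywords internal
fiml_pattern_stats <- function(X) {
  X <- as.matrix(X)
  obs <- !is.na(X)
  keep <- rowSums(obs) > 0L
  X <- X[keep, , drop = FALSE]
  obs <- obs[keep, , drop = FALSE]
  if (nrow(X) == 0L) return(list())
  key <- apply(obs, 1L, function(r) paste(which(r), collapse = ","))
  out <- lapply(split(seq_len(nrow(X)), key), function(rows) {
    idx <- which(obs[rows[1L], ])
    M <- X[rows, idx, drop = FALSE]
    n <- nrow(M)
    m <- colMeans(M)
    Mc <- sweep(M, 2L, m)
    list(idx = idx, n = n, mean = m, scatter = crossprod(Mc) / n)
  })
  unname(out)
}

# -2LL of N(mu, Sigma) over a list of pattern statistics. Returns Inf for a
# non-positive-definite (sub)matrix so optimizers back away from the region.
#' @keywords internal
fiml_m2ll <- function(stats, mu, Sigma) {
  total <- 0
  for (pt in stats) {
    o <- pt$idx
    S <- Sigma[o, o, drop = FALSE]
    ch <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(ch)) return(Inf)
    logdet <- 2 * sum(log(diag(ch)))
    Sinv <- chol2inv(ch)
    d <- pt$mean - mu[o]
    total <- total + pt$n * (length(o) * log(2 * pi) + logdet +
      sum(Sinv * pt$scatter) + drop(crossprod(d, Sinv %*% d)))
  }
  total
}

# Row-wise -2LL, used as an independent cross-check of the sufficient-
# statistic route (complete data only).
#' @keywords internal
fiml_m2ll_rowwise <- function(X, mu, Sigma) {
  X <- as.matrix(X)
  ch <- chol(Sigma)
  Sinv <- chol2inv(ch)
  logdet <- 2 * sum(log(diag(ch)))
  p <- ncol(X)
  total <- 0
  for (i in seq_len(nrow(X))) {
    d <- X[i, ] - mu
    total <- total + p * log(2 * pi) + logdet + drop(crossprod(d, Sinv %*% d))
  }
  total
}

# Minimize fn with optim/BFGS plus jittered restarts; fn must return Inf
# outside the feasible region.
#' @keywords internal
fiml_optimize <- function(par, fn, restarts = 5L, jitter_sd = 0.25,
                          maxit = 1000L, reltol = 1e-12) {
  best <- NULL
  p0 <- par
  # parameters can live on very different scales (e.g. BMI-level vs
  # slope-level paths); parscale keeps finite-difference gradients sane
  pscale <- pmax(abs(p0), 0.05)
  for (k in 0:restarts) {
    pk <- if (k == 0L) p0 else p0 + stats::rnorm(length(p0), 0,
                                                 jitter_sd * k * pscale)
    if (!is.finite(fn(pk))) next
    res <- tryCatch(
      stats::optim(pk, fn, method = "BFGS",
                   control = list(maxit = maxit, reltol = reltol,
                                  parscale = pscale)),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$value)) next
    # polish with Nelder-Mead to guard against flat BFGS exits
    res2 <- tryCatch(
      stats::optim(res$par, fn,
                   control = list(maxit = 2000L, reltol = reltol,
                                  parscale = pscale)),
      error = function(e) NULL)
    if (!is.null(res2) && is.finite(res2$value) && res2$value < res$value) {
      res2$convergence <- min(res$convergence, res2$convergence)
      res <- res2
    }
    if (is.null(best) || res$value < best$value) best <- res
    if (best$convergence == 0L) break
  }
  if (is.null(best))
    stop("optimization failed: no finite objective value reached", call. = FALSE)
  best
}

# Central-difference Hessian and Jacobian used for delta-method CIs.
#' @keywords internal
num_jacobian <- function(f, x, eps = 1e-5) {
  f0 <- f(x)
  J <- matrix(NA_real_, length(f0), length(x))
  for (j in seq_along(x)) {
    h <- eps * max(1, abs(x[j]))
    xp <- x; xp[j] <- xp[j] + h
    xm <- x; xm[j] <- xm[j] - h
    J[, j] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}
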