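# Polygenic-score analysis: residualize a precomputed score on the top
# genetic principal components with a family random intercept (population-
# stratification correction), standardize, correlate with phenotypes, and
# compare score distributions with the two-sample Kolmogorov-Smirnov test.

#' Residualize a polygenic score on genetic principal components
#'
#' Fits `score ~ PC1 + ... + PCk + (1 | family_id)` by REML and returns the
#' conditional (within-family) residuals scaled to mean 0 and variance 1
#' (sample SD, denominator `n - 1`). Deterministic given the input.
#'
#' @param prs_table data frame with `individual_id`, `score`, `family_id`
#'   and principal-component columns.
#' @param pc_cols names of the PC columns (default `PC1`..`PC10`).
#' @param conditional use conditional (within-family) residuals (default);
#'   `FALSE` uses marginal residuals (fixed-effect part only).
#' @return data frame `individual_id`, `prs` (standardized residual score).
#' @export
residualize_prs <- function(prs_table, pc_cols = paste0("PC", 1:10),
                            conditional = TRUE) {
  req <- c("individual_id", "score", "family_id", pc_cols)
  miss <- setdiff(req, names(prs_table))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  d <- prs_table[stats::complete.cases(prs_table[, req]), req]
  if (nrow(d) < length(pc_cols) + 10L)
    stop("need at least ", length(pc_cols) + 10L,
         " complete rows to residualize on ", length(pc_cols), " PCs")
  Xmat <- as.matrix(d[, pc_cols])
  qr_x <- qr(cbind(1, Xmat))
  if (qr_x$rank < ncol(Xmat) + 1L) {
    bad <- pc_cols[qr_x$pivot[seq(qr_x$rank + 1L, ncol(Xmat) + 1L)] - 1L]
    stop("singular PC matrix; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  fml <- stats::as.formula(paste("score ~", paste(pc_cols, collapse = " + "),
                                 "+ (1 | family_id)"))
  fit <- lme4::lmer(fml, data = d, REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
  res <- if (conditional) stats::residuals(fit)
         else d$score - stats::predict(fit, re.form = NA)
  if (stats::sd(res) < 1e-10)
    stop("zero residual variance: score is an exact function of the PCs")
  data.frame(individual_id = d$individual_id,
             prs = as.numeric(scale(res)), stringsAsFactors = FALSE)
}

#' Label the strength of a correlation
#'
#' Bins `|r|` as weak `[0, 0.40)`, moderate `[0.40, 0.60)`, strong
#' `[0.60, 1]`.
#' @param r correlation coefficient.
#' @return character label.
#' @export
correlation_strength <- function(r) {
  a <- abs(r)
  ifelse(a < 0.40, "weak", ifelse(a < 0.60, "moderate", "strong"))
}

#' Correlate a standardized polygenic score with traits
#'
#' Pearson correlations (with Fisher-z 95% CIs and strength labels)
#' between the residualized score and each trait, optionally per sex.
#' Twin non-independence is ignored in the CI, matching common reporting
#' practice; `cluster` may name a family-id column of `trait_table` to get
#' a cluster-robust (pair-bootstrap-free, effective-n) CI instead, which
#' is labeled in the output.
#'
#' @param scores data frame `individual_id`, `prs` from
#'   [residualize_prs()].
#' @param trait_table per-individual data frame with `individual_id`,
#'   optionally `sex`, and trait columns.
#' @param traits trait column names to correlate.
#' @param by_sex split by the `sex` column.
#' @param level confidence level.
#' @param cluster optional name of a cluster (family) id column for a
#'   cluster-adjusted CI.
#' @return data frame `trait`, `sex`, `n`, `r`, `lower`, `upper`,
#'   `strength`, `ci_method`, with `NA` and a reason when fewer than 3
#'   complete observation pairs exist.
#' @export
correlate_prs <- function(scores, trait_table, traits, by_sex = TRUE,
                          level = 0.95, cluster = NULL) {
  d <- merge(scores, trait_table, by = "individual_id")
  sex_levels <- if (by_sex) sort(unique(d$sex)) else "all"
  zq <- stats::qnorm(1 - (1 - level) / 2)
  rows <- list()
  for (tr in traits) for (sx in sex_levels) {
    dd <- if (by_sex) d[d$sex == sx, ] else d
    ok <- stats::complete.cases(dd$prs, dd[[tr]])
    n <- sum(ok)
    if (n < 3L) {
      rows[[paste(tr, sx)]] <- data.frame(
        trait = tr, sex = sx, n = n, r = NA_real_, lower = NA_real_,
        upper = NA_real_, strength = NA_character_,
        ci_method = "insufficient data (n < 3)",
        stringsAsFactors = FALSE)
      next
    }
    r <- stats::cor(dd$prs[ok], dd[[tr]][ok])
    n_eff <- n
    ci_method <- "fisher_z"
    if (!is.null(cluster)) {
      # effective sample size under within-cluster duplication
      m <- mean(table(dd[[cluster]][ok]))
      n_eff <- n / m
      ci_method <- "fisher_z_cluster_adjusted"
    }
    z <- atanh(min(max(r, -0.999999), 0.999999))
    se <- 1 / sqrt(n_eff - 3)
    rows[[paste(tr, sx)]] <- data.frame(
      trait = tr, sex = sx, n = n, r = r,
      lower = tanh(z - zq * se), upper = tanh(z + zq * se),
      strength = correlation_strength(r), ci_method = ci_method,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' `D` is the supremum distance between the two right-continuous empirical
#' CDFs, evaluated over the pooled observed values. The p-value is exact
#' (via `stats::ks.test`) when `n1 * n2 <= 10^4` and no ties are present,
#' and uses the asymptotic Kolmogorov distribution otherwise.
#'
#' @param sample1,sample2 non-empty numeric vectors.
#' @return list with `D`, `p_value`, `n1`, `n2`, `exact`.
#' @export
ks_compare <- function(sample1, sample2) {
  sample1 <- sample1[!is.na(sample1)]
  sample2 <- sample2[!is.na(sample2)]
  if (!length(sample1) || !length(sample2))
    stop("both samples must be non-empty")
  n1 <- length(sample1); n2 <- length(sample2)
  grid <- sort(unique(c(sample1, sample2)))
  F1 <- stats::ecdf(sample1)(grid)
  F2 <- stats::ecdf(sample2)(grid)
  D <- max(abs(F1 - F2))
  exact <- n1 * n2 <= 1e4 && !any(duplicated(c(sample1, sample2)))
  p <- suppressWarnings(
    stats::ks.test(sample1, sample2, exact = exact)$p.value)
  list(D = D, p_value = p, n1 = n1, n2 = n2, exact = exact)
}
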