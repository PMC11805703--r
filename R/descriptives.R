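# Wave-level descriptive summaries, between-wave mean-BMI arithmetic, and
# ANOVA-based intraclass correlations by zygosity.

#' Per-wave, per-sex descriptive summary
#'
#' Means and SDs of age and BMI per sex and wave, with a Welch two-sample
#' t-test p-value for the sex difference in BMI at each wave. When a
#' trajectories table is supplied its intercept and slope columns are
#' summarized the same way (as pseudo-waves `"intercept"` and `"slope"`,
#' with `NA` age columns).
#'
#' @param long_table long-format phenotype table (`individual_id`, `sex`,
#'   `wave`, `age`, `bmi`).
#' @param trajectories optional data frame with `individual_id`, `sex`,
#'   `intercept`, `slope`.
#' @return data frame with columns `wave`, `sex`, `n`, `age_mean`,
#'   `age_sd`, `bmi_mean`, `bmi_sd`, `p_sex`.
#' @export
wave_summary <- function(long_table, trajectories = NULL) {
  stopifnot(nrow(long_table) > 0,
            all(c("sex", "wave", "age", "bmi") %in% names(long_table)))
  cell <- function(values, ages, wave, sex) {
    values <- values[!is.na(values)]
    data.frame(wave = as.character(wave), sex = sex, n = length(values),
               age_mean = mean(ages, na.rm = TRUE),
               age_sd = stats::sd(ages, na.rm = TRUE),
               bmi_mean = mean(values),
               bmi_sd = stats::sd(values),
               p_sex = NA_real_, stringsAsFactors = FALSE)
  }
  rows <- list()
  for (w in sort(unique(long_table$wave))) {
    dw <- long_table[long_table$wave == w & !is.na(long_table$bmi), ]
    sexes <- sort(unique(dw$sex))
    for (sx in sexes)
      rows[[paste(w, sx)]] <- cell(dw$bmi[dw$sex == sx],
                                   dw$age[dw$sex == sx], w, sx)
    if (length(sexes) == 2L &&
        all(table(dw$sex) >= 2L)) {
      # Welch t-test; constant data (t undefined) resolves by mean equality
      p <- tryCatch(stats::t.test(bmi ~ sex, data = dw)$p.value,
                    error = function(e) {
                      mm <- tapply(dw$bmi, dw$sex, mean)
                      if (abs(diff(mm)) < 1e-12) 1 else 0
                    })
      for (sx in sexes) rows[[paste(w, sx)]]$p_sex <- p
    }
  }
  if (!is.null(trajectories)) {
    for (tr in intersect(c("intercept", "slope"), names(trajectories))) {
      sexes <- sort(unique(trajectories$sex))
      for (sx in sexes) {
        v <- trajectories[[tr]][trajectories$sex == sx]
        rows[[paste(tr, sx)]] <- cell(v, NA_real_, tr, sx)
      }
      if (length(sexes) == 2L) {
        p <- stats::t.test(trajectories[[tr]][trajectories$sex == sexes[1L]],
                           trajectories[[tr]][trajectories$sex == sexes[2L]])$p.value
        for (sx in sexes) rows[[paste(tr, sx)]]$p_sex <- p
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Difference of mean BMI between two waves
#'
#' `mean(wave_b) - mean(wave_a)` for one sex, from a [wave_summary()]
#' table (or any table with `wave`, `sex`, `bmi_mean` columns, e.g. a
#' published means table).
#'
#' @param summary a wave summary table.
#' @param wave_a,wave_b wave identifiers (coerced to character).
#' @param sex sex to use.
#' @return list with `difference` (full precision) and `rounded`
#'   (2 decimals, the convention of cohort report tables).
#' @export
bmi_change <- function(summary, wave_a, wave_b, sex) {
  pick <- function(w) {
    row <- summary[summary$wave == as.character(w) & summary$sex == sex, ]
    if (nrow(row) != 1L)
      stop("wave ", w, " for sex ", sex, " not present (or duplicated)")
    row$bmi_mean
  }
  d <- pick(wave_b) - pick(wave_a)
  list(difference = d, rounded = round(d, 2))
}

#' ANOVA intraclass correlation for twin pairs
#'
#' One-way random-effects ICC for clusters of size 2:
#' `(MSB - MSW) / (MSB + MSW)` with mean squares from `stats::aov` of the
#' trait on pair membership. Negative estimates are reported as-is.
#'
#' @param pair_table per-individual data frame with `pair_id` and the
#'   trait column; only complete pairs (both co-twins observed) are used.
#' @param trait trait column name.
#' @return list with `icc`, `n_pairs`, and the mean squares.
#' @export
compute_icc <- function(pair_table, trait) {
  d <- pair_table[!is.na(pair_table[[trait]]), c("pair_id", trait)]
  keep <- names(which(table(d$pair_id) == 2L))
  d <- d[d$pair_id %in% keep, ]
  if (length(keep) < 2L) stop("need at least two complete pairs")
  if (stats::var(d[[trait]]) < 1e-14)
    stop("zero total variance: intraclass correlation undefined")
  d$pair_id <- factor(d$pair_id)
  fml <- stats::as.formula(paste0("`", trait, "` ~ pair_id"))
  ms <- summary(stats::aov(fml, data = d))[[1L]][["Mean Sq"]]
  msb <- ms[1L]; msw <- ms[2L]
  list(icc = (msb - msw) / (msb + msw), n_pairs = length(keep),
       ms_between = msb, ms_within = msw)
}

#' ICC table by zygosity-by-sex group
#'
#' @param data per-individual table with `pair_id`, `sex`, `zygosity`,
#'   `opposite_sex` and trait columns.
#' @param traits trait column names.
#' @return data frame with `trait`, `group`, `icc`, `n_pairs`.
#' @export
icc_table <- function(data, traits) {
  data$group <- ifelse(data$opposite_sex, "DZOS",
                       paste0(data$zygosity, data$sex))
  rows <- list()
  for (tr in traits) for (g in intersect(GROUP_LABELS, unique(data$group))) {
    res <- tryCatch(compute_icc(data[data$group == g, ], tr),
                    error = function(e) NULL)
    if (is.null(res)) next
    rows[[paste(tr, g)]] <- data.frame(trait = tr, group = g,
                                       icc = res$icc,
                                       n_pairs = res$n_pairs,
                                       stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Heuristic model suggestion from MZ/DZ intraclass correlations
#'
#' The classical reading of the twin correlations: dominance (ADE) is
#' suggested when `rDZ < rMZ / 2`, shared environment (ACE) when
#' `rDZ > rMZ / 2`, and the parsimonious AE when `rDZ` is within a
#' tolerance band of exactly half `rMZ`. A heuristic only — model choice
#' is settled by likelihood comparison, never by this rule.
#'
#' @param icc_mz,icc_dz MZ and DZ intraclass correlations.
#' @param tol half-width of the AE band around `rMZ / 2`.
#' @return one of `"AE-leaning"`, `"ADE-leaning"`, `"ACE-leaning"`.
#' @export
suggest_model <- function(icc_mz, icc_dz, tol = 0.05) {
  half <- icc_mz / 2
  if (abs(icc_dz - half) <= tol) "AE-leaning"
  else if (icc_dz < half) "ADE-leaning"
  else "ACE-leaning"
}
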