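# Synthetic twin-cohort generator. Emulates a five-wave longitudinal BMI
# study of MZ and DZ (same- and opposite-sex) twin pairs: four latent traits
# (BMI at the first two waves plus an adult trajectory intercept and slope)
# with an additive-genetic / unique-environment architecture, longitudinal
# observations derived from the trajectory traits, and a polygenic score
# loading on the first genetic factor.

GROUP_LABELS <- c("MZM", "MZF", "DZM", "DZF", "DZOS")

#' Construct lower-triangular component loadings from variance shares
#'
#' Builds the Cholesky factor of a component covariance matrix
#' `diag(sqrt(share) * sd) %*% R %*% diag(sqrt(share) * sd)` so that
#' generating architectures can be specified on the interpretable scale of
#' per-trait variance shares and cross-trait component correlations.
#'
#' @param share numeric vector of per-trait variance shares in `[0, 1]`.
#' @param sds per-trait phenotypic standard deviations.
#' @param R component correlation matrix (defaults to identity).
#' @return a lower-triangular loading matrix `T` with `T %*% t(T)` equal to
#'   the implied component covariance.
#' @export
component_loadings <- function(share, sds, R = diag(length(share))) {
  k <- length(share)
  stopifnot(length(sds) == k, nrow(R) == k, ncol(R) == k)
  d <- sqrt(share) * sds
  Sigma <- diag(d, k) %*% R %*% diag(d, k)
  if (all(d == 0)) return(matrix(0, k, k))
  ok <- d > 0
  Tm <- matrix(0, k, k)
  if (any(ok)) {
    Tm[ok, ok] <- t(chol(Sigma[ok, ok, drop = FALSE]))
  }
  Tm
}

default_trait_architecture <- function() {
  labels <- c("bmi11.5", "bmi14", "intercept", "slope")
  sym <- function(M, i, j, v) { M[i, j] <- v; M[j, i] <- v; M }
  rA <- diag(4)
  rA <- sym(rA, 1, 2, 0.85); rA <- sym(rA, 1, 3, 0.74); rA <- sym(rA, 1, 4, 0.44)
  rA <- sym(rA, 2, 3, 0.83); rA <- sym(rA, 2, 4, 0.50); rA <- sym(rA, 3, 4, 0.52)
  rE <- diag(4)
  rE <- sym(rE, 1, 2, 0.35); rE <- sym(rE, 1, 3, 0.29); rE <- sym(rE, 1, 4, 0.12)
  rE <- sym(rE, 2, 3, 0.34); rE <- sym(rE, 2, 4, 0.10); rE <- sym(rE, 3, 4, 0.01)
  a2 <- c(0.84, 0.84, 0.80, 0.635)
  sds <- c(2.56, 2.65, 2.77, 0.10)
  list(labels = labels,
       T_A = component_loadings(a2, sds, rA),
       T_E = component_loadings(1 - a2, sds, rE))
}

#' Simulation configuration for a synthetic twin cohort
#'
#' Defaults describe a five-wave BMI follow-up: mean observation ages about
#' 11.5, 14, 17.5, 24 and 37 years, sex-specific trait means, and an
#' AE architecture (heritabilities around 0.8 for the BMI levels and 0.64
#' for the adult slope) with cross-trait genetic correlations in the
#' 0.44-0.85 range. Loading matrices may be a single matrix (shared by both
#' sexes) or a `list(M = , F = )` pair for sex-limitation scenarios.
#'
#' @param n_pairs_per_group named count of twin pairs per zygosity-by-sex
#'   group (`MZM`, `MZF`, `DZM`, `DZF`, `DZOS`).
#' @param trait_labels ordered trait names; the default four are BMI at the
#'   first two waves plus the adult trajectory intercept and slope.
#' @param true_paths_A,true_paths_C,true_paths_E lower-triangular `k x k`
#'   loading matrices (or per-sex lists) for the additive-genetic, shared-
#'   environment and unique-environment components.
#' @param fixed_means `2 x k` matrix of per-sex trait means (rows `M`, `F`).
#' @param wave_ages list of `c(mean, sd)` observation-age pairs, one per wave.
#' @param obs_residual_sd within-person measurement noise (kg/m^2) added to
#'   the adult-wave observations generated from intercept and slope.
#' @param prs_loading correlation of the polygenic score with the first
#'   genetic factor, in `[0, 1]`.
#' @param missing_rate per-observation missingness probability in `[0, 1)`.
#' @param bmi_window plausibility window for generated BMI (kg/m^2).
#' @param seed integer seed; `simulate_cohort` is deterministic given it.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(n_pairs_per_group = c(MZM = 100, MZF = 100,
                                                    DZM = 100, DZF = 100,
                                                    DZOS = 100),
                              trait_labels = NULL,
                              true_paths_A = NULL,
                              true_paths_C = NULL,
                              true_paths_E = NULL,
                              fixed_means = NULL,
                              wave_ages = list(c(11.42, 0.30), c(14.04, 0.08),
                                               c(17.62, 0.26), c(24.22, 1.64),
                                               c(37.17, 1.47)),
                              obs_residual_sd = 0.5,
                              prs_loading = 0.35,
                              missing_rate = 0,
                              bmi_window = c(10, 60),
                              seed = 1L) {
  arch <- default_trait_architecture()
  if (is.null(trait_labels)) trait_labels <- arch$labels
  k <- length(trait_labels)
  if (is.null(true_paths_A)) {
    if (k != 4L) stop("true_paths_A must be supplied for non-default traits")
    true_paths_A <- arch$T_A
  }
  if (is.null(true_paths_E)) {
    if (k != 4L) stop("true_paths_E must be supplied for non-default traits")
    true_paths_E <- arch$T_E
  }
  if (is.null(true_paths_C)) true_paths_C <- matrix(0, k, k)
  if (is.null(fixed_means)) {
    if (k == 4L) {
      fixed_means <- rbind(M = c(17.71, 19.34, 21.77, 0.24),
                           F = c(17.54, 19.35, 20.99, 0.22))
    } else {
      fixed_means <- rbind(M = rep(0, k), F = rep(0, k))
    }
  }
  colnames(fixed_means) <- trait_labels
  cfg <- structure(list(
    n_pairs_per_group = n_pairs_per_group,
    trait_labels = trait_labels,
    true_paths_A = true_paths_A,
    true_paths_C = true_paths_C,
    true_paths_E = true_paths_E,
    fixed_means = fixed_means,
    wave_ages = wave_ages,
    obs_residual_sd = obs_residual_sd,
    prs_loading = prs_loading,
    missing_rate = missing_rate,
    bmi_window = bmi_window,
    seed = as.integer(seed)
  ), class = "simulation_config")
  validate_simulation_config(cfg)
  cfg
}

paths_for_sex <- function(x, sex) {
  if (is.list(x) && !is.matrix(x)) x[[sex]] else x
}

validate_simulation_config <- function(cfg) {
  k <- length(cfg$trait_labels)
  grp <- cfg$n_pairs_per_group
  if (!all(names(grp) %in% GROUP_LABELS) || any(grp < 0))
    stop("n_pairs_per_group must be non-negative counts named among ",
         paste(GROUP_LABELS, collapse = ", "))
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)")
  if (cfg$prs_loading < 0 || cfg$prs_loading > 1)
    stop("prs_loading must lie in [0, 1]")
  for (sex in c("M", "F")) {
    for (comp in c("A", "C", "E")) {
      Tm <- paths_for_sex(cfg[[paste0("true_paths_", comp)]], sex)
      if (!is.matrix(Tm) || nrow(Tm) != k || ncol(Tm) != k)
        stop("true_paths_", comp, " has wrong dimension: expected ", k,
             " rows matching trait_labels")
      if (any(abs(Tm[upper.tri(Tm)]) > 1e-12))
        stop("true_paths_", comp, " must be lower-triangular")
    }
    tot <- implied_total_variance(cfg, sex)
    if (any(tot <= 0))
      stop("implied total variance non-positive for trait '",
           cfg$trait_labels[which(tot <= 0)[1L]], "'")
  }
  invisible(cfg)
}

implied_component_cov <- function(cfg, sex, comp) {
  Tm <- paths_for_sex(cfg[[paste0("true_paths_", comp)]], sex)
  tcrossprod(Tm)
}

implied_total_variance <- function(cfg, sex) {
  diag(implied_component_cov(cfg, sex, "A") +
       implied_component_cov(cfg, sex, "C") +
       implied_component_cov(cfg, sex, "E"))
}

simulation_truth <- function(cfg) {
  per_sex <- lapply(c(M = "M", F = "F"), function(sex) {
    SA <- implied_component_cov(cfg, sex, "A")
    SC <- implied_component_cov(cfg, sex, "C")
    SE <- implied_component_cov(cfg, sex, "E")
    Stot <- SA + SC + SE
    safe_cor <- function(S) {
      d <- sqrt(diag(S))
      out <- S / outer(d, d)
      out[!is.finite(out)] <- NA_real_
      out
    }
    list(a2 = diag(SA) / diag(Stot),
         c2 = diag(SC) / diag(Stot),
         e2 = diag(SE) / diag(Stot),
         r_A = safe_cor(SA), r_C = safe_cor(SC), r_E = safe_cor(SE),
         Sigma_A = SA, Sigma_C = SC, Sigma_E = SE, Sigma = Stot,
         mz_cross_cov = SA + SC,
         dz_cross_cov = 0.5 * SA + SC)
  })
  structure(list(config = cfg, per_sex = per_sex), class = "simulation_truth")
}

#' Simulate a twin cohort with known genetic architecture
#'
#' Draws latent additive-genetic (A), shared-environment (C) and unique-
#' environment (E) factor vectors per twin — A identical within MZ pairs and
#' correlated 0.5 within DZ pairs via a `sqrt(0.5)`-shared / `sqrt(0.5)`-
#' unique construction, C identical within pairs, E independent — and maps
#' them through the configured lower-triangular loadings to trait values.
#' With the default trait set, a five-wave longitudinal table is also built:
#' the first two waves observe the adolescent BMI traits directly and the
#' adult waves are generated from each individual's intercept and slope as
#' `bmi(age) = intercept + slope * (age - 17.5) + N(0, obs_residual_sd)`.
#' A polygenic score is generated as
#' `prs_loading * A1 + sqrt(1 - prs_loading^2) * noise` and standardized.
#'
#' @param config a [simulation_config()].
#' @return a list of class `twin_cohort` with elements `traits` (wide
#'   per-individual trait table), `phenotypes` (long wave table or `NULL`
#'   for non-default traits), `prs`, `pcs`, and `truth`
#'   (implied variance shares, component correlations, cross-twin
#'   covariances).
#' @export
simulate_cohort <- function(config) {
  cfg <- validate_simulation_config(config)
  set.seed(cfg$seed)
  k <- length(cfg$trait_labels)
  grp_counts <- cfg$n_pairs_per_group[cfg$n_pairs_per_group > 0]

  group_frames <- list()
  pair_offset <- 0L
  for (g in names(grp_counts)) {
    n <- grp_counts[[g]]
    zyg <- if (startsWith(g, "MZ")) "MZ" else "DZ"
    os <- identical(g, "DZOS")
    sexes <- switch(g,
      MZM = c("M", "M"), MZF = c("F", "F"),
      DZM = c("M", "M"), DZF = c("F", "F"), DZOS = c("M", "F"))
    A_sh <- matrix(stats::rnorm(n * k), n, k)
    C_sh <- matrix(stats::rnorm(n * k), n, k)
    latA <- vector("list", 2L)
    vals <- vector("list", 2L)
    for (b in 1:2) {
      sex <- sexes[b]
      A <- if (zyg == "MZ") A_sh else
        sqrt(0.5) * A_sh + sqrt(0.5) * matrix(stats::rnorm(n * k), n, k)
      E <- matrix(stats::rnorm(n * k), n, k)
      V <- A %*% t(paths_for_sex(cfg$true_paths_A, sex)) +
        C_sh %*% t(paths_for_sex(cfg$true_paths_C, sex)) +
        E %*% t(paths_for_sex(cfg$true_paths_E, sex))
      V <- sweep(V, 2L, cfg$fixed_means[sex, ], "+")
      latA[[b]] <- A[, 1L]
      vals[[b]] <- V
    }
    pair_id <- sprintf("P%05d", pair_offset + seq_len(n))
    pair_offset <- pair_offset + n
    gf <- data.frame(
      individual_id = paste0(rep(pair_id, each = 2L), "_", rep(1:2, n)),
      pair_id = rep(pair_id, each = 2L),
      birth_order = rep(1:2, n),
      sex = rep(sexes, n),
      zygosity = zyg, opposite_sex = os, group = g,
      stringsAsFactors = FALSE)
    interleave <- function(x1, x2) {
      out <- matrix(NA_real_, 2L * n, NCOL(x1))
      out[seq(1L, 2L * n, by = 2L), ] <- as.matrix(x1)
      out[seq(2L, 2L * n, by = 2L), ] <- as.matrix(x2)
      out
    }
    vmat <- interleave(vals[[1L]], vals[[2L]])
    for (j in seq_len(k)) gf[[cfg$trait_labels[j]]] <- vmat[, j]
    gf$.A1 <- drop(interleave(latA[[1L]], latA[[2L]]))
    group_frames[[g]] <- gf
  }
  traits <- do.call(rbind, group_frames)
  rownames(traits) <- NULL
  a1 <- traits$.A1
  traits$.A1 <- NULL

  phenotypes <- NULL
  default_labels <- c("bmi11.5", "bmi14", "intercept", "slope")
  if (all(default_labels %in% cfg$trait_labels) &&
      length(cfg$wave_ages) == 5L) {
    # ages drawn per pair (co-twins share a birth date and survey time)
    pair_ids <- unique(traits$pair_id)
    ages <- sapply(cfg$wave_ages, function(wa) {
      z <- stats::rnorm(length(pair_ids))
      z <- pmin(pmax(z, -3), 3)
      wa[1L] + wa[2L] * z
    })
    nind <- nrow(traits)
    age_mat <- ages[match(traits$pair_id, pair_ids), , drop = FALSE]
    bmi_adult <- traits$intercept +
      traits$slope * (age_mat[, 3:5, drop = FALSE] - 17.5) +
      matrix(stats::rnorm(nind * 3L, 0, cfg$obs_residual_sd), nind, 3L)
    bmi_mat <- cbind(traits$bmi11.5, traits$bmi14, bmi_adult)
    bmi_mat <- pmin(pmax(bmi_mat, cfg$bmi_window[1L]), cfg$bmi_window[2L])
    ph <- data.frame(
      individual_id = rep(traits$individual_id, each = 5L),
      pair_id = rep(traits$pair_id, each = 5L),
      birth_order = rep(traits$birth_order, each = 5L),
      sex = rep(traits$sex, each = 5L),
      zygosity = rep(traits$zygosity, each = 5L),
      opposite_sex = rep(traits$opposite_sex, each = 5L),
      wave = rep(1:5, nind),
      age = as.vector(t(age_mat)),
      bmi = as.vector(t(bmi_mat)),
      stringsAsFactors = FALSE)
    if (cfg$missing_rate > 0) {
      drop <- stats::runif(nrow(ph)) < cfg$missing_rate
      ph <- ph[!drop, , drop = FALSE]
      rownames(ph) <- NULL
    }
    phenotypes <- ph
  }

  lam <- cfg$prs_loading
  raw <- lam * a1 + sqrt(1 - lam^2) * stats::rnorm(length(a1))
  prs <- data.frame(individual_id = traits$individual_id,
                    family_id = traits$pair_id,
                    score = as.numeric(scale(raw)),
                    stringsAsFactors = FALSE)
  pcs <- data.frame(individual_id = prs$individual_id,
                    stringsAsFactors = FALSE)
  for (j in 1:10) pcs[[paste0("PC", j)]] <- stats::rnorm(nrow(pcs))

  structure(list(traits = traits, phenotypes = phenotypes, prs = prs,
                 pcs = pcs, truth = simulation_truth(cfg)),
            class = "twin_cohort")
}

#' Write a simulated cohort to plain-text files
#'
#' Emits `phenotypes.csv` (long wave table), `traits.csv`, `prs.tsv`,
#' `pcs.tsv` and `truth.json` under `dir`.
#'
#' @param cohort a `twin_cohort` from [simulate_cohort()].
#' @param dir output directory (created if absent).
#' @return invisibly, the named vector of file paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(phenotypes = file.path(dir, "phenotypes.csv"),
             traits = file.path(dir, "traits.csv"),
             prs = file.path(dir, "prs.tsv"),
             pcs = file.path(dir, "pcs.tsv"),
             truth = file.path(dir, "truth.json"))
  if (!is.null(cohort$phenotypes))
    utils::write.csv(cohort$phenotypes, paths["phenotypes"], row.names = FALSE)
  utils::write.csv(cohort$traits, paths["traits"], row.names = FALSE)
  utils::write.table(cohort$prs, paths["prs"], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(cohort$pcs, paths["pcs"], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  tr <- cohort$truth
  jsonlite::write_json(list(
    trait_labels = tr$config$trait_labels,
    per_sex = lapply(tr$per_sex, function(s)
      lapply(s, function(x) unname(as.matrix(x))))),
    paths["truth"], digits = NA, auto_unbox = TRUE)
  invisible(paths)
}

#' @export
print.twin_cohort <- function(x, ...) {
  cat("Simulated twin cohort:", length(unique(x$traits$pair_id)), "pairs,",
      nrow(x$traits), "individuals\n")
  pairs_per_group <- table(x$traits$group) / 2L
  cat("Pairs per group:", paste(names(pairs_per_group), pairs_per_group,
                                sep = "=", collapse = ", "), "\n")
  if (!is.null(x$phenotypes))
    cat("Longitudinal observations:", nrow(x$phenotypes), "\n")
  invisible(x)
}
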