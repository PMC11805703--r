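# Small cohort constructors shared across tests. All fixtures are built in
# code; nothing is read from disk except the packaged reference means.

# Single-trait AE cohort (MZ + DZ male groups), unit trait variance.
ae_cohort <- function(a2, n_pairs, seed, sexes = c("MZM", "DZM"),
                      e2 = 1 - a2) {
  npg <- stats::setNames(rep(n_pairs, length(sexes)), sexes)
  cfg <- simulation_config(
    n_pairs_per_group = npg, trait_labels = "y",
    true_paths_A = matrix(sqrt(a2)), true_paths_E = matrix(sqrt(e2)),
    true_paths_C = matrix(0),
    fixed_means = rbind(M = 0, F = 0), seed = seed)
  simulate_cohort(cfg)
}

# Single-trait CE cohort: rMZ = rDZ = c2 by construction.
ce_cohort <- function(c2, n_pairs, seed) {
  cfg <- simulation_config(
    n_pairs_per_group = c(MZM = n_pairs, DZM = n_pairs), trait_labels = "y",
    true_paths_A = matrix(0), true_paths_C = matrix(sqrt(c2)),
    true_paths_E = matrix(sqrt(1 - c2)),
    fixed_means = rbind(M = 0, F = 0), seed = seed)
  simulate_cohort(cfg)
}

# Two-trait AE cohort with chosen genetic/environmental correlations.
ae2_cohort <- function(a2 = c(0.6, 0.6), rA = 0.6, rE = 0.1, n_pairs = 500,
                       seed = 1, sexes = c("MZM", "DZM")) {
  RA <- matrix(c(1, rA, rA, 1), 2)
  RE <- matrix(c(1, rE, rE, 1), 2)
  npg <- stats::setNames(rep(n_pairs, length(sexes)), sexes)
  cfg <- simulation_config(
    n_pairs_per_group = npg, trait_labels = c("t1", "t2"),
    true_paths_A = component_loadings(a2, c(1, 1), RA),
    true_paths_E = component_loadings(1 - a2, c(1, 1), RE),
    fixed_means = rbind(M = c(0, 0), F = c(0, 0)), seed = seed)
  simulate_cohort(cfg)
}

reference_means <- function() {
  utils::read.csv(system.file("extdata", "wave_means_reference.csv",
                              package = "twintraj"))
}

# Closed-form one-way ANOVA intraclass correlation for a complete
# n x 2 pair matrix (independent arithmetic oracle; avoids a factor with
# one level per pair in aov at large n).
icc_pairs <- function(X) {
  pm <- rowMeans(X)
  msb <- 2 * stats::var(pm)
  msw <- sum((X[, 1] - X[, 2])^2 / 2) / nrow(X)
  (msb - msw) / (msb + msw)
}
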