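test_that("regeneration with the same seed is bit-identical, different seeds differ", {
  cfg <- simulation_config(n_pairs_per_group = c(MZM = 30, DZF = 30),
                           seed = 42)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1, s2)
  cfg2 <- cfg; cfg2$seed <- 43L
  s3 <- simulate_cohort(cfg2)
  expect_false(identical(s1$traits$bmi14, s3$traits$bmi14))
})

test_that("MZ co-twins are identical when the unique environment is removed", {
  cfg <- simulation_config(
    n_pairs_per_group = c(MZM = 50), trait_labels = "y",
    true_paths_A = matrix(1), true_paths_E = matrix(0),
    fixed_means = rbind(M = 0, F = 0), seed = 7)
  sim <- simulate_cohort(cfg)
  w <- reshape(sim$traits[, c("pair_id", "birth_order", "y")],
               idvar = "pair_id", timevar = "birth_order",
               direction = "wide")
  expect_lt(max(abs(w$y.1 - w$y.2)), 1e-10)
})

test_that("without familial components cross-twin correlations vanish", {
  cfg <- simulation_config(
    n_pairs_per_group = c(MZM = 2000, DZM = 2000), trait_labels = "y",
    true_paths_A = matrix(0), true_paths_C = matrix(0),
    true_paths_E = matrix(1), fixed_means = rbind(M = 0, F = 0), seed = 5)
  sim <- simulate_cohort(cfg)
  g <- build_twin_groups(sim$traits, "y")
  for (gg in g) {
    r <- cor(gg$X[, 1], gg$X[, 2])
    expect_lt(abs(r), 3 / sqrt(gg$n_pairs))
  }
})

test_that("an AE trait reproduces rMZ = a2 and rDZ = a2/2 within sampling error", {
  sim <- ae_cohort(a2 = 0.84, n_pairs = 2000, seed = 11)
  g <- build_twin_groups(sim$traits, "y")
  z_tol <- 3 / sqrt(2000 - 3)
  r_mz <- cor(g$MZM$X[, 1], g$MZM$X[, 2])
  r_dz <- cor(g$DZM$X[, 1], g$DZM$X[, 2])
  expect_lt(abs(atanh(r_mz) - atanh(0.84)), z_tol)
  expect_lt(abs(atanh(r_dz) - atanh(0.42)), z_tol)
})

test_that("the truth manifest satisfies its structural identities", {
  sim <- simulate_cohort(simulation_config(
    n_pairs_per_group = c(MZM = 5, DZOS = 5), seed = 3))
  for (sx in c("M", "F")) {
    tr <- sim$truth$per_sex[[sx]]
    expect_lt(max(abs(tr$a2 + tr$c2 + tr$e2 - 1)), 1e-10)
    # DZ cross-twin genetic covariance is half the MZ one, element-wise
    expect_lt(max(abs((tr$dz_cross_cov - tr$Sigma_C) -
                        0.5 * (tr$mz_cross_cov - tr$Sigma_C))), 1e-10)
  }
})

test_that("empirical cross-twin covariances converge to the implied values", {
  sim <- ae_cohort(a2 = 0.6, n_pairs = 5000, seed = 17)
  g <- build_twin_groups(sim$traits, "y")
  # SE of a covariance of unit-variance traits is ~ sqrt((1 + r^2) / n)
  for (lbl in c("MZM", "DZM")) {
    truth <- if (lbl == "MZM") 0.6 else 0.3
    emp <- cov(g[[lbl]]$X[, 1], g[[lbl]]$X[, 2])
    se <- sqrt((1 + truth^2) / g[[lbl]]$n_pairs)
    expect_lt(abs(emp - truth), 3 * se)
  }
})

test_that("with zero missingness every individual has all waves", {
  sim <- simulate_cohort(simulation_config(
    n_pairs_per_group = c(MZF = 40, DZOS = 40), missing_rate = 0, seed = 9))
  waves_per_ind <- table(sim$phenotypes$individual_id)
  expect_true(all(waves_per_ind == 5L))
  # and generated BMI respects the plausibility window
  expect_true(all(sim$phenotypes$bmi >= 10 & sim$phenotypes$bmi <= 60))
  # MZ pairs are same-sex, each pair has exactly two members
  mz <- sim$traits[sim$traits$zygosity == "MZ", ]
  expect_true(all(tapply(mz$sex, mz$pair_id,
                         function(s) length(unique(s))) == 1L))
  expect_true(all(table(sim$traits$pair_id) == 2L))
})

test_that("invalid configurations are rejected with informative errors", {
  expect_error(simulation_config(missing_rate = 1.2), "missing_rate")
  expect_error(simulation_config(n_pairs_per_group = c(MZM = -1)),
               "non-negative")
  expect_error(simulation_config(trait_labels = c("a", "b"),
                                 true_paths_A = matrix(1),
                                 true_paths_E = diag(2)),
               "dimension|rows")
  # non-lower-triangular loadings rejected
  expect_error(simulation_config(
    trait_labels = c("a", "b"),
    true_paths_A = matrix(c(1, 0.5, 0.5, 1), 2),
    true_paths_E = diag(2),
    fixed_means = rbind(M = c(0, 0), F = c(0, 0))),
    "lower-triangular")
  # zero total variance names the offending trait
  expect_error(simulation_config(
    trait_labels = c("a", "b"),
    true_paths_A = diag(c(1, 0)), true_paths_E = diag(c(1, 0)),
    fixed_means = rbind(M = c(0, 0), F = c(0, 0))),
    "'b'")
})

test_that("the polygenic score is standardized and tracks the first genetic factor", {
  sim <- ae_cohort(a2 = 0.64, n_pairs = 1500, seed = 23)
  expect_equal(mean(sim$prs$score), 0, tolerance = 1e-12)
  expect_equal(var(sim$prs$score), 1, tolerance = 1e-12)
  d <- merge(sim$prs, sim$traits, by = "individual_id")
  r <- cor(d$score, d$y)
  expect_lt(abs(r - 0.35 * sqrt(0.64)), 3 / sqrt(nrow(d) - 3))
})
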