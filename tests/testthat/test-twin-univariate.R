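test_that("saturated -2LL matches the closed-form bivariate Gaussian value", {
  sim <- ae_cohort(a2 = 0.5, n_pairs = 300, seed = 2)
  g <- build_twin_groups(sim$traits, "y")
  sat <- fit_saturated(g)
  for (lbl in names(g)) {
    X <- g[[lbl]]$X
    n <- nrow(X); m <- colMeans(X)
    S <- crossprod(sweep(X, 2, m)) / n
    oracle <- n * (2 * log(2 * pi) + log(det(S)) + 2)
    expect_equal(sat$per_group[[lbl]]$m2ll, oracle, tolerance = 1e-10)
  }
  # permuting pair order leaves the likelihood unchanged
  g2 <- g
  set.seed(1)
  g2$MZM$X <- g2$MZM$X[sample(nrow(g2$MZM$X)), ]
  expect_equal(fit_saturated(g2)$minus2LL, sat$minus2LL, tolerance = 1e-10)
})

test_that("a degenerate group (twin1 == twin2) is flagged, not crashed", {
  y <- rnorm(20, 22, 2)
  d <- data.frame(individual_id = paste0("P", rep(1:20, each = 2), "_",
                                         rep(1:2, 20)),
                  pair_id = paste0("P", rep(1:20, each = 2)),
                  birth_order = rep(1:2, 20), sex = "M", zygosity = "MZ",
                  opposite_sex = FALSE, y = rep(y, each = 2))
  g <- build_twin_groups(d, "y")
  expect_warning(sat <- fit_saturated(g), "singular")
  expect_identical(sat$singular_groups, "MZM")
  expect_true(is.na(sat$minus2LL))
})

test_that("FIML equals the direct complete-data likelihood and handles missingness", {
  sim <- ae_cohort(a2 = 0.6, n_pairs = 200, seed = 13)
  g <- build_twin_groups(sim$traits, "y")
  fit <- fit_variance_components(g, twin_model_spec(c("A", "E"),
                                                    "no_sex_difference"))
  # recompute the fitted -2LL row by row (independent of sufficient stats)
  model <- twintraj:::uv_assemble(fit$par, fit$spec, fit$tmpl)
  direct <- 0
  for (gg in g) {
    mom <- twintraj:::uv_group_moments(model, gg)
    direct <- direct + twintraj:::fiml_m2ll_rowwise(gg$X, mom$mu, mom$Sigma)
  }
  expect_equal(fit$minus2LL, direct, tolerance = 1e-8)
  # knock out some co-twins: FIML still fits, -2LL decomposes by pattern
  Xm <- g$MZM$X; Xm[1:40, 2] <- NA
  g$MZM$X <- Xm
  fit_m <- fit_variance_components(g, twin_model_spec(c("A", "E"),
                                                      "no_sex_difference"))
  expect_true(fit_m$converged)
  expect_lt(abs(fit_m$shares["A", "M"] - fit$shares["A", "M"]), 0.1)
})

test_that("ML AE estimates agree with the Falconer moment oracle", {
  # both estimators are consistent for a2; at n = 50000 pairs/group their
  # sampling difference (SD ~ 0.009) sits well inside the 0.03 band
  sim <- ae_cohort(a2 = 0.7, n_pairs = 50000, seed = 19)
  g <- build_twin_groups(sim$traits, "y")
  fit <- fit_variance_components(g, twin_model_spec(c("A", "E"),
                                                    "no_sex_difference"))
  # the classical rMZ/rDZ are ANOVA intraclass correlations
  fal <- falconer_estimate(icc_pairs(g$MZM$X), icc_pairs(g$DZM$X))
  expect_lt(abs(fit$shares["A", "M"] - fal["a2"]), 0.03)
  expect_lt(abs(fit$shares["A", "M"] - 0.7), 0.03)
})

test_that("CE data fit with ACE recovers a2 ~ 0 and c2 ~ the truth", {
  sim <- ce_cohort(c2 = 0.5, n_pairs = 2000, seed = 29)
  g <- build_twin_groups(sim$traits, "y")
  fit <- fit_variance_components(g, twin_model_spec(c("A", "C", "E"),
                                                    "no_sex_difference"))
  expect_lt(fit$shares["A", "M"], 0.05)
  expect_lt(abs(fit$shares["C", "M"] - 0.5), 0.05)
})

test_that("the E-only model reduces to independent normals", {
  sim <- ae_cohort(a2 = 0.4, n_pairs = 150, seed = 37)
  g <- build_twin_groups(sim$traits, "y")
  fit <- fit_variance_components(g, twin_model_spec("E",
                                                    "no_sex_difference"))
  y <- unlist(lapply(g, function(gg) as.vector(gg$X)))
  v_ml <- mean((y - mean(y))^2)
  oracle <- length(y) * (log(2 * pi) + log(v_ml) + 1)
  expect_equal(fit$minus2LL, oracle, tolerance = 1e-6)
})

test_that("nested models never beat their reference and comparisons behave", {
  sim <- ae_cohort(a2 = 0.6, n_pairs = 400, seed = 41)
  g <- build_twin_groups(sim$traits, "y")
  ace <- fit_variance_components(g, twin_model_spec(c("A", "C", "E"),
                                                    "no_sex_difference"))
  ae <- fit_variance_components(g, twin_model_spec(c("A", "E"),
                                                   "no_sex_difference"))
  e <- fit_variance_components(g, twin_model_spec("E", "no_sex_difference"))
  expect_gte(ae$minus2LL - ace$minus2LL, -1e-4)
  expect_gte(e$minus2LL - ae$minus2LL, -1e-4)
  cmp <- compare_models(list(ae, e), reference = ace)
  expect_s3_class(cmp, "model_comparison")
  expect_true(all(cmp$delta_minus2LL[-1] >= -1e-4))
  # true a2 = 0.6: E-only should be rejected, AE selected over ACE
  expect_lt(cmp$p[cmp$model == "E/no_sex_difference"], 1e-6)
  expect_identical(attr(cmp, "selected"), "AE/no_sex_difference")
  # identical model vs itself: delta 0, p = 1
  self_cmp <- compare_models(list(ace), reference = ace)
  expect_equal(self_cmp$delta_minus2LL[2], 0, tolerance = 1e-10)
  expect_equal(self_cmp$p[2], 1)
  # mismatched data rejected
  sim2 <- ae_cohort(a2 = 0.6, n_pairs = 400, seed = 43)
  g2 <- build_twin_groups(sim2$traits, "y")
  ae2 <- fit_variance_components(g2, twin_model_spec(c("A", "E"),
                                                     "no_sex_difference"))
  expect_error(compare_models(list(ae2), reference = ace), "fingerprint")
  # a model with more parameters than the reference is not nested
  expect_error(compare_models(list(ace), reference = ae), "not nested")
})

test_that("birth-order mean shifts are detected by the assumption test", {
  sim <- ae_cohort(a2 = 0.5, n_pairs = 500, seed = 47)
  tr <- sim$traits
  tr$y[tr$birth_order == 2] <- tr$y[tr$birth_order == 2] + 5
  g <- build_twin_groups(tr, "y")
  cmp <- test_assumptions(g, spec = twin_model_spec(c("A", "C", "E"),
                                                    "no_sex_difference"))
  con_row <- cmp[cmp$model == "saturated_constrained", ]
  expect_lt(con_row$p, 0.001)
  expect_true(con_row$violation)
})

test_that("sex-limitation: halved female paths reject the no-sex-difference model", {
  a_m <- sqrt(0.8); a_f <- a_m / 2
  cfg <- simulation_config(
    n_pairs_per_group = c(MZM = 1000, MZF = 1000, DZM = 1000, DZF = 1000),
    trait_labels = "y",
    true_paths_A = list(M = matrix(a_m), F = matrix(a_f)),
    true_paths_E = list(M = matrix(sqrt(0.2)), F = matrix(sqrt(0.2))),
    fixed_means = rbind(M = 0, F = 0), seed = 53)
  sim <- simulate_cohort(cfg)
  g <- build_twin_groups(sim$traits, "y")
  full <- fit_variance_components(g, twin_model_spec(c("A", "E"), "full"))
  nosex <- fit_variance_components(g, twin_model_spec(c("A", "E"),
                                                      "no_sex_difference"))
  cmp <- compare_models(list(nosex), reference = full)
  expect_lt(cmp$p[2], 0.01)
  expect_gt(full$shares["A", "M"], full$shares["A", "F"])
})

test_that("estimates are invariant to relabeling co-twins under exchangeability", {
  sim <- ae_cohort(a2 = 0.6, n_pairs = 300, seed = 59)
  g <- build_twin_groups(sim$traits, "y")
  fit1 <- fit_variance_components(g, twin_model_spec(c("A", "E"),
                                                     "no_sex_difference"))
  g$MZM$X <- g$MZM$X[, 2:1]
  g$DZM$X <- g$DZM$X[, 2:1]
  fit2 <- fit_variance_components(g, twin_model_spec(c("A", "E"),
                                                     "no_sex_difference"))
  expect_equal(fit1$shares, fit2$shares, tolerance = 1e-6)
  expect_equal(fit1$minus2LL, fit2$minus2LL, tolerance = 1e-8)
})

test_that("profile CIs bracket the estimate, nest across levels, and flag boundaries", {
  sim <- ae_cohort(a2 = 0.8, n_pairs = 500, seed = 61)
  g <- build_twin_groups(sim$traits, "y")
  fit <- fit_variance_components(g, twin_model_spec(c("A", "E"),
                                                    "no_sex_difference"))
  ci95 <- profile_ci(fit, "A", "both", level = 0.95)
  ci99 <- profile_ci(fit, "A", "both", level = 0.99)
  expect_lte(ci95$lower, ci95$estimate)
  expect_gte(ci95$upper, ci95$estimate)
  expect_true(ci95$lower >= 0 && ci95$upper <= 1)
  expect_lte(ci99$lower, ci95$lower)
  expect_gte(ci99$upper, ci95$upper)
  # a component at the boundary: fit ACE to CE-free AE data -> c2 ~ 0
  ace <- fit_variance_components(g, twin_model_spec(c("A", "C", "E"),
                                                    "no_sex_difference"))
  ci_c <- profile_ci(ace, "C", "both")
  expect_equal(ci_c$lower, 0)
  expect_true(ci_c$lower_at_boundary)
})

test_that("model specification rules are enforced", {
  expect_error(twin_model_spec(c("A", "C", "D", "E")), "simultaneously")
  expect_error(twin_model_spec(c("A", "C")), "mandatory")
  expect_error(twin_model_spec("Q"), "subset")
  spec <- twin_model_spec(c("E", "A"))
  expect_identical(spec$components, c("A", "E"))
})
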