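# A tiny deterministic long table: n individuals with known intercepts and
# slopes observed at the three adult waves.
make_lines <- function(intercepts, slopes, noise_sd = 0, seed = 1,
                       ages = c(17.5, 24, 37)) {
  set.seed(seed)
  n <- length(intercepts)
  data.frame(
    individual_id = rep(sprintf("I%03d", seq_len(n)), each = length(ages)),
    sex = rep(rep(c("M", "F"), length.out = n), each = length(ages)),
    wave = rep(seq(3, 2 + length(ages)), n),
    age = rep(ages, n),
    bmi = rep(intercepts, each = length(ages)) +
      rep(slopes, each = length(ages)) * (rep(ages, n) - 17.5) +
      rnorm(n * length(ages), 0, noise_sd))
}

test_that("complete-individual selection retains exactly the fully observed", {
  d <- make_lines(rep(22, 10), rep(0.2, 10))
  expect_message(out <- select_complete_individuals(d), "0 of 10")
  expect_identical(out, d)
  # remove wave 5 for 4 individuals
  drop_ids <- sprintf("I%03d", 1:4)
  d2 <- d[!(d$individual_id %in% drop_ids & d$wave == 5), ]
  expect_message(out2 <- select_complete_individuals(d2), "4 of 10")
  expect_length(unique(out2$individual_id), 6L)
  # nobody complete -> explicit error
  d3 <- d[d$wave != 5, ]
  expect_error(suppressMessages(select_complete_individuals(d3)),
               "no eligible individuals")
})

test_that("retention under independent missingness matches the binomial rate", {
  sim <- simulate_cohort(simulation_config(
    n_pairs_per_group = c(MZM = 500, MZF = 500), missing_rate = 0.3,
    seed = 21))
  n_all <- 2000
  kept <- tryCatch(
    suppressMessages(select_complete_individuals(sim$phenotypes)),
    error = function(e) NULL)
  frac <- if (is.null(kept)) 0 else
    length(unique(kept$individual_id)) / n_all
  p <- 0.7^3
  expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / n_all))
})

test_that("noise-free lines are recovered exactly by the growth model", {
  set.seed(4)
  n <- 60
  ints <- rnorm(n, 22, 2); slps <- rnorm(n, 0.25, 0.08)
  d <- make_lines(ints, slps, noise_sd = 1e-4)
  fit <- fit_growth_model(d, by_sex = FALSE)
  expect_true(fit$converged)
  expect_equal(fit$fixed_intercept, mean(ints), tolerance = 1e-3)
  expect_equal(fit$fixed_slope, mean(slps), tolerance = 1e-3)
  tr <- extract_individual_trajectories(fit)
  ord <- match(sprintf("I%03d", seq_len(n)), tr$individual_id)
  expect_lt(max(abs(tr$intercept[ord] - ints)), 1e-3)
  expect_lt(max(abs(tr$slope[ord] - slps)), 1e-3)
})

test_that("the fixed slope is recovered on a synthetic cohort", {
  sim <- simulate_cohort(simulation_config(
    n_pairs_per_group = c(MZM = 125, DZM = 125), seed = 31,
    obs_residual_sd = 1.0))
  d <- sim$phenotypes[sim$phenotypes$wave %in% 3:5, ]
  fit <- fit_growth_model(d, by_sex = FALSE)
  # truth: configured male fixed slope 0.24; SE from the random-slope spread
  se <- sqrt(fit$random_effects_cov[2, 2] / fit$n_individuals +
               as.matrix(vcov(fit$model))[2, 2])
  expect_lt(abs(fit$fixed_slope - 0.24), 3 * max(se, 0.01))
})

test_that("without random effects the fit equals pooled OLS", {
  d <- make_lines(rnorm(40, 22, 2), rnorm(40, 0.2, 0.1), noise_sd = 0.8,
                  seed = 6)
  fit <- fit_growth_model(d, by_sex = FALSE, random_effects = FALSE)
  ols <- lm(bmi ~ I(age - 17.5), data = d)
  expect_equal(fit$fixed_intercept, unname(coef(ols)[1]), tolerance = 1e-6)
  expect_equal(fit$fixed_slope, unname(coef(ols)[2]), tolerance = 1e-6)
  tr <- extract_individual_trajectories(fit)
  expect_equal(nrow(tr), 40L)
  expect_true(all(tr$intercept == fit$fixed_intercept))
})

test_that("BLUP trajectories shrink relative to per-individual OLS", {
  d <- make_lines(rnorm(80, 22, 2.5), rnorm(80, 0.25, 0.1), noise_sd = 1.5,
                  seed = 8)
  fit <- fit_growth_model(d, by_sex = FALSE)
  tr <- extract_individual_trajectories(fit)
  ols_int <- sapply(split(d, d$individual_id), function(di)
    coef(lm(bmi ~ I(age - 17.5), data = di))[1])
  expect_lt(var(tr$intercept), var(ols_int) + 1e-12)
  # BLUP deviations are centered: mean of estimates ~ fixed effect
  expect_equal(mean(tr$intercept), fit$fixed_intercept, tolerance = 0.02)
  expect_equal(mean(tr$slope), fit$fixed_slope, tolerance = 0.005)
})

test_that("the likelihood is invariant to row order and stratified fits keep IDs", {
  d <- make_lines(rnorm(30, 22, 2), rnorm(30, 0.2, 0.1), noise_sd = 1,
                  seed = 12)
  f1 <- fit_growth_model(d, by_sex = FALSE)
  f2 <- fit_growth_model(d[sample(nrow(d)), ], by_sex = FALSE)
  expect_equal(f1$log_likelihood, f2$log_likelihood, tolerance = 1e-6)
  fs <- fit_growth_model(d, by_sex = TRUE)
  trs <- extract_individual_trajectories(fs)
  expect_setequal(trs$individual_id, unique(d$individual_id))
  expect_equal(nrow(trs), 30L)
})

test_that("individuals with too few observations are dropped with a message", {
  d <- make_lines(rep(22, 5), rep(0.2, 5))
  d <- d[!(d$individual_id == "I001" & d$wave == 5), ]
  expect_message(fit <- fit_growth_model(d, by_sex = FALSE), "dropped")
  expect_equal(fit$n_individuals, 4L)
})
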