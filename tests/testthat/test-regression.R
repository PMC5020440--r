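# Regression ladder, VIF, Spearman, descriptives.

ranked_fixture <- function(n_pool = 800, n_sub = 400, seed = 31, mech = NULL) {
  pool <- generate_pool(cohort_config(pool_size = n_pool, seed = seed))
  mech <- mech %||% judgement_mechanism("rank", intercept = 2.78, slope = 3.42,
                                        target_r2 = 0.22)
  generate_judgements(pool, mech, n_sub = n_sub, seed = seed + 1)
}

test_that("OLS coefficients match the normal-equations oracle", {
  sub <- ranked_fixture()
  fit <- fit_judgement_model(sub, "judge_drunk", model = 4)
  X <- cbind(1, as.matrix(sub[, c("brac", "rank_rel", "group_mean_distance",
                                  "duration_h", "after_11pm")]),
             male = as.numeric(sub$gender == "M"),
             as.matrix(sub[, c("fast", "age")]))
  oracle <- normal_eq_ols(X, sub$judge_drunk)
  expect_equal(unname(coef(fit$fit)), unname(oracle), tolerance = 1e-8)
})

test_that("noise-free rank data are recovered exactly by Model 2", {
  mech <- judgement_mechanism("rank", intercept = 1.5, slope = 4.2, noise_sd = 0)
  sub <- ranked_fixture(mech = mech)
  fit <- fit_judgement_model(sub, "judge_drunk", model = 2)
  expect_equal(unname(coef(fit$fit)), c(1.5, 4.2), tolerance = 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
})

test_that("a constant outcome gives zero slopes and zero R-squared", {
  sub <- ranked_fixture()
  sub$judge_drunk <- 5
  fit <- fit_judgement_model(sub, "judge_drunk", model = 3)
  expect_equal(unname(coef(fit$fit))[-1], rep(0, 3), tolerance = 1e-12)
  expect_equal(fit$r_squared, 0)
  expect_equal(unname(tidy(fit)$beta[-1]), rep(0, 3))
})

test_that("R-squared never decreases along the nested ladder and beta(M1) is the Pearson r", {
  sub <- ranked_fixture(seed = 33)
  r2 <- vapply(1:4, function(m) fit_judgement_model(sub, "judge_drunk", model = m)$r_squared,
               numeric(1))
  expect_gte(r2[3], r2[1])
  expect_gte(r2[3], r2[2])
  expect_gte(r2[4], r2[3])

  f1 <- fit_judgement_model(sub, "judge_drunk", model = 1)
  expect_equal(unname(f1$beta["brac"]), cor(sub$judge_drunk, sub$brac), tolerance = 1e-10)
})

test_that("the distance and raw forms of the group-mean control give identical R-squared", {
  sub <- ranked_fixture(seed = 34)
  f_dist <- fit_judgement_model(sub, "judge_drunk", model = 3, group_mean = "distance")
  f_raw <- fit_judgement_model(sub, "judge_drunk", model = 3, group_mean = "raw")
  expect_equal(f_dist$r_squared, f_raw$r_squared, tolerance = 1e-12)
  # BrAC + signed distance and BrAC + raw mean span the same column space,
  # so the rank coefficient agrees too
  expect_equal(coef(f_dist$fit)[["rank_rel"]], coef(f_raw$fit)[["rank_rel"]], tolerance = 1e-8)
})

test_that("VIF matches the bivariate closed form and an independent implementation", {
  set.seed(41)
  x <- rnorm(300)
  z <- 0.9 * x + sqrt(1 - 0.81) * rnorm(300)
  v <- compute_vif(data.frame(x, z))
  r <- cor(x, z)
  expect_equal(unname(v), rep(1 / (1 - r^2), 2), tolerance = 1e-10)

  # near-orthogonal predictors: VIF ~ 1
  w <- rnorm(300)
  expect_lt(max(compute_vif(data.frame(x, w))), 1.05)

  # sum-plus-noise collinearity: all three large, equal to brute-force
  s <- x + w + rnorm(300, sd = 0.05)
  v3 <- compute_vif(data.frame(x, w, s))
  expect_true(all(v3 > 50))
  brute <- vapply(1:3, function(j) {
    d <- data.frame(x, w, s)
    1 / (1 - summary(lm(d[[j]] ~ ., data = d[-j]))$r.squared)
  }, numeric(1))
  expect_equal(unname(v3), brute, tolerance = 1e-8)

  # cross-check the Model 4 design against car's implementation
  skip_if_not_installed("car")
  sub <- ranked_fixture(seed = 42)
  fit <- fit_judgement_model(sub, "judge_drunk", model = 4)
  expect_equal(fit$vif, car::vif(fit$fit)[names(fit$vif)], tolerance = 1e-8)
})

test_that("perfect collinearity yields infinite VIF but a named singularity error in fits", {
  set.seed(43)
  x <- rnorm(100)
  expect_equal(unname(compute_vif(data.frame(x, x2 = 2 * x))), c(Inf, Inf))
  expect_error(compute_vif(data.frame(x, k = rep(1, 100))), "zero-variance")

  # one reference group: group_mean_distance = brac - constant, aliased with brac
  survey <- toy_survey(runif(60, 1, 80))
  survey$judge_drunk <- rnorm(60, 5)
  ranked <- rank_brac(survey)
  expect_error(fit_judgement_model(ranked, "judge_drunk", model = 3), "collinear")
})

test_that("spearman_rho handles monotone, tied and constant inputs", {
  expect_equal(spearman_rho(1:10, (1:10)^3), 1)
  expect_equal(spearman_rho(1:10, -(1:10)), -1)
  expect_equal(spearman_rho(1:5, c(1, 2, 3, 5, 4)), 0.9)
  expect_warning(r <- spearman_rho(rep(1, 5), 1:5), "constant")
  expect_true(is.na(r))
  expect_error(spearman_rho(1:3, 1:4), "equal length")
})

test_that("summary-statistic t test reproduces textbook cases", {
  same <- t_from_summary(10, 2, 50, 10, 2, 50)
  expect_equal(same$statistic, 0)
  # agrees with t.test on raw data sharing those summaries
  set.seed(44)
  a <- rnorm(40); b <- rnorm(45, 0.5)
  raw <- t.test(a, b, var.equal = TRUE)
  fromsum <- t_from_summary(mean(a), sd(a), 40, mean(b), sd(b), 45)
  expect_equal(fromsum$statistic, unname(raw$statistic), tolerance = 1e-10)
  expect_equal(fromsum$p.value, raw$p.value, tolerance = 1e-10)
})

test_that("descriptives report the expected layout and null-case statistics", {
  pool <- generate_pool(cohort_config(pool_size = 600, seed = 45))
  mech <- judgement_mechanism("rank", intercept = 2.78, slope = 3.42, target_r2 = 0.22)
  sub <- generate_judgements(pool, mech, n_sub = 200, seed = 46)
  d <- descriptives(pool, sub)
  expect_equal(nrow(d$summary), 10)
  expect_true(all(is.na(d$summary$sd[d$summary$variable %in%
    c("Proportion surveyed after 11 pm", "Proportion male")])))
  expect_gt(d$gender_t$statistic, 0)      # men drink more by construction
  expect_lt(d$location_anova$p.value, 0.05)  # location offsets are real
  expect_equal(d$location_anova$df1, 3)

  # the two genders holding identical values -> t exactly 0
  flat <- toy_survey(rep(c(10, 20, 30, 40), 2), gender = rep(c("M", "F"), each = 4),
                     location = rep(1:2, 4))
  expect_equal(descriptives(flat)$gender_t$statistic, 0)
})

test_that("under equal location means the ANOVA F hovers around 1", {
  set.seed(47)
  fs <- replicate(50, {
    pool <- toy_survey(rnorm(400, 50, 10),
                       gender = sample(c("M", "F"), 400, TRUE),
                       location = sample(1:4, 400, TRUE))
    descriptives(pool)$location_anova$statistic
  })
  expect_gt(mean(fs), 0.6)
  expect_lt(mean(fs), 1.5)
})

test_that("listwise deletion is applied and logged", {
  sub <- ranked_fixture(seed = 48)
  sub$fast[1:25] <- NA
  expect_message(fit <- fit_judgement_model(sub, "judge_drunk", model = 4), "listwise")
  expect_equal(fit$n_used, nrow(sub) - 25)
  expect_equal(fit$n_dropped, 25)
})
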