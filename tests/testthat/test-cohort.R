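# Synthetic cohort generator: determinism, composition, calibration, and
# the generative judgement mechanisms.

test_that("pool generation is deterministic and matches the configured composition", {
  cfg <- cohort_config(seed = 42)
  pool1 <- generate_pool(cfg)
  pool2 <- generate_pool(cfg)
  expect_identical(pool1, pool2)
  expect_false(identical(pool1$brac, generate_pool(cfg, seed = 43)$brac))

  expect_equal(nrow(pool1), 1862)
  expect_equal(sum(pool1$gender == "M"), round(0.632 * 1862))
  expect_equal(sum(pool1$brac == 0), round(0.05 * 1862))
  expect_true(all(pool1$brac >= 0))
  expect_true(all(pool1$duration_h >= 0))
  expect_true(all(pool1$age >= 18))
  expect_true(all(pool1$fast >= 0 & pool1$fast <= 16))
  expect_true(all(pool1$after_11pm %in% 0:1))
  expect_equal(nrow(reference_groups(pool1)), 8)
})

test_that("degenerate zero-BrAC fraction puts everyone at zero", {
  pool <- generate_pool(cohort_config(pool_size = 100, zero_brac_fraction = 1, seed = 3))
  expect_true(all(pool$brac == 0))
})

test_that("positive BrAC moments are calibrated to the configured targets", {
  # one gender, no location spread: sample moments must converge to the
  # configured mean/SD (truncation is compensated by moment matching)
  cfg <- cohort_config(
    pool_size = 50000, male_fraction = 1, n_locations = 1,
    location_offsets = 0, zero_brac_fraction = 0, seed = 9
  )
  x <- generate_pool(cfg)$brac
  se_mean <- sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - 52.3), 3 * se_mean)
  expect_lt(abs(sd(x) - 30.0) / 30.0, 0.02)

  # female branch too, smaller n
  cfg_f <- cohort_config(
    pool_size = 20000, male_fraction = 0, n_locations = 1,
    location_offsets = 0, zero_brac_fraction = 0, seed = 10
  )
  xf <- generate_pool(cfg_f)$brac
  expect_lt(abs(mean(xf) - 43.0), 3 * sd(xf) / sqrt(length(xf)))
})

test_that("invalid configuration fields are rejected by name", {
  expect_error(cohort_config(male_fraction = 1.5), "male_fraction")
  expect_error(cohort_config(zero_brac_fraction = -0.1), "zero_brac_fraction")
  expect_error(cohort_config(brac_male = c(50, -1)), "brac_male")
  expect_error(cohort_config(location_offsets = c(1, 2)), "location_offsets")
  expect_error(cohort_config(pool_size = 4, n_locations = 4), "pool_size")
  expect_error(cohort_config(location_offsets = c(-60, 0, 0, 60)), "offset")
})

test_that("null mechanism yields constant ratings; eta = 1 weighted mechanism equals the rank one", {
  pool <- generate_pool(cohort_config(pool_size = 300, seed = 5))
  flat <- judgement_mechanism("rank", intercept = 4, slope = 0, noise_sd = 0)
  sub <- generate_judgements(pool, flat, n_sub = 50, seed = 6)
  expect_true(all(sub$judge_drunk == 4))
  expect_true(all(sub$judge_cirrhosis == 4))

  mech_r <- judgement_mechanism("rank", intercept = 2, slope = 3, noise_sd = 0.5)
  mech_w <- judgement_mechanism("weighted_rank", eta = 1, intercept = 2, slope = 3, noise_sd = 0.5)
  s1 <- generate_judgements(pool, mech_r, n_sub = 100, seed = 7)
  s2 <- generate_judgements(pool, mech_w, n_sub = 100, seed = 7)
  expect_equal(s1$judge_drunk, s2$judge_drunk, tolerance = 1e-12)
})

test_that("noise-free rank ratings are an exact affine function of relative rank", {
  pool <- generate_pool(cohort_config(pool_size = 400, seed = 8))
  mech <- judgement_mechanism("rank", intercept = 2.78, slope = 3.42, noise_sd = 0)
  sub <- generate_judgements(pool, mech, n_sub = 200, seed = 9)
  fit <- lm(judge_drunk ~ rank_rel, data = sub)
  expect_equal(unname(coef(fit)), c(2.78, 3.42), tolerance = 1e-10)
  expect_lt(max(abs(residuals(fit))), 1e-10)
})

test_that("target_r2 noise tuning lands near the requested variance share", {
  pool <- generate_pool(cohort_config(pool_size = 2000, seed = 11))
  mech <- judgement_mechanism("rank", intercept = 2.78, slope = 3.42, target_r2 = 0.22)
  sub <- generate_judgements(pool, mech, n_sub = 1500, seed = 12)
  r2 <- cor(sub$judge_drunk, sub$rank_rel)^2
  expect_lt(abs(r2 - 0.22), 0.05)
})

test_that("only positive-BrAC members can be sampled, and replace extends the draw", {
  pool <- generate_pool(cohort_config(pool_size = 100, zero_brac_fraction = 0.5, seed = 13))
  mech <- judgement_mechanism("rank", intercept = 1, slope = 1, noise_sd = 0)
  n_eligible <- sum(pool$brac > 0)
  expect_error(generate_judgements(pool, mech, n_sub = n_eligible + 1, seed = 1), "eligible")
  sub <- generate_judgements(pool, mech, n_sub = n_eligible + 50, seed = 1, replace = TRUE)
  expect_equal(nrow(sub), n_eligible + 50)
  expect_true(all(sub$brac > 0))
})

test_that("discretized ratings are integers clipped to the 1-10 scale", {
  pool <- generate_pool(cohort_config(pool_size = 300, seed = 14))
  mech <- judgement_mechanism("rank", intercept = 0, slope = 20, noise_sd = 2, discretize = TRUE)
  sub <- generate_judgements(pool, mech, n_sub = 150, seed = 15)
  expect_true(all(sub$judge_drunk == round(sub$judge_drunk)))
  expect_true(all(sub$judge_drunk >= 1 & sub$judge_drunk <= 10))
})

test_that("mechanism arguments are validated", {
  expect_error(judgement_mechanism("rank", eta = 0), "eta")
  expect_error(judgement_mechanism("rank", noise_sd = -1), "noise_sd")
  expect_error(judgement_mechanism("rank", noise_sd = 1, target_r2 = 0.5), "not both")
  expect_error(judgement_mechanism("rank", covariate_effects = c(bogus = 1)), "covariate_effects")
})
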