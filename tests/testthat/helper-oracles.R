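# Independent oracles used across the suite.

# O(n^2) pairwise comparator counting within one group.
brute_counts <- function(brac) {
  n <- length(brac)
  below <- vapply(seq_len(n), function(i) sum(brac < brac[i]), numeric(1))
  above <- vapply(seq_len(n), function(i) sum(brac > brac[i]), numeric(1))
  data.frame(below = below, above = above)
}

# Weighted rank straight from the counts (same degenerate convention).
brute_sr <- function(below, above, eta) {
  denom <- below + eta * above
  ifelse(denom == 0, 0.5, 0.5 + (below - eta * above) / (2 * denom))
}

# OLS by the normal equations.
normal_eq_ols <- function(X, y) {
  drop(solve(crossprod(X), crossprod(X, y)))
}

# A multi-group survey table with arbitrary BrAC values (no covariates).
toy_survey <- function(brac, gender = "M", location = 1) {
  tibble::tibble(
    id = sprintf("t%03d", seq_along(brac)),
    brac = brac,
    gender = factor(gender, levels = c("M", "F")),
    location = factor(location, levels = sort(unique(location))),
    duration_h = 5, after_11pm = 1L, fast = 6, age = 25,
    judge_drunk = NA_real_, judge_extreme = NA_real_,
    judge_health = NA_real_, judge_cirrhosis = NA_real_
  )
}

# Generating coefficients used in recovery checks: the covariate-adjusted
# model's published effects for the two primary outcomes.
m4_mech_drunk <- function() {
  judgement_mechanism(
    "rank", intercept = 0.87, slope = 3.78,
    noise_sd = 1.98 * sqrt(1 - 0.26),
    covariate_effects = c(
      brac = -0.01, group_mean_distance = 0.03, duration_h = 0.09,
      after_11pm = 0.30, male = -0.24, fast = -0.01, age = 0.003
    )
  )
}

m4_mech_extreme <- function() {
  judgement_mechanism(
    "rank", intercept = 0.91, slope = 3.73,
    noise_sd = 2.26 * sqrt(1 - 0.16),
    covariate_effects = c(
      brac = -0.02, group_mean_distance = 0.03, duration_h = 0.09,
      after_11pm = 0.28, male = -0.20, fast = 0.07, age = -0.001
    )
  )
}
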