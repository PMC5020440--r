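# Synthetic street-survey cohort: a pool of breath-tested respondents in
# gender x location reference groups, plus a judgement subsample whose
# ratings are generated from a configurable mechanism (rank-based,
# weighted-rank-based, or absolute-BrAC-based).

# --- truncated-normal machinery -------------------------------------------

# Mean and SD of a normal(mu, sigma) left-truncated at `lower`.
tn_moments <- function(mu, sigma, lower) {
  a <- (lower - mu) / sigma
  lam <- dnorm(a) / pnorm(a, lower.tail = FALSE)
  m <- mu + sigma * lam
  v <- sigma^2 * (1 + a * lam - lam^2)
  c(mean = m, sd = sqrt(v))
}

# Latent (mu, sigma) such that the truncated draw has the target moments.
# Cached: the same handful of gender x location cells recur across pools.
calib_cache <- new.env(parent = emptyenv())

tn_latent_params <- function(target_mean, target_sd, lower = 0) {
  key <- paste(format(c(target_mean, target_sd, lower), digits = 15), collapse = "|")
  hit <- calib_cache[[key]]
  if (!is.null(hit)) {
    return(hit)
  }
  obj <- function(p) {
    mo <- tn_moments(p[1], exp(p[2]), lower)
    sum((mo - c(target_mean, target_sd))^2)
  }
  fit <- optim(c(target_mean, log(target_sd)), obj,
               control = list(reltol = 1e-15, maxit = 5000))
  if (sqrt(fit$value) > 1e-4) {
    abort(sprintf(
      "brac_params: no truncated normal attains mean %.3f, SD %.3f above %.1f",
      target_mean, target_sd, lower
    ))
  }
  out <- c(mu = fit$par[1], sigma = exp(fit$par[2]))
  calib_cache[[key]] <- out
  out
}

# Inverse-CDF sampler; mean/sd/lower may be vectors matched to n.
rtruncnorm <- function(n, mean, sd, lower) {
  p0 <- pnorm(lower, mean, sd)
  qnorm(runif(n, p0, 1), mean, sd)
}

# --- configuration ---------------------------------------------------------

check_meansd <- function(x, field) {
  if (!is.numeric(x) || length(x) != 2 || anyNA(x)) {
    abort(sprintf("`%s` must be a numeric c(mean, sd) pair", field))
  }
  if (x[2] <= 0) abort(sprintf("`%s`: SD must be > 0", field))
  setNames(as.numeric(x), c("mean", "sd"))
}

check_prop <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a proportion in [0, 1]", field))
  }
  as.numeric(x)
}

#' Configure a synthetic survey cohort
#'
#' Defaults emulate the published street survey: 1,862 breath-tested
#' respondents across 2 genders x 4 locations (8 reference groups),
#' 63.2% male, positive BrAC drawn per gender x location cell from a
#' 0-truncated normal that is moment-matched so the *realised* positive-BrAC
#' mean/SD equal the configured targets (male 52.3/30.0, female 43.0/27.8
#' ug/100 ml, shifted by additive location offsets), a small zero-BrAC
#' fraction, and covariates drawn independently of BrAC.
#'
#' @param pool_size Number of respondents in the full ranking pool.
#' @param male_fraction Proportion of the pool that is male; the realised
#'   male count is `round(male_fraction * pool_size)`.
#' @param n_locations Number of survey locations (reference groups are
#'   gender x location cells, so there are `2 * n_locations` of them).
#' @param brac_male,brac_female Target `c(mean, sd)` of positive BrAC by
#'   gender, in ug alcohol / 100 ml breath.
#' @param location_offsets Additive shifts (ug/100 ml) applied to the
#'   gender target mean in each location; length `n_locations`.  The
#'   defaults create the between-location spread that makes rank and
#'   absolute BrAC meaningfully different measures.
#' @param zero_brac_fraction Proportion of the pool with BrAC exactly 0
#'   (present in the environment but not drinking); these respondents
#'   still count as ranking comparators.
#' @param judgement_subsample Default size of the judgement subsample.
#' @param duration `c(mean, sd)` of session duration (hours), truncated at 0.
#' @param p_after_11pm Probability a respondent is surveyed after 11 pm.
#' @param fast `c(mean, sd)` of the FAST score, clipped to `[0, 16]`.
#' @param age `c(mean, sd)` of age (years), truncated at 18.
#' @param seed Default integer seed used by [generate_pool()].
#'
#' @return An object of class `cohort_config` (a validated list).
#' @seealso [generate_pool()], [generate_judgements()]
#' @export
#' @examples
#' cfg <- cohort_config(pool_size = 500, seed = 1)
#' pool <- generate_pool(cfg)
#' dplyr::count(pool, gender, location)
cohort_config <- function(pool_size = 1862,
                          male_fraction = 0.632,
                          n_locations = 4,
                          brac_male = c(mean = 52.3, sd = 30.0),
                          brac_female = c(mean = 43.0, sd = 27.8),
                          location_offsets = c(-8, -3, 3, 8),
                          zero_brac_fraction = 0.05,
                          judgement_subsample = 400,
                          duration = c(mean = 5.36, sd = 3.62),
                          p_after_11pm = 0.60,
                          fast = c(mean = 6.18, sd = 3.49),
                          age = c(mean = 26.28, sd = 8.78),
                          seed = 1L) {
  if (!is.numeric(pool_size) || length(pool_size) != 1 || pool_size < 1) {
    abort("`pool_size` must be a positive count")
  }
  if (!is.numeric(n_locations) || length(n_locations) != 1 || n_locations < 1) {
    abort("`n_locations` must be a positive count")
  }
  pool_size <- as.integer(pool_size)
  n_locations <- as.integer(n_locations)
  if (pool_size < 2 * n_locations) {
    abort("`pool_size` must be at least the number of gender x location groups")
  }
  if (length(location_offsets) != n_locations || !is.numeric(location_offsets)) {
    abort("`location_offsets` must be numeric with one offset per location")
  }
  if (!is.numeric(judgement_subsample) || judgement_subsample < 0) {
    abort("`judgement_subsample` must be a nonnegative count")
  }
  cfg <- list(
    pool_size = pool_size,
    male_fraction = check_prop(male_fraction, "male_fraction"),
    n_locations = n_locations,
    brac_male = check_meansd(brac_male, "brac_male"),
    brac_female = check_meansd(brac_female, "brac_female"),
    location_offsets = as.numeric(location_offsets),
    zero_brac_fraction = check_prop(zero_brac_fraction, "zero_brac_fraction"),
    judgement_subsample = as.integer(judgement_subsample),
    duration = check_meansd(duration, "duration"),
    p_after_11pm = check_prop(p_after_11pm, "p_after_11pm"),
    fast = check_meansd(fast, "fast"),
    age = check_meansd(age, "age"),
    seed = as.integer(seed)
  )
  for (g in c("brac_male", "brac_female")) {
    for (off in cfg$location_offsets) {
      m <- cfg[[g]]["mean"] + off
      if (m <= 0) abort(sprintf("`location_offsets`: %s mean %.1f + offset %.1f is not positive", g, cfg[[g]]["mean"], off))
    }
  }
  structure(cfg, class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat(sprintf("  pool: %d respondents, %.1f%% male, %d locations (%d reference groups)\n",
              x$pool_size, 100 * x$male_fraction, x$n_locations, 2L * x$n_locations))
  cat(sprintf("  positive BrAC targets: male %.1f (SD %.1f), female %.1f (SD %.1f) ug/100 ml\n",
              x$brac_male["mean"], x$brac_male["sd"], x$brac_female["mean"], x$brac_female["sd"]))
  cat(sprintf("  location offsets: %s; zero-BrAC fraction %.2f\n",
              paste(format(x$location_offsets), collapse = ", "), x$zero_brac_fraction))
  cat(sprintf("  judgement subsample: %d; seed %d\n", x$judgement_subsample, x$seed))
  invisible(x)
}

# --- pool generation -------------------------------------------------------

#' Generate a synthetic respondent pool
#'
#' Draws a full ranking pool: gender (fixed count from `male_fraction`),
#' a uniformly random location, positive BrAC from the per-cell
#' moment-matched truncated normal, an exact `zero_brac_fraction` share of
#' zero readings, and independent covariates.  Deterministic for a fixed
#' seed: the same `config` and `seed` reproduce the table exactly.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#'
#' @return A survey tibble (one row per respondent) with columns `id`,
#'   `brac`, `gender`, `location`, `duration_h`, `after_11pm`, `fast`,
#'   `age`, and the four judgement columns (all `NA`; see
#'   [generate_judgements()]).  The seed used is recorded in
#'   `attr(, "seed")`.
#' @export
#' @examples
#' pool <- generate_pool(cohort_config(pool_size = 200, seed = 7))
#' summary(pool$brac)
generate_pool <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$pool_size
  set.seed(seed)

  n_male <- round(config$male_fraction * n)
  gender <- factor(rep(c("M", "F"), c(n_male, n - n_male)), levels = c("M", "F"))
  location <- factor(sample.int(config$n_locations, n, replace = TRUE),
                     levels = seq_len(config$n_locations))

  target_mean <- ifelse(gender == "M", config$brac_male["mean"], config$brac_female["mean"]) +
    config$location_offsets[as.integer(location)]
  target_sd <- ifelse(gender == "M", config$brac_male["sd"], config$brac_female["sd"])

  cells <- !duplicated(data.frame(target_mean, target_sd))
  mu <- sigma <- numeric(n)
  for (i in which(cells)) {
    par <- tn_latent_params(target_mean[i], target_sd[i], lower = 0)
    sel <- target_mean == target_mean[i] & target_sd == target_sd[i]
    mu[sel] <- par["mu"]
    sigma[sel] <- par["sigma"]
  }
  brac <- rtruncnorm(n, mu, sigma, lower = 0)

  n_zero <- round(config$zero_brac_fraction * n)
  if (n_zero > 0) brac[sample.int(n, n_zero)] <- 0

  duration_h <- rtruncnorm(n, config$duration["mean"], config$duration["sd"], lower = 0)
  after_11pm <- rbinom(n, 1L, config$p_after_11pm)
  fast <- pmin(16, pmax(0, rnorm(n, config$fast["mean"], config$fast["sd"])))
  age <- rtruncnorm(n, config$age["mean"], config$age["sd"], lower = 18)

  out <- tibble::tibble(
    id = sprintf("r%05d", seq_len(n)),
    brac = brac,
    gender = gender,
    location = location,
    duration_h = duration_h,
    after_11pm = after_11pm,
    fast = fast,
    age = age,
    judge_drunk = NA_real_,
    judge_extreme = NA_real_,
    judge_health = NA_real_,
    judge_cirrhosis = NA_real_
  )
  attr(out, "seed") <- as.integer(seed)
  out
}

# --- judgement mechanism ---------------------------------------------------

#' Specify the generative mechanism for judgement ratings
#'
#' Encodes how a synthetic respondent's 1-10 ratings arise from their
#' standing in the pool: an affine function of relative rank (`"rank"`),
#' of the eta-weighted rank (`"weighted_rank"`), or of raw BrAC
#' (`"absolute"`), plus optional covariate effects and Gaussian noise.
#' This is the generative counterpart of the regression ladder: data built
#' with one mechanism let you check which regression model identifies it.
#'
#' @param kind One of `"rank"`, `"weighted_rank"`, `"absolute"`.
#' @param intercept,slope Affine coefficients on the judgement scale
#'   (slope per unit predictor).
#' @param eta Comparison-bias parameter (> 0); used only by
#'   `"weighted_rank"`.  `eta = 1` reduces to `"rank"`.
#' @param noise_sd Residual SD on the judgement scale (>= 0).
#' @param target_r2 Alternative to `noise_sd`: tune the noise so the
#'   systematic part explains this share of the rating variance (the
#'   realised noise SD is `sd(signal) * sqrt((1 - r2) / r2)` on the
#'   sampled respondents).
#' @param covariate_effects Optional named numeric vector of additional
#'   linear effects; names drawn from `brac`, `group_mean_distance`,
#'   `duration_h`, `after_11pm`, `male`, `fast`, `age`.
#' @param discretize If `TRUE`, round ratings and clip to the 1-10
#'   instrument scale; the default leaves them continuous so least-squares
#'   recovery of the generating coefficients is unbiased.
#'
#' @return An object of class `judgement_mechanism`.
#' @export
#' @examples
#' judgement_mechanism("rank", intercept = 2.78, slope = 3.42, target_r2 = 0.22)
judgement_mechanism <- function(kind = c("rank", "weighted_rank", "absolute"),
                                intercept = 0,
                                slope = 1,
                                eta = 1,
                                noise_sd = NULL,
                                target_r2 = NULL,
                                covariate_effects = NULL,
                                discretize = FALSE) {
  kind <- match.arg(kind)
  if (!is.numeric(eta) || length(eta) != 1 || is.na(eta) || eta <= 0) {
    abort("`eta` must be a positive number")
  }
  if (!is.null(noise_sd) && !is.null(target_r2)) {
    abort("give `noise_sd` or `target_r2`, not both")
  }
  if (is.null(noise_sd) && is.null(target_r2)) noise_sd <- 0
  if (!is.null(noise_sd) && (!is.numeric(noise_sd) || noise_sd < 0)) {
    abort("`noise_sd` must be >= 0")
  }
  if (!is.null(target_r2) && (!is.numeric(target_r2) || target_r2 <= 0 || target_r2 >= 1)) {
    abort("`target_r2` must lie strictly between 0 and 1")
  }
  if (!is.null(covariate_effects)) {
    allowed <- c("brac", "group_mean_distance", covariate_cols, "male")
    bad <- setdiff(names(covariate_effects), allowed)
    if (is.null(names(covariate_effects)) || length(bad)) {
      abort(paste0("`covariate_effects` must be named from: ", paste(allowed, collapse = ", ")))
    }
  }
  structure(
    list(kind = kind, intercept = intercept, slope = slope, eta = eta,
         noise_sd = noise_sd, target_r2 = target_r2,
         covariate_effects = covariate_effects, discretize = isTRUE(discretize)),
    class = "judgement_mechanism"
  )
}

#' Generate a judgement subsample from a pool
#'
#' Samples `n_sub` judgement-eligible respondents (positive BrAC, ranked
#' within the *full* pool's gender x location groups) and fills their four
#' rating columns from the mechanism: `rating = intercept + slope *
#' predictor + covariate effects + noise`, with independent noise per
#' rating.  Zero-BrAC respondents never receive ratings — they are
#' comparators only.
#'
#' @param pool A survey tibble, e.g. from [generate_pool()].
#' @param mech A [judgement_mechanism()].
#' @param n_sub Subsample size.
#' @param seed Integer seed for sampling and noise.
#' @param replace Sample respondents with replacement (allows `n_sub`
#'   beyond the number of eligible members; each draw gets independent
#'   noise).
#'
#' @return A tibble of `n_sub` sampled rows with rank columns (see
#'   [rank_brac()]) and the four ratings filled.
#' @export
#' @examples
#' pool <- generate_pool(cohort_config(pool_size = 300, seed = 2))
#' mech <- judgement_mechanism("rank", intercept = 2.78, slope = 3.42, noise_sd = 1.75)
#' sub <- generate_judgements(pool, mech, n_sub = 100, seed = 3)
#' cor(sub$judge_drunk, sub$rank_rel)
generate_judgements <- function(pool, mech, n_sub, seed = 1L, replace = FALSE) {
  stopifnot(inherits(mech, "judgement_mechanism"))
  if (nrow(pool) == 0) abort("`pool` is empty")
  ranked <- rank_brac(pool, eta = mech$eta)
  eligible <- which(ranked$brac > 0 & !is.na(ranked$rank_rel))
  if (length(eligible) == 0) abort("no judgement-eligible respondents (all BrAC are 0)")
  if (!replace && n_sub > length(eligible)) {
    abort(sprintf("n_sub = %d exceeds the %d judgement-eligible pool members (set replace = TRUE to resample)",
                  n_sub, length(eligible)))
  }
  set.seed(seed)
  idx <- eligible[sample.int(length(eligible), n_sub, replace = replace)]
  sub <- ranked[idx, ]

  predictor <- switch(mech$kind,
    rank = sub$rank_rel,
    weighted_rank = sub$rank_wt,
    absolute = sub$brac
  )
  lp <- mech$intercept + mech$slope * predictor
  if (!is.null(mech$covariate_effects)) {
    X <- cbind(
      brac = sub$brac,
      group_mean_distance = sub$group_mean_distance,
      duration_h = sub$duration_h,
      after_11pm = sub$after_11pm,
      male = as.numeric(sub$gender == "M"),
      fast = sub$fast,
      age = sub$age
    )
    ce <- mech$covariate_effects
    lp <- lp + as.vector(X[, names(ce), drop = FALSE] %*% ce)
  }
  noise_sd <- mech$noise_sd
  if (is.null(noise_sd)) {
    sig <- sd(lp)
    if (!is.finite(sig) || sig == 0) {
      abort("`target_r2` needs a non-constant systematic signal")
    }
    noise_sd <- sig * sqrt((1 - mech$target_r2) / mech$target_r2)
  }
  for (col in judgement_cols) {
    y <- lp + rnorm(length(lp), 0, noise_sd)
    if (mech$discretize) y <- pmin(10, pmax(1, round(y)))
    sub[[col]] <- y
  }
  attr(sub, "noise_sd") <- noise_sd
  attr(sub, "seed") <- as.integer(seed)
  sub
}
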