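# The four-model regression ladder.  Model 1 regresses a judgement on
# absolute BrAC alone, Model 2 on relative rank alone, Model 3 on both plus
# the distance from the reference-group mean (the rival central-tendency
# account), and Model 4 adds the sensitivity covariates.  If judgements are
# rank-based, the rank term should survive Model 3/4 while BrAC collapses.

#' Predictor set for a ladder model
#'
#' @param model Integer 1-4.
#' @param group_mean `"distance"` (default) uses the signed distance of the
#'   respondent's BrAC from their reference-group mean as the
#'   central-tendency control; `"raw"` uses the group mean itself.  The two
#'   span the same column space alongside BrAC, so fits have identical R².
#'
#' @return Character vector of predictor column names.
#' @export
#' @examples
#' model_predictors(3)
model_predictors <- function(model, group_mean = c("distance", "raw")) {
  gm <- switch(match.arg(group_mean), distance = "group_mean_distance", raw = "group_mean_brac")
  switch(as.character(model),
    "1" = "brac",
    "2" = "rank_rel",
    "3" = c("brac", "rank_rel", gm),
    "4" = c("brac", "rank_rel", gm, "duration_h", "after_11pm", "male", "fast", "age"),
    abort("`model` must be 1, 2, 3 or 4")
  )
}

#' Fit one model of the judgement regression ladder
#'
#' Ordinary least squares on the judgement-eligible rows (positive BrAC,
#' listwise-complete on the outcome and predictors).  Standardized
#' coefficients come from refitting on z-scored variables (binary
#' predictors z-scored like continuous ones, n-1 SDs); confidence
#' intervals are normal-theory two-sided 95% bounds; VIFs follow the
#' auxiliary-regression definition `1 / (1 - R²_j)` (see [compute_vif()]).
#'
#' @param data A *ranked* survey table (see [rank_brac()]); models 2-4 need
#'   the rank columns computed within the full pool.
#' @param outcome One of [judgement_outcomes()] (or any numeric column).
#' @param model Ladder model 1-4.
#' @param group_mean Passed to [model_predictors()].
#' @param quiet Suppress the listwise-deletion message.
#'
#' @return An object of class `judgement_fit`; see [tidy.judgement_fit()]
#'   and [glance.judgement_fit()].
#' @export
#' @examples
#' pool <- generate_pool(cohort_config(pool_size = 600, seed = 11))
#' mech <- judgement_mechanism("rank", intercept = 2.78, slope = 3.42, target_r2 = 0.22)
#' sub <- generate_judgements(pool, mech, n_sub = 300, seed = 12)
#' fit <- fit_judgement_model(sub, "judge_drunk", model = 3)
#' tidy(fit)
#' glance(fit)
fit_judgement_model <- function(data, outcome, model = 3,
                                group_mean = c("distance", "raw"),
                                quiet = FALSE) {
  group_mean <- match.arg(group_mean)
  predictors <- model_predictors(model, group_mean)
  if (!outcome %in% names(data)) abort(paste0("no such outcome column: ", outcome))
  if (model != 1 && !all(c("rank_rel", "group_mean_brac") %in% names(data))) {
    abort("rank columns missing: run rank_brac() on the full pool before fitting")
  }
  if (!"male" %in% names(data) && "gender" %in% names(data)) {
    data$male <- as.numeric(data$gender == "M")
  }

  vars <- c(outcome, predictors)
  eligible <- !is.na(data$brac) & data$brac > 0
  complete <- complete.cases(data[, vars, drop = FALSE])
  d <- data[eligible & complete, vars, drop = FALSE]
  n_dropped <- sum(eligible) - nrow(d)
  if (!quiet && n_dropped > 0) {
    inform(sprintf("listwise deletion: %d of %d eligible rows dropped (missing %s)",
                   n_dropped, sum(eligible), paste(vars, collapse = "/")))
  }
  if (nrow(d) <= length(predictors) + 1) {
    abort(sprintf("only %d usable rows for %d predictors", nrow(d), length(predictors)))
  }

  X <- model.matrix(reformulate(predictors), data = d)
  qr_X <- qr(X)
  if (qr_X$rank < ncol(X)) {
    aliased <- colnames(X)[qr_X$pivot[(qr_X$rank + 1):ncol(X)]]
    abort(paste0("design is rank-deficient; collinear column(s): ",
                 paste(aliased, collapse = ", ")))
  }

  f <- reformulate(predictors, response = outcome)
  fit <- lm(f, data = d)

  y <- d[[outcome]]
  constant_outcome <- var(y) == 0
  if (constant_outcome) {
    beta <- setNames(rep(0, length(predictors)), predictors)
    r2 <- 0
  } else {
    dz <- as.data.frame(lapply(d, function(col) as.numeric(scale(col))))
    # A zero-variance predictor would already have tripped the rank check.
    std_fit <- lm(f, data = dz)
    beta <- coef(std_fit)[predictors]
    # summary.lm warns on exact fits; R^2 = 1 is a legitimate noise-free case
    r2 <- suppressWarnings(summary(fit))$r.squared
  }

  vif <- if (length(predictors) >= 2) compute_vif(d[, predictors, drop = FALSE]) else
    setNames(NA_real_, predictors)

  structure(
    list(
      fit = fit,
      outcome = outcome,
      model = as.integer(model),
      predictors = predictors,
      group_mean = group_mean,
      n_used = nrow(d),
      n_dropped = n_dropped,
      beta = beta,
      r_squared = r2,
      vif = vif,
      constant_outcome = constant_outcome
    ),
    class = "judgement_fit"
  )
}

signif_band <- function(p) {
  dplyr::case_when(
    is.na(p) ~ "",
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ ""
  )
}

#' Tidy a judgement-ladder fit
#'
#' @param x A `judgement_fit`.
#' @param ... Unused.
#'
#' @return A tibble with one row per term: `term`, `estimate` (b), `beta`
#'   (standardized), `conf.low`/`conf.high` (95% CI on b), `statistic`,
#'   `p.value`, `signif` (star band), `vif`.
#' @method tidy judgement_fit
#' @export
tidy.judgement_fit <- function(x, ...) {
  sm <- suppressWarnings(summary(x$fit))$coefficients
  ci <- suppressWarnings(confint(x$fit))
  terms <- rownames(sm)
  tibble::tibble(
    term = terms,
    estimate = sm[, "Estimate"],
    beta = c(NA_real_, x$beta)[match(terms, c("(Intercept)", names(x$beta)))],
    conf.low = ci[terms, 1],
    conf.high = ci[terms, 2],
    statistic = sm[, "t value"],
    p.value = if (x$constant_outcome) NA_real_ else sm[, "Pr(>|t|)"],
    signif = signif_band(if (x$constant_outcome) rep(NA_real_, length(terms)) else sm[, "Pr(>|t|)"]),
    vif = c(NA_real_, x$vif)[match(terms, c("(Intercept)", names(x$vif)))]
  )
}

#' One-row summary of a judgement-ladder fit
#'
#' @param x A `judgement_fit`.
#' @param ... Unused.
#'
#' @return A tibble: `outcome`, `model`, `r.squared`, `adj.r.squared`,
#'   `sigma`, `n_used`, `n_dropped`.
#' @method glance judgement_fit
#' @export
glance.judgement_fit <- function(x, ...) {
  sm <- suppressWarnings(summary(x$fit))
  tibble::tibble(
    outcome = x$outcome,
    model = x$model,
    r.squared = x$r_squared,
    adj.r.squared = if (x$constant_outcome) 0 else sm$adj.r.squared,
    sigma = sm$sigma,
    n_used = x$n_used,
    n_dropped = x$n_dropped
  )
}

#' @export
print.judgement_fit <- function(x, ...) {
  cat(sprintf("<judgement_fit> Model %d: %s ~ %s  (n = %d, R^2 = %.3f)\n",
              x$model, x$outcome, paste(x$predictors, collapse = " + "),
              x$n_used, x$r_squared))
  print(tidy(x), n = Inf)
  invisible(x)
}

#' Coefficient plot for a judgement-ladder fit
#'
#' @param object A `judgement_fit`.
#' @param ... Unused.
#'
#' @return A ggplot: point estimates with 95% CI bars per term (intercept
#'   omitted).
#' @method autoplot judgement_fit
#' @export
autoplot.judgement_fit <- function(object, ...) {
  td <- tidy(object)
  td <- td[td$term != "(Intercept)", ]
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high)) +
    ggplot2::labs(
      x = "coefficient (95% CI)", y = NULL,
      title = sprintf("Model %d: %s", object$model, object$outcome)
    )
}

#' Variance inflation factors by auxiliary regression
#'
#' For each predictor, regress it on all the others and report
#' `VIF = 1 / (1 - R²)` of that auxiliary regression.  Values above 10 are
#' conventionally read as harmful collinearity; perfect collinearity is
#' reported as `Inf`, not an error.
#'
#' @param design A data frame or matrix of two or more predictors, each
#'   with nonzero variance.
#'
#' @return A named numeric vector of VIFs (all >= 1).
#' @export
#' @examples
#' x <- rnorm(100); z <- 0.9 * x + sqrt(1 - 0.81) * rnorm(100)
#' compute_vif(data.frame(x, z))
compute_vif <- function(design) {
  design <- as.data.frame(design)
  if (ncol(design) < 2) abort("VIF needs at least two predictors")
  zero_var <- vapply(design, function(col) var(col) == 0, logical(1))
  if (any(zero_var)) {
    abort(paste0("zero-variance predictor(s): ", paste(names(design)[zero_var], collapse = ", ")))
  }
  out <- vapply(seq_along(design), function(j) {
    aux <- cbind(.target = design[[j]], design[, -j, drop = FALSE])
    r2 <- suppressWarnings(summary(lm(.target ~ ., data = aux)))$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  setNames(out, names(design))
}

#' Spearman rank correlation
#'
#' Mid-rank tie handling; complete pairs only.  Constant input has no
#' defined rank correlation and is reported as `NA` with a warning.
#'
#' @param x,y Equal-length numeric vectors, at least 3 complete pairs.
#'
#' @return A single correlation in `[-1, 1]`, or `NA`.
#' @export
#' @examples
#' spearman_rho(1:5, c(1, 2, 3, 5, 4))   # 0.9
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length")
  ok <- complete.cases(x, y)
  if (sum(ok) < 3) abort("need at least 3 complete pairs")
  x <- x[ok]; y <- y[ok]
  if (var(x) == 0 || var(y) == 0) {
    warn("constant input: Spearman correlation undefined")
    return(NA_real_)
  }
  cor(x, y, method = "spearman")
}

#' Pooled two-sample t statistic from summary statistics
#'
#' Equal-variance two-sample t computed from group means, SDs and sizes
#' alone — the check one can do against published tables without raw data.
#'
#' @param mean1,sd1,n1 First group's mean, SD and size.
#' @param mean2,sd2,n2 Second group's.
#'
#' @return A tibble: `statistic`, `df`, `p.value`, `mean_diff`.
#' @export
#' @examples
#' t_from_summary(52.3, 30.0, 1177, 43.0, 27.8, 685)
t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tval <- (mean1 - mean2) / se
  df <- n1 + n2 - 2
  tibble::tibble(
    statistic = tval,
    df = df,
    p.value = 2 * pt(-abs(tval), df),
    mean_diff = mean1 - mean2
  )
}

#' Descriptive statistics and group comparisons
#'
#' Per-variable means/SDs (proportions for the binary variables) for the
#' judgement subsample, a pooled-variance two-sample t test of BrAC by
#' gender on the full pool, and a one-way ANOVA of BrAC by location.
#'
#' @param pool The full survey pool.
#' @param subsample Optional judgement subsample; defaults to the pool rows
#'   with at least one rating answered.
#'
#' @return An object of class `cohort_descriptives`: a list of tibbles
#'   `summary`, `gender_t`, `location_anova`.
#' @export
#' @examples
#' pool <- generate_pool(cohort_config(pool_size = 400, seed = 3))
#' descriptives(pool)$gender_t
descriptives <- function(pool, subsample = NULL) {
  if (nrow(pool) == 0) abort("`pool` is empty")
  if (is.null(subsample)) {
    any_rating <- rowSums(!is.na(pool[, judgement_cols, drop = FALSE])) > 0
    subsample <- if (any(any_rating)) pool[any_rating, ] else pool
  }

  num_row <- function(var, label) {
    x <- subsample[[var]]
    tibble::tibble(variable = label, value = mean(x, na.rm = TRUE), sd = sd(x, na.rm = TRUE))
  }
  prop_row <- function(x, label) {
    tibble::tibble(variable = label, value = mean(x, na.rm = TRUE), sd = NA_real_)
  }
  summary_tbl <- dplyr::bind_rows(
    num_row("judge_drunk", "Perceived drunkenness"),
    num_row("judge_extreme", "Extreme drinking"),
    num_row("judge_health", "Long-term health"),
    num_row("judge_cirrhosis", "Liver cirrhosis"),
    num_row("brac", "BrAC (ug alcohol/100 ml breath)"),
    num_row("duration_h", "Session duration (hours)"),
    prop_row(subsample$after_11pm, "Proportion surveyed after 11 pm"),
    prop_row(as.numeric(subsample$gender == "M"), "Proportion male"),
    num_row("fast", "FAST"),
    num_row("age", "Age (years)")
  )

  tt <- t.test(brac ~ gender, data = pool, var.equal = TRUE)
  gender_t <- tibble::tibble(
    statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p.value = tt$p.value,
    mean_M = unname(tt$estimate[1]),
    mean_F = unname(tt$estimate[2])
  )

  an <- anova(lm(brac ~ location, data = pool))
  location_anova <- tibble::tibble(
    statistic = an[["F value"]][1],
    df1 = an[["Df"]][1],
    df2 = an[["Df"]][2],
    p.value = an[["Pr(>F)"]][1]
  )

  structure(
    list(summary = summary_tbl, gender_t = gender_t, location_anova = location_anova),
    class = "cohort_descriptives"
  )
}

#' @export
print.cohort_descriptives <- function(x, ...) {
  cat("Descriptive statistics (judgement subsample)\n")
  print(as.data.frame(x$summary), row.names = FALSE, digits = 4)
  cat(sprintf("\nBrAC by gender (pooled t): t = %.2f, df = %d, p = %.3g (M %.1f vs F %.1f)\n",
              x$gender_t$statistic, x$gender_t$df, x$gender_t$p.value,
              x$gender_t$mean_M, x$gender_t$mean_F))
  cat(sprintf("BrAC by location (one-way ANOVA): F(%d, %d) = %.1f, p = %.3g\n",
              x$location_anova$df1, x$location_anova$df2,
              x$location_anova$statistic, x$location_anova$p.value))
  invisible(x)
}
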