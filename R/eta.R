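# Grid-search estimation of the comparison-bias parameter eta.  For each
# grid value the weighted rank SR(eta) is recomputed from the stored
# comparator counts and the outcome is regressed on it; the eta with the
# greatest R-squared is selected.  eta < 1 reads as a downward bias:
# judgements lean on the more sober comparators.

#' Profile R-squared over an eta grid
#'
#' Recomputes the weighted rank `SR(eta)` for every judgement-eligible
#' respondent at each grid value (default 0.01 to 5 in steps of 0.01) and
#' fits the simple regression `outcome ~ SR(eta)`; the profile of
#' R-squared values identifies the comparison bias.  Ties at the maximum
#' (within 1e-12) are broken toward the smallest eta.
#'
#' @param data A ranked survey table carrying `below`/`above` comparator
#'   counts from [rank_brac()] on the full pool.
#' @param outcome Rating column to profile.
#' @param grid_start,grid_stop,grid_step Grid definition; `grid_start`
#'   must be positive.
#' @param adjust_covariates If `TRUE`, each grid fit also includes the
#'   sensitivity covariates (duration, after-11pm, gender, FAST, age);
#'   the default is the plain simple regression.
#'
#' @return An object of class `eta_profile`: the `(eta, r_squared)` grid
#'   tibble, `best_eta`, `best_r_squared`, and `n_used`.
#' @export
#' @examples
#' pool <- generate_pool(cohort_config(pool_size = 500, seed = 21))
#' mech <- judgement_mechanism("weighted_rank", eta = 0.7,
#'                             intercept = 2.78, slope = 3.42, target_r2 = 0.4)
#' sub <- generate_judgements(pool, mech, n_sub = 400, seed = 22)
#' prof <- scan_eta(sub, "judge_drunk", grid_stop = 2)
#' prof$best_eta
scan_eta <- function(data, outcome,
                     grid_start = 0.01, grid_stop = 5.0, grid_step = 0.01,
                     adjust_covariates = FALSE) {
  if (!is.numeric(grid_start) || grid_start <= 0) abort("`grid_start` must be positive")
  if (grid_step <= 0) abort("`grid_step` must be positive")
  if (grid_stop < grid_start) abort("`grid_stop` must be >= `grid_start`")
  if (!all(c("below", "above") %in% names(data))) {
    abort("comparator counts missing: run rank_brac() on the full pool first")
  }
  if (!outcome %in% names(data)) abort(paste0("no such outcome column: ", outcome))

  keep <- !is.na(data$brac) & data$brac > 0 & !is.na(data[[outcome]]) & !is.na(data$rank_rel)
  d <- data[keep, , drop = FALSE]
  if (nrow(d) < 10) {
    abort(sprintf("only %d judgement-eligible respondents with %s (need >= 10)", nrow(d), outcome))
  }

  grid <- seq(grid_start, grid_stop, by = grid_step)
  y <- d[[outcome]]
  if (var(y) == 0) abort(paste0(outcome, " is constant: R-squared profile undefined"))

  SR <- vapply(grid, function(e) weighted_rank_counts(d$below, d$above, e),
               numeric(nrow(d)))
  if (adjust_covariates) {
    if (!"male" %in% names(d)) d$male <- as.numeric(d$gender == "M")
    covs <- as.data.frame(d[, c("duration_h", "after_11pm", "male", "fast", "age")])
    r2 <- apply(SR, 2, function(sr) {
      summary(lm(y ~ ., data = cbind(sr = sr, covs)))$r.squared
    })
  } else {
    r2 <- suppressWarnings(as.vector(cor(y, SR)))^2
  }

  best <- max(r2, na.rm = TRUE)
  idx <- which(!is.na(r2) & r2 >= best - 1e-12)
  if (length(idx) > 1) {
    inform(sprintf("%d grid points tie at the maximal R-squared; smallest eta (%.2f) selected",
                   length(idx), grid[idx[1]]))
  }
  idx <- idx[1]

  structure(
    list(
      outcome = outcome,
      grid = tibble::tibble(eta = grid, r_squared = r2),
      best_eta = grid[idx],
      best_r_squared = r2[idx],
      n_used = nrow(d),
      adjusted = isTRUE(adjust_covariates)
    ),
    class = "eta_profile"
  )
}

#' @rdname scan_eta
#' @param x,object An `eta_profile`.
#' @param ... Unused.
#' @method tidy eta_profile
#' @export
tidy.eta_profile <- function(x, ...) x$grid

#' @rdname scan_eta
#' @method glance eta_profile
#' @export
glance.eta_profile <- function(x, ...) {
  tibble::tibble(
    outcome = x$outcome,
    best_eta = x$best_eta,
    best_r_squared = x$best_r_squared,
    n_used = x$n_used,
    adjusted = x$adjusted
  )
}

#' @export
print.eta_profile <- function(x, ...) {
  cat(sprintf("<eta_profile> %s: best eta = %.2f (R^2 = %.3f, n = %d%s)\n",
              x$outcome, x$best_eta, x$best_r_squared, x$n_used,
              if (x$adjusted) ", covariate-adjusted" else ""))
  invisible(x)
}

#' @rdname scan_eta
#' @method autoplot eta_profile
#' @export
autoplot.eta_profile <- function(object, ...) {
  ggplot2::ggplot(object$grid, ggplot2::aes(x = .data$eta, y = .data$r_squared)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_eta, linetype = "dashed") +
    ggplot2::labs(
      x = expression(eta), y = expression(R^2),
      title = sprintf("%s: best eta = %.2f", object$outcome, object$best_eta),
      subtitle = "eta < 1: more influence from more sober comparators"
    )
}
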