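# Reference groups and rank transforms.  A respondent's standing is judged
# against the other members of their gender x location cell: `below` counts
# comparators with strictly lower BrAC, `above` strictly higher, and the
# relative rank is below / (n - 1).  The weighted rank re-weights upward
# comparisons by eta, so eta < 1 means the more sober comparators dominate.

#' Weighted rank from comparator counts
#'
#' Computes `SR = 0.5 + (below - eta * above) / (2 * (below + eta * above))`
#' for vectors of strictly-below / strictly-above comparator counts.
#' At `eta = 1` (tie-free counts) this reduces exactly to the relative rank
#' `below / (n - 1)`.  When `below` and `above` are both 0 (everyone tied)
#' the symmetric limit 0.5 is returned.
#'
#' @param below,above Numeric vectors of comparator counts.
#' @param eta Positive scalar comparison-bias parameter; values below 1
#'   up-weight more-sober comparators, above 1 more-intoxicated ones.
#'
#' @return A numeric vector of weighted ranks in `[0, 1]`.
#' @export
#' @examples
#' weighted_rank_counts(below = 3, above = 1, eta = c(1))   # 0.75
#' weighted_rank_counts(below = 0, above = 9, eta = 0.3)    # minimum -> 0
weighted_rank_counts <- function(below, above, eta) {
  if (!is.numeric(eta) || length(eta) != 1 || is.na(eta) || eta <= 0) {
    abort("`eta` must be a positive number")
  }
  if (any(below < 0, na.rm = TRUE) || any(above < 0, na.rm = TRUE)) {
    abort("comparator counts must be nonnegative")
  }
  denom <- below + eta * above
  ifelse(denom == 0, 0.5, 0.5 + (below - eta * above) / (2 * denom))
}

#' Rank respondents within their reference groups
#'
#' Adds comparator counts and rank columns to a survey table.  Groups are
#' all observed gender x location combinations of the *input* table, so
#' rank a judgement subsample by ranking the full pool first and then
#' subsetting — ranking the subsample directly would use the wrong
#' comparison pool.  Zero-BrAC respondents are ranked like everyone else
#' (they are legitimate comparators); eligibility filtering is a separate,
#' later step ([judgement_eligible()]).
#'
#' @param data A survey table with `brac`, `gender`, `location` columns.
#' @param eta Positive comparison-bias parameter for the weighted rank
#'   column `rank_wt`.
#' @param ties `"strict"` (default) counts only strictly lower / strictly
#'   higher BrAC, so tied members fall in neither count; `"midrank"`
#'   splits ties evenly between the two counts (sensitivity mode).
#'
#' @return The input tibble plus columns `n_group`, `below`, `above`,
#'   `rank_rel` (relative rank in `[0, 1]`), `rank_wt` (weighted rank at
#'   `eta`), `group_mean_brac` and `group_mean_distance` (own BrAC minus
#'   own group's mean BrAC).  Members of singleton groups get `NA` ranks
#'   (with a warning); rows missing gender or location are dropped with a
#'   warning naming their ids.
#' @export
#' @examples
#' pool <- generate_pool(cohort_config(pool_size = 200, seed = 5))
#' ranked <- rank_brac(pool)
#' dplyr::select(ranked, id, brac, below, above, rank_rel) |> head()
rank_brac <- function(data, eta = 1, ties = c("strict", "midrank")) {
  ties <- match.arg(ties)
  need <- c("brac", "gender", "location")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    abort(paste0("`data` lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  bad <- is.na(data$gender) | is.na(data$location)
  if (any(bad)) {
    ids <- if ("id" %in% names(data)) data$id[bad] else which(bad)
    warn(paste0(sum(bad), " record(s) missing gender/location dropped: ",
                paste(head(ids, 5), collapse = ", "),
                if (sum(bad) > 5) ", ..." else ""))
    data <- data[!bad, , drop = FALSE]
  }
  if (anyNA(data$brac) || any(data$brac < 0)) {
    abort("`brac` must be nonnegative and non-missing")
  }

  out <- data |>
    dplyr::group_by(.data$gender, .data$location) |>
    dplyr::mutate(
      n_group = dplyr::n(),
      below = rank(.data$brac, ties.method = "min") - 1,
      above = dplyr::n() - rank(.data$brac, ties.method = "max"),
      group_mean_brac = mean(.data$brac)
    ) |>
    dplyr::ungroup()

  if (ties == "midrank") {
    n_tied <- out$n_group - 1 - out$below - out$above
    out$below <- out$below + n_tied / 2
    out$above <- out$above + n_tied / 2
  }

  singleton <- out$n_group == 1
  if (any(singleton)) {
    warn(paste0(sum(singleton), " respondent(s) in singleton reference groups: rank undefined, set to NA"))
  }
  out$rank_rel <- ifelse(singleton, NA_real_, out$below / (out$n_group - 1))
  # A member tied with every comparator has no defined standing; both rank
  # statistics take the symmetric limit 0.5 (degenerate, so it is logged).
  all_tied <- !singleton & out$below == 0 & out$above == 0
  if (any(all_tied)) {
    inform(paste0(sum(all_tied), " respondent(s) tied with all comparators; rank set to 0.5"))
    out$rank_rel[all_tied] <- 0.5
  }
  out$rank_wt <- weighted_rank_counts(out$below, out$above, eta)
  out$rank_wt[singleton] <- NA_real_
  out$group_mean_distance <- out$brac - out$group_mean_brac
  out
}

#' Summarise the gender x location reference groups
#'
#' @param data A survey table with `brac`, `gender`, `location`.
#'
#' @return A tibble with one row per observed gender x location group:
#'   `gender`, `location`, `n` (all members, zero-BrAC included), `n_zero_brac`,
#'   and `mean_brac`.  The mean of `n - 1` over groups is the average
#'   comparison-set size.
#' @export
#' @examples
#' groups <- reference_groups(generate_pool(cohort_config(seed = 1)))
#' mean(groups$n - 1)   # 231.75 for 1,862 respondents in 8 groups
reference_groups <- function(data) {
  data |>
    dplyr::filter(!is.na(.data$gender), !is.na(.data$location)) |>
    dplyr::group_by(.data$gender, .data$location) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_zero_brac = sum(.data$brac == 0),
      mean_brac = mean(.data$brac),
      .groups = "drop"
    )
}

#' Judgement-analysis eligibility
#'
#' Respondents with a BrAC of 0 were present in the environment (and so
#' count as ranking comparators) but are excluded from rank-judgement
#' analyses.  Optionally also requires a specific rating and the Model 4
#' covariate set to be non-missing.
#'
#' @param data A survey table.
#' @param outcome Optional rating column name that must be non-missing.
#' @param require_covariates If `TRUE`, additionally require complete
#'   `duration_h`, `after_11pm`, `fast`, `age` and `gender` (the Model 4
#'   covariates).
#'
#' @return A logical vector, one flag per row.
#' @export
#' @examples
#' pool <- generate_pool(cohort_config(pool_size = 100, seed = 4))
#' table(judgement_eligible(pool))
judgement_eligible <- function(data, outcome = NULL, require_covariates = FALSE) {
  ok <- !is.na(data$brac) & data$brac > 0
  if (!is.null(outcome)) {
    if (!outcome %in% names(data)) abort(paste0("no such outcome column: ", outcome))
    ok <- ok & !is.na(data[[outcome]])
  }
  if (isTRUE(require_covariates)) {
    ok <- ok & complete.cases(data[, c(covariate_cols, "gender")])
  }
  ok
}
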