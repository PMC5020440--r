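# The simulate -> rank -> fit -> scan -> report pipeline and its file
# formats.  Survey CSV dialect (one row per respondent, empty string =
# missing): id, brac_ug_per_100ml, gender {M,F}, location {1..n},
# survey_after_23h {0,1}, session_duration_h, fast_score, age_years,
# judge_drunk, judge_extreme, judge_health15y, judge_cirrhosis15y.

csv_dialect <- c(
  id = "id",
  brac_ug_per_100ml = "brac",
  gender = "gender",
  location = "location",
  survey_after_23h = "after_11pm",
  session_duration_h = "duration_h",
  fast_score = "fast",
  age_years = "age",
  judge_drunk = "judge_drunk",
  judge_extreme = "judge_extreme",
  judge_health15y = "judge_health",
  judge_cirrhosis15y = "judge_cirrhosis"
)

#' Read a survey CSV
#'
#' Parses the survey dialect (see Details) into the internal survey table,
#' validating every row: BrAC nonnegative, gender in `{M, F}`, location a
#' positive integer code, the after-23h flag in `{0, 1}`.  Violations are
#' reported per row and abort the read.
#'
#' @details Columns: `id`, `brac_ug_per_100ml`, `gender`, `location`,
#'   `survey_after_23h`, `session_duration_h`, `fast_score`, `age_years`,
#'   `judge_drunk`, `judge_extreme`, `judge_health15y`,
#'   `judge_cirrhosis15y`.  Header required, UTF-8, decimal point, empty
#'   string for missing.
#'
#' @param path Path to the CSV file.
#' @param n_locations Number of location codes the file may use (levels of
#'   the `location` factor); defaults to the codes observed.
#'
#' @return A survey tibble (see [generate_pool()] for the column contract).
#' @export
read_survey <- function(path, n_locations = NULL) {
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      id = readr::col_character(),
      brac_ug_per_100ml = readr::col_double(),
      gender = readr::col_character(),
      location = readr::col_integer(),
      survey_after_23h = readr::col_integer(),
      session_duration_h = readr::col_double(),
      fast_score = readr::col_double(),
      age_years = readr::col_double(),
      judge_drunk = readr::col_double(),
      judge_extreme = readr::col_double(),
      judge_health15y = readr::col_double(),
      judge_cirrhosis15y = readr::col_double()
    ),
    na = c("", "NA")
  )
  missing_cols <- setdiff(names(csv_dialect), names(raw))
  if (length(missing_cols)) {
    abort(paste0("survey CSV lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  problems <- character()
  bad_rows <- function(cond, what) {
    rows <- which(cond)
    if (length(rows)) {
      problems <<- c(problems, sprintf("row %d: %s", head(rows, 10), what))
    }
  }
  bad_rows(!is.na(raw$brac_ug_per_100ml) & raw$brac_ug_per_100ml < 0, "negative BrAC")
  bad_rows(is.na(raw$brac_ug_per_100ml), "missing BrAC")
  bad_rows(!is.na(raw$gender) & !raw$gender %in% c("M", "F"), "gender not M/F")
  bad_rows(!is.na(raw$location) & raw$location < 1, "location code < 1")
  bad_rows(!is.na(raw$survey_after_23h) & !raw$survey_after_23h %in% c(0L, 1L),
           "survey_after_23h not 0/1")
  if (length(problems)) {
    abort(paste0("survey CSV failed validation:\n", paste(problems, collapse = "\n")))
  }

  n_loc <- n_locations %||% max(raw$location, na.rm = TRUE)
  out <- tibble::tibble(
    id = raw$id,
    brac = raw$brac_ug_per_100ml,
    gender = factor(raw$gender, levels = c("M", "F")),
    location = factor(raw$location, levels = seq_len(n_loc)),
    duration_h = raw$session_duration_h,
    after_11pm = as.integer(raw$survey_after_23h),
    fast = raw$fast_score,
    age = raw$age_years,
    judge_drunk = raw$judge_drunk,
    judge_extreme = raw$judge_extreme,
    judge_health = raw$judge_health15y,
    judge_cirrhosis = raw$judge_cirrhosis15y
  )
  out
}

#' Write a survey table as CSV
#'
#' Inverse of [read_survey()]: writes the survey dialect with empty
#' strings for missing values.  `write_survey()` then `read_survey()`
#' round-trips the table exactly.
#'
#' @param data A survey tibble.
#' @param path Output path.
#'
#' @return `path`, invisibly.
#' @export
write_survey <- function(data, path) {
  out <- tibble::tibble(
    id = data$id,
    brac_ug_per_100ml = data$brac,
    gender = as.character(data$gender),
    location = as.integer(as.character(data$location)),
    survey_after_23h = as.integer(data$after_11pm),
    session_duration_h = data$duration_h,
    fast_score = data$fast,
    age_years = data$age,
    judge_drunk = data$judge_drunk,
    judge_extreme = data$judge_extreme,
    judge_health15y = data$judge_health,
    judge_cirrhosis15y = data$judge_cirrhosis
  )
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Run the full rank-judgement analysis pipeline
#'
#' Orchestrates the whole analysis: obtain a survey table (read a CSV, or
#' simulate a pool and judgement subsample from a [cohort_config()]),
#' build gender x location reference groups and ranks on the full pool,
#' filter to judgement-eligible respondents, fit Models 1-4 for each of
#' the four outcomes, compute collinearity diagnostics (Spearman rho of
#' BrAC vs rank and VIFs), profile eta per outcome, and assemble the
#' descriptives.  Every filtering step logs its in/out counts.
#'
#' @param input Path to a survey CSV, an existing survey tibble, or a
#'   [cohort_config()] (in which case a pool and judgement subsample are
#'   simulated).
#' @param mechanism Optional [judgement_mechanism()] used when simulating;
#'   defaults to a rank mechanism with intercept 2.78, slope 3.42 and
#'   noise tuned to R² 0.22.
#' @param seed Integer seed for the simulate path (the subsample draw uses
#'   `seed + 1`).
#' @param n_sub Judgement subsample size when simulating; defaults to the
#'   config's `judgement_subsample`.
#' @param group_mean Central-tendency control used in Models 3-4; see
#'   [model_predictors()].
#' @param eta_grid Named numeric `c(start, stop, step)` for [scan_eta()].
#' @param quiet Suppress progress messages.
#'
#' @return An object of class `analysis_report`: tibbles `groups`,
#'   `table2` (terms of all 16 fits), `fit_summaries`, `collinearity`,
#'   `eta_results`; the `descriptives`; a list of the underlying
#'   `judgement_fit` and `eta_profile` objects; and `provenance` (config
#'   hash, seed, package version, timestamp).
#' @export
#' @examples
#' \donttest{
#' rep <- run_pipeline(cohort_config(seed = 1), seed = 1)
#' rep$eta_results
#' }
run_pipeline <- function(input,
                         mechanism = NULL,
                         seed = 1L,
                         n_sub = NULL,
                         group_mean = c("distance", "raw"),
                         eta_grid = c(start = 0.01, stop = 5, step = 0.01),
                         quiet = FALSE) {
  group_mean <- match.arg(group_mean)
  say <- function(...) if (!quiet) inform(sprintf(...))

  simulated <- inherits(input, "cohort_config")
  if (simulated) {
    pool <- generate_pool(input, seed = seed)
    mech <- mechanism %||%
      judgement_mechanism("rank", intercept = 2.78, slope = 3.42, target_r2 = 0.22)
    sub <- generate_judgements(pool, mech, n_sub = n_sub %||% input$judgement_subsample,
                               seed = seed + 1L)
    survey <- pool
    survey[match(sub$id, survey$id), judgement_cols] <- sub[, judgement_cols]
    say("simulated pool of %d respondents; %d judgement ratings generated", nrow(pool), nrow(sub))
    input_desc <- list(kind = "simulated", config = unclass(input),
                       mechanism = unclass(mech))
  } else if (is.character(input)) {
    survey <- read_survey(input)
    say("read %d respondents from %s", nrow(survey), input)
    input_desc <- list(kind = "csv", path = input)
  } else if (is.data.frame(input)) {
    survey <- input
    input_desc <- list(kind = "table", n = nrow(input))
  } else {
    abort("`input` must be a survey CSV path, a survey table, or a cohort_config")
  }

  ranked <- rank_brac(survey)
  groups <- reference_groups(survey)
  say("%d reference groups; mean comparison-set size (n - 1) = %.2f",
      nrow(groups), mean(groups$n - 1))

  has_rating <- rowSums(!is.na(ranked[, judgement_cols, drop = FALSE])) > 0
  eligible <- judgement_eligible(ranked)
  say("eligibility: %d of %d respondents have BrAC > 0; %d answered judgement questions",
      sum(eligible), nrow(ranked), sum(has_rating & eligible))
  if (!any(has_rating & eligible)) {
    abort("no judgement-eligible respondents: every rated respondent has BrAC 0 or no ratings exist")
  }
  judge_rows <- ranked[has_rating & eligible, , drop = FALSE]

  fits <- list()
  for (outcome in judgement_cols) {
    if (all(is.na(judge_rows[[outcome]]))) {
      say("outcome %s has no responses; skipped", outcome)
      next
    }
    for (m in 1:4) {
      fits[[paste(outcome, m, sep = ".")]] <-
        fit_judgement_model(ranked, outcome, model = m, group_mean = group_mean, quiet = TRUE)
    }
  }
  table2 <- purrr::map_dfr(fits, function(f) {
    dplyr::mutate(tidy(f), outcome = f$outcome, model = f$model, .before = 1)
  })
  fit_summaries <- purrr::map_dfr(fits, glance)

  rho <- spearman_rho(judge_rows$brac, judge_rows$rank_rel)
  vif3 <- compute_vif(judge_rows[, model_predictors(3, group_mean)])
  collinearity <- tibble::tibble(
    diagnostic = c("spearman_rho_brac_rank", paste0("vif_", names(vif3))),
    value = c(rho, unname(vif3))
  )

  profiles <- purrr::map(
    setNames(unique(fit_summaries$outcome), unique(fit_summaries$outcome)),
    function(o) scan_eta(ranked, o,
                         grid_start = eta_grid[["start"]],
                         grid_stop = eta_grid[["stop"]],
                         grid_step = eta_grid[["step"]])
  )
  eta_results <- purrr::map_dfr(profiles, glance)

  desc <- descriptives(survey, subsample = judge_rows)

  provenance <- list(
    package = "ranknorms",
    version = as.character(packageVersion("ranknorms")),
    seed = as.integer(seed),
    group_mean = group_mean,
    input = input_desc,
    config_hash = rlang::hash(list(input_desc, group_mean, eta_grid, seed)),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )

  structure(
    list(
      groups = groups,
      descriptives = desc,
      table2 = table2,
      fit_summaries = fit_summaries,
      collinearity = collinearity,
      eta_results = eta_results,
      fits = fits,
      eta_profiles = profiles,
      survey = survey,
      provenance = provenance
    ),
    class = "analysis_report"
  )
}

# JSON-serialisable payload; the timestamp is carried separately so
# payloads from identical configs/seeds are byte-identical.
report_payload <- function(report) {
  prov <- report$provenance
  prov$timestamp <- NULL
  list(
    provenance = prov,
    groups = as.data.frame(report$groups),
    table1 = as.data.frame(report$descriptives$summary),
    gender_t = as.data.frame(report$descriptives$gender_t),
    location_anova = as.data.frame(report$descriptives$location_anova),
    table2 = as.data.frame(report$table2),
    fit_summaries = as.data.frame(report$fit_summaries),
    collinearity = as.data.frame(report$collinearity),
    eta_results = as.data.frame(report$eta_results)
  )
}

#' Write an analysis report to disk
#'
#' Writes `report.json` (the full numeric payload; timestamp kept in a
#' sidecar field so the payload is reproducible) and `tables.txt` (the
#' rendered text tables) into `dir`.
#'
#' @param report An `analysis_report` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#'
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "analysis_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  payload <- report_payload(report)
  jsonlite::write_json(
    list(payload = payload, generated_at = report$provenance$timestamp),
    file.path(dir, "report.json"),
    auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE
  )
  writeLines(capture.output(print(report)), file.path(dir, "tables.txt"))
  invisible(dir)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("== Rank-based social norms analysis report ==\n")
  cat(sprintf("(%s v%s, seed %d, config %s)\n\n",
              x$provenance$package, x$provenance$version,
              x$provenance$seed, substr(x$provenance$config_hash, 1, 8)))
  cat(sprintf("Reference groups (%d; mean comparison-set size %.2f):\n",
              nrow(x$groups), mean(x$groups$n - 1)))
  print(as.data.frame(x$groups), row.names = FALSE, digits = 4)
  cat("\n")
  print(x$descriptives)
  cat("\nRegression ladder (b with 95% CI, standardized beta, VIF):\n")
  for (o in unique(x$table2$outcome)) {
    cat(sprintf("\n-- %s --\n", o))
    block <- x$table2[x$table2$outcome == o, ]
    block$outcome <- NULL
    print(as.data.frame(block), row.names = FALSE, digits = 3)
    gl <- x$fit_summaries[x$fit_summaries$outcome == o, c("model", "r.squared", "n_used")]
    cat("R^2 by model: ",
        paste(sprintf("M%d = %.3f", gl$model, gl$r.squared), collapse = ", "),
        sprintf("  (n = %d)\n", gl$n_used[1]))
  }
  cat("\nCollinearity diagnostics:\n")
  print(as.data.frame(x$collinearity), row.names = FALSE, digits = 4)
  cat("\nComparison-bias (eta) scans:\n")
  print(as.data.frame(x$eta_results), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Histogram of positive BrAC by gender
#'
#' Mirrors the standard cohort figure: the distribution of breath alcohol
#' among respondents who yielded a positive reading, split by gender.
#'
#' @param data A survey table.
#' @param binwidth Histogram bin width in ug/100 ml.
#'
#' @return A ggplot object.
#' @export
plot_brac_histogram <- function(data, binwidth = 10) {
  d <- data[!is.na(data$brac) & data$brac > 0, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$brac, fill = .data$gender)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            position = "identity", alpha = 0.6) +
    ggplot2::labs(x = "BrAC (ug alcohol / 100 ml breath)", y = "respondents",
                  fill = "gender")
}
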