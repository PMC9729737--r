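## End-to-end orchestration: eligibility accounting, demographic
## summaries, and a config-driven pipeline writing CSV artifacts.

round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

covariate_columns <- function() {
  c("age", "sex", "site", "education", "smoking", "sleep_rating",
    "tv_minutes", "recpa_minutes")
}

#' Apply the eligibility filters
#'
#' Sequential filtering: participants failing the accelerometry valid-week
#' rule are removed first, then participants missing any covariate; a
#' participant failing both rules is counted once, at the first stage.
#'
#' @param cohort Cohort data.frame with a `participant_id` column and the
#'   covariate columns.
#' @param accel_included Logical vector aligned to rows: passed the
#'   accelerometry valid-week rule.
#' @return List: `data` (the analysis table) and `report` (class
#'   `eligibility_report`: `n_enrolled`, `n_removed_invalid_accelerometry`,
#'   `n_removed_missing_covariates`, `n_final`).
#' @export
apply_eligibility <- function(cohort, accel_included) {
  if (anyDuplicated(cohort$participant_id))
    stop("duplicate participant ids")
  if (length(accel_included) != nrow(cohort))
    stop("accelerometry flags must align with participants")
  n0 <- nrow(cohort)
  s1 <- cohort[accel_included, , drop = FALSE]
  n_accel <- n0 - nrow(s1)
  covs <- intersect(covariate_columns(), names(s1))
  ok <- stats::complete.cases(s1[, covs, drop = FALSE])
  s2 <- s1[ok, , drop = FALSE]
  n_cov <- nrow(s1) - nrow(s2)
  report <- structure(list(n_enrolled = n0,
                           n_removed_invalid_accelerometry = n_accel,
                           n_removed_missing_covariates = n_cov,
                           n_final = nrow(s2)),
                      class = "eligibility_report")
  list(data = s2, report = report)
}

#' @export
print.eligibility_report <- function(x, ...) {
  cat("Eligibility accounting\n")
  cat("  enrolled:                      ", x$n_enrolled, "\n")
  cat("  removed, invalid accelerometry:", x$n_removed_invalid_accelerometry, "\n")
  cat("  removed, missing covariates:   ", x$n_removed_missing_covariates, "\n")
  cat("  final analysis sample:         ", x$n_final, "\n")
  invisible(x)
}

summ_num <- function(variable, x, digits = 1) {
  data.frame(variable = variable, level = "",
             value = if (sum(!is.na(x)) < 2)
               paste0(formatC(mean(x, na.rm = TRUE), digits = digits,
                              format = "f"), " ± NA")
             else paste0(formatC(mean(x, na.rm = TRUE), digits = digits,
                                 format = "f"), " ± ",
                         formatC(stats::sd(x, na.rm = TRUE), digits = digits,
                                 format = "f")),
             mean = mean(x, na.rm = TRUE),
             sd = if (sum(!is.na(x)) < 2) NA_real_ else stats::sd(x, na.rm = TRUE),
             count = NA_real_, percent = NA_real_)
}

summ_cat <- function(variable, x) {
  tab <- table(x)
  do.call(rbind, lapply(names(tab), function(l) {
    pct <- round_half_up(100 * tab[[l]] / length(x))
    data.frame(variable = variable, level = l,
               value = paste0(tab[[l]], " (", pct, "%)"),
               mean = NA_real_, sd = NA_real_,
               count = as.numeric(tab[[l]]), percent = pct)
  }))
}

#' Demographic summary of the analysis sample
#'
#' Mean and SD for numeric variables, count (percentage of column n,
#' rounded half away from zero) for categorical variables, plus daily
#' behaviour minutes and their hour equivalents.
#'
#' @param data Analysis table (minute columns plus covariates).
#' @return data.frame: `variable`, `level`, formatted `value`, and numeric
#'   `mean`, `sd`, `count`, `percent`.
#' @export
summarize_demographics <- function(data) {
  if (!nrow(data)) stop("empty table")
  rows <- list(summ_num("age", data$age))
  if (!is.null(data$sex)) rows <- c(rows, list(summ_cat("sex", data$sex)))
  if (!is.null(data$education))
    rows <- c(rows, list(summ_num("education_years", data$education)))
  if (!is.null(data$smoking))
    rows <- c(rows, list(summ_cat("smoking", data$smoking)))
  for (p in intersect(tu_parts(), names(data))) {
    rows <- c(rows, list(summ_num(paste0(p, "_min"), data[[p]], digits = 0),
                         summ_num(paste0(p, "_h"), data[[p]] / 60, digits = 1)))
  }
  if (!is.null(data$sleep_rating)) {
    sq <- ifelse(data$sleep_rating <= 1, "good", "bad")
    rows <- c(rows, list(summ_cat("sleep_quality", factor(sq, c("good", "bad")))))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Default pipeline configuration
#'
#' @param seed Integer seed driving every random stage.
#' @param out_dir Directory for the CSV artifacts.
#' @param n,n_invalid_accel,n_missing_covariate Cohort roster, see
#'   [cohort_config()].
#' @param outcomes Outcome columns to analyse.
#' @param realloc_focal,realloc_max_delta Reallocation-curve settings.
#' @return Named list accepted by [run_pipeline()].
#' @export
pipeline_config <- function(seed = 1, out_dir = tempfile("codatime_run_"),
                            n = 426, n_invalid_accel = 21,
                            n_missing_covariate = 21,
                            outcomes = c("global_cognition", "ltm", "stm",
                                         "exec", "speed"),
                            realloc_focal = "mvpa", realloc_max_delta = 60) {
  list(seed = seed, out_dir = out_dir, n_participants = n,
       n_invalid_accel = n_invalid_accel,
       n_missing_covariate = n_missing_covariate, outcomes = outcomes,
       realloc_focal = realloc_focal, realloc_max_delta = realloc_max_delta)
}

read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- pipeline_config()
  base[names(cfg)] <- cfg
  base
}

#' Run the simulate-and-analyse pipeline
#'
#' Generates a synthetic cohort, applies the eligibility filters, derives
#' moderators and ilr coordinates, runs the per-outcome backward-selection
#' analysis with FDR adjustment, computes a reallocation prediction curve
#' at the compositional mean, and writes every artifact as CSV plus a
#' plain-text report. Deterministic given the config.
#'
#' @param config A [pipeline_config()] list, or the path to a YAML file of
#'   the same keys (the participant count is keyed `n_participants`).
#' @return Invisible list: `cohort`, `analysis` (prepared table),
#'   `eligibility`, `demographics`, `study`, `study_table`, `curve`,
#'   `files` (paths written).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- generate_cohort(cohort_config(
    n = config$n_participants, seed = config$seed,
    n_invalid_accel = config$n_invalid_accel,
    n_missing_covariate = config$n_missing_covariate))
  elig <- apply_eligibility(cohort, cohort$accel_valid)
  analysis <- prepare_analysis_data(elig$data)
  demo <- summarize_demographics(analysis)
  study <- run_study(analysis, config$outcomes)
  tab <- format_study_table(study)
  base_comp <- compositional_mean(as.matrix(analysis[, tu_parts()]))
  grid <- one_for_remaining_grid(base_comp, config$realloc_focal,
                                 max_delta = config$realloc_max_delta)
  oc <- config$outcomes[[1]]
  fit <- fit_model(analysis, study[[oc]]$spec)
  prof <- reference_profile(analysis, study[[oc]]$spec)
  curve <- predict_response_curve(fit, grid, prof)

  f <- list(
    cohort = file.path(config$out_dir, "cohort.csv"),
    composition = file.path(config$out_dir, "compositions.csv"),
    demographics = file.path(config$out_dir, "demographics.csv"),
    study = file.path(config$out_dir, "term_tables.csv"),
    curve = file.path(config$out_dir, "reallocation_curve.csv"),
    report = file.path(config$out_dir, "report.txt"))
  utils::write.csv(cohort, f$cohort, row.names = FALSE)
  utils::write.csv(analysis[, c("participant_id", tu_parts())],
                   f$composition, row.names = FALSE)
  utils::write.csv(demo, f$demographics, row.names = FALSE)
  utils::write.csv(tab, f$study, row.names = FALSE)
  utils::write.csv(curve, f$curve, row.names = FALSE)
  con <- file(f$report, "w")
  on.exit(close(con))
  rep <- elig$report
  writeLines(c("codatime pipeline report",
               paste("seed:", config$seed),
               paste("enrolled:", rep$n_enrolled),
               paste("removed (invalid accelerometry):",
                     rep$n_removed_invalid_accelerometry),
               paste("removed (missing covariates):",
                     rep$n_removed_missing_covariates),
               paste("final analysis sample:", rep$n_final),
               paste("outcomes analysed:",
                     paste(config$outcomes, collapse = ", ")),
               vapply(names(study), function(o) {
                 paste0("  ", o, ": n = ", study[[o]]$n,
                        ", composition ",
                        if (study[[o]]$spec$composition) "retained" else "removed")
               }, character(1))), con)
  invisible(list(cohort = cohort, analysis = analysis,
                 eligibility = elig$report, demographics = demo,
                 study = study, study_table = tab, curve = curve, files = f))
}
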