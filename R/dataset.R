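# Episode-level change-score datasets. One row per (participant, period)
# episode: participant_id, cohort, episode_label, period, then one numeric
# change-score column per panel variable. Missing cells stay NA; nothing is
# imputed at load time.

dataset_id_columns <- c("participant_id", "cohort", "episode_label", "period")

#' Load a change-score dataset from CSV
#'
#' Reads, type-checks and validates an episode table against a panel and a
#' cohort design. Unknown columns are rejected, non-numeric change cells are
#' reported by row and column, and episode labels must agree with the
#' cohort's schedule (retest cohorts only contribute `"Retest"` episodes).
#' Missing cells are kept as `NA` — downstream contrasts handle missingness
#' explicitly (listwise deletion by default).
#'
#' @param path CSV file path (comma-separated, UTF-8, header row).
#' @param panel the variable panel, default [default_panel()].
#' @param design the cohort design, default [default_design()].
#' @return a validated tibble of episodes.
#' @export
load_dataset <- function(path, panel = default_panel(), design = default_design()) {
  panel <- validate_panel(panel)
  header <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  missing <- setdiff(dataset_id_columns, header)
  if (length(missing) > 0) {
    stop_modulearn(paste0("dataset is missing mandatory column(s): ",
                          paste(missing, collapse = ", ")),
                   "modulearn_format_error")
  }
  unknown <- setdiff(header, c(dataset_id_columns, panel$variable_id))
  if (length(unknown) > 0) {
    stop_modulearn(paste0("dataset contains unknown column(s): ",
                          paste(unknown, collapse = ", ")),
                   "modulearn_format_error")
  }
  vars <- intersect(panel$variable_id, header)
  types <- c(
    setNames(list(readr::col_character(), readr::col_character(),
                  readr::col_character(), readr::col_integer()),
             dataset_id_columns),
    setNames(rep(list(readr::col_double()), length(vars)), vars))
  # readr's own parse warning is superseded by the typed error below
  data <- suppressWarnings(
    readr::read_csv(path, col_types = do.call(readr::cols, types),
                    na = c("", "NA")))
  probs <- readr::problems(data)
  if (nrow(probs) > 0) {
    p1 <- probs[1, ]
    stop_modulearn(
      sprintf("non-numeric value in row %d, column '%s' (%s)",
              p1$row, header[p1$col], p1$actual),
      "modulearn_parse_error")
  }
  validate_dataset(data, panel, design)
}

#' Validate a change-score dataset
#'
#' @param data an episode tibble (see [load_dataset()] for the layout).
#' @param panel the variable panel.
#' @param design the cohort design.
#' @return the validated dataset, column-ordered as id columns then panel
#'   variables.
#' @export
validate_dataset <- function(data, panel = default_panel(), design = default_design()) {
  panel <- validate_panel(panel)
  design <- validate_design(design)
  data <- tibble::as_tibble(data)

  missing <- setdiff(c(dataset_id_columns, panel$variable_id), names(data))
  if (length(missing) > 0) {
    stop_modulearn(paste0("dataset is missing column(s): ",
                          paste(head(missing, 5), collapse = ", ")),
                   "modulearn_format_error")
  }
  unknown <- setdiff(names(data), c(dataset_id_columns, panel$variable_id))
  if (length(unknown) > 0) {
    stop_modulearn(paste0("dataset contains unknown column(s): ",
                          paste(unknown, collapse = ", ")),
                   "modulearn_format_error")
  }
  bad_cohort <- setdiff(unique(data$cohort), design$cohort)
  if (length(bad_cohort) > 0) {
    stop_modulearn(paste0("unknown cohort label(s): ",
                          paste(bad_cohort, collapse = ", ")),
                   "modulearn_validation_error")
  }

  expected <- design_episode_labels(design)
  joined <- dplyr::left_join(
    data[dataset_id_columns], expected, by = c("cohort", "period"),
    suffix = c("", ".expected"))
  bad <- which(is.na(joined$episode_label.expected) |
                 joined$episode_label != joined$episode_label.expected)
  if (length(bad) > 0) {
    b <- joined[bad[1], ]
    stop_modulearn(
      sprintf(paste0("episode_label '%s' (row %d) is inconsistent with the ",
                     "schedule of cohort %s in period %d"),
              b$episode_label, bad[1], b$cohort, b$period),
      "modulearn_validation_error")
  }

  dup <- duplicated(data[c("participant_id", "period")])
  if (any(dup)) {
    d <- data[which(dup)[1], ]
    stop_modulearn(
      sprintf("participant %s has more than one episode in period %d",
              d$participant_id, d$period),
      "modulearn_validation_error")
  }

  data[c(dataset_id_columns, panel$variable_id)]
}

#' Write a change-score dataset to CSV
#' @param data a validated episode tibble.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path) {
  readr::write_csv(data, path)
  invisible(path)
}
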