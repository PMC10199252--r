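# The distress panel: 68 change-score variables over 16 clinical
# questionnaires, each with an improvement direction (+1 when a raw-score
# DECREASE means improvement, i.e. distress-coded; -1 when an INCREASE means
# improvement, i.e. wellbeing-coded).

panel_columns <- c("variable_id", "questionnaire", "subscale_name",
                   "is_total_score", "improvement_direction")

#' The packaged 68-variable distress panel
#'
#' Returns the default panel of 68 self-report change-score variables grouped
#' under 16 clinically relevant questionnaires (ADHD self-report, NPI-40,
#' Borderline Personality Questionnaire, Machiavellianism scale, Mental Health
#' Continuum, Pain Catastrophizing Scale, Satisfaction With Life, Intolerance
#' of Uncertainty, BDI-II, Trier Inventory for Chronic Stress, UCLA
#' Loneliness, Perceived Stress Scale, Pittsburgh Sleep Quality Index,
#' Freiburg Bodily Complaints, Toronto Alexithymia, STAI). Wellbeing-coded
#' scales (Mental Health Continuum, Satisfaction With Life) carry
#' `improvement_direction = -1`; all distress-coded scales carry `+1`.
#'
#' The exact subscale inventory of the original study is not public; this
#' panel distributes standard subscales of the 16 named instruments so the
#' total is exactly 68. It is plain data: read your own panel with
#' [read_panel()] to replace it.
#'
#' @return a tibble with columns `variable_id`, `questionnaire`,
#'   `subscale_name`, `is_total_score`, `improvement_direction`.
#' @export
#' @examples
#' p <- default_panel()
#' nrow(p)                      # 68
#' dplyr::n_distinct(p$questionnaire)  # 16
default_panel <- function() {
  sub <- function(q, subs, totals = "total") {
    tibble::tibble(
      variable_id = paste0(q, "_", subs),
      questionnaire = q,
      subscale_name = gsub("_", " ", subs),
      is_total_score = subs %in% totals
    )
  }
  p <- dplyr::bind_rows(
    sub("adhd", c("attention", "impulsivity", "hyperactivity", "total")),
    sub("npi",  c("authority", "exhibitionism", "superiority", "entitlement",
                  "exploitativeness", "self_sufficiency", "vanity", "total")),
    sub("bpq",  c("impulsivity", "affective_instability", "abandonment",
                  "relationships", "self_image", "suicide_self_harm",
                  "emptiness", "intense_anger", "quasi_psychotic", "total")),
    sub("mach", "total"),
    sub("mhc",  c("emotional_wellbeing", "social_wellbeing",
                  "psychological_wellbeing", "total")),
    sub("pcs",  c("rumination", "magnification", "helplessness", "total")),
    sub("swls", "total"),
    sub("ius",  c("prospective_anxiety", "inhibitory_anxiety",
                  "negative_affect_uncertainty", "total")),
    sub("bdi",  c("cognitive", "somatic_affective", "total")),
    sub("tics", c("work_overload", "social_overload", "work_demands",
                  "work_discontent", "excessive_demands",
                  "lack_social_recognition", "social_tension",
                  "social_isolation", "chronic_worrying", "screening_total"),
        totals = "screening_total"),
    sub("ucla", "total"),
    sub("pss",  "total"),
    sub("psqi", "total"),
    sub("fbl",  c("general_complaints", "emotional_reactivity",
                  "cardiovascular", "gastrointestinal", "head_neck",
                  "tension", "sensory", "pain", "tiredness", "total")),
    sub("tas",  c("difficulty_identifying", "difficulty_describing",
                  "external_thinking", "total")),
    sub("stai", c("state_anxiety", "trait_anxiety"))
  )
  p$improvement_direction <- ifelse(p$questionnaire %in% c("mhc", "swls"), -1L, 1L)
  validate_panel(p)
}

#' Validate a distress panel
#'
#' Checks column presence, unique variable ids and the improvement-direction
#' coding. Returns the panel (as a tibble) invisibly usable in a pipe.
#'
#' @param panel a data frame with the columns of [default_panel()].
#' @return the validated panel as a tibble.
#' @export
validate_panel <- function(panel) {
  panel <- tibble::as_tibble(panel)
  missing <- setdiff(panel_columns, names(panel))
  if (length(missing) > 0) {
    stop_modulearn(
      paste0("panel is missing mandatory column(s): ",
             paste(missing, collapse = ", ")),
      "modulearn_format_error")
  }
  if (anyDuplicated(panel$variable_id)) {
    dup <- unique(panel$variable_id[duplicated(panel$variable_id)])
    stop_modulearn(paste0("duplicated variable_id: ", paste(dup, collapse = ", ")),
                   "modulearn_validation_error")
  }
  if (!all(panel$improvement_direction %in% c(-1L, 1L))) {
    stop_modulearn("improvement_direction must be +1 or -1 for every variable",
                   "modulearn_validation_error")
  }
  panel$is_total_score <- as.logical(panel$is_total_score)
  panel$improvement_direction <- as.integer(panel$improvement_direction)
  panel[panel_columns]
}

#' Read a panel definition from CSV or YAML
#'
#' @param path file path; format chosen by extension (`.yml`/`.yaml` for
#'   YAML, anything else is read as CSV).
#' @return a validated panel tibble.
#' @export
read_panel <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    raw <- yaml::read_yaml(path)
    panel <- purrr::map_dfr(raw, tibble::as_tibble)
  } else {
    panel <- readr::read_csv(path, show_col_types = FALSE,
                             col_types = readr::cols(
                               variable_id = "c", questionnaire = "c",
                               subscale_name = "c", is_total_score = "l",
                               improvement_direction = "i"))
  }
  validate_panel(panel)
}

#' Write a panel definition to CSV
#' @param panel a validated panel tibble.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  readr::write_csv(validate_panel(panel), path)
  invisible(path)
}

#' Compute a change score
#'
#' Change scores are post-module minus pre-module questionnaire scores.
#' Missing values propagate: if either score is `NA` the change is `NA`.
#'
#' @param pre_score,post_score numeric vectors of equal length.
#' @return `post_score - pre_score`.
#' @export
#' @examples
#' compute_change(pre_score = 12, post_score = 10)  # -2
compute_change <- function(pre_score, post_score) {
  ok <- function(x) is.numeric(x) || all(is.na(x)) # bare NA is fine
  if (!ok(pre_score) || !ok(post_score)) {
    stop_modulearn("pre_score and post_score must be numeric",
                   "modulearn_contract_error")
  }
  as.numeric(post_score) - as.numeric(pre_score)
}
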