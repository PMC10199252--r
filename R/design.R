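# Cohort design: which cohorts exist, how many participants each has, and
# which training module each cohort practices in each 3-month period. A
# cohort with an empty schedule is a retest control: its episodes are labeled
# "Retest" for every period of the study.

module_labels <- c("Presence", "Affect", "Perspective")
retest_label <- "Retest"

#' Construct a cohort design
#'
#' @param cohort character vector of cohort labels (e.g. `"RCC"`, `"TC1"`).
#' @param size integer vector of participant counts.
#' @param schedule list of character vectors; each the ordered module labels
#'   practiced per 3-month period. An empty vector marks a retest control
#'   cohort, which contributes `"Retest"` episodes in every study period.
#' @return a tibble with columns `cohort`, `size`, `schedule` (list-column),
#'   of class `cohort_design`.
#' @export
#' @examples
#' cohort_design(
#'   cohort = c("RCC", "TC1"),
#'   size = c(90, 80),
#'   schedule = list(character(), c("Presence", "Affect", "Perspective")))
cohort_design <- function(cohort, size, schedule) {
  d <- tibble::tibble(cohort = as.character(cohort),
                      size = as.integer(size),
                      schedule = schedule)
  validate_design(d)
}

#' The packaged four-cohort study design
#'
#' One retest control cohort (RCC, n = 90) and three training cohorts:
#' TC1 (n = 80) practicing Presence, Affect, Perspective; TC2 (n = 81)
#' practicing Presence, Perspective, Affect; TC3 (n = 81) practicing a single
#' Affect period. Total 332 participants. The TC1/TC2 orders are the two
#' counterbalanced arms (Presence and Perspective are never counterbalanced
#' against each other, which is why that contrast is forbidden downstream).
#'
#' @return a `cohort_design` tibble.
#' @export
default_design <- function() {
  cohort_design(
    cohort = c("RCC", "TC1", "TC2", "TC3"),
    size = c(90L, 80L, 81L, 81L),
    schedule = list(character(),
                    c("Presence", "Affect", "Perspective"),
                    c("Presence", "Perspective", "Affect"),
                    c("Affect")))
}

#' Validate a cohort design
#' @param design a data frame with columns `cohort`, `size`, `schedule`.
#' @return the validated design.
#' @export
validate_design <- function(design) {
  design <- tibble::as_tibble(design)
  missing <- setdiff(c("cohort", "size", "schedule"), names(design))
  if (length(missing) > 0) {
    stop_modulearn(paste0("design is missing column(s): ",
                          paste(missing, collapse = ", ")),
                   "modulearn_format_error")
  }
  if (anyDuplicated(design$cohort)) {
    stop_modulearn("cohort labels must be unique", "modulearn_validation_error")
  }
  if (any(design$size < 1L)) {
    stop_modulearn("cohort sizes must be >= 1", "modulearn_validation_error")
  }
  for (i in seq_len(nrow(design))) {
    sch <- design$schedule[[i]]
    if (length(sch) == 0) next
    if (!all(sch %in% module_labels)) {
      stop_modulearn(paste0("unknown module label in schedule of cohort ",
                            design$cohort[i]), "modulearn_validation_error")
    }
    if (anyDuplicated(sch)) {
      stop_modulearn(paste0("schedule of cohort ", design$cohort[i],
                            " repeats a module"), "modulearn_validation_error")
    }
  }
  structure(design[c("cohort", "size", "schedule")],
            class = c("cohort_design", class(tibble::tibble())))
}

# number of 3-month periods in the study = longest training schedule
n_periods <- function(design) {
  max(1L, max(lengths(design$schedule)))
}

# expand a design into one row per (cohort, period) with its episode label;
# retest cohorts get "Retest" for every study period, training cohorts only
# the periods their schedule covers
design_episode_labels <- function(design) {
  np <- n_periods(design)
  purrr::map_dfr(seq_len(nrow(design)), function(i) {
    sch <- design$schedule[[i]]
    if (length(sch) == 0) {
      tibble::tibble(cohort = design$cohort[i], period = seq_len(np),
                     episode_label = retest_label)
    } else {
      tibble::tibble(cohort = design$cohort[i], period = seq_along(sch),
                     episode_label = sch)
    }
  })
}

#' Read a cohort design from YAML
#'
#' The YAML maps each cohort label to a `size` and a `schedule` list, e.g.
#' `RCC: {size: 90, schedule: []}`.
#'
#' @param path YAML file path.
#' @return a validated `cohort_design`.
#' @export
read_design <- function(path) {
  raw <- yaml::read_yaml(path)
  cohort_design(
    cohort = names(raw),
    size = purrr::map_int(raw, ~ as.integer(.x$size)),
    schedule = unname(purrr::map(raw, ~ as.character(.x$schedule %||% character()))))
}

#' Write a cohort design to YAML
#' @param design a validated `cohort_design`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  design <- validate_design(design)
  out <- purrr::map(seq_len(nrow(design)), function(i) {
    list(size = design$size[i], schedule = as.list(design$schedule[[i]]))
  })
  names(out) <- design$cohort
  yaml::write_yaml(out, path)
  invisible(path)
}
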