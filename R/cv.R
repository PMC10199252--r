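# Contrast construction and the repeated cross-validation engine: builds
# episode-level binary problems, runs group-aware stratified 10-fold CV over
# a set of classifier specs (filtered specs re-run the four-stage variable
# filter inside every training fold), and tests balanced accuracy against
# chance with a one-sided Wilcoxon signed-rank test.

contrast_names <- c("TrainingVsRetest", "PresenceVsAffect", "AffectVsPerspective")

#' Construct a contrast specification
#'
#' The three supported contrasts are training-vs-retest (first-period
#' training episodes pooled against retest episodes) and the two module
#' contrasts Presence-vs-Affect and Affect-vs-Perspective. Presence and
#' Perspective are never counterbalanced against each other in the cohort
#' design, so `"PresenceVsPerspective"` is rejected at construction.
#'
#' @param name one of `"TrainingVsRetest"`, `"PresenceVsAffect"`,
#'   `"AffectVsPerspective"`.
#' @param positive_class label coded as the positive (second factor) class;
#'   defaults to the first-named module (`"Presence"`, `"Perspective"`) for
#'   the module contrasts — the coding under which negative coefficients of
#'   distress-coded variables point to that module — and `"Training"` for
#'   training-vs-retest.
#' @param all_periods for `"TrainingVsRetest"` only: pool episodes from all
#'   periods instead of the default first-period-only design (in which every
#'   participant contributes exactly one episode).
#' @return an object of class `contrast_spec`.
#' @export
contrast_spec <- function(name, positive_class = NULL, all_periods = FALSE) {
  if (identical(name, "PresenceVsPerspective") ||
      identical(name, "PerspectiveVsPresence")) {
    stop_modulearn(
      "the Presence and Perspective modules are not counterbalanced and cannot be contrasted directly",
      "modulearn_validation_error")
  }
  if (length(name) != 1L || !name %in% contrast_names) {
    stop_modulearn(paste0("unknown contrast: ", paste(name, collapse = ", ")),
                   "modulearn_contract_error")
  }
  classes <- switch(name,
                    TrainingVsRetest = c("Retest", "Training"),
                    PresenceVsAffect = c("Affect", "Presence"),
                    AffectVsPerspective = c("Affect", "Perspective"))
  positive <- positive_class %||% classes[2]
  if (!positive %in% classes) {
    stop_modulearn("positive_class must be one of the contrast's classes",
                   "modulearn_contract_error")
  }
  structure(list(name = name,
                 classes = c(setdiff(classes, positive), positive),
                 positive = positive,
                 all_periods = isTRUE(all_periods)),
            class = "contrast_spec")
}

#' Build the classification problem for a contrast
#'
#' Selects the episodes the contrast compares, keeps complete cases on the
#' panel variables (listwise deletion; nothing is imputed), and returns the
#' design matrix, binary labels (positive class second factor level) and the
#' participant grouping used for leakage-safe folds.
#'
#' @param dataset a validated episode tibble.
#' @param contrast a [contrast_spec()] or a contrast name.
#' @param panel the variable panel.
#' @return a list of class `contrast_data` with elements `X` (matrix), `y`
#'   (factor), `groups` (participant ids), `episodes` (the retained rows)
#'   and `contrast`.
#' @export
build_contrast <- function(dataset, contrast, panel = default_panel()) {
  if (is.character(contrast)) contrast <- contrast_spec(contrast)
  stopifnot(inherits(contrast, "contrast_spec"))
  panel <- validate_panel(panel)
  vars <- intersect(panel$variable_id, names(dataset))
  if (length(vars) == 0) {
    stop_modulearn("dataset contains no panel variables", "modulearn_format_error")
  }

  if (contrast$name == "TrainingVsRetest") {
    rows <- dataset
    if (!contrast$all_periods) rows <- dplyr::filter(rows, .data$period == 1L)
    rows <- dplyr::filter(rows, .data$episode_label %in% c(module_labels, retest_label))
    cls <- ifelse(rows$episode_label == retest_label, "Retest", "Training")
  } else {
    wanted <- contrast$classes
    rows <- dplyr::filter(dataset, .data$episode_label %in% wanted)
    cls <- rows$episode_label
  }
  complete <- complete.cases(rows[vars])
  rows <- rows[complete, ]
  cls <- cls[complete]

  tab <- table(factor(cls, levels = contrast$classes))
  if (any(tab < 10L)) {
    short <- names(tab)[tab < 10L][1]
    stop_modulearn(
      sprintf("class %s has only %d complete episodes (need >= 10)",
              short, tab[short]),
      "modulearn_data_error")
  }
  structure(list(X = as_X_matrix(rows[vars]),
                 y = factor(cls, levels = contrast$classes),
                 groups = rows$participant_id,
                 episodes = rows,
                 contrast = contrast),
            class = "contrast_data")
}

#' The default four-classifier set
#'
#' Logistic regression and random forest, each with and without the
#' four-stage variable filter.
#'
#' @return a named list of [classifier_spec()] objects.
#' @export
default_classifier_set <- function() {
  list(
    logistic_regression = classifier_spec("logistic_regression"),
    logistic_regression_filtered = classifier_spec("logistic_regression", filtered = TRUE),
    random_forest = classifier_spec("random_forest"),
    random_forest_filtered = classifier_spec("random_forest", filtered = TRUE))
}

#' Repeated group-aware stratified cross-validation
#'
#' Runs `n_repeats` independent stratified `n_folds`-fold cross-validations.
#' Folds never split a participant's episodes across train and test and are
#' shared across classifier specs within a repetition. Filtered specs run
#' the four-stage selection pipeline on each training fold and fit on the
#' surviving variables, falling back to all variables when none survive
#' (counted in the result). The per-repetition score of a spec is its mean
#' held-out balanced accuracy over folds.
#'
#' @param X complete-case episode-by-variable matrix.
#' @param y binary labels (positive class = second factor level).
#' @param groups optional participant ids.
#' @param specs a named list of [classifier_spec()]s (default
#'   [default_classifier_set()]).
#' @param n_folds folds per repetition (default 10).
#' @param n_repeats repetitions (default 10).
#' @param seed master seed.
#' @param control a [selection_control()] for the filtered specs.
#' @return an object of class `cv_result`; see [glance.cv_result()].
#' @export
run_cv <- function(X, y, groups = NULL, specs = default_classifier_set(),
                   n_folds = 10L, n_repeats = 10L, seed = 1L,
                   control = selection_control()) {
  X <- as_X_matrix(X)
  y <- as_binary_y(y)
  if (is.null(names(specs)) || any(names(specs) == "")) {
    names(specs) <- vapply(specs, function(s) {
      paste0(s$family, if (s$filtered) "_filtered" else "")
    }, character(1))
  }
  any_filtered <- any(vapply(specs, function(s) s$filtered, logical(1)))
  vars <- colnames(X)

  bac_rows <- list()
  fallbacks <- setNames(integer(length(specs)), names(specs))
  rep_sets <- vector("list", n_repeats) # fold-aggregated selections per rep
  need <- if (control$fold_aggregation == "majority") floor(n_folds / 2) + 1L else 1L

  for (r in seq_len(n_repeats)) {
    folds <- make_folds(y, groups, n_folds, seed = child_seed(seed, 201L, r))
    assert_group_integrity(folds, groups)
    # the filter depends only on the training fold, so filtered specs share it
    fold_sel <- if (any_filtered) {
      lapply(seq_len(n_folds), function(f) {
        fold_pipeline(X, y, rows = which(folds != f),
                      seed = child_seed(seed, 202L, r, f), control = control)
      })
    }
    if (any_filtered) {
      counts <- table(unlist(fold_sel))
      rep_sets[[r]] <- sort(names(counts)[counts >= need])
    }
    for (si in seq_along(specs)) {
      spec <- specs[[si]]
      fold_bac <- vapply(seq_len(n_folds), function(f) {
        tr <- folds != f
        use <- vars
        if (spec$filtered) {
          use <- fold_sel[[f]]
          if (length(use) == 0) {
            fallbacks[si] <<- fallbacks[si] + 1L
            use <- vars
          }
        }
        fit <- fit_classifier(spec, X[tr, use, drop = FALSE], y[tr],
                              seed = child_seed(seed, 203L, r, f, si))
        pred <- predict(fit, X[!tr, use, drop = FALSE])
        balanced_accuracy(y[!tr], pred)
      }, numeric(1))
      bac_rows[[length(bac_rows) + 1L]] <- tibble::tibble(
        spec_id = names(specs)[si], family = spec$family,
        filtered = spec$filtered, repetition = r, bac = mean(fold_bac))
    }
  }

  bacs <- dplyr::bind_rows(bac_rows)
  summary <- bacs |>
    dplyr::group_by(.data$spec_id, .data$family, .data$filtered) |>
    dplyr::summarise(
      median_bac = median(.data$bac),
      q25 = unname(quantile(.data$bac, 0.25)),
      q75 = unname(quantile(.data$bac, 0.75)),
      p_value = if (dplyr::n() >= 5) test_above_chance(.data$bac) else NA_real_,
      .groups = "drop")

  trace <- if (any_filtered) {
    counts <- table(unlist(rep_sets))
    rate <- setNames(numeric(length(vars)), vars)
    rate[names(counts)] <- as.numeric(counts) / n_repeats
    new_selection_trace(vars, rate, rep_sets, 0.95, n_repeats)
  }
  structure(list(bacs = bacs, summary = summary, trace = trace,
                 fallbacks = fallbacks, n_folds = n_folds,
                 n_repeats = n_repeats, seed = as.integer(seed)),
            class = "cv_result")
}

#' Build a contrast and cross-validate it in one call
#'
#' @inheritParams build_contrast
#' @inheritParams run_cv
#' @return a `cv_result` with the contrast name attached.
#' @export
analyze_contrast <- function(dataset, contrast, panel = default_panel(),
                             specs = default_classifier_set(), n_folds = 10L,
                             n_repeats = 10L, seed = 1L,
                             control = selection_control()) {
  cd <- build_contrast(dataset, contrast, panel)
  res <- run_cv(cd$X, cd$y, cd$groups, specs = specs, n_folds = n_folds,
                n_repeats = n_repeats, seed = seed, control = control)
  res$contrast <- cd$contrast$name
  res
}

#' One-sided Wilcoxon signed-rank test of balanced accuracy against chance
#'
#' Tests whether the median per-repetition balanced accuracy exceeds 0.5.
#' Uses the exact signed-rank distribution for n <= 25 untied values and the
#' normal approximation with continuity correction otherwise. Repetitions
#' exactly at 0.5 drop out of the statistic, as usual for signed ranks; if
#' all values equal 0.5 the sample is degenerate and p = 1 is returned with
#' a warning.
#'
#' @param bacs numeric vector of per-repetition balanced accuracies
#'   (at least 5).
#' @return the one-sided p-value.
#' @export
test_above_chance <- function(bacs) {
  if (length(bacs) < 5L) {
    stop_modulearn("need at least 5 per-repetition values",
                   "modulearn_contract_error")
  }
  z <- bacs - 0.5
  if (all(z == 0)) {
    warn("all balanced accuracies equal 0.5; the signed-rank sample is degenerate",
         class = "modulearn_degenerate_sample")
    return(1)
  }
  nz <- z[z != 0]
  exact <- length(nz) <= 25L && !any(duplicated(abs(nz)))
  ht <- suppressWarnings(
    wilcox.test(bacs, mu = 0.5, alternative = "greater",
                exact = exact, correct = TRUE))
  unname(ht$p.value)
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result>", if (!is.null(x$contrast)) x$contrast else "",
      sprintf("%d x %d-fold CV\n", x$n_repeats, x$n_folds))
  print(glance(x))
  invisible(x)
}

#' Per-repetition balanced accuracies of a CV run
#' @param x a `cv_result`.
#' @param ... unused.
#' @return a tibble with one row per (spec, repetition).
#' @method tidy cv_result
#' @export
tidy.cv_result <- function(x, ...) x$bacs

#' Summary of a CV run
#' @param x a `cv_result`.
#' @param ... unused.
#' @return a tibble with one row per spec: median balanced accuracy, IQR
#'   bounds, and the Wilcoxon p-value against chance.
#' @method glance cv_result
#' @export
glance.cv_result <- function(x, ...) x$summary

#' Write the standard result files of a CV run
#'
#' Writes `bac_per_repetition.tsv`, `bac_summary.tsv`, `selection_rates.tsv`
#' (when a filtered spec ran) and `run_metadata.json` into a directory.
#'
#' @param result a `cv_result`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cv_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(result$bacs, file.path(dir, "bac_per_repetition.tsv"))
  readr::write_tsv(result$summary, file.path(dir, "bac_summary.tsv"))
  if (!is.null(result$trace)) {
    write_selection_trace(result$trace, file.path(dir, "selection_rates.tsv"))
  }
  meta <- list(
    package = "modulearn",
    version = as.character(utils::packageVersion("modulearn")),
    contrast = result$contrast,
    seed = result$seed, n_folds = result$n_folds, n_repeats = result$n_repeats,
    filter_fallbacks = as.list(result$fallbacks))
  jsonlite::write_json(meta, file.path(dir, "run_metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
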