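# Four-stage stability selection:
#   stage 1  per-algorithm informativeness (random forest, sum-of-trees
#            ensemble, elastic net), each thresholded by its own
#            scale-free cutoff
#   stage 2  majority vote: keep variables flagged by >= 2 of the 3
#   stage 3  bootstrap forward/backward stepwise refinement on median
#            out-of-bootstrap balanced accuracy of a logistic model
#   stage 4  repeat stages 1-3 inside repeated stratified 10-fold CV and
#            keep variables whose selection rate reaches a threshold
#            (default 0.95 over the configured repetitions)

#' Control parameters for the selection pipeline
#'
#' @param n_bootstrap bootstrap resamples in the stepwise stage (default 100).
#' @param improvement_tolerance minimum gain in median out-of-bootstrap
#'   balanced accuracy a forward addition must deliver (default 0.005,
#'   about twice the Monte-Carlo error of the median at 100 resamples, so
#'   chance-level jitter cannot admit a variable).
#' @param fold_aggregation how folds aggregate within one repetition: a
#'   variable counts as selected in a repetition when the stage-1..3 pipeline
#'   selects it in a `"majority"` of folds (default) or in `"any"` fold.
#' @param rf,brt,en classifier specs for the three stage-1 algorithms; override
#'   to change hyperparameters (e.g. fewer trees for small problems).
#' @return a list of class `selection_control`.
#' @export
selection_control <- function(n_bootstrap = 100L,
                              improvement_tolerance = 0.005,
                              fold_aggregation = c("majority", "any"),
                              rf = classifier_spec("random_forest"),
                              brt = classifier_spec("bayesian_regression_tree"),
                              en = classifier_spec("elastic_net")) {
  structure(list(n_bootstrap = as.integer(n_bootstrap),
                 improvement_tolerance = improvement_tolerance,
                 fold_aggregation = match.arg(fold_aggregation),
                 rf = rf, brt = brt, en = en),
            class = "selection_control")
}

#' Stage 1: per-algorithm candidate sets
#'
#' Fits the three importance-producing algorithms and thresholds each one's
#' scores with a scale-free cutoff. The random forest and the sum-of-trees
#' ensemble are calibrated with shadow variables: the design matrix is
#' augmented with 20 row-permuted copies of randomly chosen columns, and a
#' real variable is a candidate only if its importance exceeds the largest
#' importance any shadow attains. Shadows are noise by construction, so
#' their maximum estimates the upper ~95% envelope of the no-signal
#' importance distribution. The elastic net's candidates are the variables
#' with nonzero coefficients on its inner-CV path.
#'
#' @param X complete-case episode-by-variable matrix.
#' @param y binary labels.
#' @param seed integer seed.
#' @param control a [selection_control()].
#' @return a named list of three character vectors (`random_forest`,
#'   `bayesian_regression_tree`, `elastic_net`).
#' @export
stage1_candidates <- function(X, y, seed = 1L, control = selection_control()) {
  X <- as_X_matrix(X)
  # canonical column order so results are equivariant under input permutation
  X <- X[, order(colnames(X)), drop = FALSE]
  vars <- colnames(X)
  n_shadow <- min(length(vars), 20L)
  shadow <- with_seed(child_seed(seed, 11L), {
    src <- sample(length(vars), n_shadow)
    apply(X[, src, drop = FALSE], 2, sample)
  })
  colnames(shadow) <- paste0(".shadow_", seq_len(n_shadow))
  Xa <- cbind(X, shadow)

  pick_shadowed <- function(fit) {
    imp <- importance(fit)
    cutoff <- max(imp[colnames(shadow)])
    real <- imp[vars]
    vars[real > cutoff]
  }
  rf_fit <- fit_classifier(control$rf, Xa, y, child_seed(seed, 12L))
  brt_fit <- fit_classifier(control$brt, Xa, y, child_seed(seed, 13L))
  en_fit <- fit_classifier(control$en, X, y, child_seed(seed, 14L))
  en_imp <- importance(en_fit)
  list(random_forest = pick_shadowed(rf_fit),
       bayesian_regression_tree = pick_shadowed(brt_fit),
       elastic_net = vars[en_imp > 0])
}

#' Stage 2: majority vote across algorithms
#'
#' @param sets a list of three character vectors of candidate variables.
#' @return the variables present in at least two of the three sets, sorted.
#' @export
#' @examples
#' majority_vote(list(c("a", "b"), c("b", "c"), c("b", "d")))  # "b"
majority_vote <- function(sets) {
  stopifnot(length(sets) == 3L)
  counts <- table(unlist(lapply(sets, unique)))
  sort(names(counts)[counts >= 2])
}

# stratified bootstrap resamples with their out-of-bootstrap complements;
# 0-based indices ready for the C++ scorer
make_bootstraps <- function(y01, B, seed) {
  idx0 <- which(y01 == 0L)
  idx1 <- which(y01 == 1L)
  with_seed(as.integer(seed), {
    lapply(seq_len(B), function(b) {
      tr <- c(sample(idx0, length(idx0), replace = TRUE),
              sample(idx1, length(idx1), replace = TRUE))
      te <- setdiff(seq_along(y01), unique(tr))
      list(tr = tr - 1L, te = te - 1L)
    })
  })
}

#' Stage 3: bootstrap forward/backward stepwise refinement
#'
#' Greedy forward pass: starting from the empty set (chance score 0.5),
#' repeatedly add the candidate that most improves the median
#' out-of-bootstrap balanced accuracy of a logistic model across `B`
#' stratified bootstrap resamples, stopping when no addition improves it by
#' more than `improvement_tolerance`. Backward pass: remove any variable
#' whose removal does not reduce the median score (no tolerance there, so a
#' genuinely contributing variable is kept). All comparisons share one set
#' of resamples
#' (common random numbers), and ties break lexicographically by variable id,
#' so the result is deterministic given the seed.
#'
#' @param X complete-case episode-by-variable matrix.
#' @param y binary labels.
#' @param candidates character vector of candidate variables (subset of
#'   `colnames(X)`); an empty set returns an empty selection.
#' @param B number of bootstrap resamples (default 100).
#' @param seed integer seed.
#' @param improvement_tolerance see [selection_control()].
#' @return a sorted character vector, a subset of `candidates`.
#' @export
bootstrap_stepwise <- function(X, y, candidates, B = 100L, seed = 1L,
                               improvement_tolerance = 0.005) {
  if (length(candidates) == 0) return(character())
  X <- as_X_matrix(X)
  y01 <- as.integer(as_binary_y(y)) - 1L
  bad <- setdiff(candidates, colnames(X))
  if (length(bad) > 0) {
    stop_modulearn(paste0("candidates outside X: ", paste(bad, collapse = ", ")),
                   "modulearn_contract_error")
  }
  boots <- make_bootstraps(y01, B, seed)
  tr <- lapply(boots, `[[`, "tr")
  te <- lapply(boots, `[[`, "te")
  cand <- sort(unique(candidates)) # lexicographic order drives tie-breaking
  picked <- .stepwise_select(X[, cand, drop = FALSE], as.double(y01), tr, te,
                             improvement_tolerance)
  cand[picked]
}

# one training fold through stages 1-3
fold_pipeline <- function(X, y, rows, seed, control) {
  sets <- stage1_candidates(X[rows, , drop = FALSE], y[rows],
                            seed = child_seed(seed, 1L), control = control)
  cand <- majority_vote(sets)
  bootstrap_stepwise(X[rows, , drop = FALSE], y[rows], cand,
                     B = control$n_bootstrap, seed = child_seed(seed, 2L),
                     improvement_tolerance = control$improvement_tolerance)
}

#' Stage 4: repeated-CV stability selection
#'
#' Runs the stage-1..3 pipeline on every training fold of
#' `n_repetitions` independent stratified `n_folds`-fold cross-validations.
#' Within a repetition a variable counts as selected when the pipeline picks
#' it in a majority of folds (configurable); its selection rate is the
#' fraction of repetitions selecting it, and the final set holds the
#' variables whose rate reaches the replicability threshold `tau`
#' (default 0.95).
#'
#' @param X complete-case episode-by-variable matrix.
#' @param y binary labels.
#' @param groups optional participant ids for leakage-safe folds.
#' @param n_repetitions number of cross-validation repetitions (the study
#'   criterion uses 200).
#' @param n_folds folds per repetition (default 10).
#' @param tau selection-rate threshold in (0, 1] (default 0.95).
#' @param seed master seed; every repetition/fold/bootstrap derives its own
#'   child seed.
#' @param control a [selection_control()].
#' @return an object of class `selection_trace` with per-variable selection
#'   rates, per-repetition sets, the threshold and the final set.
#' @export
run_selection <- function(X, y, groups = NULL, n_repetitions = 200L,
                          n_folds = 10L, tau = 0.95, seed = 1L,
                          control = selection_control()) {
  X <- as_X_matrix(X)
  y <- as_binary_y(y)
  if (!is_scalar_number(tau) || tau <= 0 || tau > 1) {
    stop_modulearn("tau must lie in (0, 1]", "modulearn_parameter_error")
  }
  if (n_repetitions < 1L) {
    stop_modulearn("n_repetitions must be >= 1", "modulearn_parameter_error")
  }
  vars <- colnames(X)
  need <- if (control$fold_aggregation == "majority") floor(n_folds / 2) + 1L else 1L

  per_rep <- vector("list", n_repetitions)
  for (r in seq_len(n_repetitions)) {
    folds <- make_folds(y, groups, n_folds, seed = child_seed(seed, 101L, r))
    assert_group_integrity(folds, groups)
    fold_sets <- lapply(seq_len(n_folds), function(f) {
      fold_pipeline(X, y, rows = which(folds != f),
                    seed = child_seed(seed, 102L, r, f), control = control)
    })
    counts <- table(unlist(fold_sets))
    per_rep[[r]] <- sort(names(counts)[counts >= need])
  }

  rate <- vapply(vars, function(v) {
    mean(vapply(per_rep, function(s) v %in% s, logical(1)))
  }, numeric(1))
  new_selection_trace(vars, rate, per_rep, tau, n_repetitions)
}

new_selection_trace <- function(vars, rate, per_rep, tau, n_repetitions) {
  selected <- rate >= tau - 1e-12
  structure(list(
    n_repetitions = as.integer(n_repetitions),
    tau = tau,
    rates = tibble::tibble(variable_id = vars, selection_rate = unname(rate),
                           selected = unname(selected)),
    per_repetition = per_rep,
    final_set = sort(vars[selected])),
    class = "selection_trace")
}

#' Re-threshold a selection trace
#' @param trace a `selection_trace`.
#' @param tau new selection-rate threshold in (0, 1].
#' @return a new `selection_trace` with the same rates and a new final set.
#' @export
rethreshold <- function(trace, tau) {
  stopifnot(inherits(trace, "selection_trace"))
  new_selection_trace(trace$rates$variable_id, trace$rates$selection_rate,
                      trace$per_repetition, tau, trace$n_repetitions)
}

#' @export
print.selection_trace <- function(x, ...) {
  cat("<selection_trace> ", x$n_repetitions, " repetitions, tau = ", x$tau,
      "\n  final set (", length(x$final_set), "): ",
      paste(x$final_set, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @method tidy selection_trace
#' @export
tidy.selection_trace <- function(x, ...) {
  dplyr::arrange(x$rates, dplyr::desc(.data$selection_rate), .data$variable_id)
}

#' Write a selection trace as TSV
#'
#' Columns `variable_id`, `selection_rate`, `selected_flag` — the data
#' behind the usual lollipop selection-rate panel.
#'
#' @param trace a `selection_trace`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_selection_trace <- function(trace, path) {
  out <- tidy(trace)
  names(out)[3] <- "selected_flag"
  readr::write_tsv(out, path)
  invisible(path)
}
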