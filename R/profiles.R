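# Effect profiles: turn a selected variable set into interpretable output —
# exemplary logistic coefficients, improvement-oriented Cohen's d and
# one-sided Welch tests against the other module and the retest cohort, and
# the specific-effect flag (both comparisons significant).

#' Exemplary logistic regression on a selected variable set
#'
#' Unpenalized logistic fit on z-standardized predictors, so coefficients
#' are comparable across facets. The positive class is the second level of
#' `y`: positive coefficients point to the positive-class module, negative
#' coefficients to the other. Under (quasi-)separation the fit falls back to
#' a tiny ridge (1e-6) with a flagged warning; standard errors then come
#' from the ridge-penalized information matrix.
#'
#' @param X episode-by-variable matrix of the selected variables, complete
#'   cases.
#' @param y binary labels.
#' @return a tibble with columns `variable_id`, `estimate`, `std_error`,
#'   `p_value`, plus attribute `positive` (the positive-class label).
#' @export
fit_final_logistic <- function(X, y) {
  X <- as_X_matrix(X)
  if (ncol(X) == 0) {
    stop_modulearn("the selected variable set is empty", "modulearn_contract_error")
  }
  y <- as_binary_y(y)
  if (anyNA(X)) {
    stop_modulearn("X contains missing values", "modulearn_contract_error")
  }
  Xs <- scale(X)
  if (any(!is.finite(Xs))) {
    stop_modulearn("a selected variable is constant; cannot standardize",
                   "modulearn_data_error")
  }
  y01 <- as.integer(y) - 1L
  fit <- suppressWarnings(glm(y01 ~ Xs, family = binomial()))
  p <- fit$fitted.values
  separated <- !fit$converged || any(p > 1 - 1e-8 | p < 1e-8)
  if (!separated) {
    sm <- summary(fit)$coefficients[-1, , drop = FALSE]
    out <- tibble::tibble(variable_id = colnames(X),
                          estimate = unname(sm[, 1]),
                          std_error = unname(sm[, 2]),
                          p_value = unname(sm[, 4]))
  } else {
    warn("separation detected; falling back to ridge-regularized logistic fit",
         class = "modulearn_separation_warning")
    lam <- 1e-6
    g <- glmnet::glmnet(pad_matrix(Xs), y01, family = "binomial", alpha = 0,
                        lambda = lam, standardize = FALSE)
    beta <- as.numeric(coef(g))[seq_len(ncol(X) + 1)]
    eta <- drop(cbind(1, Xs) %*% beta)
    w <- stats::plogis(eta) * (1 - stats::plogis(eta))
    A <- crossprod(cbind(1, Xs) * sqrt(w))
    diag(A) <- diag(A) + nrow(X) * lam
    se <- sqrt(diag(solve(A)))
    zst <- beta[-1] / se[-1]
    out <- tibble::tibble(variable_id = colnames(X),
                          estimate = beta[-1],
                          std_error = se[-1],
                          p_value = 2 * pnorm(-abs(zst)))
  }
  attr(out, "positive") <- levels(y)[2]
  attr(out, "separation_fallback") <- separated
  out
}

check_two_groups <- function(changes_a, changes_b, direction) {
  if (length(changes_a) < 2L || length(changes_b) < 2L) {
    stop_modulearn("both groups need at least 2 values", "modulearn_contract_error")
  }
  if (!direction %in% c(-1, 1)) {
    stop_modulearn("direction must be +1 or -1", "modulearn_contract_error")
  }
}

#' Improvement-oriented Cohen's d between two change-score groups
#'
#' `d = direction * (mean(changes_b) - mean(changes_a)) / pooled SD`, with
#' the two-sample pooled SD on `n_a + n_b - 2` degrees of freedom. Oriented
#' so that `d > 0` means group `a` (the module) improved more than group `b`
#' (the comparator): for distress-coded variables (`direction = +1`) a
#' larger raw-score *decrease* in `a` is positive d, for wellbeing-coded
#' variables (`direction = -1`) a larger *increase* is.
#'
#' @param changes_a change scores of the module group (>= 2 values).
#' @param changes_b change scores of the comparator group (>= 2 values).
#' @param direction the variable's improvement direction, +1 or -1.
#' @return Cohen's d.
#' @export
#' @examples
#' cohens_d(rnorm(100, -0.3), rnorm(100, 0), direction = +1)
cohens_d <- function(changes_a, changes_b, direction = 1) {
  check_two_groups(changes_a, changes_b, direction)
  na <- length(changes_a); nb <- length(changes_b)
  sp2 <- ((na - 1) * stats::var(changes_a) + (nb - 1) * stats::var(changes_b)) /
    (na + nb - 2)
  if (sp2 <= 0) {
    stop_modulearn("pooled standard deviation is zero; d is undefined",
                   "modulearn_data_error")
  }
  direction * (mean(changes_b) - mean(changes_a)) / sqrt(sp2)
}

#' One-sided Welch test in the improvement direction
#'
#' Welch's unequal-variance t statistic with Satterthwaite degrees of
#' freedom, testing whether group `a` improved more than group `b` (same
#' orientation as [cohens_d()]); the alternative is one-sided in the
#' improvement direction. A pooled Student variant is available.
#'
#' @inheritParams cohens_d
#' @param var_equal use the pooled-variance Student t instead of Welch.
#' @return a list with elements `t`, `df` and `p` (one-sided).
#' @export
welch_t <- function(changes_a, changes_b, direction = 1, var_equal = FALSE) {
  check_two_groups(changes_a, changes_b, direction)
  imp_a <- -direction * changes_a
  imp_b <- -direction * changes_b
  ht <- tryCatch(
    stats::t.test(imp_a, imp_b, alternative = "greater", var.equal = var_equal),
    error = function(e) {
      stop_modulearn("groups are essentially constant; t is undefined",
                     "modulearn_data_error")
    })
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Build the module-specific effect profile of a selected variable set
#'
#' For each selected variable: fit the exemplary logistic regression over
#' the contrast's episodes, attribute the variable to a module by the sign
#' of its coefficient — a variable belongs to the module toward which its
#' improvement direction points, i.e. to the positive class when
#' `-improvement_direction * beta > 0` — then compute improvement-oriented
#' Cohen's d and a one-sided test against (i) the other module's episodes
#' and (ii) the retest cohort's episodes. A variable belongs to the specific effect
#' profile of its module when both comparisons are significant
#' (one-sided, `alpha = 0.05` by default).
#'
#' @param dataset a validated episode tibble containing both modules and
#'   retest episodes.
#' @param contrast a module [contrast_spec()] (`"PresenceVsAffect"` or
#'   `"AffectVsPerspective"`) or its name.
#' @param selected non-empty character vector of selected variable ids.
#' @param panel the variable panel.
#' @param retest_window `"matched"` (default): compare against retest
#'   episodes from the same periods in which the attributed module was
#'   practiced; `"first"`: first-period retest episodes only.
#' @param alpha one-sided significance level for the specific-effect flag.
#' @param p_adjust `"none"` (default) or `"BH"`: multiplicity correction
#'   applied to each comparison's p-values across variables before flagging.
#' @param var_equal use Student's pooled t instead of Welch.
#' @return a tibble of class `effect_profile`: one row per selected
#'   variable with the logistic coefficient, both d values and p-values,
#'   and `specific_effect`.
#' @export
build_profile <- function(dataset, contrast, selected,
                          panel = default_panel(),
                          retest_window = c("matched", "first"),
                          alpha = 0.05, p_adjust = c("none", "BH"),
                          var_equal = FALSE) {
  if (is.character(contrast)) contrast <- contrast_spec(contrast)
  retest_window <- match.arg(retest_window)
  p_adjust <- match.arg(p_adjust)
  if (contrast$name == "TrainingVsRetest") {
    stop_modulearn("effect profiles are defined for module contrasts only",
                   "modulearn_contract_error")
  }
  if (length(selected) == 0) {
    stop_modulearn("the selected variable set is empty", "modulearn_contract_error")
  }
  panel <- validate_panel(panel)
  bad <- setdiff(selected, panel$variable_id)
  if (length(bad) > 0) {
    stop_modulearn(paste0("selected variables outside the panel: ",
                          paste(bad, collapse = ", ")),
                   "modulearn_contract_error")
  }

  cd <- build_contrast(dataset, contrast, panel)
  coefs <- fit_final_logistic(cd$X[, selected, drop = FALSE], cd$y)
  positive <- attr(coefs, "positive")
  other_of <- setNames(rev(contrast$classes), contrast$classes)

  retest_all <- dataset[dataset$episode_label == retest_label, ]
  retest_all <- retest_all[complete.cases(retest_all[selected]), ]
  if (nrow(retest_all) < 2L) {
    stop_modulearn("no usable retest episodes for the retest comparison",
                   "modulearn_data_error")
  }

  dirs <- setNames(panel$improvement_direction, panel$variable_id)
  rows <- purrr::pmap_dfr(coefs, function(variable_id, estimate, std_error, p_value) {
    # improvement-oriented attribution: distress-coded variables point to the
    # positive class through negative coefficients, wellbeing-coded through
    # positive ones
    mod <- if (-dirs[[variable_id]] * estimate >= 0) positive else other_of[[positive]]
    oth <- other_of[[mod]]
    ep <- cd$episodes
    ch_mod <- ep[[variable_id]][ep$episode_label == mod]
    ch_oth <- ep[[variable_id]][ep$episode_label == oth]
    mod_periods <- unique(ep$period[ep$episode_label == mod])
    rt <- switch(retest_window,
                 matched = retest_all[retest_all$period %in% mod_periods, ],
                 first = retest_all[retest_all$period == 1L, ])
    if (nrow(rt) < 2L) {
      stop_modulearn("retest window contains fewer than 2 episodes",
                     "modulearn_data_error")
    }
    dir <- dirs[[variable_id]]
    t_oth <- welch_t(ch_mod, ch_oth, dir, var_equal = var_equal)
    t_rt <- welch_t(ch_mod, rt[[variable_id]], dir, var_equal = var_equal)
    tibble::tibble(
      variable_id = variable_id, module = mod,
      estimate = estimate, std_error = std_error, p_value = p_value,
      d_vs_other_module = cohens_d(ch_mod, ch_oth, dir),
      p_vs_other_module = t_oth$p,
      d_vs_retest = cohens_d(ch_mod, rt[[variable_id]], dir),
      p_vs_retest = t_rt$p)
  })
  if (p_adjust == "BH") {
    rows$p_vs_other_module <- stats::p.adjust(rows$p_vs_other_module, "BH")
    rows$p_vs_retest <- stats::p.adjust(rows$p_vs_retest, "BH")
  }
  rows$specific_effect <- rows$p_vs_other_module < alpha & rows$p_vs_retest < alpha
  structure(rows, class = c("effect_profile", class(tibble::tibble())),
            contrast = contrast$name, alpha = alpha,
            retest_window = retest_window)
}

#' Write an effect profile as TSV plus a radar-profile JSON
#'
#' The TSV has one row per variable. The JSON maps each module to its
#' specific-effect variables' d-vs-retest values — the data behind a radar
#' chart of module effect profiles.
#'
#' @param profile an `effect_profile`.
#' @param path output TSV path.
#' @param json_path optional JSON path (default: `path` with `.json`).
#' @return `path`, invisibly.
#' @export
write_effect_profile <- function(profile, path, json_path = NULL) {
  readr::write_tsv(profile, path)
  json_path <- json_path %||% sub("\\.tsv$", ".json", path)
  spec <- profile[profile$specific_effect, ]
  radar <- split(setNames(as.list(spec$d_vs_retest), spec$variable_id),
                 spec$module)
  jsonlite::write_json(radar, json_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
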