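# Synthetic change-score generator. Emulates the statistical structure the
# analysis assumes: 68 correlated questionnaire facets with block
# correlation (stronger within a questionnaire than between), cohort
# schedules, a shared per-participant random intercept across periods,
# planted module-specific standardized improvement effects, and optional
# missingness/dropout. Multivariate normal throughout.

#' Construct a noise specification
#'
#' @param within_questionnaire_correlation correlation between two facets of
#'   the same questionnaire (default 0.4).
#' @param between_questionnaire_correlation correlation between facets of
#'   different questionnaires (default 0.1).
#' @param sd per-variable residual standard deviation, length 1 or one per
#'   panel variable (default 1).
#' @param intercept_variance variance of the per-participant random
#'   intercept shared by all of a participant's episodes, as a fraction of
#'   each variable's residual variance (default 0.1). Induces within-
#'   participant dependence across periods.
#' @param missing_rate probability that any one change-score cell is missing
#'   (default 0).
#' @param dropout_rate probability that a participant drops out after a
#'   uniformly chosen period, losing all later episodes (default 0).
#' @return a list of class `noise_spec`.
#' @export
noise_spec <- function(within_questionnaire_correlation = 0.4,
                       between_questionnaire_correlation = 0.1,
                       sd = 1,
                       intercept_variance = 0.1,
                       missing_rate = 0,
                       dropout_rate = 0) {
  ns <- list(within = within_questionnaire_correlation,
             between = between_questionnaire_correlation,
             sd = sd,
             intercept_variance = intercept_variance,
             missing_rate = missing_rate,
             dropout_rate = dropout_rate)
  if (!is_scalar_number(ns$within) || !is_scalar_number(ns$between) ||
      abs(ns$within) > 1 || abs(ns$between) > 1) {
    stop_modulearn("correlations must be finite and in [-1, 1]",
                   "modulearn_parameter_error")
  }
  if (any(!is.finite(ns$sd)) || any(ns$sd <= 0)) {
    stop_modulearn("sd must be positive and finite", "modulearn_parameter_error")
  }
  if (!is_scalar_number(ns$intercept_variance) || ns$intercept_variance < 0) {
    stop_modulearn("intercept_variance must be >= 0", "modulearn_parameter_error")
  }
  for (r in c(ns$missing_rate, ns$dropout_rate)) {
    if (!is_scalar_number(r) || r < 0 || r >= 1) {
      stop_modulearn("rates must lie in [0, 1)", "modulearn_parameter_error")
    }
  }
  structure(ns, class = "noise_spec")
}

#' Read a noise specification from YAML
#' @param path YAML file path with fields named as in [noise_spec()].
#' @return a `noise_spec`.
#' @export
read_noise_spec <- function(path) {
  do.call(noise_spec, yaml::read_yaml(path))
}

# residual block correlation matrix (within/between questionnaire), scaled
# to a covariance by the per-variable sd. The shared participant intercept
# adds `iv * sd_i * sd_j` to every within-episode covariance, so the
# residual correlations are adjusted downward to make the MARGINAL
# correlations equal the requested within/between values:
#   marginal rho = (rho_resid + iv) / (1 + iv)  =>  rho_resid = rho(1+iv) - iv
# Cholesky doubles as the positive-definiteness check.
panel_covariance <- function(panel, noise) {
  p <- nrow(panel)
  iv <- noise$intercept_variance
  adj <- function(rho) rho * (1 + iv) - iv
  rho <- matrix(adj(noise$between), p, p)
  same_q <- outer(panel$questionnaire, panel$questionnaire, "==")
  rho[same_q] <- adj(noise$within)
  diag(rho) <- 1
  sdv <- rep(noise$sd, length.out = p)
  sigma <- rho * (sdv %o% sdv)
  chol_sigma <- tryCatch(chol(sigma), error = function(e) {
    stop_modulearn("implied change-score correlation matrix is not positive definite",
                   "modulearn_parameter_error")
  })
  list(sigma = sigma, chol = chol_sigma, sd = sdv)
}

#' Generate a synthetic change-score dataset
#'
#' Draws one 68-vector of change scores per episode from a multivariate
#' normal with the block correlation of `noise`. The mean of variable v in
#' module-M episodes is `improvement_direction(v) * (-d(M, v)) * total_sd(v)`
#' where `total_sd` includes the participant-intercept variance, so a planted
#' improvement `d > 0` moves distress-coded variables down and
#' wellbeing-coded variables up by exactly `d` total standard deviations
#' relative to retest. Retest means are 0. Identical seeds give identical
#' datasets.
#'
#' @param design a `cohort_design` (default [default_design()]).
#' @param panel a variable panel (default [default_panel()]).
#' @param effects an `effect_spec` of planted improvements, or `NULL` for no
#'   effects.
#' @param noise a `noise_spec`.
#' @param seed integer seed; required, there is no hidden entropy.
#' @return a validated episode tibble (see [load_dataset()]).
#' @export
#' @examples
#' d <- simulate_change_scores(effects = default_effect_spec(), seed = 1)
#' dplyr::count(d, cohort, episode_label)
simulate_change_scores <- function(design = default_design(),
                                   panel = default_panel(),
                                   effects = NULL,
                                   noise = noise_spec(),
                                   seed) {
  if (missing(seed) || !is_scalar_number(seed)) {
    stop_modulearn("an integer seed is required", "modulearn_contract_error")
  }
  design <- validate_design(design)
  panel <- validate_panel(panel)
  if (!inherits(noise, "noise_spec")) noise <- do.call(noise_spec, noise)
  em <- effect_matrix(effects, panel)
  cov <- panel_covariance(panel, noise)
  p <- nrow(panel)
  total_sd <- cov$sd * sqrt(1 + noise$intercept_variance)
  # per-label mean vectors; retest (and any unplanted pair) is zero
  mu <- matrix(0, nrow = length(module_labels) + 1L, ncol = p,
               dimnames = list(c(module_labels, retest_label), panel$variable_id))
  for (m in module_labels) {
    mu[m, ] <- panel$improvement_direction * (-em[m, ]) * total_sd
  }
  if (any(!is.finite(mu))) {
    stop_modulearn("planted effects produce non-finite means",
                   "modulearn_parameter_error")
  }

  labels <- design_episode_labels(design)
  with_seed(as.integer(seed), {
    episodes <- purrr::map_dfr(seq_len(nrow(design)), function(i) {
      coh <- design$cohort[i]
      ids <- sprintf("%s_%03d", coh, seq_len(design$size[i]))
      lab <- labels[labels$cohort == coh, ]
      tidyr::crossing(participant_id = ids, period = lab$period) |>
        dplyr::left_join(lab, by = "period") |>
        dplyr::arrange(.data$participant_id, .data$period)
    })
    n <- nrow(episodes)
    z <- matrix(rnorm(n * p), n, p) %*% cov$chol
    # shared participant intercept, scaled to each variable's sd
    pid <- factor(episodes$participant_id)
    u <- rnorm(nlevels(pid), sd = sqrt(noise$intercept_variance))
    z <- z + (u[as.integer(pid)] %o% cov$sd)
    z <- z + mu[episodes$episode_label, , drop = FALSE]
    colnames(z) <- panel$variable_id

    if (noise$missing_rate > 0) {
      z[runif(length(z)) < noise$missing_rate] <- NA_real_
    }
    keep <- rep(TRUE, n)
    if (noise$dropout_rate > 0) {
      np <- n_periods(design)
      drops <- runif(nlevels(pid)) < noise$dropout_rate
      last <- ifelse(drops, sample(np - 1L, nlevels(pid), replace = TRUE), np)
      keep <- episodes$period <= last[as.integer(pid)]
    }
    out <- dplyr::bind_cols(
      episodes[c("participant_id", "cohort", "episode_label", "period")],
      tibble::as_tibble(z))[keep, ]
    validate_dataset(out, panel, design)
  })
}
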