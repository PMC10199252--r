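# Shared fixtures, all generated in code.

# plain gaussian toy: first `n_signal` variables carry a standardized mean
# difference `d` between the two classes, the rest are pure noise
make_toy <- function(n = 200, p = 6, d = 2, n_signal = 1, seed = 1,
                     labels = c("a", "b")) {
  withr::with_seed(seed, {
    y <- factor(rep(labels, length.out = n), levels = labels)
    X <- matrix(rnorm(n * p), n, p)
    if (n_signal > 0) {
      shift <- (as.integer(y) - 1L) * d
      X[, seq_len(n_signal)] <- X[, seq_len(n_signal), drop = FALSE] + shift
    }
    colnames(X) <- sprintf("v%02d", seq_len(p))
    list(X = X, y = y)
  })
}

# a small 3-questionnaire panel for IO and generator edge tests
tiny_panel <- function() {
  validate_panel(tibble::tibble(
    variable_id = c("qa_s1", "qa_s2", "qb_s1", "qb_s2", "qc_total"),
    questionnaire = c("qa", "qa", "qb", "qb", "qc"),
    subscale_name = c("s1", "s2", "s1", "s2", "total"),
    is_total_score = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    improvement_direction = c(1L, 1L, 1L, -1L, 1L)))
}

tiny_design <- function() {
  cohort_design(
    cohort = c("RCC", "TC1"),
    size = c(12L, 12L),
    schedule = list(character(), c("Presence", "Affect")))
}

# write a dataset CSV built from rows given as a list of character vectors
write_csv_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# independent univariate AUC oracle (rank-based, no package code)
univariate_auc <- function(x, y) {
  y <- as.integer(factor(y)) - 1L
  r <- rank(x)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  max(auc, 1 - auc)
}
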