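test_that("majority vote keeps exactly the variables named by at least two algorithms", {
  expect_equal(majority_vote(list(c("a", "b"), c("b", "c"), c("b", "d"))), "b")
  expect_setequal(majority_vote(list(c("a", "b"), c("a", "c"), c("b", "c"))),
                  c("a", "b", "c"))
  expect_equal(majority_vote(list(character(), character(), "a")), character())
  expect_equal(majority_vote(list(c("a", "a", "b"), "a", character())), "a")
})

test_that("stage 1 flags the single informative variable in all three algorithm sets", {
  toy <- make_toy(n = 200, p = 10, d = 2, n_signal = 1, seed = 12)
  sets <- stage1_candidates(toy$X, toy$y, seed = 1)
  expect_named(sets, c("random_forest", "bayesian_regression_tree", "elastic_net"))
  for (s in sets) expect_true("v01" %in% s)
  expect_true("v01" %in% majority_vote(sets))
  # deterministic under a fixed seed
  expect_identical(sets, stage1_candidates(toy$X, toy$y, seed = 1))
})

test_that("stage 1 is calibrated on pure noise and the majority vote cleans it up", {
  # each algorithm's cutoff targets the ~95% null envelope, so single-set
  # sizes average at most ~5% of variables; agreement between two
  # algorithms on the same noise variable is rare, so the voted set is
  # near-empty
  sizes <- NULL; voted <- NULL
  for (s in 1:5) {
    toy <- make_toy(n = 250, p = 68, d = 0, n_signal = 0, seed = 12 + s)
    sets <- stage1_candidates(toy$X, toy$y, seed = s + 1)
    sizes <- c(sizes, lengths(sets))
    voted <- c(voted, length(majority_vote(sets)))
  }
  expect_lte(mean(sizes), 0.05 * 68)
  # two algorithms agreeing on the same noise variable is much rarer than a
  # single-set flag, though shared training data keeps it above the
  # independence rate; the stepwise and stability stages remove the rest
  expect_lte(mean(voted), 0.05 * 68)
  expect_true(all(voted <= ceiling(0.1 * 68)))
})

test_that("bootstrap stepwise keeps one of a redundant pair and drops pure noise", {
  withr::with_seed(14, {
    shift <- rep(c(0, 1.5), 100)
    v1 <- rnorm(200) + shift
    X <- cbind(v1 = v1, v2 = v1 + rnorm(200, sd = 0.01), v3 = rnorm(200))
    y <- factor(rep(c("a", "b"), 100))
  })
  # redundancy: the copy adds no information, so exactly one survives
  kept <- vapply(1:5, function(i) {
    paste(bootstrap_stepwise(X, y, c("v1", "v2"), B = 100, seed = i),
          collapse = ",")
  }, character(1))
  expect_true(all(kept %in% c("v1", "v2")))
  # pure noise stays out (checked across seeds; admission would need the
  # median OOB BAC to clear chance by more than its own Monte-Carlo error)
  noise_sel <- vapply(1:10, function(i) {
    length(bootstrap_stepwise(X, y, "v3", B = 100, seed = 10 + i))
  }, integer(1))
  expect_lte(sum(noise_sel), 1L)
  # empty candidate set is a no-op, not an error
  expect_identical(bootstrap_stepwise(X, y, character(), seed = 1), character())
  expect_error(bootstrap_stepwise(X, y, "v9", seed = 1),
               class = "modulearn_contract_error")
})

test_that("stepwise is deterministic given the seed", {
  toy <- make_toy(n = 150, p = 8, d = 1.2, n_signal = 3, seed = 15)
  s1 <- bootstrap_stepwise(toy$X, toy$y, colnames(toy$X), seed = 5)
  s2 <- bootstrap_stepwise(toy$X, toy$y, colnames(toy$X), seed = 5)
  expect_identical(s1, s2)
})

test_that("threshold selection and monotonicity follow the selection-rate contract", {
  tr <- modulearn:::new_selection_trace(
    vars = c("a", "b", "c"), rate = c(1.00, 0.96, 0.90),
    per_rep = list(), tau = 0.95, n_repetitions = 100)
  expect_setequal(tr$final_set, c("a", "b"))
  # tau1 >= tau2 implies final_set(tau1) subset of final_set(tau2)
  taus <- c(0.5, 0.8, 0.9, 0.95, 0.99, 1)
  sets <- lapply(taus, function(t) rethreshold(tr, t)$final_set)
  for (i in seq_along(taus)[-1]) {
    expect_true(all(sets[[i]] %in% sets[[i - 1]]))
  }
  expect_error(run_selection(make_toy()$X, make_toy()$y, tau = 1.5),
               class = "modulearn_parameter_error")
})

test_that("repeated-CV selection recovers planted strong signals and nothing else", {
  # three independent strong signals (d = 1.5) among 20 variables
  toy <- make_toy(n = 160, p = 20, d = 1.5, n_signal = 3, seed = 16)
  tr <- run_selection(toy$X, toy$y, n_repetitions = 4, n_folds = 5,
                      tau = 0.95, seed = 6)
  expect_equal(tr$n_repetitions, 4L)
  expect_setequal(tr$final_set, c("v01", "v02", "v03"))
  expect_true(all(tr$rates$selection_rate >= 0 & tr$rates$selection_rate <= 1))
  # rates are repetition fractions of the per-repetition sets
  v_rate <- vapply(tr$rates$variable_id, function(v) {
    mean(vapply(tr$per_repetition, function(s) v %in% s, logical(1)))
  }, numeric(1))
  expect_equal(unname(v_rate), tr$rates$selection_rate)
})

test_that("null data yield an empty final set across independent generator seeds", {
  for (s in 1:3) {
    toy <- make_toy(n = 120, p = 12, d = 0, n_signal = 0, seed = 20 + s)
    tr <- run_selection(toy$X, toy$y, n_repetitions = 3, n_folds = 5,
                        tau = 0.95, seed = s)
    expect_identical(tr$final_set, character(0))
  }
})

test_that("permuting variable order permutes the trace accordingly", {
  toy <- make_toy(n = 120, p = 8, d = 1.5, n_signal = 2, seed = 17)
  perm <- c(5, 3, 8, 1, 7, 2, 4, 6)
  tr1 <- run_selection(toy$X, toy$y, n_repetitions = 2, n_folds = 5, seed = 9)
  tr2 <- run_selection(toy$X[, perm], toy$y, n_repetitions = 2, n_folds = 5,
                       seed = 9)
  expect_equal(tr1$rates$variable_id[perm], tr2$rates$variable_id)
  expect_equal(tr1$rates$selection_rate[perm], tr2$rates$selection_rate)
  expect_identical(tr1$final_set, tr2$final_set)
})

test_that("selection traces export as TSV with rates and flags", {
  tr <- modulearn:::new_selection_trace(
    vars = c("a", "b"), rate = c(0.98, 0.1), per_rep = list(),
    tau = 0.95, n_repetitions = 50)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_selection_trace(tr, f)
  back <- readr::read_tsv(f, show_col_types = FALSE)
  expect_equal(names(back), c("variable_id", "selection_rate", "selected_flag"))
  expect_equal(back$selection_rate, c(0.98, 0.1))
  expect_equal(back$selected_flag, c(TRUE, FALSE))
})
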