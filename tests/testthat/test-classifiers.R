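families <- c("logistic_regression", "random_forest",
              "bayesian_regression_tree", "elastic_net")

test_that("balanced accuracy matches hand computations and its anchors", {
  # TP = 3, FN = 1, TN = 2, FP = 2 -> (3/4 + 2/4) / 2 = 0.625
  y_true <- c(1, 1, 1, 1, 0, 0, 0, 0)
  y_pred <- c(1, 1, 1, 0, 1, 1, 0, 0)
  expect_equal(balanced_accuracy(y_true, y_pred), 0.625)
  expect_equal(balanced_accuracy(y_true, y_true), 1)
  # all-one-class predictions sit at chance for any class mix
  expect_equal(balanced_accuracy(c(1, 1, 1, 0), c(1, 1, 1, 1)), 0.5)
  expect_equal(balanced_accuracy(c(1, 0, 0, 0, 0, 0), rep(0, 6)), 0.5)
  expect_error(balanced_accuracy(rep(1, 4), rep(1, 4)),
               class = "modulearn_data_error")
  expect_error(balanced_accuracy(1:3, 1:2), class = "modulearn_contract_error")
})

test_that("balanced accuracy is invariant to relabeling and within-class duplication", {
  withr::with_seed(42, {
    for (i in 1:20) {
      y <- sample(c("a", "b"), 30, replace = TRUE)
      if (length(unique(y)) < 2) next
      p <- sample(c("a", "b"), 30, replace = TRUE)
      b1 <- balanced_accuracy(y, p)
      swap <- function(v) ifelse(v == "a", "b", "a")
      expect_equal(balanced_accuracy(swap(y), swap(p)), b1)
      dup <- c(seq_along(y), which(y == "a"))  # duplicate one class's rows
      expect_equal(balanced_accuracy(y[dup], p[dup]), b1)
    }
  })
})

test_that("every family separates a linearly separable toy perfectly in training", {
  # two clusters five sd apart: a separating threshold on v01 exists by construction
  toy <- make_toy(n = 10, p = 2, d = 5, seed = 3)
  for (fam in families) {
    fit <- fit_classifier(classifier_spec(fam), toy$X, toy$y, seed = 9)
    pred <- predict(fit, toy$X)
    expect_equal(balanced_accuracy(toy$y, pred), 1.0, info = fam)
    expect_equal(as.character(pred), as.character(toy$y), info = fam)
  }
})

test_that("degenerate inputs are rejected", {
  toy <- make_toy(n = 20, p = 2, seed = 4)
  for (fam in families) {
    spec <- classifier_spec(fam)
    expect_error(fit_classifier(spec, toy$X, factor(rep("a", 20))),
                 class = "modulearn_data_error", info = fam)
    expect_error(
      fit_classifier(spec, toy$X, factor(c("a", rep("b", 19)), levels = c("a", "b"))),
      class = "modulearn_data_error", info = fam)
  }
  Xna <- toy$X; Xna[1, 1] <- NA
  expect_error(fit_classifier(classifier_spec("logistic_regression"), Xna, toy$y),
               class = "modulearn_contract_error")
  expect_error(classifier_spec("svm"), class = "modulearn_contract_error")
  expect_error(classifier_spec("random_forest", gamma = 2),
               class = "modulearn_contract_error")
})

test_that("fits are deterministic given a seed", {
  toy <- make_toy(n = 80, p = 5, d = 1, seed = 5)
  new <- make_toy(n = 40, p = 5, d = 1, seed = 6)
  for (fam in families) {
    f1 <- fit_classifier(classifier_spec(fam), toy$X, toy$y, seed = 21)
    f2 <- fit_classifier(classifier_spec(fam), toy$X, toy$y, seed = 21)
    expect_identical(predict(f1, new$X), predict(f2, new$X), info = fam)
  }
})

test_that("prediction enforces the training variable contract", {
  toy <- make_toy(n = 30, p = 3, seed = 7)
  fit <- fit_classifier(classifier_spec("logistic_regression"), toy$X, toy$y)
  expect_length(predict(fit, toy$X[0, , drop = FALSE]), 0L)
  expect_error(predict(fit, toy$X[, 1:2]), class = "modulearn_contract_error")
  extra <- cbind(toy$X, v99 = rnorm(30))
  expect_error(predict(fit, extra), class = "modulearn_contract_error")
  # column order does not matter
  expect_identical(predict(fit, toy$X[, c(3, 1, 2)]), predict(fit, toy$X))
})

test_that("the single informative variable gets the top importance score in all three families", {
  toy <- make_toy(n = 200, p = 6, d = 2, n_signal = 1, seed = 8)
  # oracle: v01 dominates by univariate AUC
  aucs <- apply(toy$X, 2, univariate_auc, y = toy$y)
  expect_equal(names(which.max(aucs)), "v01")
  for (fam in c("random_forest", "bayesian_regression_tree", "elastic_net")) {
    fit <- fit_classifier(classifier_spec(fam), toy$X, toy$y, seed = 31)
    imp <- importance(fit)
    expect_length(imp, 6L)
    expect_true(all(is.finite(imp)))
    expect_true(all(imp >= 0))
    expect_equal(names(which.max(imp)), "v01", info = fam)
  }
  fit_lr <- fit_classifier(classifier_spec("logistic_regression"), toy$X, toy$y)
  expect_error(importance(fit_lr), class = "modulearn_contract_error")
})

test_that("on all-noise data no random-forest score exceeds its label-permutation null", {
  toy <- make_toy(n = 120, p = 8, d = 0, n_signal = 0, seed = 9)
  fit <- fit_classifier(classifier_spec("random_forest"), toy$X, toy$y, seed = 1)
  imp <- importance(fit)
  # permutation oracle: refit under shuffled labels to draw the null
  null <- withr::with_seed(99, {
    unlist(lapply(1:12, function(i) {
      yp <- sample(toy$y)
      importance(fit_classifier(classifier_spec("random_forest"), toy$X, yp,
                                seed = 100 + i))
    }))
  })
  expect_lt(max(imp), quantile(null, 0.99) + 1e-12)
})

test_that("elastic-net scores are exactly zero for unpenalized-to-zero coefficients", {
  toy <- make_toy(n = 150, p = 8, d = 3, n_signal = 1, seed = 10)
  fit <- fit_classifier(classifier_spec("elastic_net"), toy$X, toy$y, seed = 2)
  imp <- importance(fit)
  expect_gt(imp[["v01"]], 0)
  expect_true(sum(imp == 0) >= 4) # strong regularization zeroes noise exactly
})

test_that("held-out accuracy sits at chance under label permutation for every family", {
  toy <- make_toy(n = 80, p = 5, d = 1.5, n_signal = 2, seed = 11)
  train <- seq_len(40); test <- 41:80
  for (fam in families) {
    meds <- withr::with_seed(7, {
      vapply(1:100, function(i) {
        yp <- sample(toy$y)
        fit <- fit_classifier(classifier_spec(fam), toy$X[train, ], yp[train],
                              seed = i)
        balanced_accuracy(yp[test], predict(fit, toy$X[test, ]))
      }, numeric(1))
    })
    expect_lt(abs(median(meds) - 0.5), 0.03 + 1e-12)
  }
})
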