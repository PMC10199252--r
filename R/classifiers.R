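# Uniform contract over the four classifier families used throughout the
# pipeline. All fits are deterministic given a seed; all expose the same
# fit/predict surface, and the three importance-producing families expose a
# per-variable informativeness score:
#   elastic_net             |coefficient| on the inner-CV regularization path
#   random_forest           out-of-bag permutation importance (clamped at 0)
#   bayesian_regression_tree tree-inclusion proportion of a boosted
#                            sum-of-trees ensemble (the BART-style posterior
#                            inclusion analogue)

classifier_families <- c("logistic_regression", "random_forest",
                         "bayesian_regression_tree", "elastic_net")

default_hyperparameters <- list(
  logistic_regression = list(ridge_fallback = 1e-6),
  random_forest = list(num_trees = 500, mtry = NA_real_),
  bayesian_regression_tree = list(num_trees = 50, max_depth = 2,
                                  learning_rate = 0.1),
  elastic_net = list(alpha = 0.5, nfolds = 5,
                     lambda_predict = "lambda.min",
                     lambda_importance = "lambda.1se")
)

#' Construct a classifier specification
#'
#' @param family one of `"logistic_regression"`, `"random_forest"`,
#'   `"bayesian_regression_tree"`, `"elastic_net"`. The Bayesian-regression-
#'   tree family is realized as a boosted sum-of-trees ensemble whose
#'   variable-inclusion proportions play the role of posterior inclusion;
#'   the engine is recorded in fit metadata.
#' @param filtered should the four-stage variable filter be applied on each
#'   training fold before fitting (see [run_selection()])?
#' @param ... hyperparameter overrides, validated against a per-family
#'   schema. Defaults: random forest 500 trees and sqrt(p) variables per
#'   split; elastic net mixing alpha = 0.5 with the path chosen by inner
#'   5-fold CV; boosted trees 50 trees of depth 2 at learning rate 0.1;
#'   logistic regression unpenalized with a 1e-6 ridge fallback under
#'   separation.
#' @return an object of class `classifier_spec`.
#' @export
classifier_spec <- function(family, filtered = FALSE, ...) {
  if (length(family) != 1L || !family %in% classifier_families) {
    stop_modulearn(paste0("unknown classifier family: ",
                          paste(family, collapse = ", ")),
                   "modulearn_contract_error")
  }
  hp <- default_hyperparameters[[family]]
  extra <- list(...)
  unknown <- setdiff(names(extra), names(hp))
  if (length(unknown) > 0) {
    stop_modulearn(paste0("unknown hyperparameter(s) for ", family, ": ",
                          paste(unknown, collapse = ", ")),
                   "modulearn_contract_error")
  }
  hp[names(extra)] <- extra
  structure(list(family = family, filtered = isTRUE(filtered),
                 hyperparameters = hp),
            class = "classifier_spec")
}

#' @export
print.classifier_spec <- function(x, ...) {
  cat("<classifier_spec> ", x$family,
      if (x$filtered) " (filtered)" else " (unfiltered)", "\n", sep = "")
  invisible(x)
}

# canonicalize labels: factor with 2 levels; positive class = second level
as_binary_y <- function(y) {
  y <- if (is.factor(y)) droplevels(y) else factor(y)
  if (nlevels(y) < 2L) {
    stop_modulearn("y has a single class; a binary contrast is required",
                   "modulearn_data_error")
  }
  if (nlevels(y) > 2L) {
    stop_modulearn("y has more than two classes", "modulearn_contract_error")
  }
  y
}

as_X_matrix <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) > 0 && is.null(colnames(X))) {
    colnames(X) <- paste0("V", seq_len(ncol(X)))
  }
  storage.mode(X) <- "double"
  X
}

#' Fit a classifier
#'
#' @param spec a [classifier_spec()].
#' @param X episode-by-variable numeric matrix or data frame; no missing
#'   values.
#' @param y binary labels (factor, character or logical); the positive class
#'   is the second factor level.
#' @param seed integer seed; every family is deterministic given it.
#' @return an object of class `modulearn_fit`.
#' @export
fit_classifier <- function(spec, X, y, seed = 1L) {
  stopifnot(inherits(spec, "classifier_spec"))
  X <- as_X_matrix(X)
  y <- as_binary_y(y)
  if (nrow(X) != length(y)) {
    stop_modulearn("X and y lengths differ", "modulearn_contract_error")
  }
  if (anyNA(X)) {
    stop_modulearn("X contains missing values; contrasts are complete-case",
                   "modulearn_contract_error")
  }
  if (min(table(y)) < 2L) {
    stop_modulearn("need at least 2 episodes per class", "modulearn_data_error")
  }
  hp <- spec$hyperparameters
  y01 <- as.integer(y) - 1L
  fitted <- with_seed(as.integer(seed), switch(
    spec$family,
    logistic_regression = fit_logistic(X, y01, hp),
    elastic_net = fit_elastic_net(X, y01, hp),
    random_forest = fit_random_forest(X, y, hp, seed),
    bayesian_regression_tree = fit_boosted_trees(X, y01, hp, seed)
  ))
  structure(list(spec = spec, variables = colnames(X), levels = levels(y),
                 positive = levels(y)[2], seed = as.integer(seed),
                 engine = fitted$engine, model = fitted),
            class = "modulearn_fit")
}

fit_logistic <- function(X, y01, hp) {
  fit <- suppressWarnings(glm.fit(cbind(`(Intercept)` = 1, X), y01,
                                  family = binomial()))
  p <- fit$fitted.values
  separated <- !fit$converged || any(p > 1 - 1e-8 | p < 1e-8)
  if (separated) {
    # quasi-separation: refit with a tiny ridge so coefficients stay finite
    g <- glmnet::glmnet(pad_matrix(X), y01, family = "binomial", alpha = 0,
                        lambda = hp$ridge_fallback, standardize = FALSE)
    list(engine = "glmnet_ridge_fallback", glmnet = g, padded = ncol(X) < 2)
  } else {
    list(engine = "glm", coef = fit$coefficients)
  }
}

# glmnet needs >= 2 columns; pad single-variable designs with a zero column
pad_matrix <- function(X) {
  if (ncol(X) >= 2) X else cbind(X, `..pad` = 0)
}

fit_elastic_net <- function(X, y01, hp) {
  nfolds <- max(3L, min(hp$nfolds, min(table(y01))))
  cv <- glmnet::cv.glmnet(pad_matrix(X), y01, family = "binomial",
                          alpha = hp$alpha, nfolds = nfolds)
  list(engine = "cv.glmnet", cv = cv, padded = ncol(X) < 2)
}

fit_random_forest <- function(X, y, hp, seed) {
  mtry <- if (is.na(hp$mtry)) max(1L, floor(sqrt(ncol(X)))) else as.integer(hp$mtry)
  rf <- ranger::ranger(x = as.data.frame(X), y = y,
                       num.trees = hp$num_trees, mtry = mtry,
                       importance = "permutation",
                       seed = as.integer(seed), num.threads = 1)
  list(engine = "ranger", rf = rf)
}

fit_boosted_trees <- function(X, y01, hp, seed) {
  dm <- xgboost::xgb.DMatrix(X, label = y01, nthread = 1)
  bst <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = hp$max_depth,
                  eta = hp$learning_rate, nthread = 1,
                  seed = as.integer(seed)),
    data = dm, nrounds = hp$num_trees, verbose = 0)
  list(engine = "xgboost", bst = bst, n_trees = hp$num_trees)
}

#' Predict class labels
#'
#' @param object a `modulearn_fit`.
#' @param newdata matrix or data frame whose columns are exactly the model's
#'   training variables (any order); extra or missing columns are contract
#'   errors.
#' @param ... unused.
#' @return a factor of predicted labels with the training levels.
#' @export
predict.modulearn_fit <- function(object, newdata, ...) {
  X <- as_X_matrix(newdata)
  if (!setequal(colnames(X), object$variables)) {
    extra <- setdiff(colnames(X), object$variables)
    miss <- setdiff(object$variables, colnames(X))
    stop_modulearn(
      paste0("newdata columns must match the training variables",
             if (length(miss)) paste0("; missing: ", paste(miss, collapse = ", ")),
             if (length(extra)) paste0("; unknown: ", paste(extra, collapse = ", "))),
      "modulearn_contract_error")
  }
  X <- X[, object$variables, drop = FALSE]
  if (nrow(X) == 0) {
    return(factor(character(), levels = object$levels))
  }
  m <- object$model
  prob <- switch(
    object$spec$family,
    logistic_regression = if (m$engine == "glm") {
      stats::plogis(drop(cbind(1, X) %*% m$coef))
    } else {
      drop(predict(m$glmnet, newx = pad_matrix(X), type = "response"))
    },
    elastic_net = drop(predict(
      m$cv, newx = pad_matrix(X), type = "response",
      s = object$spec$hyperparameters$lambda_predict)),
    random_forest = NULL,
    bayesian_regression_tree = predict(m$bst, xgboost::xgb.DMatrix(X, nthread = 1))
  )
  if (object$spec$family == "random_forest") {
    pred <- predict(m$rf, data = as.data.frame(X), num.threads = 1,
                    seed = object$seed)$predictions
    return(factor(as.character(pred), levels = object$levels))
  }
  factor(object$levels[(prob > 0.5) + 1L], levels = object$levels)
}

#' Per-variable informativeness scores
#'
#' Higher scores mean more informative for the fitted contrast. Defined for
#' the three importance-producing families only: the elastic net returns
#' absolute coefficients on its inner-CV regularization path
#' (`lambda_importance`, default the conservative `lambda.1se` end); the
#' random forest returns out-of-bag permutation importance clamped at zero;
#' the sum-of-trees ensemble returns the proportion of trees whose splits
#' use the variable.
#'
#' @param model a `modulearn_fit`.
#' @return a named numeric vector, one finite score per training variable.
#' @export
importance <- function(model) {
  stopifnot(inherits(model, "modulearn_fit"))
  fam <- model$spec$family
  vars <- model$variables
  m <- model$model
  scores <- switch(
    fam,
    logistic_regression = stop_modulearn(
      "importance is not defined for the logistic_regression family",
      "modulearn_contract_error"),
    elastic_net = {
      cf <- coef(m$cv, s = model$spec$hyperparameters$lambda_importance)
      v <- setNames(abs(as.numeric(cf))[-1], rownames(cf)[-1])
      v[vars]
    },
    random_forest = pmax(m$rf$variable.importance[vars], 0),
    bayesian_regression_tree = {
      # parse the booster dump directly: one block per tree, split lines
      # carry [feature<th]; inclusion proportion = share of trees using v
      dump <- xgboost::xgb.dump(m$bst, with_stats = FALSE)
      tree_id <- cumsum(grepl("^booster\\[", dump))
      feat <- regmatches(dump, regexpr("\\[[^]<]+<", dump))
      has_split <- lengths(regmatches(dump, gregexpr("<", dump))) > 0 &
        grepl("\\[", dump)
      used <- unique(data.frame(
        tree = tree_id[has_split],
        feature = substring(feat, 2, nchar(feat) - 1L)))
      prop <- table(used$feature) / m$n_trees
      v <- setNames(rep(0, length(vars)), vars)
      v[names(prop)[names(prop) %in% vars]] <- prop[names(prop) %in% vars]
      v
    })
  stopifnot(all(is.finite(scores)))
  setNames(as.numeric(scores), vars)
}

#' Balanced accuracy
#'
#' The mean of sensitivity and specificity (per-class recall averaged over
#' the two classes), so 0.5 is chance for any class mix.
#'
#' @param y_true true binary labels; must contain both classes.
#' @param y_pred predicted labels of the same length.
#' @return a fraction in `[0, 1]`.
#' @export
#' @examples
#' balanced_accuracy(c(1, 1, 1, 1, 0, 0, 0, 0),
#'                   c(1, 1, 1, 0, 0, 0, 1, 1))  # (0.75 + 0.5) / 2
balanced_accuracy <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop_modulearn("y_true and y_pred lengths differ", "modulearn_contract_error")
  }
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  classes <- unique(y_true)
  if (length(classes) < 2L) {
    stop_modulearn("balanced accuracy is undefined when y_true has one class",
                   "modulearn_data_error")
  }
  recalls <- vapply(classes, function(cl) {
    mean(y_pred[y_true == cl] == cl)
  }, numeric(1))
  mean(recalls)
}
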