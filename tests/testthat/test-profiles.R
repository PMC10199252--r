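test_that("Cohen's d matches its closed form, anchors and antisymmetry", {
  a <- c(1, 2, 3, 4); b <- c(3, 4, 5, 6)
  # hand computation: means 2.5 / 4.5, pooled var = 5/3
  expect_equal(cohens_d(a, b, +1), (4.5 - 2.5) / sqrt(5 / 3))
  expect_equal(cohens_d(a, a, +1), 0)
  expect_equal(cohens_d(a, b, -1), -cohens_d(a, b, +1))
  expect_error(cohens_d(c(1, 1), c(1, 1), +1), class = "modulearn_data_error")
  expect_error(cohens_d(1, b, +1), class = "modulearn_contract_error")
  expect_error(cohens_d(a, b, 2), class = "modulearn_contract_error")
})

test_that("the d estimator is calibrated at the study's group sizes", {
  # a variable planted at d = 0.25, module n = 161 vs retest n = 90
  withr::with_seed(50, {
    dhat <- vapply(1:300, function(i) {
      cohens_d(rnorm(161, mean = -0.25), rnorm(90), direction = +1)
    }, numeric(1))
  })
  expect_equal(mean(dhat), 0.25, tolerance = 0.02)
})

test_that("the one-sided Welch test matches hand computation and null anchors", {
  w <- welch_t(c(1, 2, 3), c(4, 5, 6), direction = +1)
  expect_equal(w$t, 3 / sqrt(2 / 3), tolerance = 1e-6)  # = 3.674
  expect_equal(w$df, 4, tolerance = 1e-9)
  expect_equal(w$p, stats::pt(3 / sqrt(2 / 3), 4, lower.tail = FALSE),
               tolerance = 1e-9)
  expect_lt(w$p, 0.05)
  # identical groups: t = 0, one-sided p = 0.5
  g <- c(0.3, -0.2, 0.8, 0.1)
  expect_equal(welch_t(g, g, +1)$p, 0.5)
  expect_error(welch_t(1, g, +1), class = "modulearn_contract_error")
  expect_error(welch_t(c(2, 2), c(2, 2), +1), class = "modulearn_data_error")
  # Student variant uses pooled df
  ws <- welch_t(c(1, 2, 3), c(4, 5, 7), +1, var_equal = TRUE)
  expect_equal(ws$df, 4)
})

test_that("the exemplary logistic fit recovers the planted coefficient sign", {
  withr::with_seed(51, {
    y <- factor(rep(c("Presence", "Affect"), 200), levels = c("Presence", "Affect"))
    x1 <- rnorm(400) + (y == "Affect") * 1.0
    x2 <- rnorm(400)
    X <- cbind(a_signal = x1, b_noise = x2)
  })
  fit <- fit_final_logistic(X, y)
  expect_equal(fit$variable_id, c("a_signal", "b_noise"))
  # positive class is Affect: the Affect-shifted predictor gets beta > 0
  expect_equal(attr(fit, "positive"), "Affect")
  expect_gt(fit$estimate[1], 0)
  expect_lt(fit$p_value[1], 0.05)
  expect_error(fit_final_logistic(X[, 0], y), class = "modulearn_contract_error")
})

test_that("a predictor independent of the outcome is rarely significant", {
  hits <- vapply(1:20, function(i) {
    withr::with_seed(600 + i, {
      y <- factor(rep(c("a", "b"), 60))
      X <- cbind(v = rnorm(120))
    })
    fit_final_logistic(X, y)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(!hits), 0.9)
})

test_that("separation falls back to a flagged ridge fit with finite output", {
  y <- factor(rep(c("a", "b"), each = 20))
  X <- cbind(sep = c(rnorm(20, -3), rnorm(20, 3)))
  expect_warning(fit <- fit_final_logistic(X, y),
                 class = "modulearn_separation_warning")
  expect_true(all(is.finite(fit$estimate)))
  expect_true(all(is.finite(fit$std_error)))
  expect_gt(fit$estimate[1], 0)
})

test_that("profiles attribute strongly planted variables to their module with specific effects", {
  es <- default_effect_spec()
  es$d <- es$d * 4  # strong variant so attribution is unambiguous
  ds <- simulate_change_scores(effects = es, seed = 52)
  presence_vars <- es$variable_id[es$module == "Presence"]
  affect_vars <- es$variable_id[es$module == "Affect"]
  selected <- c(presence_vars, affect_vars)
  prof <- build_profile(ds, "PresenceVsAffect", selected)
  expect_s3_class(prof, "effect_profile")
  expect_setequal(prof$variable_id, selected)          # profile = selection
  p_rows <- prof[prof$variable_id %in% presence_vars, ]
  expect_true(all(p_rows$module == "Presence"))
  expect_true(all(p_rows$estimate < 0))                # Presence = negative side
  expect_true(all(p_rows$specific_effect))
  expect_true(all(p_rows$d_vs_other_module > 0))
  expect_true(all(p_rows$d_vs_retest > 0))
  a_rows <- prof[prof$variable_id %in% affect_vars, ]
  expect_true(all(a_rows$module == "Affect"))
  expect_true(all(a_rows$estimate > 0))
})

test_that("null data with a forced dummy selection rarely claim specific effects", {
  flags <- unlist(lapply(1:10, function(i) {
    ds <- simulate_change_scores(seed = 700 + i)
    prof <- build_profile(ds, "AffectVsPerspective",
                          c("bdi_total", "ucla_total", "psqi_total"))
    prof$specific_effect
  }))
  expect_gte(mean(!flags), 0.9)
})

test_that("flipping the class coding flips coefficients but not specific-effect flags", {
  es <- default_effect_spec()
  es$d <- es$d * 4
  ds <- simulate_change_scores(effects = es, seed = 53)
  sel <- es$variable_id[es$module %in% c("Presence", "Affect")]
  p1 <- build_profile(ds, contrast_spec("PresenceVsAffect"), sel)
  p2 <- build_profile(ds, contrast_spec("PresenceVsAffect",
                                        positive_class = "Affect"), sel)
  m1 <- p1[order(p1$variable_id), ]
  m2 <- p2[order(p2$variable_id), ]
  expect_equal(m1$estimate, -m2$estimate, tolerance = 1e-6)
  expect_equal(m1$module, m2$module)
  expect_equal(m1$specific_effect, m2$specific_effect)
})

test_that("profile preconditions are enforced", {
  ds <- simulate_change_scores(seed = 54)
  expect_error(build_profile(ds, "PresenceVsAffect", character()),
               class = "modulearn_contract_error")
  expect_error(build_profile(ds, "TrainingVsRetest", "bdi_total"),
               class = "modulearn_contract_error")
  expect_error(build_profile(ds, "PresenceVsAffect", "not_a_variable"),
               class = "modulearn_contract_error")
  no_retest <- ds[ds$cohort != "RCC", ]
  expect_error(build_profile(no_retest, "PresenceVsAffect", "bdi_total"),
               class = "modulearn_data_error")
})

test_that("profiles export as TSV plus a module-keyed radar JSON", {
  es <- default_effect_spec(); es$d <- es$d * 4
  ds <- simulate_change_scores(effects = es, seed = 55)
  sel <- es$variable_id[es$module %in% c("Presence", "Affect")]
  prof <- build_profile(ds, "PresenceVsAffect", sel)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_effect_profile(prof, f)
  back <- readr::read_tsv(f, show_col_types = FALSE)
  expect_equal(nrow(back), nrow(prof))
  radar <- jsonlite::read_json(sub("\\.tsv$", ".json", f))
  expect_true(all(names(radar) %in% c("Presence", "Affect", "Perspective")))
  expect_true(all(unlist(lapply(radar, names)) %in% prof$variable_id))
})
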