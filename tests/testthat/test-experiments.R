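test_that("cohort splitting is disjoint, stratified and seeded", {
  d <- generate_cohort(quick_config(seed = 1, n = 500))
  sp <- split_cohort(d, 0.2, seed = 3)
  expect_equal(nrow(sp$train$stays) + nrow(sp$test$stays), 500)
  expect_length(intersect(sp$train$stays$stay_id, sp$test$stays$stay_id), 0)
  expect_lt(abs(mean(sp$train$stays$died) - mean(sp$test$stays$died)), 0.05)
  sp2 <- split_cohort(d, 0.2, seed = 3)
  expect_identical(sp2$test$stays$stay_id, sp$test$stays$stay_id)
  expect_error(split_cohort(d, 0), "test_fraction")
  expect_error(split_cohort(d, 1), "test_fraction")
})

test_that("top-k selection ranks by score with lexicographic ties", {
  scores <- tibble::tibble(lab_name = c("A", "B", "C"),
                           composite_score = c(0.3, 0.2, 0.1))
  expect_equal(select_top_k_features(scores, 2), c("A", "B"))
  expect_equal(select_top_k_features(scores, 3), c("A", "B", "C"))
  tie <- tibble::tibble(lab_name = c("zz", "aa", "mm"),
                        composite_score = c(0.5, 0.2, 0.2))
  expect_equal(select_top_k_features(tie, 2), c("zz", "aa"))
  expect_error(select_top_k_features(scores, 4), "k must be")
})

test_that("fold changes follow the signed-ratio convention", {
  expect_equal(fold_change(1058, 619), -(1058 / 619))
  expect_equal(round(fold_change(1058, 619), 1), -1.7)
  expect_equal(round(fold_change(770, 418), 1), -1.8)
  expect_equal(fold_change(100, 100), 1)
  expect_true(no_difference(100, 100))
  expect_false(no_difference(995, 431))
  expect_error(fold_change(0, 10), "positive")
})

test_that("weighted KNN degenerates correctly", {
  withr::local_seed(1)
  x <- matrix(rnorm(40), nrow = 10)
  y <- rep(c(0L, 1L), 5)
  xt <- matrix(rnorm(12), nrow = 3)
  # equal weights reproduce the unweighted prediction
  expect_equal(knn_weighted_predict(x, xt, y, weights = rep(2, 4),
                                    n_neighbors = 3),
               knn_weighted_predict(x, xt, y, n_neighbors = 3))
  # zero weight removes a column from the distance
  x2 <- x; x2[, 1] <- 1e6 * rnorm(10)
  expect_equal(knn_weighted_predict(x2, xt, y, weights = c(0, 1, 1, 1),
                                    n_neighbors = 3),
               knn_weighted_predict(x2[, -1], xt[, -1], y, n_neighbors = 3))
  # one training point predicts its own label
  expect_equal(knn_weighted_predict(x[1, , drop = FALSE], xt, y[1],
                                    n_neighbors = 1),
               rep(y[1], 3))
  expect_error(knn_weighted_predict(x, xt, y, n_neighbors = 11),
               "n_neighbors")
  expect_error(knn_weighted_predict(x, xt, y, weights = c(-1, 1, 1, 1),
                                    n_neighbors = 2), "non-negative")
})

test_that("per-lab weights broadcast over the lab's columns", {
  d <- generate_cohort(quick_config(seed = 2, n = 10, n_null = 1))
  fm <- build_lab_features(d, c("lactate", "null1"))
  w <- broadcast_lab_weights(fm, c(lactate = 2, null1 = 0.5))
  expect_equal(unique(w[fm$columns$lab_name == "lactate"]), 2)
  expect_equal(unique(w[fm$columns$lab_name == "null1"]), 0.5)
  expect_error(broadcast_lab_weights(fm, c(lactate = 2)), "null1")
})

test_that("experiments are deterministic and expose complexity when defined", {
  d <- generate_cohort(quick_config(seed = 3, n = 160))
  sp <- split_cohort(d, 0.25, seed = 1)
  spec <- experiment_spec("logistic_regression", labs = c("lactate", "null1"),
                          cv_folds = 3, seed = 7)
  r1 <- run_experiment(spec, sp$train, sp$test)
  r2 <- run_experiment(spec, sp$train, sp$test)
  expect_identical(r1$auc, r2$auc)
  expect_identical(r1$n_nonzero, r2$n_nonzero)
  expect_gte(r1$auc, 0); expect_lte(r1$auc, 1)
  expect_lte(r1$n_nonzero, r1$n_coefficients)
  expect_equal(count_nonzero_coefficients(r1), r1$n_nonzero)
  expect_equal(r1$n_coefficients, 2 * 48 * 5)
  # ROC endpoints and monotonicity
  expect_true(all(diff(r1$roc$fpr) >= 0))
  expect_true(all(diff(r1$roc$tpr) >= 0))

  nn_spec <- experiment_spec("neural_network", labs = "lactate",
                             cv_folds = 2, seed = 7)
  nn <- run_experiment(nn_spec, sp$train, sp$test)
  expect_true(is.na(nn$n_nonzero))
  expect_error(count_nonzero_coefficients(nn), "not defined")
})

test_that("KNN specs are restricted to the Labs subset", {
  expect_error(experiment_spec("knn_unweighted", labs = "x",
                               subset = "Labs+demo"), "Labs data subset")
  expect_error(experiment_spec("knn_weighted", labs = "x"), "lab_weights")
})

test_that("gradient boosting reports lab weights for the ranking source", {
  d <- generate_cohort(quick_config(seed = 4, n = 160))
  sp <- split_cohort(d, 0.25, seed = 1)
  spec <- experiment_spec("gradient_boosting", labs = c("lactate", "null1"),
                          cv_folds = 3, seed = 7)
  r <- run_experiment(spec, sp$train, sp$test)
  fm <- build_lab_features(sp$train, c("lactate", "null1"))
  w <- model_lab_weights(r, fm)
  expect_setequal(w$lab_name, c("lactate", "null1"))
  # the planted lab should dominate importance
  expect_equal(w$lab_name[1], "lactate")
})

test_that("fidelity compares variants against an explicit baseline", {
  base <- structure(list(spec = list(model = "m", subset = "Labs"),
                         auc = 0.64), class = "experiment_result")
  v1 <- structure(list(spec = list(model = "m", subset = "Labs+demo"),
                       auc = 0.73), class = "experiment_result")
  v2 <- structure(list(spec = list(model = "m", subset = "Labs"),
                       auc = 0.63), class = "experiment_result")
  rep <- fidelity_report(list(v1, v2), base)
  expect_equal(rep$delta_auc, c(0.09, -0.01))
  expect_equal(rep$comparable, c(FALSE, TRUE))
  expect_equal(fidelity_report(list(base), base)$delta_auc, 0)
  expect_error(fidelity_report(list(v1)), "baseline")
})
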