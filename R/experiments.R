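#' Split a cohort into training and test sets
#'
#' Patient-level split, stratified on the mortality label so the death rates
#' of the two parts stay close (the usual design for mortality benchmarks).
#'
#' @param dataset An [ehr_dataset()].
#' @param test_fraction Fraction of stays held out, in (0, 1).
#' @param seed Integer seed controlling the split.
#' @return List with `train` and `test` [ehr_dataset()]s.
#' @export
split_cohort <- function(dataset, test_fraction = 0.2, seed = 1L) {
  stopifnot(inherits(dataset, "ehr_dataset"))
  if (test_fraction <= 0 || test_fraction >= 1) {
    abort("test_fraction must be in (0, 1)")
  }
  stays <- dataset$stays
  test_ids <- withr::with_seed(seed, {
    unlist(lapply(split(stays$stay_id, stays$died), function(ids) {
      sample(ids, round(length(ids) * test_fraction))
    }), use.names = FALSE)
  })
  list(train = subset_stays(dataset, setdiff(stays$stay_id, test_ids)),
       test = subset_stays(dataset, test_ids))
}

#' Restrict a dataset to a set of stays
#'
#' @param dataset An [ehr_dataset()].
#' @param stay_ids Stay ids to retain.
#' @return The restricted [ehr_dataset()].
#' @export
subset_stays <- function(dataset, stay_ids) {
  ehr_dataset(dataset$stays[dataset$stays$stay_id %in% stay_ids, ],
              dataset$labs[dataset$labs$stay_id %in% stay_ids, ],
              dataset$events[dataset$events$stay_id %in% stay_ids, ])
}

#' Select the top-k laboratories by a ranking score
#'
#' @param scores Tibble with `lab_name` and one numeric score column (e.g.
#'   `composite_score` from [composite_lab_scores()], or aggregated model
#'   weights).
#' @param k Number of laboratories to keep; ties at the cut are broken by
#'   lab name so selection is deterministic.
#' @return Character vector of `k` laboratory names, in rank order.
#' @export
select_top_k_features <- function(scores, k) {
  score_col <- setdiff(names(scores), c("lab_name", "rank"))
  score_col <- score_col[vapply(scores[score_col], is.numeric, logical(1))][1]
  if (is.na(score_col)) abort("no numeric score column found")
  if (k < 1 || k > nrow(scores)) {
    abort(sprintf("k must be in [1, %d]", nrow(scores)))
  }
  ord <- order(-scores[[score_col]], scores$lab_name)
  scores$lab_name[ord][seq_len(k)]
}

#' Specify one modelling experiment
#'
#' @param model One of `"logistic_regression"`, `"gradient_boosting"`,
#'   `"neural_network"`, `"knn_unweighted"`, `"knn_weighted"`. KNN models use
#'   the Labs subset only.
#' @param labs Laboratories entering the design matrix (e.g. from
#'   [select_top_k_features()] or the expert-filtered list).
#' @param subset Data subset tag (see [build_design()]).
#' @param event_list Events to encode for event-bearing subsets.
#' @param cv_folds Cross-validation folds for the (small) hyperparameter
#'   search; 10 by default.
#' @param lab_weights Named per-lab weights for `"knn_weighted"` (broadcast
#'   to each lab's columns).
#' @param horizon Hour slots (default 48).
#' @param seed Seed controlling folds and model initialisation; a result is
#'   fully determined by (spec, data).
#' @return Object of class `experiment_spec`.
#' @export
experiment_spec <- function(model = c("logistic_regression",
                                      "gradient_boosting", "neural_network",
                                      "knn_unweighted", "knn_weighted"),
                            labs, subset = "Labs", event_list = NULL,
                            cv_folds = 10, lab_weights = NULL, horizon = 48,
                            seed = 1L) {
  model <- match.arg(model)
  subset <- match.arg(subset, SUBSET_LEVELS)
  if (grepl("^knn", model) && subset != "Labs") {
    abort("KNN experiments use the Labs data subset only")
  }
  if (model == "knn_weighted" && is.null(lab_weights)) {
    abort("knn_weighted requires lab_weights")
  }
  structure(list(model = model, labs = labs, subset = subset,
                 event_list = event_list, cv_folds = cv_folds,
                 lab_weights = lab_weights, horizon = horizon,
                 seed = as.integer(seed)),
            class = "experiment_spec")
}

#' Run one experiment: fit with CV-selected hyperparameters, evaluate on test
#'
#' Builds the spec's design matrices for the training and test cohorts, fits
#' the standardizer on training rows only, selects hyperparameters by
#' cross-validated AUC over a deliberately small grid, refits on the full
#' training set and evaluates once on the held-out test set.
#'
#' @param spec An [experiment_spec()].
#' @param train,test [ehr_dataset()]s from [split_cohort()].
#' @return Object of class `experiment_result`: `auc`, `roc` (tibble of
#'   FPR/TPR points), `n_coefficients`, `n_nonzero` (NA unless the model
#'   family supports it), `chosen` hyperparameters, and the spec.
#' @export
run_experiment <- function(spec, train, test) {
  stopifnot(inherits(spec, "experiment_spec"))
  fm_train <- build_design(train, spec$labs, spec$subset, spec$event_list,
                           spec$horizon)
  fm_test <- build_design(test, spec$labs, spec$subset, spec$event_list,
                          spec$horizon)
  std <- fit_standardizer(fm_train)
  x_train <- apply_standardizer(fm_train, std)$values
  x_test <- apply_standardizer(fm_test, std)$values
  y_train <- train$stays$died[match(rownames(x_train), train$stays$stay_id)]
  y_test <- test$stays$died[match(rownames(x_test), test$stays$stay_id)]
  if (length(unique(y_train)) < 2) {
    abort("training labels are single-class; cannot fit a classifier")
  }

  fit <- withr::with_seed(spec$seed, switch(
    spec$model,
    logistic_regression = fit_lr(x_train, y_train, spec$cv_folds),
    gradient_boosting = fit_gb(x_train, y_train, spec$cv_folds),
    neural_network = fit_nn(x_train, y_train, spec$cv_folds),
    knn_unweighted = fit_knn(x_train, y_train, spec$cv_folds, weights = NULL),
    knn_weighted = fit_knn(x_train, y_train, spec$cv_folds,
                           weights = broadcast_lab_weights(fm_train,
                                                           spec$lab_weights))
  ))
  p_test <- fit$predict(x_test)
  roc_obj <- pROC::roc(response = y_test, predictor = as.numeric(p_test),
                       levels = c(0, 1), direction = "<", quiet = TRUE)
  structure(list(
    spec = spec,
    auc = as.numeric(pROC::auc(roc_obj)),
    roc = tibble::tibble(fpr = rev(1 - roc_obj$specificities),
                         tpr = rev(roc_obj$sensitivities)),
    n_coefficients = ncol(x_train),
    n_nonzero = fit$n_nonzero,
    column_weights = fit$column_weights,
    chosen = fit$chosen,
    predictions = tibble::tibble(stay_id = rownames(x_test),
                                 died = y_test,
                                 score = as.numeric(p_test))),
    class = "experiment_result")
}

#' @exportS3Method base::print
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result> %s / %s: AUC %.3f (%d coefficients%s)\n",
              x$spec$model, x$spec$subset, x$auc, x$n_coefficients,
              if (is.na(x$n_nonzero)) ""
              else sprintf(", %d non-zero", x$n_nonzero)))
  invisible(x)
}

# deterministic stratified fold assignment (relies on caller's seeded RNG)
make_folds <- function(y, k) {
  folds <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    folds[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
  }
  folds
}

cv_auc <- function(x, y, folds, fit_predict) {
  aucs <- vapply(sort(unique(folds)), function(f) {
    p <- fit_predict(x[folds != f, , drop = FALSE], y[folds != f],
                     x[folds == f, , drop = FALSE])
    fast_auc(y[folds == f], p)
  }, numeric(1))
  mean(aucs, na.rm = TRUE)
}

# rank-based AUC (identical to the trapezoidal ROC area), used inside CV loops
fast_auc <- function(y, p) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  (sum(rank(p)[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# L1-penalized logistic regression; 3-point lambda grid selected by CV AUC,
# so non-zero coefficient counts are a meaningful complexity measure
fit_lr <- function(x, y, cv_folds) {
  lmax <- max(abs(crossprod(x, y - mean(y)))) / length(y)
  grid <- lmax * c(0.3, 0.1, 0.03)
  foldid <- make_folds(y, cv_folds)
  cv_aucs <- matrix(NA_real_, nrow = cv_folds, ncol = length(grid))
  for (f in seq_len(cv_folds)) {
    tr <- foldid != f
    # capped iterations: planted signals can make folds near-separable, where
    # unbounded coordinate descent at small lambda stalls without improving
    # the CV ranking of the grid
    path <- suppressWarnings(
      glmnet::glmnet(x[tr, , drop = FALSE], y[tr], family = "binomial",
                     alpha = 1, lambda = grid, standardize = FALSE,
                     maxit = 2e4))
    p <- predict(path, x[!tr, , drop = FALSE], type = "response")
    for (j in seq_len(ncol(p))) {
      cv_aucs[f, j] <- fast_auc(y[!tr], p[, j])
    }
  }
  lambda <- grid[which.max(colMeans(cv_aucs, na.rm = TRUE))]
  fit <- suppressWarnings(
    glmnet::glmnet(x, y, family = "binomial", alpha = 1, lambda = grid,
                   standardize = FALSE, maxit = 2e4))
  beta <- as.numeric(fit$beta[, match(lambda, fit$lambda)])
  list(predict = function(newx) {
    as.numeric(predict(fit, newx = newx, s = lambda, type = "response"))
  },
  n_nonzero = sum(beta != 0),
  column_weights = beta,
  chosen = list(lambda = lambda))
}

# gradient boosting (xgboost); grid over tree depth x rounds by CV AUC;
# complexity = number of features with non-zero importance
fit_gb <- function(x, y, cv_folds, depths = c(2, 3), rounds = c(40, 80)) {
  foldid <- make_folds(y, cv_folds)
  fold_list <- split(seq_along(y), foldid)
  best <- NULL
  for (d in depths) {
    params <- list(objective = "binary:logistic", max_depth = d, eta = 0.3,
                   nthread = 1, eval_metric = "auc")
    cv <- xgboost::xgb.cv(params = params,
                          data = xgboost::xgb.DMatrix(x, label = y),
                          nrounds = max(rounds), folds = fold_list,
                          verbose = 0)
    log <- as.data.frame(cv$evaluation_log)
    for (r in rounds) {
      auc <- log$test_auc_mean[r]
      if (is.null(best) || auc > best$auc) {
        best <- list(auc = auc, depth = d, nrounds = r)
      }
    }
  }
  params <- list(objective = "binary:logistic", max_depth = best$depth,
                 eta = 0.3, nthread = 1)
  fit <- xgboost::xgb.train(params = params,
                            data = xgboost::xgb.DMatrix(x, label = y),
                            nrounds = best$nrounds, verbose = 0)
  imp <- xgboost::xgb.importance(model = fit)
  col_w <- setNames(rep(0, ncol(x)), colnames(x))
  col_w[imp$Feature] <- imp$Gain
  list(predict = function(newx) {
    as.numeric(predict(fit, xgboost::xgb.DMatrix(newx)))
  },
  n_nonzero = nrow(imp),
  column_weights = unname(col_w),
  chosen = list(max_depth = best$depth, nrounds = best$nrounds))
}

# single-hidden-layer neural network (nnet); size grid by CV AUC
fit_nn <- function(x, y, cv_folds, sizes = c(2, 4), decay = 0.01,
                   maxit = 150) {
  foldid <- make_folds(y, cv_folds)
  fit_one <- function(xtr, ytr, size) {
    nnet::nnet(xtr, ytr, size = size, decay = decay, maxit = maxit,
               entropy = TRUE, trace = FALSE,
               MaxNWts = (ncol(xtr) + 2) * size + size + 10)
  }
  aucs <- vapply(sizes, function(s) {
    cv_auc(x, y, foldid, function(xtr, ytr, xte) {
      as.numeric(predict(fit_one(xtr, ytr, s), xte))
    })
  }, numeric(1))
  size <- sizes[which.max(aucs)]
  fit <- fit_one(x, y, size)
  # first-layer weight matrix: per hidden unit a bias row then one row per input
  w1 <- matrix(fit$wts[seq_len((ncol(x) + 1) * size)], nrow = ncol(x) + 1)
  list(predict = function(newx) as.numeric(predict(fit, newx)),
       n_nonzero = NA_integer_,
       column_weights = rowSums(abs(w1[-1, , drop = FALSE])),
       chosen = list(size = size))
}

fit_knn <- function(x, y, cv_folds, weights = NULL,
                    neighbor_grid = c(5, 15, 31)) {
  neighbor_grid <- neighbor_grid[neighbor_grid < nrow(x)]
  foldid <- make_folds(y, cv_folds)
  aucs <- vapply(neighbor_grid, function(k) {
    cv_auc(x, y, foldid, function(xtr, ytr, xte) {
      knn_weighted_predict(xtr, xte, ytr, weights = weights,
                           n_neighbors = min(k, nrow(xtr)))
    })
  }, numeric(1))
  k <- neighbor_grid[which.max(aucs)]
  list(predict = function(newx) {
    knn_weighted_predict(x, newx, y, weights = weights, n_neighbors = k)
  },
  n_nonzero = NA_integer_,
  chosen = list(n_neighbors = k))
}

#' Weighted k-nearest-neighbour mortality probabilities
#'
#' Distance between stays is weighted Euclidean,
#' `d(x, y) = sqrt(sum_j w_j (x_j - y_j)^2)`; the predicted probability for a
#' test stay is the fraction of deaths among its `n_neighbors` nearest
#' training stays. All-ones weights recover ordinary (unweighted) KNN.
#'
#' @param train_x,test_x Numeric matrices with identical columns.
#' @param labels 0/1 training labels.
#' @param weights Per-column non-negative weights (`NULL` = all ones). Use
#'   [broadcast_lab_weights()] to expand per-laboratory weights.
#' @param n_neighbors Neighbourhood size (at most `nrow(train_x)`).
#' @return Numeric vector of predicted probabilities, one per test row.
#' @export
knn_weighted_predict <- function(train_x, test_x, labels, weights = NULL,
                                 n_neighbors = 5) {
  if (n_neighbors > nrow(train_x)) {
    abort("n_neighbors exceeds the number of training stays")
  }
  if (is.null(weights)) weights <- rep(1, ncol(train_x))
  if (any(weights < 0)) abort("weights must be non-negative")
  sw <- sqrt(weights)
  a <- sweep(train_x, 2, sw, "*")
  b <- sweep(test_x, 2, sw, "*")
  # squared distances via the expansion |a - b|^2 = |a|^2 + |b|^2 - 2 a.b
  d2 <- outer(rowSums(b^2), rowSums(a^2), "+") - 2 * tcrossprod(b, a)
  apply(d2, 1, function(row) {
    mean(labels[order(row)[seq_len(n_neighbors)]])
  })
}

#' Expand per-laboratory weights to per-column weights
#'
#' @param fm A [feature_matrix()].
#' @param lab_weights Named non-negative weights, one per laboratory in the
#'   matrix's lab block. Non-lab columns receive weight 1.
#' @return Numeric vector of per-column weights.
#' @export
broadcast_lab_weights <- function(fm, lab_weights) {
  stopifnot(inherits(fm, "feature_matrix"))
  w <- rep(1, nrow(fm$columns))
  is_lab <- fm$columns$block == "lab"
  hit <- match(fm$columns$lab_name[is_lab], names(lab_weights))
  if (anyNA(hit)) {
    abort(sprintf("missing weight for lab(s): %s",
                  paste(unique(fm$columns$lab_name[is_lab][is.na(hit)]),
                        collapse = ", ")))
  }
  w[is_lab] <- unname(lab_weights[hit])
  w
}

#' Count non-zero coefficients of a trained model
#'
#' Model complexity in the sense of coefficient sparsity: the number of
#' non-zero entries of the logistic-regression coefficient vector, or the
#' number of features with non-zero importance for gradient boosting. Not
#' defined for neural networks or KNN, whose complexity is unrelated to
#' coefficient counts.
#'
#' @param result An [run_experiment()] result.
#' @return Integer count.
#' @export
count_nonzero_coefficients <- function(result) {
  stopifnot(inherits(result, "experiment_result"))
  if (!result$spec$model %in% c("logistic_regression", "gradient_boosting")) {
    abort(sprintf(paste0("non-zero coefficient counts are not defined for ",
                         "model `%s`"), result$spec$model))
  }
  as.integer(result$n_nonzero)
}

#' Signed fold change between two complexity counts
#'
#' Returns `-(a / b)` when the count decreased (`b < a`) and `+(b / a)`
#' otherwise, matching the convention of reporting a decrease from `a` to
#' `b` as a negative fold.
#'
#' @param a,b Positive counts (before, after).
#' @return Signed ratio.
#' @seealso [no_difference()]
#' @export
fold_change <- function(a, b) {
  if (a <= 0 || b <= 0) abort("fold_change requires positive counts")
  if (b < a) -(a / b) else b / a
}

#' Are two complexity counts practically equal?
#'
#' Counts whose ratio is below 1.5 are treated as showing no difference.
#'
#' @param a,b Positive counts.
#' @return Logical.
#' @export
no_difference <- function(a, b) {
  if (a <= 0 || b <= 0) abort("no_difference requires positive counts")
  max(a, b) / min(a, b) < 1.5
}

#' Fidelity of variant models against a baseline
#'
#' Reports each variant's AUC difference from the baseline model of the same
#' family (conventionally the 42-top-ranked-feature Labs model); differences
#' within 0.03 in magnitude are flagged as comparable.
#'
#' @param results List of [run_experiment()] results.
#' @param baseline The baseline [run_experiment()] result.
#' @param tolerance Comparability threshold on `|delta_auc|` (default 0.03).
#' @return Tibble with `model`, `subset`, `auc`, `delta_auc`, `comparable`.
#' @export
fidelity_report <- function(results, baseline, tolerance = 0.03) {
  if (missing(baseline) || !inherits(baseline, "experiment_result")) {
    abort("a baseline experiment_result is required")
  }
  rows <- lapply(results, function(r) {
    tibble::tibble(model = r$spec$model, subset = r$spec$subset,
                   auc = r$auc, delta_auc = r$auc - baseline$auc,
                   comparable = abs(r$auc - baseline$auc) <= tolerance)
  })
  dplyr::bind_rows(rows)
}

#' Aggregate model weights per laboratory
#'
#' Ranking source for gradient boosting and neural networks: each
#' laboratory's weight is the sum over its columns of absolute coefficient
#' magnitude — feature importances for gradient boosting, absolute
#' first-layer weights for the neural network, absolute coefficients for
#' logistic regression.
#'
#' @param result An [run_experiment()] result whose spec subset is `"Labs"`.
#' @param fm The training [feature_matrix()] the model was fitted on (used
#'   for the column-to-lab mapping); if omitted, column names of the model
#'   matrix are parsed.
#' @return Tibble `lab_name`, `weight`, sorted descending.
#' @export
model_lab_weights <- function(result, fm) {
  stopifnot(inherits(result, "experiment_result"))
  per_col <- result$column_weights
  if (is.null(per_col)) abort("result carries no per-column weights")
  cols <- fm$columns
  stopifnot(length(per_col) == nrow(cols))
  out <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(lab_name = cols$lab_name, w = per_col),
                    .data$lab_name),
    weight = sum(abs(.data$w)), .groups = "drop")
  dplyr::arrange(out[!is.na(out$lab_name), ], dplyr::desc(.data$weight),
                 .data$lab_name)
}
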