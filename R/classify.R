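# Repeated cross-validation machinery shared by the lasso model and the
# single-feature logistic regressions.
#
# Fold draws are stratified by default: within each class, shuffled
# indices are dealt round-robin across folds, so every fold's class mix is
# as close to the cohort's as possible. Any draw whose training split
# would contain fewer than `min_train_class` members of a class (or a
# single class outright) is re-drawn.
draw_folds <- function(labels, n_folds, stratify = TRUE, min_train_class = 1) {
  n <- length(labels)
  for (attempt in 1:50) {
    if (stratify) {
      fold <- integer(n)
      for (cl in unique(labels)) {
        idx <- sample(which(labels == cl))
        fold[idx] <- rep_len(sample(n_folds), length(idx))
      }
    } else {
      fold <- sample(rep_len(sample(n_folds), n))
    }
    ok <- all(vapply(seq_len(n_folds), function(f) {
      tr <- table(labels[fold != f])
      length(tr) == 2 && min(tr) >= min_train_class && any(fold == f)
    }, logical(1)))
    if (ok) return(fold)
  }
  stop("could not draw a fold assignment with two classes in every training split",
       call. = FALSE)
}

# One repetition of k-fold CV: returns pooled accuracy and (optionally) the
# feature names with nonzero coefficients in any fold.
# fit_predict(x_train, y_train, x_test) -> list(prob = P(HD), nonzero = chr)
cv_one_repetition <- function(x, y, n_folds, fit_predict, stratify = TRUE,
                              min_train_class = 1) {
  fold <- draw_folds(y, n_folds, stratify, min_train_class)
  correct <- 0L
  nonzero <- character(0)
  for (f in seq_len(n_folds)) {
    test <- fold == f
    fp <- fit_predict(x[!test, , drop = FALSE], y[!test], x[test, , drop = FALSE])
    pred <- ifelse(fp$prob >= 0.5, "HD", "LD")  # ties resolved toward HD
    correct <- correct + sum(pred == y[test])
    nonzero <- union(nonzero, fp$nonzero)
  }
  list(accuracy = correct / length(y), nonzero = nonzero)
}

# One repetition of the cross-validated lasso: a single-level k-fold CV in
# the style of cv.glmnet/cvglmnet. The lambda grid is fit on each training
# split, lambda chosen by minimum mean CV deviance across the same folds,
# and accuracy taken from the prevalidated held-out predictions at that
# lambda (link scale; >= 0 classifies as HD, so exact ties go to HD).
# Returns the repetition accuracy and the features with nonzero
# coefficients in the full-data fit at the selected lambda.
lasso_cv_repetition <- function(x, y, n_folds,
                                lambda_rule = c("lambda.min", "lambda.1se")) {
  lambda_rule <- match.arg(lambda_rule)
  yb <- as.integer(y == "HD")
  foldid <- draw_folds(y, n_folds, stratify = TRUE, min_train_class = 2)
  # small-n binomial fits trigger harmless convergence notes from glmnet
  cvfit <- suppressWarnings(
    glmnet::cv.glmnet(x, yb, family = "binomial", alpha = 1,
                      foldid = foldid, type.measure = "deviance",
                      standardize = TRUE, keep = TRUE))
  lam <- if (lambda_rule == "lambda.min") cvfit$lambda.min else cvfit$lambda.1se
  i <- match(lam, cvfit$lambda)
  link <- cvfit$fit.preval[, i]
  pred <- ifelse(link >= 0, "HD", "LD")
  cf <- as.matrix(stats::coef(cvfit, s = lam))[-1, 1]
  list(accuracy = mean(pred == y), nonzero = names(cf)[cf != 0])
}

#' Extract the feature matrix and labels from a cohort table
#'
#' @param table Tibble with `subject_id`, a label column and feature
#'   columns (all remaining numeric columns).
#' @param label_col Name of the label column (values `"HD"`/`"LD"`).
#' @return List: `x` (subjects x features matrix), `y` (character labels),
#'   `features` (names), `subject_id`.
#' @export
cohort_matrix <- function(table, label_col = "group") {
  stopifnot("subject_id" %in% names(table), label_col %in% names(table))
  feats <- setdiff(names(table), c("subject_id", label_col))
  x <- as.matrix(table[feats])
  if (anyNA(x)) stop("cohort table contains missing values", call. = FALSE)
  y <- as.character(table[[label_col]])
  stopifnot(all(y %in% c("HD", "LD")))
  if (min(table(y)) < 2) stop("need at least 2 subjects per class", call. = FALSE)
  list(x = x, y = y, features = feats, subject_id = table$subject_id)
}

#' Repeated cross-validated lasso classification accuracy
#'
#' Fits an L1-penalized logistic regression (lasso) predicting HD vs. LD
#' from the LFP features, evaluated by stratified k-fold cross-validation
#' repeated many times with fresh fold assignments. Each repetition is a
#' single-level CV in the cv.glmnet style: the regularization strength is
#' chosen by minimum mean CV deviance across the folds and accuracy is the
#' fraction of subjects correctly classified from the prevalidated
#' held-out predictions at that strength (probability threshold 0.5; exact
#' ties resolved toward HD). The mean over repetitions is the headline
#' accuracy.
#'
#' @param table Cohort tibble (see [cohort_matrix()]).
#' @param folds CV folds (default 4).
#' @param repetitions Number of CV repetitions (default 100).
#' @param seed Integer seed; fixes all fold draws.
#' @param label_col Label column name.
#' @param lambda_rule `"lambda.min"` (default) or `"lambda.1se"`.
#' @return An object of class `lasso_cv`: list with `mean_cv_accuracy`,
#'   `per_repetition_accuracies`, `selected_features` (tibble: `feature`,
#'   `frequency` of nonzero coefficients across repetitions), `folds`,
#'   `repetitions`, `seed`.
#' @export
cv_lasso_accuracy <- function(table, folds = 4, repetitions = 100, seed = 1,
                              label_col = "group",
                              lambda_rule = "lambda.min") {
  cm <- cohort_matrix(table, label_col)
  stopifnot(folds >= 2, folds <= nrow(cm$x), repetitions >= 1)
  sel_count <- stats::setNames(numeric(length(cm$features)), cm$features)
  acc <- withr::with_seed(seed, {
    vapply(seq_len(repetitions), function(r) {
      rep_res <- lasso_cv_repetition(cm$x, cm$y, folds, lambda_rule)
      sel_count[rep_res$nonzero] <<- sel_count[rep_res$nonzero] + 1
      rep_res$accuracy
    }, numeric(1))
  })
  structure(
    list(mean_cv_accuracy = mean(acc), per_repetition_accuracies = acc,
         selected_features = tibble::tibble(
           feature = cm$features,
           frequency = unname(sel_count[cm$features]) / repetitions),
         folds = folds, repetitions = repetitions, seed = seed),
    class = "lasso_cv"
  )
}

#' @export
print.lasso_cv <- function(x, ...) {
  ci <- stats::quantile(x$per_repetition_accuracies, c(0.025, 0.975))
  cat(sprintf("<lasso_cv> mean CV accuracy %.1f%% (repetition 95%% interval %.1f-%.1f%%), %d folds x %d repetitions\n",
              100 * x$mean_cv_accuracy, 100 * ci[1], 100 * ci[2],
              x$folds, x$repetitions))
  invisible(x)
}

#' Label-permutation null for the lasso classifier
#'
#' Repeats the full repeated-CV lasso procedure on copies of the cohort
#' table whose labels have been randomly shuffled (features untouched); the
#' permutation mean accuracies form the null distribution against which the
#' real model's accuracy is judged. Percentile 95% intervals summarise the
#' real (over repetitions) and null (over permutations) distributions.
#'
#' @inheritParams cv_lasso_accuracy
#' @param n_permutations Number of label permutations (default 100).
#' @param real Optionally, a precomputed `lasso_cv` for the unpermuted
#'   table; computed here when `NULL`.
#' @return An object of class `permutation_result`: list with `real`
#'   (`lasso_cv`), `null_accuracies`, `real_mean`, `null_mean`, `real_ci`,
#'   `null_ci` (percentile 95%), `n_permutations`, `seed`.
#' @export
permutation_null <- function(table, n_permutations = 100, folds = 4,
                             repetitions = 100, seed = 1,
                             label_col = "group", lambda_rule = "lambda.min",
                             real = NULL) {
  stopifnot(n_permutations >= 1)
  if (is.null(real)) {
    real <- cv_lasso_accuracy(table, folds, repetitions, seed, label_col,
                              lambda_rule)
  }
  perm_seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max,
                                                  2 * n_permutations))
  null_acc <- vapply(seq_len(n_permutations), function(p) {
    ptab <- table
    ptab[[label_col]] <- withr::with_seed(perm_seeds[2 * p - 1],
                                          sample(table[[label_col]]))
    cv_lasso_accuracy(ptab, folds, repetitions, seed = perm_seeds[2 * p],
                      label_col, lambda_rule)$mean_cv_accuracy
  }, numeric(1))
  structure(
    list(real = real, null_accuracies = null_acc,
         real_mean = real$mean_cv_accuracy, null_mean = mean(null_acc),
         real_ci = unname(stats::quantile(real$per_repetition_accuracies,
                                          c(0.025, 0.975))),
         null_ci = unname(stats::quantile(null_acc, c(0.025, 0.975))),
         n_permutations = n_permutations, seed = seed),
    class = "permutation_result"
  )
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> real mean %.1f%% (95%% CI %.1f-%.1f%%) vs. permuted mean %.1f%% (95%% CI %.1f-%.1f%%), %d permutations\n",
              100 * x$real_mean, 100 * x$real_ci[1], 100 * x$real_ci[2],
              100 * x$null_mean, 100 * x$null_ci[1], 100 * x$null_ci[2],
              x$n_permutations))
  invisible(x)
}

#' Does the real model outperform chance?
#'
#' The model beats chance when its mean cross-validated accuracy exceeds
#' the 97.5th percentile of the permutation-null accuracy distribution.
#'
#' @param result A `permutation_result`.
#' @return One-row tibble: `real_mean_pct`, `real_ci_low_pct`,
#'   `real_ci_high_pct`, the same for the null, and `outperforms_chance`.
#' @export
compare_real_vs_null <- function(result) {
  stopifnot(inherits(result, "permutation_result"))
  upper <- stats::quantile(result$null_accuracies, 0.975, names = FALSE)
  tibble::tibble(
    real_mean_pct = 100 * result$real_mean,
    real_ci_low_pct = 100 * result$real_ci[1],
    real_ci_high_pct = 100 * result$real_ci[2],
    null_mean_pct = 100 * result$null_mean,
    null_ci_low_pct = 100 * result$null_ci[1],
    null_ci_high_pct = 100 * result$null_ci[2],
    outperforms_chance = result$real_mean > upper
  )
}

glm_fit_predict <- function(x_train, y_train, x_test) {
  df <- data.frame(y = as.integer(y_train == "HD"), x = x_train[, 1])
  if (stats::sd(df$x) == 0) {
    # constant feature: intercept-only model, majority-class probability
    prob <- rep(mean(df$y), nrow(x_test))
  } else {
    fit <- suppressWarnings(stats::glm(y ~ x, data = df, family = stats::binomial()))
    prob <- suppressWarnings(
      as.numeric(stats::predict(fit, data.frame(x = x_test[, 1]),
                                type = "response")))
  }
  list(prob = prob, nonzero = character(0))
}

#' Single-feature information ranking
#'
#' Exhaustive single-feature logistic regressions: each feature alone is
#' used to predict HD vs. LD under the same repeated-CV accuracy scheme as
#' the full model, and judged against its own per-feature
#' label-permutation null. A feature is flagged informative when its real
#' mean accuracy exceeds the 95th percentile of its null. Output is ranked
#' by real mean accuracy.
#'
#' @inheritParams cv_lasso_accuracy
#' @param n_permutations Label permutations per feature.
#' @return An object of class `feature_importance`: tibble with columns
#'   `feature`, `real_accuracy`, `null_mean`, `null_p95`,
#'   `exceeds_null_95`, `rank`.
#' @export
single_feature_importance <- function(table, folds = 4, repetitions = 20,
                                      n_permutations = 50, seed = 1,
                                      label_col = "group") {
  cm <- cohort_matrix(table, label_col)
  feat_seeds <- withr::with_seed(seed,
    sample.int(.Machine$integer.max, length(cm$features)))

  one_feature <- function(j) {
    xj <- cm$x[, j, drop = FALSE]
    seeds <- withr::with_seed(feat_seeds[j],
      sample.int(.Machine$integer.max, 1 + n_permutations))
    rep_cv <- function(y, s, reps) {
      withr::with_seed(s, mean(vapply(seq_len(reps), function(r) {
        cv_one_repetition(xj, y, folds, glm_fit_predict)$accuracy
      }, numeric(1))))
    }
    real <- rep_cv(cm$y, seeds[1], repetitions)
    null <- vapply(seq_len(n_permutations), function(p) {
      yp <- withr::with_seed(seeds[1 + p], sample(cm$y))
      rep_cv(yp, seeds[1 + p], max(2, repetitions %/% 4))
    }, numeric(1))
    tibble::tibble(feature = cm$features[j], real_accuracy = real,
                   null_mean = mean(null),
                   null_p95 = stats::quantile(null, 0.95, names = FALSE),
                   exceeds_null_95 = real > stats::quantile(null, 0.95,
                                                            names = FALSE))
  }
  res <- purrr::map_dfr(seq_along(cm$features), one_feature) |>
    dplyr::arrange(dplyr::desc(.data$real_accuracy)) |>
    dplyr::mutate(rank = dplyr::row_number())
  class(res) <- c("feature_importance", class(res))
  res
}
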