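#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a mixed ANOVA result
#'
#' @param x A `mixed_anova`.
#' @param ... Unused.
#' @return Tibble with one row per effect: `effect`, `F`, `df1`, `df2`,
#'   `p`, `partial_eta_sq`.
#' @method tidy mixed_anova
#' @export
tidy.mixed_anova <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' Tidy a repeated-CV lasso result
#'
#' One row per repetition with its pooled CV accuracy.
#' @param x A `lasso_cv`.
#' @param ... Unused.
#' @return Tibble: `repetition`, `accuracy`.
#' @method tidy lasso_cv
#' @export
tidy.lasso_cv <- function(x, ...) {
  tibble::tibble(repetition = seq_along(x$per_repetition_accuracies),
                 accuracy = x$per_repetition_accuracies)
}

#' @rdname tidy.lasso_cv
#' @return `glance` returns a one-row summary: `mean_cv_accuracy`, `folds`,
#'   `repetitions`, `n_selected_features` (nonzero in >= 50% of
#'   repetitions).
#' @method glance lasso_cv
#' @export
glance.lasso_cv <- function(x, ...) {
  tibble::tibble(mean_cv_accuracy = x$mean_cv_accuracy,
                 folds = x$folds, repetitions = x$repetitions,
                 n_selected_features = sum(x$selected_features$frequency >= 0.5))
}

#' Tidy a permutation-null result
#'
#' Long table of accuracies: the real model's per-repetition accuracies and
#' the permutation-null mean accuracies.
#' @param x A `permutation_result`.
#' @param ... Unused.
#' @return Tibble: `distribution` (`"real"`/`"permuted"`), `accuracy`.
#' @method tidy permutation_result
#' @export
tidy.permutation_result <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(distribution = "real",
                   accuracy = x$real$per_repetition_accuracies),
    tibble::tibble(distribution = "permuted", accuracy = x$null_accuracies)
  )
}

#' @rdname tidy.permutation_result
#' @return `glance` returns [compare_real_vs_null()]'s one-row summary.
#' @method glance permutation_result
#' @export
glance.permutation_result <- function(x, ...) {
  compare_real_vs_null(x)
}
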