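#' Tidy a fitted class-balanced logistic model
#'
#' @param x A `fet_logistic`.
#' @param ... Unused.
#' @return Tibble with `term` and `estimate` (log-odds scale).
#' @exportS3Method generics::tidy
tidy.fet_logistic <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = as.numeric(x$coefficients))
}

#' @rdname tidy.fet_logistic
#' @return `glance()`: one row with model size and solver diagnostics.
#' @exportS3Method generics::glance
glance.fet_logistic <- function(x, ...) {
  tibble::tibble(n_features = length(x$features),
                 lambda = x$lambda,
                 weight_positive = as.numeric(x$class_weights["1"]),
                 weight_negative = as.numeric(x$class_weights["0"]),
                 converged = x$converged,
                 iterations = x$iterations)
}

#' Tidy a feature-selection result
#'
#' @param x A `fet_selection` from [rfe_select()].
#' @param ... Unused.
#' @return The cross-validated AUC per candidate feature count, with the
#'   chosen size flagged.
#' @exportS3Method generics::tidy
tidy.fet_selection <- function(x, ...) {
  dplyr::mutate(x$cv_auc_by_k, chosen = .data$k == x$chosen_k)
}

#' @rdname tidy.fet_selection
#' @exportS3Method generics::glance
glance.fet_selection <- function(x, ...) {
  tibble::tibble(n_candidates = length(x$retained_after_pcc),
                 chosen_k = x$chosen_k,
                 best_cv_auc = max(x$cv_auc_by_k$mean_auc),
                 repeats = x$repeats, folds = x$folds)
}

#' Tidy an evaluation report
#'
#' @param x A `fet_evaluation`.
#' @param ... Unused.
#' @return The metric table as a plain tibble.
#' @exportS3Method generics::tidy
tidy.fet_evaluation <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname tidy.fet_evaluation
#' @exportS3Method generics::glance
glance.fet_evaluation <- function(x, ...) {
  cm <- attr(x, "confusion")
  tibble::tibble(threshold = attr(x, "threshold"),
                 n_boot = attr(x, "n_boot"),
                 tp = cm["tp"], fp = cm["fp"], tn = cm["tn"], fn = cm["fn"])
}

#' Tidy a nested cross-validation report
#'
#' @param x A `fet_nested_cv`.
#' @param ... Unused.
#' @return Per-split, per-variant outer test AUCs.
#' @exportS3Method generics::tidy
tidy.fet_nested_cv <- function(x, ...) {
  x$results
}

#' @rdname tidy.fet_nested_cv
#' @exportS3Method generics::glance
glance.fet_nested_cv <- function(x, ...) {
  x$summary
}
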