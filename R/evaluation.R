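confusion_metrics <- function(prob, labels, threshold) {
  pred <- as.integer(prob >= threshold)
  tp <- sum(pred == 1 & labels == 1); fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0); fn <- sum(pred == 0 & labels == 1)
  c(auc = auc_rank(prob, labels),
    accuracy = (tp + tn) / length(labels),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_)
}

#' Evaluate a fitted model on a cohort with bootstrap confidence intervals
#'
#' Computes AUC (midrank statistic), accuracy, sensitivity, specificity,
#' PPV and NPV at the probability threshold, with 95% percentile-bootstrap
#' confidence intervals over patients (resampling with replacement and
#' recomputing every metric; single-class resamples are redrawn so the
#' number of resamples is exact).
#'
#' @param prob Predicted event probabilities.
#' @param labels Binary outcome labels (0/1).
#' @param threshold Classification cut-off on the probability (default 0.5,
#'   the natural value under class-balanced training).
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Integer seed for the resampling.
#' @param variant,cohort Optional labels stored in the report.
#' @return A tibble of class `fet_evaluation`: one row per metric with
#'   `estimate`, `ci_lower`, `ci_upper`; confusion counts, threshold and
#'   resample bookkeeping in attributes.
#' @export
evaluate_predictions <- function(prob, labels, threshold = 0.5,
                                 n_boot = 1000, seed = 1L,
                                 variant = NA_character_,
                                 cohort = NA_character_) {
  stopifnot(length(prob) == length(labels))
  if (length(unique(labels)) < 2)
    abort("both classes must be present for evaluation")
  point <- confusion_metrics(prob, labels, threshold)
  n <- length(labels)
  local_seed(seed)
  boot <- matrix(NA_real_, n_boot, length(point))
  redraws <- 0
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(labels[idx])) == 2) break
      redraws <- redraws + 1
    }
    boot[b, ] <- confusion_metrics(prob[idx], labels[idx], threshold)
  }
  ci <- apply(boot, 2, quantile, probs = c(0.025, 0.975), na.rm = TRUE,
              type = 7)
  out <- tibble::tibble(
    variant = variant, cohort = cohort, metric = names(point),
    estimate = as.numeric(point),
    ci_lower = ci[1, ], ci_upper = ci[2, ])
  pred <- as.integer(prob >= threshold)
  attr(out, "confusion") <- c(
    tp = sum(pred == 1 & labels == 1), fp = sum(pred == 1 & labels == 0),
    tn = sum(pred == 0 & labels == 0), fn = sum(pred == 0 & labels == 1))
  attr(out, "threshold") <- threshold
  attr(out, "n_boot") <- n_boot
  attr(out, "redraws") <- redraws
  class(out) <- c("fet_evaluation", class(out))
  out
}

#' Evaluate one variant of a fitted model set
#'
#' @param model_set A `fet_model_set` from [fit_survival_models()].
#' @param variant Variant name.
#' @param cohort `"train"` or `"test"`.
#' @inheritParams evaluate_predictions
#' @return A `fet_evaluation` tibble.
#' @export
evaluate_model <- function(model_set, variant, cohort = "test",
                           threshold = 0.5, n_boot = 1000, seed = 1L) {
  pr <- variant_probabilities(model_set, variant, cohort)
  evaluate_predictions(pr$prob, pr$sts_label, threshold, n_boot, seed,
                       variant = variant, cohort = cohort)
}

#' Integrated discrimination improvement between nested models
#'
#' IDI is the change in discrimination slope: the mean predicted risk
#' difference (extended minus baseline) among events, plus the reverse
#' difference among non-events. The z statistic divides the IDI by the
#' standard error of the paired differences,
#' `sqrt(var(d_events)/n_events + var(d_nonevents)/n_nonevents)`, and the
#' p value is two-sided normal.
#'
#' @param base_probs,ext_probs Predicted probabilities of the baseline and
#'   extended models on the same patients.
#' @param labels Binary outcome labels.
#' @return One-row tibble: `idi`, `z`, `p_value`, and the component means.
#' @export
compute_idi <- function(base_probs, ext_probs, labels) {
  stopifnot(length(base_probs) == length(ext_probs),
            length(base_probs) == length(labels))
  ev <- labels == 1
  n1 <- sum(ev); n0 <- sum(!ev)
  if (n1 < 2 || n0 < 2) abort("need at least 2 events and 2 non-events")
  d <- ext_probs - base_probs
  idi <- mean(d[ev]) - mean(d[!ev])
  se <- sqrt(var(d[ev]) / n1 + var(d[!ev]) / n0)
  z <- if (se > 0) idi / se else 0
  tibble::tibble(
    idi = idi, z = z, p_value = 2 * pnorm(-abs(z)),
    mean_diff_events = mean(d[ev]), mean_diff_nonevents = mean(d[!ev]),
    n_events = n1, n_nonevents = n0)
}

#' Nested cross-validation stability of the whole pipeline
#'
#' For each of `outer_splits` stratified 70/30 splits (distinct seeds
#' derived from the master seed), the complete pipeline - correlation
#' filter, recursive feature elimination, model fitting - is rerun entirely
#' within the outer training set and scored on the outer test set. Feature
#' selection is repeated independently per split, so the report also lists
#' the per-split selected features.
#'
#' @param table Cohort feature table (as for [fit_survival_models()]).
#' @param variants Variants to track.
#' @param outer_splits Number of outer splits (default 5).
#' @param seed Master seed.
#' @param ... Passed on to [fit_survival_models()].
#' @return Object of class `fet_nested_cv`: tibble `results` (split,
#'   variant, test AUC), list `selected_by_split`, and a `summary` tibble
#'   with per-variant mean, sd and range of the outer test AUCs.
#' @export
nested_cv <- function(table, variants = c("clinical", "TTP", "clinical-TTP"),
                      outer_splits = 5, seed = 1L, ...) {
  local_seed(seed)
  split_seeds <- sample.int(2^30, outer_splits)
  res <- list(); sel <- list()
  for (s in seq_len(outer_splits)) {
    ms <- fit_survival_models(table, variants = variants,
                              seed = split_seeds[s], ...)
    aucs <- vapply(variants, function(v) {
      pr <- variant_probabilities(ms, v, "test")
      auc_rank(pr$prob, pr$sts_label)
    }, numeric(1))
    res[[s]] <- tibble::tibble(split = s, variant = variants,
                               test_auc = aucs)
    sel[[s]] <- purrr::map(ms$selections, "selected")
  }
  results <- dplyr::bind_rows(res)
  summary <- results |>
    dplyr::group_by(.data$variant) |>
    dplyr::summarise(mean_auc = mean(.data$test_auc),
                     sd_auc = sd(.data$test_auc),
                     range_auc = max(.data$test_auc) - min(.data$test_auc),
                     .groups = "drop")
  structure(list(results = results, selected_by_split = sel,
                 summary = summary, outer_splits = outer_splits,
                 seed = seed),
            class = "fet_nested_cv")
}

#' @export
print.fet_nested_cv <- function(x, ...) {
  cat(sprintf("<fet_nested_cv> %d outer splits\n", x$outer_splits))
  print(x$summary)
  invisible(x)
}
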