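clinical_covariate_names <- function() {
  c("age", "gender", "kps", "who_grade", "mgmt", "tertp")
}

#' Stratified train/test split
#'
#' Assigns `round(n * train_fraction)` patients to the training cohort with
#' per-class allocation proportional to class size (largest-remainder
#' rounding), so the short-term-survivor rate is balanced across splits.
#'
#' @param data A data frame with an outcome column.
#' @param outcome Name of the binary outcome column (default `"sts_label"`).
#' @param train_fraction Fraction assigned to training (default 0.7).
#' @param seed Integer seed; the split is deterministic given it.
#' @return `data` with an added `.split` factor column (`"train"`/`"test"`).
#' @examples
#' co <- generate_cohort(20, images = FALSE, seed = 1)
#' table(stratified_split(co, seed = 1)$.split)
#' @export
stratified_split <- function(data, outcome = "sts_label",
                             train_fraction = 0.7, seed = 1L) {
  y <- data[[outcome]]
  if (is.null(y)) abort(paste0("no column '", outcome, "'"))
  tab <- table(y)
  if (length(tab) < 2 || any(tab < 2))
    abort("both classes need at least 2 members",
          class = "fetrad_stratification_error")
  n <- nrow(data)
  n_train <- round(n * train_fraction)
  targets <- as.numeric(tab) * train_fraction
  alloc <- floor(targets)
  rem <- targets - alloc
  short <- n_train - sum(alloc)
  if (short > 0) {
    give <- order(rem, decreasing = TRUE)[seq_len(short)]
    alloc[give] <- alloc[give] + 1
  }
  local_seed(seed)
  split <- rep("test", n)
  for (ci in seq_along(tab)) {
    idx <- which(y == names(tab)[ci])
    split[sample(idx, alloc[ci])] <- "train"
  }
  data$.split <- factor(split, levels = c("train", "test"))
  data
}

#' Standardize feature columns with training-cohort parameters
#'
#' Per feature, the training mean is subtracted and the result divided by
#' the training standard deviation (population convention, divide by n).
#' Parameters are estimated on training rows only and applied to all rows.
#' Zero-variance features are dropped with a warning.
#'
#' @param data Data frame containing the features and a `.split` column.
#' @param features Character vector of feature column names.
#' @param split Name of the split column.
#' @return List with `data` (transformed tibble) and `params` (tibble of
#'   feature, mean, sd).
#' @export
standardize_features <- function(data, features, split = ".split") {
  features <- unname(features)
  tr <- data[[split]] == "train"
  if (!any(tr)) abort("no training rows")
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  mu <- vapply(features, function(f) mean(data[[f]][tr]), numeric(1))
  sg <- vapply(features, function(f) pop_sd(data[[f]][tr]), numeric(1))
  names(mu) <- names(sg) <- features
  drop <- names(sg)[sg == 0]
  if (length(drop)) {
    warn(paste("dropping zero-variance features:",
               paste(drop, collapse = ", ")))
    features <- setdiff(features, drop)
  }
  for (f in features) data[[f]] <- (data[[f]] - mu[f]) / sg[f]
  list(data = tibble::as_tibble(data),
       params = tibble::tibble(feature = features,
                               mean = unname(mu[features]),
                               sd = unname(sg[features])))
}

#' Pairwise-correlation redundancy filter
#'
#' Iterates over feature pairs (i, j), i < j, in the given column order; if
#' the absolute Pearson correlation exceeds the threshold the second
#' feature of the pair is removed and skips all further comparisons. A pair
#' at exactly the threshold is kept.
#'
#' @param data Data frame (training rows only, by convention).
#' @param features Feature names in canonical order.
#' @param threshold Absolute correlation above which the second feature is
#'   removed (default 0.99).
#' @return Character vector of retained feature names.
#' @export
pcc_filter <- function(data, features, threshold = 0.99) {
  features <- unname(features)
  if (nrow(data) < 2) abort("need at least 2 rows")
  x <- as.matrix(data[, features, drop = FALSE])
  sds <- apply(x, 2, stats::sd)
  zv <- features[sds == 0]
  if (length(zv)) {
    warn(paste("zero-variance features treated as removable duplicates:",
               paste(zv, collapse = ", ")))
  }
  cm <- suppressWarnings(abs(cor(x)))
  cm[is.na(cm)] <- 1  # zero-variance columns: treat as perfectly redundant
  removed <- rep(FALSE, length(features))
  removed[features %in% zv] <- TRUE
  for (i in seq_along(features)) {
    if (removed[i]) next
    for (j in seq_along(features)) {
      if (j <= i || removed[j]) next
      if (cm[i, j] > threshold) removed[j] <- TRUE
    }
  }
  features[!removed]
}

#' Class-balanced L2-penalised logistic regression
#'
#' Maximum penalised likelihood with class weights
#' `w_c = n / (2 n_c)` (inversely proportional to class frequency, so that
#' `w_pos * n_pos = w_neg * n_neg`), an L2 penalty of fixed unit strength on
#' the coefficients (the intercept is unpenalised), and a damped Newton
#' solver capped at `max_iter` iterations.
#'
#' @param data Data frame of standardized inputs.
#' @param features Predictor column names.
#' @param outcome Binary outcome column name.
#' @param lambda L2 penalty strength (default 1, the unit value).
#' @param max_iter Solver iteration cap (default 1000).
#' @param tol Gradient max-norm convergence tolerance.
#' @return Object of class `fet_logistic` with elements `coefficients`
#'   (intercept first), `features`, `class_weights`, `converged`,
#'   `iterations`.
#' @export
fit_lr <- function(data, features, outcome = "sts_label", lambda = 1,
                   max_iter = 1000, tol = 1e-8, init = NULL) {
  y <- data[[outcome]]
  if (length(unique(y)) < 2) abort("both classes must be present")
  X <- cbind(`(Intercept)` = 1, as.matrix(data[, features, drop = FALSE]))
  n <- length(y)
  n1 <- sum(y == 1); n0 <- n - n1
  wc <- c(`0` = n / (2 * n0), `1` = n / (2 * n1))
  w <- ifelse(y == 1, wc["1"], wc["0"])
  p <- ncol(X)
  pen <- c(0, rep(lambda, p - 1))  # intercept unpenalised
  beta <- if (is.null(init)) numeric(p) else init
  converged <- FALSE
  iter <- 0
  loss <- function(b) {
    eta <- as.numeric(X %*% b)
    sum(w * (log1p(exp(-abs(eta))) + pmax(eta, 0) - y * eta)) +
      sum(pen * b^2) / 2
  }
  f0 <- loss(beta)
  while (iter < max_iter) {
    iter <- iter + 1
    eta <- as.numeric(X %*% beta)
    mu <- plogis(eta)
    g <- as.numeric(crossprod(X, w * (mu - y))) + pen * beta
    if (max(abs(g)) < tol) { converged <- TRUE; break }
    W <- w * mu * (1 - mu)
    H <- crossprod(X, X * W) + diag(pen, p)
    step <- tryCatch(solve(H, g), error = function(e) g / max(diag(H)))
    # backtracking damping
    t <- 1
    repeat {
      cand <- beta - t * step
      fc <- loss(cand)
      if (fc <= f0 - 1e-4 * t * sum(g * step) || t < 1e-8) break
      t <- t / 2
    }
    beta <- beta - t * step
    f0 <- loss(beta)
  }
  if (!converged && max(abs(beta)) > 1e6)
    abort("logistic solver failed to converge",
          class = "fetrad_convergence_error")
  structure(
    list(coefficients = setNames(as.numeric(beta), colnames(X)),
         features = features, outcome = outcome, class_weights = wc,
         lambda = lambda, converged = converged, iterations = iter),
    class = "fet_logistic")
}

#' @export
print.fet_logistic <- function(x, ...) {
  cat(sprintf("<fet_logistic> %d features, %s after %d iterations\n",
              length(x$features),
              if (x$converged) "converged" else "not converged",
              x$iterations))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Predicted event probabilities from a fitted logistic model
#'
#' @param object A `fet_logistic`.
#' @param newdata Data frame with the model's feature columns.
#' @param type `"response"` (probability) or `"link"` (linear predictor).
#' @param ... Unused.
#' @return Numeric vector.
#' @export
predict.fet_logistic <- function(object, newdata,
                                 type = c("response", "link"), ...) {
  type <- match.arg(type)
  miss <- setdiff(object$features, names(newdata))
  if (length(miss)) abort(paste("missing feature columns:",
                                paste(miss, collapse = ", ")),
                          class = "fetrad_schema_error")
  X <- cbind(1, as.matrix(newdata[, object$features, drop = FALSE]))
  eta <- as.numeric(X %*% object$coefficients)
  if (type == "link") eta else plogis(eta)
}

# midrank AUC of scores against binary labels
auc_rank <- function(scores, labels) {
  r <- rank(scores, ties.method = "average")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# stratified k-fold assignment
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# recursive-elimination path: order in which features are dropped, by
# smallest absolute standardized coefficient, one per refit
rfe_path <- function(data, features, outcome, lambda = 1) {
  active <- features
  sets <- list()
  sets[[length(active)]] <- active
  init <- NULL
  while (length(active) > 1) {
    fit <- fit_lr(data, active, outcome, lambda = lambda, init = init)
    cf <- abs(fit$coefficients[active])
    worst <- active[which.min(cf)]
    active <- setdiff(active, worst)
    # warm start: reuse coefficients of the surviving features
    init <- fit$coefficients[c("(Intercept)", active)]
    sets[[length(active)]] <- active
  }
  sets
}

#' Recursive feature elimination with repeated cross-validated selection of k
#'
#' For every candidate size k, recursive feature elimination (dropping the
#' feature with the smallest absolute coefficient, one per refit of the
#' class-balanced logistic model) is scored by the mean validation AUC over
#' a repeated stratified cross-validation (default 3 repeats x 5 folds).
#' The chosen k maximises the mean AUC, preferring the smallest k on ties;
#' the final feature set comes from an elimination pass on the full
#' training data at that k.
#'
#' @param data Training rows (standardized).
#' @param features Candidate feature names (after the correlation filter).
#' @param outcome Binary outcome column.
#' @param k_range Candidate feature counts (default 1:15; truncated with a
#'   warning if it exceeds the number of candidates).
#' @param repeats,folds Cross-validation geometry (default 3 x 5).
#' @param seed Integer seed for the fold draws.
#' @param lambda Penalty passed to [fit_lr()].
#' @return Object of class `fet_selection`: `selected`,
#'   `retained_after_pcc` (the input candidates), `cv_auc_by_k` tibble and
#'   `chosen_k`.
#' @export
rfe_select <- function(data, features, outcome = "sts_label",
                       k_range = 1:15, repeats = 3, folds = 5, seed = 1L,
                       lambda = 1) {
  if (max(k_range) > length(features)) {
    warn("k_range exceeds feature count; truncating")
    k_range <- k_range[k_range <= length(features)]
  }
  local_seed(seed)
  y <- data[[outcome]]
  auc_by_k <- matrix(NA_real_, length(k_range), repeats * folds)
  col <- 0
  for (r in seq_len(repeats)) {
    fold <- stratified_folds(y, folds)
    for (fd in seq_len(folds)) {
      col <- col + 1
      tr <- data[fold != fd, , drop = FALSE]
      va <- data[fold == fd, , drop = FALSE]
      sets <- rfe_path(tr, features, outcome, lambda)
      for (ki in seq_along(k_range)) {
        k <- k_range[ki]
        fit <- fit_lr(tr, sets[[k]], outcome, lambda = lambda)
        auc_by_k[ki, col] <- auc_rank(predict(fit, va), va[[outcome]])
      }
    }
  }
  mean_auc <- rowMeans(auc_by_k)
  chosen_k <- k_range[which.max(mean_auc)]  # which.max takes smallest on ties
  sets_full <- rfe_path(data, features, outcome, lambda)
  structure(
    list(selected = sets_full[[chosen_k]],
         retained_after_pcc = features,
         cv_auc_by_k = tibble::tibble(k = k_range, mean_auc = mean_auc),
         chosen_k = chosen_k, repeats = repeats, folds = folds, seed = seed),
    class = "fet_selection")
}

#' @export
print.fet_selection <- function(x, ...) {
  cat(sprintf("<fet_selection> chose k = %d of %d candidates (CV AUC %.3f)\n",
              x$chosen_k, length(x$retained_after_pcc),
              max(x$cv_auc_by_k$mean_auc)))
  cat("selected:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' Radiomic signature: the linear predictor of a fitted radiomic model
#'
#' The signature is the linear combination of the selected radiomic
#' features weighted by the logistic-regression coefficients (plus
#' intercept): the model's linear predictor, evaluated per patient to a
#' scalar.
#'
#' @param model A fitted `fet_logistic` on radiomic features.
#' @param data Data frame with the model's feature columns.
#' @return Numeric vector, one scalar per row of `data`.
#' @export
build_signature <- function(model, data) {
  predict(model, data, type = "link")
}

model_variants <- function() {
  c("TBR", "TTP", "clinical", "TBR-TTP", "clinical-TBR", "clinical-TTP",
    "clinical-TBR-TTP")
}

#' Assemble the design columns of a model variant
#'
#' Radiomic-only variants use their selected raw features; the clinical
#' variant uses the six covariates; combined variants use signature scalars
#' (not raw radiomic features) next to the covariates.
#'
#' @param variant One of `"TBR"`, `"TTP"`, `"clinical"`, `"TBR-TTP"`,
#'   `"clinical-TBR"`, `"clinical-TTP"`, `"clinical-TBR-TTP"`.
#' @param data Data frame holding clinical covariates and (for radiomic
#'   variants) the selected feature columns.
#' @param signatures Named list of signature vectors (`TBR`, `TTP`) aligned
#'   with `data` rows.
#' @param selected Named list of selected feature names per image kind.
#' @return Tibble of design columns for the variant.
#' @export
assemble_variant <- function(variant, data, signatures = list(),
                             selected = list()) {
  variant <- match.arg(variant, model_variants())
  parts <- strsplit(variant, "-")[[1]]
  out <- tibble::tibble(.rows = nrow(data))
  for (p in parts) {
    if (p == "clinical") {
      out <- dplyr::bind_cols(out, data[, clinical_covariate_names()])
    } else if (length(parts) == 1) {
      cols <- selected[[p]]
      if (is.null(cols) || !all(cols %in% names(data)))
        abort("selected features missing from table",
              class = "fetrad_schema_error")
      out <- dplyr::bind_cols(out, data[, cols])
    } else {
      if (is.null(signatures[[p]]))
        abort(paste("signature", p, "not supplied"),
              class = "fetrad_schema_error")
      sig <- tibble::tibble(x = signatures[[p]])
      names(sig) <- paste0("signature_", p)
      out <- dplyr::bind_cols(out, sig)
    }
  }
  out
}
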