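#' Fit the full clinical-radiomic model family on a cohort table
#'
#' Runs the complete training pipeline on a feature table: stratified
#' 70/30 split (unless a `.split` column is already present), training-only
#' standardization of radiomic features and of age/KPS, per-image-kind
#' correlation filtering and recursive feature elimination, radiomic model
#' fits, signature construction, and one class-balanced logistic fit per
#' model variant. Nothing downstream of the split ever touches test rows:
#' every parameter (standardization, filter, selection, coefficients) is
#' estimated on training rows only.
#'
#' @param table Cohort feature table from [extract_cohort_features()] (or
#'   of the same shape), holding the six clinical covariates, `sts_label`
#'   and `TBR_`/`TTP_`-prefixed feature columns.
#' @param variants Model variants to fit (default all seven).
#' @param k_range,repeats,folds Passed to [rfe_select()].
#' @param pcc_threshold Correlation-filter cut-off (default 0.99).
#' @param train_fraction Training fraction for the split (default 0.7).
#' @param seed Integer seed driving split and cross-validation.
#' @return Object of class `fet_model_set`: per-variant `fet_logistic` fits,
#'   selection results, signatures, standardization parameters and the split
#'   table.
#' @export
fit_survival_models <- function(table, variants = model_variants(),
                                k_range = 1:15, repeats = 3, folds = 5,
                                pcc_threshold = 0.99, train_fraction = 0.7,
                                seed = 1L) {
  stopifnot(all(variants %in% model_variants()))
  if (!".split" %in% names(table))
    table <- stratified_split(table, train_fraction = train_fraction,
                              seed = seed)
  kinds_needed <- unique(unlist(strsplit(setdiff(variants, "clinical"), "-")))
  kinds_needed <- intersect(kinds_needed, c("TBR", "TTP"))

  # clinical coding: binary covariates stay 0/1, WHO grade as indicator of
  # grade 4, age and KPS standardized like the radiomic features
  table$who_grade <- as.numeric(table$who_grade == 4)
  cont_clin <- intersect(c("age", "kps"), names(table))
  feat_cols <- list()
  for (kind in kinds_needed) {
    feat_cols[[kind]] <- grep(paste0("^", kind, "_"), names(table),
                              value = TRUE)
    if (!length(feat_cols[[kind]]))
      abort(paste("no", kind, "feature columns in table"),
            class = "fetrad_schema_error")
  }
  std <- standardize_features(table, c(unlist(feat_cols, use.names = FALSE),
                                       cont_clin))
  tab <- std$data
  # features dropped for zero training variance leave the candidate sets
  feat_cols <- purrr::map(feat_cols, intersect, std$params$feature)
  train <- tab[tab$.split == "train", , drop = FALSE]

  selections <- list(); radiomic_fits <- list(); signatures <- list()
  for (kind in kinds_needed) {
    retained <- pcc_filter(train, feat_cols[[kind]], pcc_threshold)
    sel <- rfe_select(train, retained, k_range = k_range, repeats = repeats,
                      folds = folds, seed = seed)
    fit <- fit_lr(train, sel$selected)
    selections[[kind]] <- sel
    radiomic_fits[[kind]] <- fit
    signatures[[kind]] <- build_signature(fit, tab)
  }
  selected <- purrr::map(selections, "selected")

  fits <- list()
  for (v in variants) {
    design <- assemble_variant(v, tab, signatures, selected)
    design$sts_label <- tab$sts_label
    design$.split <- tab$.split
    fits[[v]] <- fit_lr(design[design$.split == "train", , drop = FALSE],
                        setdiff(names(design), c("sts_label", ".split")))
  }

  structure(
    list(fits = fits, selections = selections,
         radiomic_fits = radiomic_fits, signatures = signatures,
         standardization = std$params, table = tab, variants = variants,
         seed = seed),
    class = "fet_model_set")
}

#' @export
print.fet_model_set <- function(x, ...) {
  cat(sprintf("<fet_model_set> %d variants: %s\n", length(x$fits),
              paste(names(x$fits), collapse = ", ")))
  for (k in names(x$selections))
    cat(sprintf("  %s: %d features selected (k = %d)\n", k,
                length(x$selections[[k]]$selected),
                x$selections[[k]]$chosen_k))
  invisible(x)
}

#' Serialize a fitted model set to JSON (plus a selection-report CSV)
#'
#' The JSON records, per variant, the coefficient vector, the selected
#' radiomic features, the standardization parameters and the seed; the CSV
#' holds the cross-validated AUC per candidate feature count for each image
#' kind.
#'
#' @param model_set A `fet_model_set`.
#' @param path Output JSON path; the selection report is written next to it
#'   as `<path>_selection.csv`.
#' @return `path`, invisibly.
#' @export
write_model_set <- function(model_set, path) {
  out <- list(
    variants = lapply(model_set$fits, function(f) list(
      coefficients = as.list(f$coefficients),
      class_weights = as.list(f$class_weights),
      converged = f$converged)),
    selected = purrr::map(model_set$selections, "selected"),
    chosen_k = purrr::map(model_set$selections, "chosen_k"),
    standardization = model_set$standardization,
    seed = model_set$seed
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  sel <- dplyr::bind_rows(
    purrr::imap(model_set$selections,
                ~ dplyr::mutate(.x$cv_auc_by_k, kind = .y)))
  readr::write_csv(sel, paste0(sub("\\.json$", "", path), "_selection.csv"))
  invisible(path)
}

#' Predicted probabilities of one variant on the model set's cohort
#'
#' @param model_set A `fet_model_set`.
#' @param variant Variant name.
#' @param cohort `"train"`, `"test"` or `"all"`.
#' @return Tibble with `.split`, `sts_label` and `prob`.
#' @export
variant_probabilities <- function(model_set, variant, cohort = "all") {
  tab <- model_set$table
  design <- assemble_variant(variant, tab, model_set$signatures,
                             purrr::map(model_set$selections, "selected"))
  prob <- predict(model_set$fits[[variant]], design)
  out <- tibble::tibble(.split = tab$.split, sts_label = tab$sts_label,
                        prob = prob)
  if (cohort != "all") out <- out[out$.split == cohort, , drop = FALSE]
  out
}
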