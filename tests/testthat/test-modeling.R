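sim_table <- function(n, p_noise = 10, beta = 2, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * (p_noise + 1)), n)
  colnames(x) <- c("signal", paste0("noise", seq_len(p_noise)))
  y <- rbinom(n, 1, plogis(beta * x[, 1]))
  dplyr::bind_cols(tibble::as_tibble(x), sts_label = y)
}

test_that("stratified splits reproduce the 141-patient arithmetic", {
  co <- tibble::tibble(sts_label = rep(c(1, 0), c(40, 101)))
  sp <- stratified_split(co, seed = 2)
  expect_equal(sum(sp$.split == "train"), 99L)
  expect_equal(sum(sp$.split == "test"), 42L)
  expect_equal(sum(sp$sts_label == 1 & sp$.split == "train"), 28L)
  expect_equal(sum(sp$sts_label == 1 & sp$.split == "test"), 12L)
  # training event rate 28/99 = 28.3%
  expect_equal(round(100 * 28 / 99, 1), 28.3)
  # n = 10 with 5 events at 0.7 gives a 7/3 split
  co2 <- tibble::tibble(sts_label = rep(c(1, 0), each = 5))
  sp2 <- stratified_split(co2, seed = 1)
  expect_equal(sum(sp2$.split == "train"), 7L)
  expect_error(stratified_split(tibble::tibble(sts_label = c(1, 0, 0))),
               class = "fetrad_stratification_error")
})

test_that("split prevalence stays balanced across simulated cohorts", {
  pvals <- vapply(1:20, function(s) {
    co <- tibble::tibble(sts_label = rep(c(1, 0), c(40, 101)))
    sp <- stratified_split(co, seed = s)
    tab <- table(sp$.split, sp$sts_label)
    suppressWarnings(prop.test(tab[, "1"], rowSums(tab))$p.value)
  }, numeric(1))
  expect_true(all(pvals > 0.5))  # allocation is deterministic, near-exact
})

test_that("standardization uses training-population parameters only", {
  df <- tibble::tibble(f = c(1, 2, 3, 10),
                       .split = c("train", "train", "train", "test"))
  out <- standardize_features(df, "f")
  expect_equal(out$data$f[1:3], c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  expect_equal(out$params$sd, sqrt(2 / 3))
  # a test value equal to the training mean maps to zero
  df2 <- tibble::tibble(f = c(1, 3, 2), .split = c("train", "train", "test"))
  expect_equal(standardize_features(df2, "f")$data$f[3], 0)
  # order statistics preserved (affine map)
  df3 <- tibble::tibble(f = rnorm(20), .split = rep("train", 20))
  expect_equal(order(standardize_features(df3, "f")$data$f), order(df3$f))
  expect_warning(standardize_features(
    tibble::tibble(f = c(1, 1), .split = c("train", "train")), "f"),
    "zero-variance")
})

test_that("the correlation filter removes the second of a redundant pair", {
  set.seed(7)
  df <- tibble::tibble(a = rnorm(200))
  df$b <- df$a                      # duplicate: PCC = 1
  df$c <- rnorm(200)                # independent
  df$d <- -df$a                     # anti-correlated counts via |PCC|
  expect_equal(pcc_filter(df, c("a", "b", "c", "d")), c("a", "c"))
  # a pair at exactly the threshold is kept
  x <- c(1, 2, 3, 4)
  y <- c(1, 2, 3, 4.8)
  r <- cor(x, y)
  df2 <- tibble::tibble(a = x, b = y)
  expect_equal(pcc_filter(df2, c("a", "b"), threshold = r), c("a", "b"))
  expect_equal(pcc_filter(df2, c("a", "b"), threshold = r - 1e-9), "a")
})

test_that("class-balanced weights follow n / (2 n_c)", {
  df <- sim_table(99, p_noise = 1, seed = 3)
  df$sts_label <- rep(c(1, 0), c(28, 71))
  fit <- fit_lr(df, "signal")
  expect_equal(unname(fit$class_weights["1"]), 99 / 56)
  expect_equal(unname(fit$class_weights["0"]), 99 / 142)
  expect_equal(unname(fit$class_weights["1"] * 28),
               unname(fit$class_weights["0"] * 71))
  # perfectly balanced classes weigh both at 1
  df2 <- sim_table(40, p_noise = 1, seed = 4)
  df2$sts_label <- rep(0:1, 20)
  fit2 <- fit_lr(df2, "signal")
  expect_equal(unname(fit2$class_weights), c(1, 1))
})

test_that("the penalised fit matches glm in the vanishing-penalty limit", {
  df <- sim_table(300, p_noise = 2, beta = 1, seed = 5)
  fit <- fit_lr(df, c("signal", "noise1", "noise2"), lambda = 1e-10)
  n1 <- sum(df$sts_label); n0 <- 300 - n1
  w <- ifelse(df$sts_label == 1, 300 / (2 * n1), 300 / (2 * n0))
  ref <- suppressWarnings(
    glm(sts_label ~ signal + noise1 + noise2, binomial(), df, weights = w))
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-5)
  # effect direction is preserved
  expect_gt(fit$coefficients["signal"], 0)
})

test_that("recursive elimination keeps the informative feature", {
  hits <- vapply(1:20, function(s) {
    df <- sim_table(200, p_noise = 14, beta = 2, seed = 100 + s)
    sel <- rfe_select(df, setdiff(names(df), "sts_label"),
                      k_range = 1:15, seed = s)
    "signal" %in% sel$selected
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("all-noise features leave cross-validated AUC near chance", {
  df <- sim_table(150, p_noise = 9, beta = 0, seed = 6)
  sel <- rfe_select(df, setdiff(names(df), "sts_label"), k_range = 1:10,
                    seed = 2)
  expect_true(all(abs(sel$cv_auc_by_k$mean_auc - 0.5) < 0.12))
  expect_equal(sel$chosen_k, sel$cv_auc_by_k$k[which.max(sel$cv_auc_by_k$mean_auc)])
})

test_that("signatures are the fitted linear predictor", {
  fit <- structure(
    list(coefficients = c(`(Intercept)` = 0, f = 2), features = "f",
         outcome = "sts_label", class_weights = c(`0` = 1, `1` = 1),
         lambda = 1, converged = TRUE, iterations = 1),
    class = "fet_logistic")
  df <- tibble::tibble(f = c(1.5, -1))
  expect_equal(build_signature(fit, df), c(3, -2))
  expect_equal(plogis(build_signature(fit, df)), predict(fit, df))
  expect_error(build_signature(fit, tibble::tibble(g = 1)),
               class = "fetrad_schema_error")
})

test_that("signatures separate the classes on an effect-bearing cohort", {
  df <- sim_table(300, p_noise = 5, beta = 2, seed = 9)
  df$.split <- "train"
  fit <- fit_lr(df, c("signal", paste0("noise", 1:5)))
  sig <- build_signature(fit, df)
  expect_lt(wilcox.test(sig ~ df$sts_label)$p.value, 1e-6)
})

test_that("variant designs have the documented column structure", {
  df <- tibble::tibble(age = rnorm(10), gender = rbinom(10, 1, 0.5),
                       kps = 80, who_grade = 1, mgmt = 0, tertp = 1,
                       TTP_f1 = rnorm(10), TTP_f2 = rnorm(10))
  sigs <- list(TBR = rnorm(10), TTP = rnorm(10))
  sel <- list(TTP = c("TTP_f1", "TTP_f2"))
  expect_equal(ncol(assemble_variant("clinical", df)), 6L)
  expect_equal(ncol(assemble_variant("TTP", df, selected = sel)), 2L)
  expect_equal(ncol(assemble_variant("TBR-TTP", df, sigs)), 2L)
  expect_equal(ncol(assemble_variant("clinical-TTP", df, sigs)), 7L)
  expect_equal(ncol(assemble_variant("clinical-TBR-TTP", df, sigs)), 8L)
  expect_named(assemble_variant("clinical-TBR-TTP", df, sigs),
               c(fetrad:::clinical_covariate_names(), "signature_TBR",
                 "signature_TTP"), ignore.order = TRUE)
  expect_error(assemble_variant("clinical-TTP", df, list()),
               class = "fetrad_schema_error")
  expect_error(assemble_variant("TBR", df, selected = list()),
               class = "fetrad_schema_error")
})
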