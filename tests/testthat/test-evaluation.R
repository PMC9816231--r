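test_that("perfect separation scores 1 on every metric", {
  prob <- c(rep(0.9, 5), rep(0.1, 5))
  y <- rep(c(1, 0), each = 5)
  ev <- evaluate_predictions(prob, y, n_boot = 50, seed = 1)
  expect_true(all(ev$estimate == 1))
})

test_that("label-independent probabilities give chance-level AUC", {
  set.seed(11)
  n <- 4000
  prob <- runif(n)
  y <- rbinom(n, 1, 0.3)
  expect_equal(fetrad:::auc_rank(prob, y), 0.5, tolerance = 0.05)
})

test_that("confusion metrics match a hand-counted 10-patient table", {
  prob <- c(0.9, 0.8, 0.6, 0.4, 0.2, 0.7, 0.55, 0.3, 0.45, 0.05)
  y <- c(1, 1, 0, 1, 0, 1, 0, 0, 0, 0)
  # at 0.5: predicted positive = {1,2,3,6,7}; TP 3, FP 2, TN 4, FN 1
  ev <- evaluate_predictions(prob, y, threshold = 0.5, n_boot = 50, seed = 2)
  est <- setNames(ev$estimate, ev$metric)
  expect_equal(unname(est["accuracy"]), 7 / 10)
  expect_equal(unname(est["sensitivity"]), 3 / 4)
  expect_equal(unname(est["specificity"]), 4 / 6)
  expect_equal(unname(est["ppv"]), 3 / 5)
  expect_equal(unname(est["npv"]), 4 / 5)
  cm <- attr(ev, "confusion")
  expect_equal(unname(cm), c(3, 2, 4, 1))
  expect_equal(unname(est["ppv"]), cm[["tp"]] / (cm[["tp"]] + cm[["fp"]]))
  expect_equal(unname(est["npv"]), cm[["tn"]] / (cm[["tn"]] + cm[["fn"]]))
})

test_that("AUC agrees with an independent implementation and is monotone-invariant", {
  set.seed(5)
  prob <- runif(60)
  prob[8] <- prob[9]  # force a tie
  y <- rbinom(60, 1, 0.4)
  a <- fetrad:::auc_rank(prob, y)
  ref <- as.numeric(suppressMessages(pROC::auc(y, prob, direction = "<")))
  expect_equal(a, ref, tolerance = 1e-12)
  expect_equal(fetrad:::auc_rank(qlogis(prob), y), a, tolerance = 1e-12)
  expect_equal(fetrad:::auc_rank(prob^3, y), a, tolerance = 1e-12)
})

test_that("bootstrap intervals bracket the point estimates deterministically", {
  set.seed(3)
  prob <- plogis(rnorm(80, sd = 2))
  y <- rbinom(80, 1, prob)
  ev1 <- evaluate_predictions(prob, y, n_boot = 300, seed = 7)
  ev2 <- evaluate_predictions(prob, y, n_boot = 300, seed = 7)
  expect_identical(tidy(ev1), tidy(ev2))
  expect_true(all(ev1$ci_lower <= ev1$estimate + 0.02))
  expect_true(all(ev1$ci_upper >= ev1$estimate - 0.02))
  expect_equal(attr(ev1, "n_boot"), 300)
})

test_that("bootstrap CIs cover the true AUC at roughly nominal rate", {
  # known-truth design: scores N(mu_1, 1) vs N(0, 1) -> AUC = pnorm(mu/sqrt 2)
  mu <- 1.2
  true_auc <- pnorm(mu / sqrt(2))
  set.seed(17)
  cover <- vapply(1:200, function(i) {
    y <- rep(c(1, 0), c(24, 56))
    s <- c(rnorm(24, mu), rnorm(56))
    ev <- evaluate_predictions(plogis(s), y, n_boot = 200, seed = i)
    lo <- ev$ci_lower[ev$metric == "auc"]
    hi <- ev$ci_upper[ev$metric == "auc"]
    lo <= true_auc && true_auc <= hi
  }, logical(1))
  expect_gte(mean(cover), 0.88)
  expect_lte(mean(cover), 0.995)
})

test_that("IDI follows its defining identity and antisymmetry", {
  p <- c(0.2, 0.3, 0.4, 0.6, 0.7, 0.8)
  y <- c(0, 0, 0, 1, 1, 1)
  expect_equal(compute_idi(p, p, y)$idi, 0)
  # shifting event probabilities up by 0.1 gives IDI exactly 0.1
  p2 <- p + 0.1 * (y == 1)
  expect_equal(compute_idi(p, p2, y)$idi, 0.1)
  # six-patient worked table
  base <- c(0.1, 0.4, 0.3, 0.6, 0.5, 0.9)
  ext <- c(0.2, 0.3, 0.1, 0.7, 0.8, 0.8)
  d <- ext - base
  hand <- (mean(d[4:6]) - mean(d[1:3]))
  res <- compute_idi(base, ext, y)
  expect_equal(res$idi, hand)
  se <- sqrt(var(d[4:6]) / 3 + var(d[1:3]) / 3)
  expect_equal(res$z, hand / se)
  expect_equal(res$p_value, 2 * pnorm(-abs(hand / se)))
  # antisymmetry
  expect_equal(compute_idi(ext, base, y)$idi, -res$idi)
  expect_error(compute_idi(base[1:3], ext[1:3], c(1, 0, 0)), "at least 2")
})

test_that("nested cross-validation is reproducible and lists per-split features", {
  co <- generate_cohort(60, grid_shape = c(20, 20, 20), seed = 44)
  tab <- extract_cohort_features(co, kinds = "TTP")
  ncv1 <- suppressWarnings(nested_cv(tab, variants = c("clinical", "clinical-TTP"),
                                     outer_splits = 3, seed = 5, k_range = 1:5,
                                     repeats = 1))
  ncv2 <- suppressWarnings(nested_cv(tab, variants = c("clinical", "clinical-TTP"),
                                     outer_splits = 3, seed = 5, k_range = 1:5,
                                     repeats = 1))
  expect_identical(tidy(ncv1), tidy(ncv2))
  expect_equal(nrow(tidy(ncv1)), 6L)
  expect_length(ncv1$selected_by_split, 3L)
  expect_true(all(c("mean_auc", "sd_auc", "range_auc") %in%
                    names(glance(ncv1))))
})
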