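test_that("the seven measures match hand-computed values", {
  m <- compute_metrics(confusion_matrix(tp = 5, fp = 0, tn = 5, fn = 0))
  expect_equal(as.numeric(m[c("precision", "recall", "accuracy",
                              "specificity", "f1", "mcc")]),
               rep(1, 6))
  expect_equal(m[["fpr"]], 0)

  m2 <- compute_metrics(confusion_matrix(tp = 3, fp = 1, tn = 4, fn = 2))
  expect_equal(m2[["precision"]], 0.75)
  expect_equal(m2[["recall"]], 0.6)
  expect_equal(m2[["accuracy"]], 0.7)
  expect_equal(m2[["specificity"]], 0.8)
  expect_equal(m2[["f1"]], 2 * 0.75 * 0.6 / 1.35)
  expect_equal(m2[["mcc"]], 10 / sqrt(600))

  m3 <- compute_metrics(confusion_matrix(tp = 0, fp = 0, tn = 5, fn = 5))
  expect_equal(m3[["precision"]], 0)
  expect_true("precision" %in% attr(m3, "degenerate"))
})

test_that("metrics equal brute-force recomputation and MCC is class-swap symmetric", {
  set.seed(11)
  for (i in 1:200) {
    n <- sample(5:100, 1)
    pred <- runif(n) < runif(1)
    truth <- runif(n) < runif(1)
    cm <- confusion_matrix(tp = sum(pred & truth), fp = sum(pred & !truth),
                           tn = sum(!pred & !truth), fn = sum(!pred & truth))
    expect_equal(as.numeric(compute_metrics(cm)),
                 as.numeric(brute_force_metrics(pred, truth)),
                 tolerance = 1e-12)
    swapped <- confusion_matrix(tp = cm$tn, fp = cm$fn, tn = cm$tp, fn = cm$fp)
    expect_equal(abs(compute_metrics(cm)[["mcc"]]),
                 abs(compute_metrics(swapped)[["mcc"]]), tolerance = 1e-12)
  }
})

test_that("confusion_from_rates inverts back through compute_metrics", {
  set.seed(3)
  for (i in 1:50) {
    r <- runif(1); s <- runif(1); p <- runif(1, 0.05, 0.95)
    m <- compute_metrics(confusion_from_rates(r, s, p))
    expect_equal(m[["recall"]], r, tolerance = 1e-12)
    expect_equal(m[["specificity"]], s, tolerance = 1e-12)
  }
  cm <- confusion_from_rates(1, 1, 0.3)
  expect_equal(cm$fp, 0); expect_equal(cm$fn, 0)
  expect_error(confusion_from_rates(1.2, 0.5), "\\[0, 1\\]")
})

test_that("k-fold splits are stratified, balanced and seed-deterministic", {
  y <- rep(c("pos", "neg"), each = 50)
  f <- kfold_split(y, 5, seed = 9)
  expect_equal(as.vector(table(f)), rep(20L, 5))
  # stratification: each fold has 10 of each label
  expect_true(all(table(f, y) == 10L))

  y2 <- rep(c("pos", "neg"), c(51, 50))
  f2 <- kfold_split(y2, 5, seed = 9)
  expect_equal(sort(as.vector(table(f2))), c(20L, 20L, 20L, 20L, 21L))

  expect_identical(kfold_split(y, 5, seed = 4), kfold_split(y, 5, seed = 4))
  expect_false(identical(kfold_split(y, 5, seed = 4), kfold_split(y, 5, seed = 5)))
  expect_error(kfold_split(y[1:3], 5, seed = 1), "exceeds")
  expect_error(kfold_split(y, 1, seed = 1), "at least 2")
})

test_that("cross-validation reaches the ceiling on separable data", {
  lx <- generate_lexicons(40, 30, seed = 31)
  cs <- generate_corpus(corpus_spec(0, 900, 0, cue_strength = 1.0, seed = 32), lx)
  bal <- make_balanced_set(cs$gold, "causal_interaction", seed = 33)
  cv <- cross_validate(bal$records, bal$y, model_params("linear", 1),
                       k = 5, seed = 33)
  expect_equal(nrow(cv$folds), 5L)
  expect_gte(cv$mean[["f1"]], 0.95)
  expect_lte(cv$sd[["f1"]], 0.05)
})

test_that("vertically averaged ROC has the documented limiting behaviour", {
  one <- data.frame(score = c(0.9, 0.8, 0.4, 0.2), label = c(TRUE, TRUE, FALSE, FALSE))
  same <- roc_vertical_average(list(one, one, one))
  expect_equal(same$auc, 1.0)
  expect_equal(same$tpr, roc_vertical_average(list(one))$tpr)

  mixed <- data.frame(score = c(0.9, 0.5, 0.6, 0.2),
                      label = c(TRUE, FALSE, TRUE, FALSE))
  r1 <- roc_vertical_average(list(mixed))
  # AUC is invariant under strictly monotone score transformation
  tr <- mixed; tr$score <- exp(5 * tr$score)
  expect_equal(roc_vertical_average(list(tr))$auc, r1$auc, tolerance = 1e-12)

  # ties are grouped into one step: all-equal scores give the diagonal
  tied <- data.frame(score = rep(1, 10), label = rep(c(TRUE, FALSE), 5))
  expect_equal(roc_vertical_average(list(tied))$auc, 0.5, tolerance = 1e-9)

  expect_warning(
    r <- roc_vertical_average(list(mixed,
                                   data.frame(score = 1, label = TRUE))),
    "single-label")
  expect_equal(r$n_folds, 1L)
})

test_that("single-fold AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(17)
  for (i in 1:20) {
    n <- sample(20:80, 1)
    lab <- runif(n) < 0.5
    if (!any(lab) || all(lab)) next
    sc <- rnorm(n) + lab
    ours <- roc_vertical_average(list(data.frame(score = sc, label = lab)),
                                 grid = seq(0, 1, length.out = 2001))
    ref <- as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE,
                                          direction = "<")))
    expect_equal(ours$auc, ref, tolerance = 2e-3)
  }
})
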