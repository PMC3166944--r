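test_that("parameter objects validate kernel-specific settings", {
  expect_error(model_params("linear", cost = -1), "positive")
  expect_error(model_params("radial_basis", gamma = 0), "gamma")
  expect_error(model_params("polynomial", degree = 0.5), "degree")
  expect_equal(model_params("sigmoid", 2, gamma = 0.5, coef0 = 1)$kernel,
               "sigmoid")
  grid <- default_param_grid()
  expect_length(grid, 45L)  # 3 linear + 6 radial + 12 sigmoid + 24 polynomial
  kernels <- vapply(grid, `[[`, "", "kernel")
  expect_setequal(unique(kernels),
                  c("linear", "polynomial", "radial_basis", "sigmoid"))
})

test_that("a linear SVM separates the separable and not the XOR pattern", {
  x <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  y_sep <- c("neg", "neg", "pos", "pos")
  m <- train_binary(x, y_sep, model_params("linear", 10))
  expect_equal(decision_scores(m, x) > 0, c(FALSE, FALSE, TRUE, TRUE))

  # identical data, params and seed give identical scores
  m2 <- train_binary(x, y_sep, model_params("linear", 10))
  expect_identical(decision_scores(m, x), decision_scores(m2, x))

  y_xor <- c("neg", "pos", "pos", "neg")
  mx <- train_binary(x, y_xor, model_params("linear", 100))
  acc <- mean((decision_scores(mx, x) > 0) == (y_xor == "pos"))
  expect_lte(acc, 0.75)  # no linear separator exceeds 3/4 on XOR

  expect_error(train_binary(x, rep("pos", 4), model_params("linear")),
               "single class")
})

test_that("balanced sets join all positives with an equal seeded negative sample", {
  lx <- generate_lexicons(40, 30, seed = 41)
  cs <- generate_corpus(corpus_spec(50, 300, 0, seed = 42), lx)
  labs <- relenz:::.gold_label_matrix(cs$gold)
  n_pos <- sum(labs[, "causal_interaction"])
  bal <- make_balanced_set(cs$gold, "causal_interaction", seed = 43)
  expect_length(bal$y, 2L * n_pos)
  expect_equal(sum(bal$y == "pos"), n_pos)
  # negatives all contain a co-occurrence
  expect_true(all(cs$gold$units$cooccur[bal$index[bal$y == "neg"]]))
  bal2 <- make_balanced_set(cs$gold, "causal_interaction", seed = 43)
  expect_identical(bal$index, bal2$index)
  bal3 <- make_balanced_set(cs$gold, "causal_interaction", seed = 44)
  expect_false(identical(bal$index, bal3$index))

  empty <- gold_corpus(cs$gold$units[, c("ref_id", "unit_index", "text")],
                       cs$gold$mentions,
                       cs$gold$labels[0, ])
  expect_error(make_balanced_set(empty, "causal_interaction"), "no positive")
})

test_that("ensemble votes count positive decisions and map to nested levels", {
  x <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  y <- c("neg", "neg", "pos", "pos")
  models <- lapply(c(0.1, 1, 10, 100), function(cost)
    train_binary(x, y, model_params("linear", cost)))
  v <- ensemble_vote(models, x)
  expect_true(all(v >= 0 & v <= 1))
  expect_equal(v, c(0, 0, 1, 1))  # unanimity both ways on separable data

  sch <- confidence_scheme()
  expect_equal(assign_confidence(c(1, 0, 0.70, 0.75, 0.5, 0.25, 0.2), sch),
               c(4L, 0L, 3L, 3L, 2L, 1L, 0L))
  expect_error(assign_confidence(1.2, sch), "\\[0, 1\\]")
  expect_error(confidence_scheme(c(0.9, 0.9, 0.5, 0.2)))

  # monotone: raising the vote never lowers the level
  votes <- sort(runif(50))
  lv <- assign_confidence(votes, sch)
  expect_true(all(diff(lv) >= 0))
})

test_that("grid search ranks by mean F1 and applies the precision/F1 filter", {
  lx <- generate_lexicons(40, 30, seed = 51)
  cs <- generate_corpus(corpus_spec(0, 350, 0, cue_strength = 1.0, seed = 52), lx)
  good <- model_params("linear", 1)
  # a radial kernel with huge gamma memorizes training points and fails CV
  bad <- model_params("radial_basis", 1, gamma = 1000)
  gs <- grid_search(cs$gold, list(good, bad), k = 3, seed = 53,
                    categories = "causal_interaction")
  expect_equal(gs$ranking[1], 1L)
  r <- gs$results
  pass <- vapply(1:2, function(g) {
    rr <- r[r$params_id == g, ]
    any(rr$precision >= 0.7 & rr$f1 >= 0.5)
  }, TRUE)
  expect_identical(sort(gs$survivors), which(pass))

  one <- grid_search(cs$gold, list(good), k = 3, seed = 53,
                     categories = "causal_interaction")
  expect_equal(one$ranking, 1L)

  expect_warning(
    none <- grid_search(cs$gold, list(bad), k = 3, seed = 53,
                        categories = "causal_interaction"),
    "no parameter set")
  expect_length(none$survivors, 0L)
})

test_that("a fitted ensemble predicts votes and levels for new units", {
  lx <- generate_lexicons(40, 30, seed = 61)
  cs <- generate_corpus(corpus_spec(0, 400, 0, cue_strength = 1.0, seed = 62), lx)
  refs <- unique(cs$gold$units$ref_id)
  set.seed(63)
  tr <- sample(refs, round(0.8 * length(refs)))
  gtr <- gold_subset(cs$gold, tr)
  gte <- gold_subset(cs$gold, setdiff(refs, tr))
  ens <- relation_ensemble(gtr, grid = list(model_params("linear", 0.5),
                                            model_params("linear", 5)),
                           k = 3, seed = 64)
  recs <- gold_records(gte, which(gte$units$cooccur))
  pred <- predict(ens, recs)
  expect_equal(nrow(pred), length(recs))
  for (cat_ in relation_categories()) {
    v <- pred[[paste0("vote_", cat_)]]
    expect_true(all(v >= 0 & v <= 1))
    expect_identical(pred[[paste0("level_", cat_)]],
                     assign_confidence(v, ens$scheme))
  }
  # on a separable corpus the committee recovers most gold labels at level 4
  labs <- relenz:::.gold_label_matrix(gte)[gte$units$cooccur, ]
  hit <- pred$level_causal_interaction == 4L
  expect_gt(sum(hit & labs[, "causal_interaction"]) /
            max(1, sum(labs[, "causal_interaction"])), 0.7)
})
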