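# Per-category binary relation classifiers.
#
# Each of the four relation categories (causal interaction, ongoing
# research, diagnostic usage, therapeutic application) gets its own binary
# soft-margin SVM trained on a balanced set: all units positively annotated
# for the category joined with an equally sized random sample of negatives
# that themselves contain an enzyme-disease co-occurrence. Category
# assignment is non-exclusive: a unit (and hence a reference) can belong to
# none, one or several categories. Agreement among the surviving
# grid-search models is converted into a four-level confidence tier with
# precision and specificity descending from level 4 to level 1.

#' The four relation categories
#' @return character vector of category names.
#' @export
relation_categories <- function() {
  c("causal_interaction", "ongoing_research",
    "diagnostic_usage", "therapeutic_application")
}

#' @keywords internal
.as_binary_label <- function(y) {
  if (is.logical(y)) y <- ifelse(y, "pos", "neg")
  y <- as.character(y)
  if (!all(y %in% c("pos", "neg"))) stop("labels must be pos/neg or logical")
  y
}

#' SVM model parameters
#'
#' @param kernel one of `"linear"`, `"polynomial"`, `"radial_basis"`,
#'   `"sigmoid"`.
#' @param cost positive soft-margin cost.
#' @param degree polynomial degree (polynomial kernel only).
#' @param gamma kernel coefficient (polynomial/radial/sigmoid).
#' @param coef0 kernel offset (polynomial/sigmoid).
#' @return an object of class `"model_params"`.
#' @export
model_params <- function(kernel = c("linear", "polynomial", "radial_basis", "sigmoid"),
                         cost = 1, degree = 3L, gamma = 1, coef0 = 0) {
  kernel <- match.arg(kernel)
  if (!is.numeric(cost) || cost <= 0) stop("cost must be positive")
  if (kernel == "polynomial" && (degree < 1L || degree != round(degree)))
    stop("degree must be a positive integer")
  if (kernel %in% c("polynomial", "radial_basis", "sigmoid") && gamma <= 0)
    stop("gamma must be positive for this kernel")
  structure(list(kernel = kernel, cost = cost, degree = as.integer(degree),
                 gamma = gamma, coef0 = coef0),
            class = "model_params")
}

#' @export
format.model_params <- function(x, ...) {
  extra <- switch(x$kernel,
    linear = "",
    polynomial = sprintf(" degree=%d gamma=%g coef0=%g", x$degree, x$gamma, x$coef0),
    radial_basis = sprintf(" gamma=%g", x$gamma),
    sigmoid = sprintf(" gamma=%g coef0=%g", x$gamma, x$coef0))
  sprintf("%s cost=%g%s", x$kernel, x$cost, extra)
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params:", format(x), ">\n"); invisible(x)
}

#' Default desk-scale parameter grid
#'
#' Spans the same axes a full-scale search would (all four kernels, cost,
#' degree, gamma, coef0) at desk scale: 4 kernels x cost {0.1, 1, 10} with
#' degree {2, 3}, gamma {0.1, 1}, coef0 {0, 1} where applicable. Larger
#' grids are a configuration choice.
#'
#' @return a list of [model_params()].
#' @export
default_param_grid <- function() {
  grid <- list()
  for (cost in c(0.1, 1, 10)) {
    grid[[length(grid) + 1L]] <- model_params("linear", cost)
    for (gamma in c(0.1, 1)) {
      grid[[length(grid) + 1L]] <- model_params("radial_basis", cost, gamma = gamma)
      for (coef0 in c(0, 1)) {
        grid[[length(grid) + 1L]] <- model_params("sigmoid", cost, gamma = gamma,
                                                  coef0 = coef0)
        for (degree in c(2L, 3L))
          grid[[length(grid) + 1L]] <- model_params("polynomial", cost,
                                                    degree = degree,
                                                    gamma = gamma, coef0 = coef0)
      }
    }
  }
  grid
}

#' Assemble a balanced training set for one category
#'
#' Joins all units positively annotated for the category with an
#' equal-size, seeded uniform random sample of negatively annotated units
#' that contain at least one enzyme-disease co-occurrence, so the balanced
#' output has size 2 x positives (prevalence 0.5).
#'
#' @param gold a gold corpus (see [gold_corpus()]).
#' @param category one of [relation_categories()].
#' @param seed integer seed for the negative sample.
#' @return list with `records` (gold units as [cooccurrence_record()]-like
#'   objects), `y` (`"pos"`/`"neg"`), `index` (row indices into the gold
#'   unit table), `category`.
#' @export
make_balanced_set <- function(gold, category, seed = 1L) {
  stopifnot(inherits(gold, "gold_corpus"), category %in% relation_categories())
  labs <- .gold_label_matrix(gold)
  pos <- which(labs[, category])
  if (length(pos) == 0L) stop("no positive units for category ", category)
  elig <- which(!labs[, category] & gold$units$cooccur)
  if (length(elig) < length(pos))
    stop(sprintf("insufficient negatives for %s: need %d, have %d",
                 category, length(pos), length(elig)))
  set.seed(as.integer(seed))
  neg <- sort(sample(elig, length(pos)))
  idx <- c(pos, neg)
  list(records = gold_records(gold, idx),
       y = rep(c("pos", "neg"), c(length(pos), length(neg))),
       index = idx, category = category)
}

#' Train one binary soft-margin SVM
#'
#' Thin, orientation-safe wrapper around a libsvm C-classification fit on
#' an already-vectorized (unit-norm tf-idf) design matrix; features are not
#' rescaled. Deterministic given data, parameters and seed.
#'
#' @param x numeric matrix or `Matrix::dgCMatrix` of feature vectors (rows =
#'   units).
#' @param y labels (`"pos"`/`"neg"` or logical); both classes must be
#'   present.
#' @param params a [model_params()].
#' @param seed integer seed.
#' @return an object of class `"svm_binary"` whose decision score is
#'   positive for the positive class.
#' @importFrom e1071 svm
#' @export
train_binary <- function(x, y, params, seed = 1L) {
  stopifnot(inherits(params, "model_params"))
  y <- .as_binary_label(y)
  if (length(unique(y)) < 2L) stop("training data contains a single class")
  set.seed(as.integer(seed))
  kern <- c(linear = "linear", polynomial = "polynomial",
            radial_basis = "radial", sigmoid = "sigmoid")[[params$kernel]]
  fit <- e1071::svm(x, factor(y, levels = c("neg", "pos")),
                    type = "C-classification", kernel = kern,
                    cost = params$cost, degree = params$degree,
                    gamma = params$gamma, coef0 = params$coef0,
                    scale = FALSE, fitted = FALSE)
  structure(list(fit = fit, params = params), class = "svm_binary")
}

#' Decision scores of a binary SVM
#'
#' @param model an `"svm_binary"` object.
#' @param x feature matrix of new units.
#' @return numeric vector; positive score means the positive class.
#' @export
decision_scores <- function(model, x) {
  stopifnot(inherits(model, "svm_binary"))
  p <- stats::predict(model$fit, x, decision.values = TRUE)
  dv <- attr(p, "decision.values")
  # libsvm reports the score for "first/second" in the column name
  sgn <- if (startsWith(colnames(dv)[1L], "pos")) 1 else -1
  as.numeric(dv[, 1L]) * sgn
}

#' @export
print.svm_binary <- function(x, ...) {
  cat(sprintf("<binary SVM: %s, %d support vectors>\n",
              format(x$params), x$fit$tot.nSV))
  invisible(x)
}

#' Grid search over SVM parameters by cross-validated F1
#'
#' Evaluates every parameter set by k-fold cross-validation on every
#' category's balanced set, ranks parameter sets by mean F1 across
#' categories, and marks as survivors the sets reaching precision >= 0.7
#' and F1 >= 0.5 in at least one category (the filter used to reduce a
#' large search to the model committee that classifies the full corpus).
#' An empty survivor set is returned as such with a warning.
#'
#' @param gold a [gold_corpus()].
#' @param grid list of [model_params()].
#' @param k folds.
#' @param seed integer seed (balanced sampling and fold assignment).
#' @param mode a [preprocess_mode()].
#' @param categories categories to evaluate (default all four).
#' @param precision_min,f1_min survivor filter thresholds.
#' @return an object of class `"grid_search"`: `results` (one row per
#'   params x category with mean metrics), `ranking` (params order by mean
#'   F1), `survivors` (indices into `grid`), `grid`.
#' @export
grid_search <- function(gold, grid, k = 5L, seed = 1L,
                        mode = preprocess_mode("removal"),
                        categories = relation_categories(),
                        precision_min = 0.7, f1_min = 0.5) {
  stopifnot(length(grid) >= 1L)
  sets <- lapply(categories, function(cat) make_balanced_set(gold, cat, seed))
  names(sets) <- categories
  rows <- list()
  for (g in seq_along(grid)) {
    for (cat in categories) {
      cv <- cross_validate(sets[[cat]]$records, sets[[cat]]$y, grid[[g]],
                           mode = mode, k = k, seed = seed)
      rows[[length(rows) + 1L]] <- data.frame(
        params_id = g, category = cat, t(cv$mean),
        stringsAsFactors = FALSE)
    }
  }
  results <- do.call(rbind, rows)
  mean_f1 <- tapply(results$f1, results$params_id, mean)
  ranking <- as.integer(names(sort(mean_f1, decreasing = TRUE)))
  surv <- vapply(seq_along(grid), function(g) {
    r <- results[results$params_id == g, ]
    any(r$precision >= precision_min & r$f1 >= f1_min)
  }, TRUE)
  survivors <- ranking[ranking %in% which(surv)]
  if (length(survivors) == 0L)
    warning("no parameter set passed the precision/F1 survivor filter")
  structure(list(results = results, ranking = ranking, survivors = survivors,
                 grid = grid, k = k, seed = seed,
                 precision_min = precision_min, f1_min = f1_min),
            class = "grid_search")
}

#' @export
print.grid_search <- function(x, ...) {
  cat(sprintf("<grid search: %d parameter set(s), %d survivor(s)>\n",
              length(x$grid), length(x$survivors)))
  top <- utils::head(x$ranking, 5L)
  for (g in top) {
    f1 <- mean(x$results$f1[x$results$params_id == g])
    cat(sprintf("  [%s] %s  mean F1 = %.3f\n",
                if (g %in% x$survivors) "*" else " ", format(x$grid[[g]]), f1))
  }
  invisible(x)
}

#' Ensemble vote fraction
#'
#' @param models non-empty list of `"svm_binary"` models for one category.
#' @param x feature matrix of units to score.
#' @return numeric vector in `[0, 1]`: per unit, the fraction of models
#'   whose decision score is positive.
#' @export
ensemble_vote <- function(models, x) {
  stopifnot(length(models) >= 1L)
  votes <- vapply(models, function(m) decision_scores(m, x) > 0,
                  logical(nrow(x)))
  rowMeans(as.matrix(votes))
}

#' Confidence tier scheme
#'
#' Maps an ensemble vote fraction to confidence levels 4 (highest
#' precision, lowest recall) down to 1, or unassigned below the level-1
#' threshold. Thresholds must be strictly decreasing from level 4 to 1.
#'
#' @param thresholds numeric vector of length 4: minimum vote fraction for
#'   levels 4, 3, 2, 1.
#' @return an object of class `"confidence_scheme"`.
#' @export
confidence_scheme <- function(thresholds = c(0.90, 0.70, 0.50, 0.25)) {
  stopifnot(length(thresholds) == 4L, all(thresholds >= 0 & thresholds <= 1),
            all(diff(thresholds) < 0))
  structure(list(thresholds = thresholds), class = "confidence_scheme")
}

#' Assign confidence levels to vote fractions
#'
#' Returns the highest level whose threshold is less than or equal to the
#' vote fraction (boundaries inclusive); fractions below the level-1
#' threshold are unassigned, encoded as level 0. Raising a vote fraction
#' can never lower the level.
#'
#' @param vote numeric vector of vote fractions in `[0, 1]`.
#' @param scheme a [confidence_scheme()].
#' @return integer vector of levels in `{4, 3, 2, 1, 0}` (0 = unassigned).
#' @export
assign_confidence <- function(vote, scheme = confidence_scheme()) {
  stopifnot(inherits(scheme, "confidence_scheme"))
  if (any(is.na(vote)) || any(vote < 0 | vote > 1))
    stop("vote fractions must lie in [0, 1]")
  th <- scheme$thresholds
  vapply(vote, function(v) {
    ok <- which(th <= v)
    if (length(ok) == 0L) 0L else 5L - min(ok)
  }, 0L)
}
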