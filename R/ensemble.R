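# The fitted relation-classification model: a committee of SVMs per
# category, selected by grid search, whose vote fraction drives the
# four-level confidence assignment.

#' Fit a per-category relation classification ensemble
#'
#' The complete training procedure: a cross-validated grid search over SVM
#' parameters on every category's balanced set, the precision/F1 survivor
#' filter, and a final committee fit of every surviving parameter set on
#' the full balanced set of each category. At prediction time the fraction
#' of committee members voting positive is mapped to confidence levels 4-1
#' (or unassigned) by the scheme's thresholds. If no parameter set survives
#' the filter, the top-ranked set is used alone (with a warning).
#'
#' @param gold a [gold_corpus()] with category labels.
#' @param mode a [preprocess_mode()].
#' @param grid list of [model_params()] to search (default
#'   [default_param_grid()]).
#' @param k cross-validation folds for the grid search.
#' @param seed integer seed (sampling, folds, training).
#' @param scheme a [confidence_scheme()].
#' @param categories categories to fit (default all four).
#' @return an object of class `"relation_ensemble"` with `print`,
#'   `summary` and `predict` methods.
#' @export
relation_ensemble <- function(gold, mode = preprocess_mode("removal"),
                              grid = default_param_grid(), k = 5L, seed = 1L,
                              scheme = confidence_scheme(),
                              categories = relation_categories()) {
  gs <- grid_search(gold, grid, k = k, seed = seed, mode = mode,
                    categories = categories)
  chosen <- gs$survivors
  if (length(chosen) == 0L) {
    warning("no survivors; falling back to the top-ranked parameter set")
    chosen <- gs$ranking[1L]
  }
  fits <- list()
  for (cat_ in categories) {
    bal <- make_balanced_set(gold, cat_, seed)
    docs <- lapply(bal$records, preprocess_unit, mode = mode)
    vocab <- build_vocabulary(docs)
    X <- vectorize_corpus(docs, vocab)
    models <- lapply(chosen, function(g) train_binary(X, bal$y, grid[[g]],
                                                      seed = seed))
    fits[[cat_]] <- list(models = models, vocab = vocab,
                         n_train = length(bal$y))
  }
  structure(list(fits = fits, mode = mode, scheme = scheme,
                 grid_search = gs, chosen = chosen, seed = seed,
                 categories = categories),
            class = "relation_ensemble")
}

#' @export
print.relation_ensemble <- function(x, ...) {
  cat(sprintf("<relation ensemble: %d categories, %d model(s) each, %s preprocessing>\n",
              length(x$fits), length(x$chosen), x$mode$mode))
  for (cat_ in names(x$fits))
    cat(sprintf("  %-24s trained on %d balanced units, vocabulary %d terms\n",
                cat_, x$fits[[cat_]]$n_train, length(x$fits[[cat_]]$vocab$terms)))
  invisible(x)
}

#' @export
summary.relation_ensemble <- function(object, ...) {
  cat("Committee parameter sets (grid-search survivors):\n")
  for (g in object$chosen)
    cat("  ", format(object$grid_search$grid[[g]]), "\n")
  cat(sprintf("Confidence thresholds (levels 4..1): %s\n",
              paste(object$scheme$thresholds, collapse = " / ")))
  print(object)
  invisible(object)
}

#' Classify co-occurrence units with a fitted ensemble
#'
#' @param object a [relation_ensemble()].
#' @param records list of [cooccurrence_record()]s (or gold units).
#' @param ... unused.
#' @return a data.frame with one row per record: `ref_id`, `unit_index`,
#'   and per category a `vote_<category>` fraction and `level_<category>`
#'   confidence level (0 = unassigned).
#' @export
predict.relation_ensemble <- function(object, records, ...) {
  stopifnot(length(records) >= 1L)
  docs <- lapply(records, preprocess_unit, mode = object$mode)
  out <- data.frame(
    ref_id = vapply(records, function(r) r$ref_id, ""),
    unit_index = vapply(records, function(r) as.integer(r$unit_index), 0L),
    stringsAsFactors = FALSE)
  for (cat_ in names(object$fits)) {
    fit <- object$fits[[cat_]]
    X <- vectorize_corpus(docs, fit$vocab)
    vote <- ensemble_vote(fit$models, X)
    out[[paste0("vote_", cat_)]] <- vote
    out[[paste0("level_", cat_)]] <- assign_confidence(vote, object$scheme)
  }
  out
}
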