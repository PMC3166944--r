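# Persistence of fitted ensembles (model bundles) and tabular metric
# reports. A bundle is a directory holding a JSON parameter manifest, one
# vocabulary TSV per category, and the serialized SVM weights.

#' Save / load a fitted relation ensemble
#'
#' @param ensemble a [relation_ensemble()].
#' @param dir bundle directory (created if missing).
#' @return `dir` (save) or the restored ensemble (load), invisibly/visibly.
#' @export
save_ensemble <- function(ensemble, dir) {
  stopifnot(inherits(ensemble, "relation_ensemble"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    mode = unclass(ensemble$mode),
    thresholds = ensemble$scheme$thresholds,
    seed = ensemble$seed,
    categories = names(ensemble$fits),
    params = lapply(ensemble$chosen, function(g)
      unclass(ensemble$grid_search$grid[[g]])))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  for (cat_ in names(ensemble$fits))
    write_vocabulary(ensemble$fits[[cat_]]$vocab,
                     file.path(dir, paste0("vocab_", cat_, ".tsv")))
  saveRDS(lapply(ensemble$fits, `[[`, "models"),
          file.path(dir, "weights.rds"))
  invisible(dir)
}

#' @rdname save_ensemble
#' @export
load_ensemble <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  models <- readRDS(file.path(dir, "weights.rds"))
  fits <- list()
  for (cat_ in manifest$categories) {
    vocab <- read_vocabulary(file.path(dir, paste0("vocab_", cat_, ".tsv")))
    fits[[cat_]] <- list(models = models[[cat_]], vocab = vocab,
                         n_train = NA_integer_)
  }
  mode <- preprocess_mode(manifest$mode$mode,
                          manifest$mode$generic_enzyme_token,
                          manifest$mode$generic_disease_token)
  structure(list(fits = fits, mode = mode,
                 scheme = confidence_scheme(manifest$thresholds),
                 grid_search = NULL, chosen = seq_along(models[[1]]),
                 seed = manifest$seed, categories = manifest$categories),
            class = "relation_ensemble")
}

#' Tabulate cross-validation metrics
#'
#' One row per fold plus `mean` and `sd` summary rows, suitable for a TSV
#' metrics report.
#'
#' @param cv a [cross_validate()] result.
#' @param category,mode labels recorded in the first two columns.
#' @return a data.frame.
#' @export
cv_metrics_table <- function(cv, category, mode) {
  stopifnot(inherits(cv, "cv_result"))
  folds <- cv$folds
  folds$fold <- as.character(folds$fold)
  summary_rows <- data.frame(fold = c("mean", "sd"),
                             rbind(cv$mean, cv$sd))
  out <- rbind(folds, summary_rows)
  cbind(data.frame(category = category,
                   preprocess_mode = if (inherits(mode, "preprocess_mode"))
                     mode$mode else as.character(mode),
                   stringsAsFactors = FALSE),
        out)
}
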