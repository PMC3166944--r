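# Confusion-matrix bookkeeping, the seven evaluation measures (precision,
# recall, accuracy, specificity, F1, MCC, FPR), stratified k-fold
# cross-validation with mean +/- sd reporting, and vertically averaged ROC
# curves with trapezoid AUC.

#' Confusion matrix
#'
#' Counts may be non-negative reals when the matrix is built from rates
#' rather than raw items (see [confusion_from_rates()]).
#'
#' @param tp,fp,tn,fn non-negative numbers, not all zero.
#' @return an object of class `"confusion_matrix"`.
#' @export
confusion_matrix <- function(tp, fp, tn, fn) {
  v <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(v < 0) || any(is.na(v))) stop("confusion counts must be non-negative")
  if (sum(v) <= 0) stop("confusion matrix must have positive total")
  structure(as.list(v), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion: tp=%g fp=%g tn=%g fn=%g>\n", x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Compute the seven evaluation measures
#'
#' precision = tp/(tp+fp); recall = tp/(tp+fn); accuracy = (tp+tn)/total;
#' specificity = tn/(tn+fp); F1 = 2PR/(P+R); MCC = (tp tn - fp fn) /
#' sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn)); fpr = fp/(fp+tn). Any 0/0
#' denominator yields 0 and is flagged in the `degenerate` attribute.
#'
#' @param cm a [confusion_matrix()].
#' @return a named numeric vector of class `"metric_set"` with components
#'   `precision`, `recall`, `accuracy`, `specificity`, `f1`, `mcc`, `fpr`.
#' @export
compute_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  tp <- cm$tp; fp <- cm$fp; tn <- cm$tn; fn <- cm$fn
  degenerate <- character(0)
  safe <- function(num, den, name) {
    if (den == 0) { degenerate <<- c(degenerate, name); return(0) }
    num / den
  }
  precision <- safe(tp, tp + fp, "precision")
  recall <- safe(tp, tp + fn, "recall")
  accuracy <- (tp + tn) / (tp + fp + tn + fn)
  specificity <- safe(tn, tn + fp, "specificity")
  f1 <- safe(2 * precision * recall, precision + recall, "f1")
  mcc <- safe(tp * tn - fp * fn,
              sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)), "mcc")
  fpr <- safe(fp, fp + tn, "fpr")
  structure(c(precision = precision, recall = recall, accuracy = accuracy,
              specificity = specificity, f1 = f1, mcc = mcc, fpr = fpr),
            degenerate = degenerate, class = c("metric_set", "numeric"))
}

#' Rebuild a balanced-prevalence confusion matrix from rates
#'
#' Produces per-unit-mass counts: `tp = prevalence * recall`,
#' `fn = prevalence * (1 - recall)`, `tn = (1 - prevalence) * specificity`,
#' `fp = (1 - prevalence) * (1 - specificity)`. With prevalence 0.5 this is
#' the balanced-test-set geometry used throughout the evaluation protocol,
#' and feeding the result to [compute_metrics()] recovers the remaining
#' measures (accuracy, MCC, ...) implied by a published recall/specificity
#' pair.
#'
#' @param recall,specificity,prevalence numbers in `[0, 1]`.
#' @return a [confusion_matrix()].
#' @export
confusion_from_rates <- function(recall, specificity, prevalence = 0.5) {
  v <- c(recall, specificity, prevalence)
  if (any(v < 0 | v > 1) || any(is.na(v)))
    stop("recall, specificity and prevalence must lie in [0, 1]")
  confusion_matrix(tp = prevalence * recall,
                   fn = prevalence * (1 - recall),
                   tn = (1 - prevalence) * specificity,
                   fp = (1 - prevalence) * (1 - specificity))
}

#' Stratified k-fold assignment
#'
#' Randomly partitions items into k folds of sizes differing by at most
#' one, stratified by label, deterministically for a given seed.
#'
#' @param y label vector (factor or coercible); its length is the number of
#'   items.
#' @param k number of folds (>= 2, <= number of items).
#' @param seed integer seed.
#' @return an integer vector of fold indices in `1..k`.
#' @export
kfold_split <- function(y, k, seed) {
  n <- length(y)
  if (k < 2L) stop("k must be at least 2")
  if (k > n) stop("k exceeds the number of items")
  y <- as.factor(y)
  set.seed(as.integer(seed))
  fold <- integer(n)
  counter <- sample.int(k, 1L)  # rotate the dealing start across labels
  for (lev in sample(levels(y))) {
    idx <- which(y == lev)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- ((counter + seq_along(idx) - 2L) %% k) + 1L
    counter <- counter + length(idx)
  }
  fold
}

#' Cross-validate a binary relation classifier
#'
#' k-fold protocol: within each fold the vocabulary is built on the
#' training portion only (test units are vectorized against it, preventing
#' document-frequency leakage), a soft-margin SVM is trained and the
#' held-out fold is scored. Folds whose training portion contains a single
#' class are skipped with a warning. Reports per-fold metric rows plus the
#' unweighted mean and sample (n-1) standard deviation.
#'
#' @param records list of [cooccurrence_record()]s (or gold units with
#'   mention spans).
#' @param y binary label vector (`"pos"`/`"neg"` factor or logical).
#' @param params a [model_params()].
#' @param mode a [preprocess_mode()].
#' @param k number of folds.
#' @param seed integer seed driving fold assignment.
#' @return an object of class `"cv_result"`: `folds` (data.frame of per-fold
#'   metrics), `mean`, `sd`, `scores` (per-fold decision scores and labels,
#'   for ROC averaging), `params`.
#' @export
cross_validate <- function(records, y, params, mode = preprocess_mode("removal"),
                           k = 5L, seed = 1L) {
  y <- .as_binary_label(y)
  docs <- lapply(records, preprocess_unit, mode = mode)
  fold <- kfold_split(y, k, seed)
  rows <- list(); scores <- list()
  for (f in sort(unique(fold))) {
    tr <- fold != f; te <- !tr
    if (length(unique(y[tr])) < 2L) {
      warning("fold ", f, " skipped: single-class training portion")
      next
    }
    vocab <- build_vocabulary(docs[tr])
    Xtr <- vectorize_corpus(docs[tr], vocab)
    Xte <- vectorize_corpus(docs[te], vocab)
    model <- train_binary(Xtr, y[tr], params, seed = seed)
    sc <- decision_scores(model, Xte)
    pred <- sc > 0
    truth <- y[te] == "pos"
    cm <- confusion_matrix(tp = sum(pred & truth), fp = sum(pred & !truth),
                           tn = sum(!pred & !truth), fn = sum(!pred & truth))
    rows[[length(rows) + 1L]] <- c(fold = f, compute_metrics(cm))
    scores[[length(scores) + 1L]] <- data.frame(score = sc, label = truth)
  }
  if (length(rows) == 0L) stop("no usable folds")
  folds <- as.data.frame(do.call(rbind, rows))
  mcols <- setdiff(names(folds), "fold")
  structure(list(folds = folds,
                 mean = colMeans(folds[mcols]),
                 sd = apply(folds[mcols], 2, stats::sd),
                 scores = scores, params = params, k = k, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, digits = 3, ...) {
  cat(sprintf("<%d-fold cross-validation (%d usable folds)>\n",
              x$k, nrow(x$folds)))
  m <- x$mean; s <- x$sd
  for (nm in names(m))
    cat(sprintf("  %-12s %s +/- %s\n", nm,
                format(round(m[[nm]], digits)), format(round(s[[nm]], digits))))
  invisible(x)
}

# Step ROC curve from decision scores, with equal scores grouped into one
# step. Returns a data.frame of (fpr, tpr) from (0,0) to (1,1).
.step_roc <- function(score, label) {
  stopifnot(any(label), any(!label))
  o <- order(score, decreasing = TRUE)
  score <- score[o]; label <- label[o]
  grp <- cumsum(!duplicated(score))
  tp <- cumsum(label); fp <- cumsum(!label)
  last <- !duplicated(grp, fromLast = TRUE)   # take each tie group whole
  data.frame(fpr = c(0, fp[last] / sum(!label)),
             tpr = c(0, tp[last] / sum(label)))
}

# Evaluate a step ROC at arbitrary fpr values. Vertical jumps happen
# exactly at their fpr: at a jump the post-jump (maximum) tpr is taken,
# between corners the curve is the segment from the post-jump tpr of the
# left corner to the pre-jump tpr of the right corner (flat for pure
# steps, diagonal for tie groups mixing both labels).
.roc_at <- function(r, at) {
  ufs <- unique(r$fpr)
  gi <- match(r$fpr, ufs)
  t_hi <- as.numeric(tapply(r$tpr, gi, max))
  t_lo <- as.numeric(tapply(r$tpr, gi, min))
  k <- findInterval(at, ufs)
  y <- t_hi[k]
  inner <- at > ufs[k] & k < length(ufs)
  if (any(inner)) {
    ki <- k[inner]
    y[inner] <- t_hi[ki] + (t_lo[ki + 1L] - t_hi[ki]) *
      (at[inner] - ufs[ki]) / (ufs[ki + 1L] - ufs[ki])
  }
  y
}

#' Vertically averaged ROC curve
#'
#' Builds a tie-grouped step ROC per fold from ranked decision scores,
#' linearly interpolates each fold's true positive rate at a fixed grid of
#' false positive rates, averages the rates vertically across folds, and
#' integrates the averaged curve by the trapezoid rule. Folds containing a
#' single label are excluded with a warning.
#'
#' @param scores list with one element per fold: a data.frame with columns
#'   `score` (real decision values) and `label` (logical, `TRUE` =
#'   positive), e.g. the `scores` component of [cross_validate()].
#' @param grid non-decreasing fpr grid in `[0, 1]`; default 101 equally
#'   spaced points.
#' @return an object of class `"roc_curve"`: `fpr`, `tpr` (averaged), `auc`,
#'   `n_folds`.
#' @export
roc_vertical_average <- function(scores, grid = seq(0, 1, length.out = 101L)) {
  stopifnot(length(scores) >= 1L, !is.unsorted(grid), all(grid >= 0 & grid <= 1))
  usable <- vapply(scores, function(s) any(s$label) && any(!s$label), TRUE)
  if (!all(usable)) warning(sum(!usable), " single-label fold(s) excluded")
  scores <- scores[usable]
  if (length(scores) == 0L) stop("no fold with both labels")
  tprs <- vapply(scores, function(s) {
    r <- .step_roc(s$score, s$label)
    .roc_at(r, grid)
  }, numeric(length(grid)))
  tpr <- rowMeans(as.matrix(tprs))
  auc <- sum(diff(grid) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(fpr = grid, tpr = tpr, auc = auc, n_folds = length(scores)),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<ROC: vertical average of %d fold(s), AUC = %.3f>\n",
              x$n_folds, x$auc))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  plot(x$fpr, x$tpr, type = "l", xlab = "False positive rate",
       ylab = "True positive rate", xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3, col = "grey")
  invisible(x)
}

#' Export ROC points as TSV
#' @param roc a `"roc_curve"` object.
#' @param path file path.
#' @export
write_roc <- function(roc, path) {
  utils::write.table(data.frame(fpr = roc$fpr, tpr = roc$tpr), path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
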