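#' Binary classification metrics from a confusion matrix
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, total accuracy
#' `(TP+TN)/total`, and Matthews correlation coefficient
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FN)(TN+FP))`. When any factor
#' of the MCC denominator is zero, MCC is defined as 0. Disease-associated
#' is the positive class throughout the package.
#'
#' @param tp,tn,fp,fn Confusion-matrix counts.
#' @return An `eval_metrics` object: list with the four counts,
#'   `sensitivity`, `specificity`, `accuracy` (fractions in `[0, 1]`) and
#'   `mcc`.
#' @export
#' @examples
#' m <- sap_metrics(tp = 10, tn = 10, fp = 0, fn = 0)
#' m$mcc  # 1
sap_metrics <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0)) stop("negative confusion counts")
  total <- sum(counts)
  if (total == 0) stop("empty confusion matrix")
  sens <- if (tp + fn > 0) tp / (tp + fn) else 0
  spec <- if (tn + fp > 0) tn / (tn + fp) else 0
  acc <- (tp + tn) / total
  den <- sqrt(as.numeric(tp + fp)) * sqrt(as.numeric(tp + fn)) *
    sqrt(as.numeric(tn + fn)) * sqrt(as.numeric(tn + fp))
  mcc <- if (den == 0) 0 else
    (as.numeric(tp) * tn - as.numeric(fp) * fn) / den
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn,
                 sensitivity = sens, specificity = spec,
                 accuracy = acc, mcc = mcc),
            class = "eval_metrics")
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat(sprintf(
    "sensitivity %.1f%%  specificity %.1f%%  accuracy %.1f%%  MCC %.2f\n",
    100 * x$sensitivity, 100 * x$specificity, 100 * x$accuracy, x$mcc))
  cat(sprintf("  (TP %d  TN %d  FP %d  FN %d)\n", x$tp, x$tn, x$fp, x$fn))
  invisible(x)
}

metrics_from_predictions <- function(truth, predicted,
                                     positive = "disease") {
  tp <- sum(truth == positive & predicted == positive)
  tn <- sum(truth != positive & predicted != positive)
  fp <- sum(truth != positive & predicted == positive)
  fn <- sum(truth == positive & predicted != positive)
  sap_metrics(tp, tn, fp, fn)
}

#' Hyperparameter grid for the random forest
#'
#' Default ranges cover the tree counts and per-split feature counts a
#' grid search over this model family typically explores (100-500 trees,
#' 1-8 candidate features per split).
#'
#' @param ntree_values Tree counts to try.
#' @param mtry_values Candidate-feature counts per split.
#' @param folds Number of cross-validation folds.
#' @param seed RNG seed governing fold assignment and tree growth.
#' @return A `tune_grid` list.
#' @export
tune_grid <- function(ntree_values = c(100, 200, 300, 400, 500),
                      mtry_values = 1:8, folds = 5, seed = 1) {
  stopifnot(length(ntree_values) > 0, length(mtry_values) > 0, folds >= 2)
  structure(list(ntree_values = as.integer(ntree_values),
                 mtry_values = as.integer(mtry_values),
                 folds = as.integer(folds), seed = as.integer(seed)),
            class = "tune_grid")
}

# Stratified fold assignment: each class spread evenly over folds.
stratified_folds <- function(y, folds, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    fold[idx] <- sample(rep(seq_len(folds), length.out = length(idx)))
  }
  fold
}

as_label_factor <- function(labels) {
  f <- factor(as.character(labels), levels = c("polymorphism", "disease"))
  if (anyNA(f)) {
    stop("labels must be 'disease' or 'polymorphism'; got: ",
         paste(unique(setdiff(labels, levels(f))), collapse = ", "))
  }
  f
}

#' Grid-searched stratified cross-validation
#'
#' For every `(ntree, mtry)` grid point, fits a random forest on each
#' training fold and predicts the held-out fold; out-of-fold predictions
#' are pooled over the folds and scored with [sap_metrics()]. The best grid
#' point maximizes pooled MCC (ties: fewer trees, then smaller `mtry`).
#' Fold assignment is stratified by class and fixed by the grid's seed, so
#' the whole procedure is reproducible.
#'
#' @param features Numeric feature matrix or data frame (rows = records).
#' @param labels Class labels, `disease` (positive) / `polymorphism`.
#' @param grid A [tune_grid()].
#' @return A `cv_result` list: `best_ntree`, `best_mtry`, `pooled`
#'   ([sap_metrics()] at the best point), `per_fold` (list of per-fold
#'   metrics at the best point), `grid_results` (data frame of pooled
#'   metrics for every grid point), and `fold` (the fold assignment).
#' @export
cross_validate <- function(features, labels, grid = tune_grid()) {
  x <- as.data.frame(features)
  y <- as_label_factor(labels)
  if (nlevels(droplevels(y)) < 2L) {
    stop("need both classes present to cross-validate")
  }
  stopifnot(nrow(x) == length(y))
  fold <- stratified_folds(y, grid$folds, grid$seed)

  mtry_vals <- unique(pmin(grid$mtry_values, ncol(x)))
  gridpts <- expand.grid(ntree = grid$ntree_values, mtry = mtry_vals)
  results <- vector("list", nrow(gridpts))
  oof_best <- NULL
  for (g in seq_len(nrow(gridpts))) {
    oof <- factor(rep(NA_character_, length(y)), levels = levels(y))
    for (f in seq_len(grid$folds)) {
      tr <- fold != f
      set.seed(grid$seed + 1000L * f + g)
      rf <- randomForest::randomForest(
        x = x[tr, , drop = FALSE], y = y[tr],
        ntree = gridpts$ntree[g], mtry = gridpts$mtry[g])
      oof[!tr] <- predict(rf, x[!tr, , drop = FALSE])
    }
    m <- metrics_from_predictions(y, oof)
    results[[g]] <- data.frame(ntree = gridpts$ntree[g],
                               mtry = gridpts$mtry[g],
                               sensitivity = m$sensitivity,
                               specificity = m$specificity,
                               accuracy = m$accuracy, mcc = m$mcc)
    results[[g]]$oof <- I(list(oof))
  }
  tab <- do.call(rbind, results)
  best <- order(-tab$mcc, tab$ntree, tab$mtry)[1]
  oof_best <- tab$oof[[best]]
  per_fold <- lapply(seq_len(grid$folds), function(f) {
    metrics_from_predictions(y[fold == f], oof_best[fold == f])
  })
  structure(list(best_ntree = tab$ntree[best], best_mtry = tab$mtry[best],
                 pooled = metrics_from_predictions(y, oof_best),
                 per_fold = per_fold,
                 grid_results = tab[, setdiff(names(tab), "oof")],
                 fold = fold),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("cross-validation best (ntree, mtry) = (", x$best_ntree, ", ",
      x$best_mtry, ")\npooled out-of-fold: ", sep = "")
  print(x$pooled)
  invisible(x)
}

#' Train a random-forest SAP classifier
#'
#' @param features Feature matrix/data frame.
#' @param labels `disease` / `polymorphism` labels.
#' @param ntree,mtry Forest hyperparameters (typically the best grid point
#'   from [cross_validate()]).
#' @param seed RNG seed for tree growth.
#' @return A `sap_model` carrying the fitted forest and the training
#'   feature schema.
#' @export
sap_train <- function(features, labels, ntree = 200, mtry = 2, seed = 1) {
  x <- as.data.frame(features)
  y <- as_label_factor(labels)
  set.seed(seed)
  rf <- randomForest::randomForest(x = x, y = y, ntree = ntree,
                                   mtry = min(mtry, ncol(x)))
  structure(list(rf = rf, schema = colnames(x), ntree = ntree,
                 mtry = mtry, seed = seed,
                 version = as.character(utils::packageVersion("psnsap"))),
            class = "sap_model")
}

#' @export
print.sap_model <- function(x, ...) {
  cat("sap_model: random forest, ntree =", x$ntree, ", mtry =", x$mtry,
      ",", length(x$schema), "features\n")
  invisible(x)
}

#' Predict classes and disease scores
#'
#' @param object A `sap_model`.
#' @param newdata Feature data frame; columns are matched to the training
#'   schema by name, and a mismatch is an error naming the missing/extra
#'   features.
#' @param ... Unused.
#' @return Data frame with `class` and `score` (fraction of trees voting
#'   disease); `class` is `disease` when `score > 0.5`.
#' @export
predict.sap_model <- function(object, newdata, ...) {
  x <- as.data.frame(newdata)
  missing <- setdiff(object$schema, colnames(x))
  extra <- setdiff(colnames(x), object$schema)
  if (length(missing) > 0L || length(extra) > 0L) {
    stop("feature schema mismatch; missing: [",
         paste(missing, collapse = ", "), "], extra: [",
         paste(extra, collapse = ", "), "]")
  }
  x <- x[, object$schema, drop = FALSE]
  votes <- predict(object$rf, x, type = "vote", norm.votes = TRUE)
  score <- votes[, "disease"]
  data.frame(class = ifelse(score > 0.5, "disease", "polymorphism"),
             score = as.numeric(score), row.names = NULL)
}

#' Save / load a trained model
#'
#' @param model A `sap_model`.
#' @param path File path.
#' @return `path` (save) or the restored `sap_model` (load).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "sap_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "sap_model")) stop("not a sap_model file: ", path)
  m
}

#' Permutation feature importance, averaged over repetitions
#'
#' Out-of-bag permutation importance (mean decrease in accuracy when one
#' feature's values are permuted) of a random forest, re-estimated `reps`
#' times with fresh seeds and averaged. The repetition smooths the
#' estimate's sampling noise; 100 repetitions is the default protocol.
#'
#' @param features Feature matrix/data frame.
#' @param labels Class labels.
#' @param ntree,mtry Forest hyperparameters.
#' @param reps Number of repetitions.
#' @param seed Base RNG seed; repetition `r` uses `seed + r`.
#' @return Named numeric vector of mean importances, sorted descending.
#' @export
permutation_importance <- function(features, labels, ntree = 200, mtry = 2,
                                   reps = 100, seed = 1) {
  stopifnot(reps >= 1)
  x <- as.data.frame(features)
  y <- as_label_factor(labels)
  acc <- matrix(0, nrow = ncol(x), ncol = reps,
                dimnames = list(colnames(x), NULL))
  for (r in seq_len(reps)) {
    set.seed(seed + r)
    rf <- randomForest::randomForest(x = x, y = y, ntree = ntree,
                                     mtry = min(mtry, ncol(x)),
                                     importance = TRUE)
    acc[, r] <- randomForest::importance(rf, type = 1, scale = FALSE)[, 1]
  }
  imp <- rowMeans(acc)
  sort(imp, decreasing = TRUE)
}

#' Top-k features by importance
#'
#' @param importances Named importance vector (any order); ties keep the
#'   input's (schema) order.
#' @param k How many features.
#' @return Character vector of `k` feature names.
#' @export
select_top_k <- function(importances, k) {
  stopifnot(k >= 0, k <= length(importances))
  if (k == 0L) return(character(0))
  names(importances)[order(-importances)][seq_len(k)]
}
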