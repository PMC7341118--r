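#' Collapse four stages into early/advanced classes
#'
#' Stages I and II form the early (lower-malignancy) class, stages III and
#' IV the advanced class — the binary contrast under which an SVM separates
#' the cohort far better than a four-way model.
#'
#' @param cohort cohort tibble (`sample_id`, `stage`).
#' @return tibble `sample_id`, `class` (factor `early` < `advanced`).
#' @export
make_binary <- function(cohort) {
  check_cohort(cohort)
  tibble(sample_id = cohort$sample_id,
         class = factor(ifelse(as.character(cohort$stage) %in% c("I", "II"),
                               "early", "advanced"),
                        levels = c("early", "advanced")))
}

binary_classes <- c("early", "advanced")

check_classes <- function(classes) {
  if (!all(c("sample_id", "class") %in% names(classes))) {
    abort("expected a tibble with columns `sample_id` and `class`")
  }
  y <- factor(as.character(classes$class), levels = binary_classes)
  if (anyNA(y)) abort("class labels must be 'early' or 'advanced'")
  if (length(unique(y)) < 2L) abort("both classes must be present")
  y
}

# stratified fold assignment; deterministic given the RNG state
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    if (length(idx) < k) abort("a class has fewer samples than folds")
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

features_matrix <- function(scores, classes) {
  sm <- score_values(scores)
  miss <- setdiff(classes$sample_id, colnames(sm))
  if (length(miss)) abort(paste0("samples absent from score matrix: ",
                                 paste(head(miss, 5), collapse = ", ")))
  t(sm[, classes$sample_id, drop = FALSE])
}

fit_svm <- function(X, y, cost, gamma) {
  e1071::svm(x = X, y = y, kernel = "radial", cost = cost, gamma = gamma,
             scale = FALSE)
}

# mean stratified-CV accuracy of an RBF SVM on a feature subset
svm_cv_accuracy <- function(X, y, fold, cost, gamma) {
  k <- max(fold)
  acc <- vapply(seq_len(k), function(f) {
    tr <- fold != f
    fit <- fit_svm(X[tr, , drop = FALSE], y[tr], cost, gamma)
    mean(predict(fit, X[!tr, , drop = FALSE]) == y[!tr])
  }, 0)
  mean(acc)
}

#' Recursive feature elimination for the stage classifier
#'
#' Starting from all pathways, repeatedly removes the `step_k` least
#' important features, where a feature's importance is the drop in
#' stratified cross-validated SVM accuracy when it is left out of the
#' current set. The subset with the best mean CV accuracy over the whole
#' elimination path is returned (ties go to the smaller subset).
#'
#' @param scores pathway-by-sample score tibble.
#' @param classes binary class tibble from [make_binary()].
#' @param step_k features removed per iteration (default 1).
#' @param folds cross-validation folds (default 5, stratified).
#' @param seed RNG seed controlling fold assignment.
#' @param cost,gamma SVM hyperparameters used during elimination; `gamma`
#'   defaults to 1 / (number of features).
#' @return object of class `rfe_result`: list with `selected` (character),
#'   `history` (tibble `n_features`, `accuracy`, `dropped`), `folds`,
#'   `seed`.
#' @export
rfe_select <- function(scores, classes, step_k = 1L, folds = 5L, seed = 1L,
                       cost = 1, gamma = NULL) {
  y <- check_classes(classes)
  X <- features_matrix(scores, classes)
  if (ncol(X) < 2L) abort("need at least 2 features for elimination")
  gamma <- gamma %||% (1 / ncol(X))
  set.seed(seed)
  fold <- stratified_folds(y, folds)

  current <- colnames(X)
  history <- list()
  best <- list(acc = -Inf, set = current)
  repeat {
    acc <- svm_cv_accuracy(X[, current, drop = FALSE], y, fold, cost, gamma)
    history[[length(history) + 1L]] <-
      tibble(n_features = length(current), accuracy = acc,
             dropped = NA_character_)
    better <- acc > best$acc ||
      (acc == best$acc && length(current) < length(best$set))
    if (better) best <- list(acc = acc, set = current)
    if (length(current) <= 1L) break
    acc_without <- vapply(current, function(f) {
      svm_cv_accuracy(X[, setdiff(current, f), drop = FALSE], y, fold,
                      cost, gamma)
    }, 0)
    # least important = whose removal hurts least (highest accuracy without)
    ord <- order(-acc_without, current)
    drop_n <- min(step_k, length(current) - 1L)
    dropped <- current[ord[seq_len(drop_n)]]
    history[[length(history)]]$dropped <- paste(dropped, collapse = ",")
    current <- setdiff(current, dropped)
  }
  structure(list(selected = sort(best$set), history = bind_rows(history),
                 folds = folds, seed = seed),
            class = "rfe_result")
}

#' Last k survivors of the elimination order
#'
#' The elimination order ranks features by importance: the features removed
#' last are the most important. This extracts the `k` survivors — the
#' natural "top-k" feature set even when the best-accuracy subset is larger
#' because accuracy plateaus over uninformative features.
#'
#' @param rfe an `rfe_result`.
#' @param k number of top features to return.
#' @return character vector of feature names (sorted).
#' @export
rfe_top_features <- function(rfe, k) {
  stopifnot(inherits(rfe, "rfe_result"))
  # replay the elimination path from the full starting set (every feature
  # ever dropped, plus the survivors, which always include the best subset)
  current <- unique(c(unlist(strsplit(
    rfe$history$dropped[!is.na(rfe$history$dropped)], ",", fixed = TRUE)),
    rfe$selected))
  for (d in rfe$history$dropped) {
    if (is.na(d) || length(current) <= k) break
    drop <- strsplit(d, ",", fixed = TRUE)[[1]]
    if (length(current) - length(drop) < k) break
    current <- setdiff(current, drop)
  }
  sort(current)
}

#' @export
print.rfe_result <- function(x, ...) {
  cat("<rfe_result> selected", length(x$selected), "features:\n  ",
      paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' @rdname rfe_select
#' @param x an `rfe_result`.
#' @param ... unused.
#' @export
tidy.rfe_result <- function(x, ...) x$history

#' Default RBF hyperparameter grid
#'
#' `C` in \{0.1, 1, 10, 100\} crossed with `gamma` in \{0.01, 0.1, 1/d, 1\}
#' where `d` is the number of features (the usual scale-free default; a
#' literal gamma of zero would make the kernel constant, so the search
#' starts from 1/d instead).
#'
#' @param d number of features.
#' @return tibble `cost`, `gamma`.
#' @export
default_grid <- function(d) {
  tidyr::expand_grid(cost = c(0.1, 1, 10, 100),
                     gamma = sort(unique(c(0.01, 0.1, 1 / d, 1))))
}

grid_search <- function(X, y, grid, fold) {
  acc <- pmap(grid, function(cost, gamma) {
    svm_cv_accuracy(X, y, fold, cost, gamma)
  })
  grid$accuracy <- unlist(acc)
  grid[order(-grid$accuracy, grid$cost, grid$gamma), ][1L, ]
}

advanced_score <- function(fit, X) {
  dv <- attr(predict(fit, X, decision.values = TRUE), "decision.values")
  first <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]][1]
  if (identical(first, "advanced")) dv[, 1L] else -dv[, 1L]
}

#' Train and evaluate the early-vs-advanced SVM
#'
#' Radial-kernel SVM on the pathway imbalance scores, evaluated by
#' stratified fivefold cross-validation: within each training fold the
#' hyperparameters are grid-searched by inner cross-validated accuracy
#' (and, when `rfe_step` is given, recursive feature elimination is re-run
#' on the training fold alone, so feature selection cannot leak test
#' information); the held-out fold supplies decision scores for the ROC.
#' Samples are shuffled by `seed` before folding.
#'
#' For comparison with a training-set-only protocol the report also carries
#' the resubstitution accuracy of a default-parameter model on all features
#' (`initial_accuracy`).
#'
#' @param scores pathway-by-sample score tibble.
#' @param classes binary class tibble from [make_binary()].
#' @param features character vector of pathways to use (default: all rows
#'   of `scores`). Ignored within folds when `rfe_step` is given.
#' @param grid hyperparameter grid (tibble `cost`, `gamma`); defaults to
#'   [default_grid()].
#' @param folds outer (and inner) cross-validation folds.
#' @param seed RNG seed.
#' @param rfe_step if non-`NULL`, re-run [rfe_select()] with this step
#'   inside every training fold (nested, leak-free protocol).
#' @return object of class `stage_svm_report`.
#' @export
train_and_evaluate <- function(scores, classes, features = NULL, grid = NULL,
                               folds = 5L, seed = 1L, rfe_step = NULL) {
  y_all <- check_classes(classes)
  features <- features %||% scores$pathway
  if (!length(features)) abort("features must be non-empty")
  if (!all(features %in% scores$pathway)) abort("unknown feature pathway")
  X_all <- features_matrix(scores, classes)

  set.seed(seed)
  perm <- sample(nrow(X_all))
  X_all <- X_all[perm, , drop = FALSE]
  y <- y_all[perm]
  ids <- classes$sample_id[perm]
  fold <- stratified_folds(y, folds)

  # resubstitution accuracy of the untuned model on all features
  d0 <- ncol(X_all)
  init_fit <- fit_svm(X_all, y, cost = 1, gamma = 1 / d0)
  initial_accuracy <- mean(predict(init_fit, X_all) == y)

  fold_rows <- list()
  roc_points <- list()
  best_params <- list()
  for (f in seq_len(folds)) {
    tr <- fold != f
    feats <- features
    if (!is.null(rfe_step)) {
      sub_classes <- tibble(sample_id = ids[tr], class = y[tr])
      feats <- rfe_select(scores, sub_classes, step_k = rfe_step,
                          folds = folds, seed = seed + f)$selected
    }
    Xtr <- X_all[tr, feats, drop = FALSE]
    Xte <- X_all[!tr, feats, drop = FALSE]
    grid_f <- grid %||% default_grid(ncol(Xtr))
    set.seed(seed + 1000L + f)
    inner_fold <- stratified_folds(y[tr], folds)
    best <- grid_search(Xtr, y[tr], grid_f, inner_fold)
    fit <- fit_svm(Xtr, y[tr], best$cost, best$gamma)

    pred <- predict(fit, Xte)
    sc <- advanced_score(fit, Xte)
    truth <- y[!tr]
    acc <- mean(pred == truth)
    tp <- sum(pred == "advanced" & truth == "advanced")
    fp <- sum(pred == "advanced" & truth == "early")
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    roc <- pROC::roc(response = truth, predictor = sc,
                     levels = binary_classes, direction = "<", quiet = TRUE)
    fold_rows[[f]] <- tibble(fold = f, cost = best$cost, gamma = best$gamma,
                             n_features = length(feats),
                             accuracy = acc, precision = prec,
                             auc = as.numeric(pROC::auc(roc)))
    roc_points[[f]] <- tibble(fold = f,
                              fpr = rev(1 - roc$specificities),
                              tpr = rev(roc$sensitivities))
    best_params[[f]] <- feats
  }
  fold_tbl <- bind_rows(fold_rows)

  structure(list(
    selected_features = sort(unique(unlist(best_params))),
    folds = fold_tbl,
    roc_points = bind_rows(roc_points),
    mean_accuracy = mean(fold_tbl$accuracy),
    mean_precision = mean(fold_tbl$precision, na.rm = TRUE),
    mean_auc = mean(fold_tbl$auc),
    initial_accuracy = initial_accuracy,
    grid = grid %||% default_grid(length(features)),
    n_folds = folds, seed = seed
  ), class = "stage_svm_report")
}

#' @export
print.stage_svm_report <- function(x, ...) {
  cat("<stage_svm_report> ", x$n_folds, "-fold stratified CV\n", sep = "")
  cat(sprintf("  mean accuracy:  %.3f\n", x$mean_accuracy))
  cat(sprintf("  mean precision: %.3f\n", x$mean_precision))
  cat(sprintf("  mean AUC:       %.3f\n", x$mean_auc))
  cat(sprintf("  initial (resubstitution) accuracy: %.3f\n",
              x$initial_accuracy))
  invisible(x)
}

#' @rdname train_and_evaluate
#' @param x a `stage_svm_report`.
#' @param ... unused.
#' @export
tidy.stage_svm_report <- function(x, ...) x$folds

#' @rdname train_and_evaluate
#' @export
glance.stage_svm_report <- function(x, ...) {
  tibble(mean_accuracy = x$mean_accuracy,
         mean_precision = x$mean_precision,
         mean_auc = x$mean_auc,
         initial_accuracy = x$initial_accuracy,
         n_folds = x$n_folds,
         n_features = length(x$selected_features))
}
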