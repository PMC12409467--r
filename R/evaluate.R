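#' Evaluate a classifier on labelled data
#'
#' Accuracy, precision, recall and F1 in percent, with the confusion
#' matrix. For a single partition the SD columns are `NA`; [cv_evaluate()]
#' and [holdout_evaluate()] report mean and SD across folds or fold
#' models.
#'
#' @param model A [train_svm()] model.
#' @param table Labelled feature table (normalized with the model's
#'   training statistics) or feature matrix.
#' @param y Labels when `table` is a matrix.
#' @return List of class `evaluation_report`: `metrics` (data frame with
#'   `metric`, `mean_pct`, `sd_pct`), `confusion` (matrix), `n`.
#' @export
evaluate <- function(model, table, y = NULL) {
  xy <- as_xy_eval(table, y)
  if (!all(unique(xy$y) %in% c(model$positive_class, model$negative_class)))
    stop_("labels %s do not match the model's classes",
          paste(setdiff(unique(xy$y),
                        c(model$positive_class, model$negative_class)),
                collapse = ", "))
  pred <- predict(model, xy$x)
  metrics <- vapply(c("accuracy", "precision", "recall", "f1"),
                    function(m) classification_metric(xy$y, pred, m,
                                                      model$positive_class),
                    numeric(1))
  lv <- c(model$negative_class, model$positive_class)
  confusion <- table(factor(xy$y, lv), factor(pred, lv),
                     dnn = c("truth", "predicted"))
  structure(
    list(metrics = data.frame(metric = names(metrics),
                              mean_pct = 100 * unname(metrics),
                              sd_pct = NA_real_),
         confusion = unclass(confusion), n = length(xy$y)),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Evaluation on n = %d\n", x$n))
  for (i in seq_len(nrow(x$metrics))) {
    if (is.na(x$metrics$sd_pct[i])) {
      cat(sprintf("  %-9s %6.1f %%\n", x$metrics$metric[i],
                  x$metrics$mean_pct[i]))
    } else {
      cat(sprintf("  %-9s %6.1f +/- %.1f %%\n", x$metrics$metric[i],
                  x$metrics$mean_pct[i], x$metrics$sd_pct[i]))
    }
  }
  invisible(x)
}

#' Cross-validated evaluation of one configuration
#'
#' Stratified k-fold cross-validation: a model is trained on each fold
#' complement and evaluated on the fold; metrics are reported as mean and
#' sample SD across folds, in percent.
#'
#' @param table Labelled, normalized feature table (or matrix plus `y`).
#' @param y Labels when `table` is a matrix.
#' @param config An [svm_config()].
#' @param k Folds (default 5).
#' @param seed Fold-assignment seed.
#' @return An `evaluation_report` with per-fold SDs and the pooled
#'   confusion matrix; `folds` holds the per-fold metric table.
#' @export
cv_evaluate <- function(table, y = NULL, config = svm_config(), k = 5L,
                        seed = 42L) {
  xy <- as_xy_eval(table, y)
  fold <- cv_folds(xy$y, k, seed)
  mts <- c("accuracy", "precision", "recall", "f1")
  per_fold <- matrix(NA_real_, k, length(mts),
                     dimnames = list(NULL, mts))
  confusion <- NULL
  for (f in seq_len(k)) {
    tr <- fold != f
    m <- train_svm(xy$x[tr, , drop = FALSE], xy$y[tr], config)
    pred <- predict(m, xy$x[!tr, , drop = FALSE])
    for (mt in mts)
      per_fold[f, mt] <- classification_metric(xy$y[!tr], pred, mt,
                                               m$positive_class)
    lv <- c(m$negative_class, m$positive_class)
    cm <- table(factor(xy$y[!tr], lv), factor(pred, lv),
                dnn = c("truth", "predicted"))
    confusion <- if (is.null(confusion)) unclass(cm)
                 else confusion + unclass(cm)
  }
  structure(
    list(metrics = data.frame(
           metric = mts,
           mean_pct = 100 * colMeans(per_fold),
           sd_pct = 100 * apply(per_fold, 2L, stats::sd)),
         confusion = confusion, n = length(xy$y),
         folds = as.data.frame(per_fold)),
    class = "evaluation_report"
  )
}

#' Hold-out evaluation with fold-model variability
#'
#' Trains one model per cross-validation fold of the training set (each on
#' its fold complement) and applies every fold model to the same hold-out
#' test set. The metric spread across fold models expresses how much the
#' hold-out performance depends on the exact training subset, which is the
#' package's reading of a mean-and-SD report on a single test partition.
#'
#' @param train,test Labelled, normalized feature tables (or matrices via
#'   `y_train`, `y_test`).
#' @param config An [svm_config()].
#' @param k Folds (default 5).
#' @param seed Fold-assignment seed.
#' @param y_train,y_test Labels for matrix input.
#' @return An `evaluation_report`; `folds` holds the per-fold-model
#'   metrics on the test set.
#' @export
holdout_evaluate <- function(train, test, config = svm_config(), k = 5L,
                             seed = 42L, y_train = NULL, y_test = NULL) {
  tr <- as_xy_eval(train, y_train)
  te <- as_xy_eval(test, y_test)
  fold <- cv_folds(tr$y, k, seed)
  mts <- c("accuracy", "precision", "recall", "f1")
  per_fold <- matrix(NA_real_, k, length(mts),
                     dimnames = list(NULL, mts))
  confusion <- NULL
  for (f in seq_len(k)) {
    keep <- fold != f
    m <- train_svm(tr$x[keep, , drop = FALSE], tr$y[keep], config)
    pred <- predict(m, te$x)
    for (mt in mts)
      per_fold[f, mt] <- classification_metric(te$y, pred, mt,
                                               m$positive_class)
    lv <- c(m$negative_class, m$positive_class)
    cm <- table(factor(te$y, lv), factor(pred, lv),
                dnn = c("truth", "predicted"))
    confusion <- if (is.null(confusion)) unclass(cm)
                 else confusion + unclass(cm)
  }
  structure(
    list(metrics = data.frame(
           metric = mts,
           mean_pct = 100 * colMeans(per_fold),
           sd_pct = 100 * apply(per_fold, 2L, stats::sd)),
         confusion = confusion / k, n = length(te$y),
         folds = as.data.frame(per_fold)),
    class = "evaluation_report"
  )
}

#' Maturity scores: signed distances from the SVM hyperplane
#'
#' The signed decision value of each sample, positive on the mature side,
#' used as a continuous maturity readout, together with a Gaussian kernel
#' density estimate of the score distribution (optionally per group).
#'
#' @param model A [train_svm()] model.
#' @param table Feature table or matrix, normalized with the model's
#'   training statistics.
#' @param groups Optional grouping labels (e.g. class or culture medium)
#'   for per-group densities.
#' @return List of class `maturity_score`: `score` (signed decision
#'   values, in margin units), `distance` (score divided by the kernel-space
#'   weight norm, the geometric distance to the hyperplane), `w_norm`,
#'   `predicted` class labels, `groups`, `density` (list of per-group
#'   `stats::density` results, plus `all`), `bandwidth`.
#' @export
maturity_score <- function(model, table, groups = NULL) {
  xy <- if (is.data.frame(table) && "class" %in% names(table)) {
    list(x = table, y = table$class)
  } else list(x = table, y = NULL)
  score <- decision_function(model, xy$x)
  # geometric distance = decision value / ||w||, with
  # ||w||^2 = a' K a in the kernel feature space
  Ksv <- kernel_matrix(model$support_vectors, model$support_vectors,
                       model$config$kernel, model$gamma,
                       model$config$degree, model$config$coef0)
  w_norm <- sqrt(max(as.numeric(
    t(model$dual_coefs) %*% Ksv %*% model$dual_coefs), 1e-12))
  if (is.null(groups) && !is.null(xy$y)) groups <- as.character(xy$y)
  dens_all <- stats::density(score)
  dens <- list(all = dens_all)
  if (!is.null(groups)) {
    for (g in unique(groups)) {
      sg <- score[groups == g]
      # per-group curves share the pooled bandwidth for comparability
      if (length(sg) >= 2L)
        dens[[g]] <- stats::density(sg, bw = dens_all$bw)
    }
  }
  structure(
    list(score = score, distance = score / w_norm, w_norm = w_norm,
         predicted = ifelse(score >= 0, model$positive_class,
                            model$negative_class),
         groups = groups, density = dens, bandwidth = dens_all$bw),
    class = "maturity_score"
  )
}

#' @export
print.maturity_score <- function(x, ...) {
  cat(sprintf("Maturity scores for %d samples (bandwidth %.3g)\n",
              length(x$score), x$bandwidth))
  if (!is.null(x$groups)) {
    for (g in unique(x$groups))
      cat(sprintf("  %-12s median %6.3f\n", g,
                  stats::median(x$score[x$groups == g])))
  }
  invisible(x)
}

as_xy_eval <- function(table, y) {
  if (is.data.frame(table)) {
    if (!"class" %in% names(table))
      stop_("feature table must have a 'class' column")
    list(x = as.matrix(table[FEATURE_NAMES]), y = as.character(table$class))
  } else {
    if (is.null(y)) stop_("labels are required for matrix input")
    list(x = table, y = as.character(y))
  }
}
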