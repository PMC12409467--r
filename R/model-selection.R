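#' Balance a feature table across classes and cell lines
#'
#' Downsamples every class to the minority-class count, choosing rows so
#' that the cell lines within each class are represented as evenly as the
#' available counts allow (lines with few recordings keep all of them; the
#' remaining quota is spread over the better-represented lines). Selection
#' within a line is a seeded simple random draw.
#'
#' @param table Feature table with `class` and `cell_line` columns.
#' @param seed Integer seed.
#' @return The balanced table (row order: as in the input).
#' @export
balance_dataset <- function(table, seed = 42L) {
  if (!all(c("class", "cell_line") %in% names(table)))
    stop_("table must have 'class' and 'cell_line' columns")
  counts <- table(table$class)
  if (length(counts) < 2L) stop_("balancing needs at least 2 classes")
  if (any(counts == 0L)) stop_("a class has zero rows")
  n_target <- min(counts)
  withr::with_seed(seed, {
    keep <- integer()
    for (cl in names(counts)) {
      idx <- which(table$class == cl)
      if (length(idx) == n_target) { keep <- c(keep, idx); next }
      by_line <- split(idx, table$cell_line[idx])
      # even allocation: serve lines in order of availability, giving each
      # at most an equal share of what remains
      avail <- vapply(by_line, length, integer(1))
      quota <- integer(length(by_line)); names(quota) <- names(by_line)
      remaining <- n_target
      n_left <- length(by_line)
      for (j in order(avail)) {
        share <- ceiling(remaining / n_left)
        take <- min(avail[j], share, remaining)
        quota[j] <- take
        remaining <- remaining - take
        n_left <- n_left - 1L
      }
      for (j in seq_along(by_line)) {
        pool <- by_line[[j]]
        keep <- c(keep,
                  if (quota[j] >= length(pool)) pool
                  else sort(sample(pool, quota[j])))
      }
    }
    out <- table[sort(keep), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Split specification for the hold-out design
#'
#' @param train_fraction Fraction of rows in the training/validation
#'   partition (default 0.8).
#' @param k_folds Cross-validation folds (default 5).
#' @param seed Integer seed (default 42).
#' @return An object of class `split_spec`.
#' @export
split_spec <- function(train_fraction = 0.8, k_folds = 5L, seed = 42L) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop_("train_fraction must be in (0, 1)")
  if (k_folds < 2L) stop_("k_folds must be >= 2")
  structure(list(train_fraction = train_fraction,
                 k_folds = as.integer(k_folds), seed = as.integer(seed)),
            class = "split_spec")
}

#' Stratified train/test split
#'
#' Pseudo-random, seeded and stratified by class; within each class the
#' test rows are spread across cell lines as evenly as possible. For a
#' balanced input the per-class training counts are equal.
#'
#' @param table Feature table with `class` (and optionally `cell_line`).
#' @param spec A [split_spec()].
#' @return List with `train` and `test` data frames (disjoint, exhaustive).
#' @export
stratified_split <- function(table, spec = split_spec()) {
  stopifnot(inherits(spec, "split_spec"))
  if (!"class" %in% names(table)) stop_("table must have a 'class' column")
  classes <- unique(table$class)
  if (any(table(table$class) < 2L))
    stop_("every class stratum needs at least 2 rows to populate both partitions")
  withr::with_seed(spec$seed, {
    test_idx <- integer()
    for (cl in classes) {
      idx <- which(table$class == cl)
      n_test <- length(idx) - round(spec$train_fraction * length(idx))
      if (n_test < 1L)
        stop_("class '%s' is too small for the requested split", cl)
      if ("cell_line" %in% names(table)) {
        by_line <- split(idx, table$cell_line[idx])
        # allocate test picks per line by largest remainder
        share <- n_test * vapply(by_line, length, integer(1)) / length(idx)
        base <- floor(share)
        rem <- n_test - sum(base)
        extra <- order(share - base, decreasing = TRUE)[seq_len(rem)]
        base[extra] <- base[extra] + 1L
        for (j in seq_along(by_line)) {
          pool <- by_line[[j]]
          take <- min(base[j], length(pool))
          if (take > 0L) test_idx <- c(test_idx, sample(pool, take))
        }
      } else {
        test_idx <- c(test_idx, sample(idx, n_test))
      }
    }
    test_idx <- sort(test_idx)
    list(train = table[-test_idx, , drop = FALSE],
         test = table[test_idx, , drop = FALSE])
  })
}

#' Stratified cross-validation fold assignment
#'
#' @param y Class labels.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1:k`, class-stratified.
#' @export
cv_folds <- function(y, k = 5L, seed = 42L) {
  if (min(table(y)) < k)
    stop_("smallest class (%d rows) cannot populate %d folds",
          min(table(y)), k)
  withr::with_seed(seed, {
    fold <- integer(length(y))
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

# Mean CV metric of one configuration over precomputed folds.
cv_metric <- function(x, y, config, fold, metric) {
  k <- max(fold)
  vals <- numeric(k)
  for (f in seq_len(k)) {
    tr <- fold != f
    m <- train_svm(x[tr, , drop = FALSE], y[tr], config, tolerance = 1e-3)
    pred <- predict(m, x[!tr, , drop = FALSE])
    vals[f] <- classification_metric(y[!tr], pred, metric,
                                     positive = m$positive_class)
  }
  vals
}

classification_metric <- function(truth, pred, metric, positive) {
  tp <- sum(pred == positive & truth == positive)
  fp <- sum(pred == positive & truth != positive)
  fn <- sum(pred != positive & truth == positive)
  switch(metric,
    accuracy = mean(pred == truth),
    precision = if (tp + fp == 0) 0 else tp / (tp + fp),
    recall = if (tp + fn == 0) 0 else tp / (tp + fn),
    f1 = {
      pr <- if (tp + fp == 0) 0 else tp / (tp + fp)
      rc <- if (tp + fn == 0) 0 else tp / (tp + fn)
      if (pr + rc == 0) 0 else 2 * pr * rc / (pr + rc)
    },
    stop_("unknown metric '%s'", metric)
  )
}

#' Random hyperparameter search
#'
#' Samples `n_iter` configurations — `C` log-uniform on `[0.1, 3]`, kernel
#' uniform over rbf/polynomial/sigmoid, `gamma` uniform over auto/scale,
#' `degree` uniform over 2:4, `coef0` uniform on `[0, 1]` — and scores each
#' by stratified k-fold cross-validation, maximizing `metric` (precision by
#' default).
#'
#' @param table Normalized feature table with `class` labels (or a matrix
#'   plus `y`).
#' @param y Labels when `table` is a matrix.
#' @param n_iter Number of sampled configurations (default 200).
#' @param metric `"precision"` (default), `"accuracy"`, `"recall"`, `"f1"`.
#' @param k Folds (default 5).
#' @param seed Integer seed.
#' @return List of class `search_result`: `best_config`, `best_score`, and
#'   the full `trials` data frame (one row per configuration, with its mean
#'   and SD CV metric).
#' @export
random_search <- function(table, y = NULL, n_iter = 200L,
                          metric = "precision", k = 5L, seed = 42L) {
  if (n_iter < 1L) stop_("n_iter must be >= 1")
  xy <- as_xy(table, y)
  fold <- cv_folds(xy$y, k, seed)
  draws <- withr::with_seed(seed, data.frame(
    C = exp(stats::runif(n_iter, log(0.1), log(3))),
    kernel = sample(c("rbf", "polynomial", "sigmoid"), n_iter, replace = TRUE),
    gamma = sample(c("auto", "scale"), n_iter, replace = TRUE),
    degree = sample(2:4, n_iter, replace = TRUE),
    coef0 = stats::runif(n_iter),
    stringsAsFactors = FALSE
  ))
  run_search(xy$x, xy$y, draws, fold, metric)
}

#' Exhaustive grid search with stratified cross-validation
#'
#' Evaluates the full Cartesian grid by stratified k-fold CV and returns
#' the configuration with the best mean metric; ties go to the first
#' configuration in enumeration order. The default grid is the package's
#' reference design: `C` in 0.1..1 by 0.1, kernel rbf/polynomial, gamma
#' auto/scale, degree 2..3, coef0 0..1 by 0.05 (1680 configurations).
#'
#' @param table Normalized feature table with `class` labels (or a matrix
#'   plus `y`).
#' @param y Labels when `table` is a matrix.
#' @param grid Data frame of configurations (columns `C`, `kernel`,
#'   `gamma`, `degree`, `coef0`); defaults to [default_grid()].
#' @param metric Metric maximized (default `"accuracy"`).
#' @param k Folds (default 5).
#' @param seed Integer seed for the fold assignment.
#' @return A `search_result` list (see [random_search()]).
#' @export
grid_search <- function(table, y = NULL, grid = default_grid(),
                        metric = "accuracy", k = 5L, seed = 42L) {
  if (!nrow(grid)) stop_("empty grid")
  xy <- as_xy(table, y)
  if (min(table(xy$y)) < k)
    stop_("folds cannot be built: smallest class < k")
  fold <- cv_folds(xy$y, k, seed)
  run_search(xy$x, xy$y, grid, fold, metric)
}

#' @rdname grid_search
#' @export
default_grid <- function() {
  expand.grid(
    coef0 = seq(0, 1, by = 0.05),
    degree = 2:3,
    gamma = c("auto", "scale"),
    kernel = c("rbf", "polynomial"),
    C = seq(0.1, 1, by = 0.1),
    stringsAsFactors = FALSE
  )[, c("C", "kernel", "gamma", "degree", "coef0")]
}

# Shared engine of random and grid search. Configurations whose inert
# parameters differ (e.g. degree for an rbf kernel) are computed once and
# the cached result reused; every row is still reported in the trial log.
run_search <- function(x, y, configs, fold, metric) {
  key <- vapply(seq_len(nrow(configs)), function(i) {
    cf <- configs[i, ]
    switch(cf$kernel,
      rbf = paste("rbf", cf$C, cf$gamma),
      polynomial = paste("poly", cf$C, cf$gamma, cf$degree, cf$coef0),
      sigmoid = paste("sig", cf$C, cf$gamma, cf$coef0))
  }, character(1))
  cache <- new.env(parent = emptyenv())
  means <- numeric(nrow(configs)); sds <- numeric(nrow(configs))
  for (i in seq_len(nrow(configs))) {
    ki <- key[i]
    if (is.null(cache[[ki]])) {
      cf <- configs[i, ]
      cfg <- svm_config(C = cf$C, kernel = cf$kernel, gamma = cf$gamma,
                        degree = cf$degree, coef0 = cf$coef0)
      cache[[ki]] <- cv_metric(x, y, cfg, fold, metric)
    }
    vals <- cache[[ki]]
    means[i] <- mean(vals); sds[i] <- stats::sd(vals)
  }
  best <- which.max(means)              # first-in-order tie break
  trials <- cbind(configs,
                  data.frame(cv_mean = means, cv_sd = sds))
  bc <- configs[best, ]
  structure(
    list(best_config = svm_config(C = bc$C, kernel = bc$kernel,
                                  gamma = bc$gamma, degree = bc$degree,
                                  coef0 = bc$coef0),
         best_score = means[best], best_index = best,
         metric = metric, trials = trials),
    class = "search_result"
  )
}

#' @export
print.search_result <- function(x, ...) {
  cat(sprintf("Hyperparameter search: %d configurations, best %s = %.4f\n",
              nrow(x$trials), x$metric, x$best_score))
  print(x$best_config)
  invisible(x)
}

as_xy <- function(table, y) {
  if (is.data.frame(table)) {
    if (!"class" %in% names(table))
      stop_("feature table must have a 'class' column")
    list(x = as.matrix(table[FEATURE_NAMES]), y = as.character(table$class))
  } else {
    if (is.null(y)) stop_("y is required when table is a matrix")
    list(x = table, y = as.character(y))
  }
}
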