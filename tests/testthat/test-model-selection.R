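test_that("balancing downsamples to the minority class with even cell lines", {
  # 130 immature + 115 mature -> 115 per class, 230 total
  tab <- rbind(
    within(test_table(65, seed = 1), class <- "immature"),
    within(test_table(65, seed = 2)[1:115, ], class <- "mature"))
  tab$recording_id <- sprintf("r%03d", seq_len(nrow(tab)))
  bal <- balance_dataset(tab, seed = 42)
  expect_identical(nrow(bal), 230L)
  expect_true(all(table(bal$class) == 115L))
})

test_that("the toy line-balancing example resolves to two per line", {
  tab <- data.frame(
    recording_id = paste0("r", 1:12),
    class = c(rep("immature", 8), rep("mature", 4)),
    cell_line = c(rep("A", 6), rep("B", 2), "A", "A", "B", "B"),
    max_c = 1:12
  )
  bal <- balance_dataset(tab, seed = 1)
  expect_identical(nrow(bal), 8L)
  counts <- table(bal$class, bal$cell_line)
  expect_identical(as.integer(counts["immature", c("A", "B")]), c(2L, 2L))
})

test_that("already balanced input keeps its row count and is seed-stable", {
  tab <- test_table(20, seed = 5)
  expect_identical(nrow(balance_dataset(tab, 7)), nrow(tab))
  b1 <- balance_dataset(rbind(tab, test_table(10, seed = 6)), 11)
  b2 <- balance_dataset(rbind(tab, test_table(10, seed = 6)), 11)
  expect_identical(b1, b2)
})

test_that("the 80-20 stratified split reproduces the reference partition sizes", {
  tab <- rbind(
    within(test_table(58, seed = 1)[1:115, ], class <- "immature"),
    within(test_table(58, seed = 2)[1:115, ], class <- "mature"))
  tab$recording_id <- sprintf("r%03d", seq_len(nrow(tab)))
  sp <- stratified_split(tab, split_spec(0.8, seed = 42))
  expect_identical(nrow(sp$train), 184L)
  expect_identical(nrow(sp$test), 46L)
  expect_true(all(table(sp$train$class) == 92L))
  expect_true(all(table(sp$test$class) == 23L))
  # deterministic membership and per-class balance within one row
  sp2 <- stratified_split(tab, split_spec(0.8, seed = 42))
  expect_identical(sp$train$recording_id, sp2$train$recording_id)
  expect_lte(diff(range(table(sp$train$class))), 1L)
  # disjoint and exhaustive
  expect_identical(sort(c(sp$train$recording_id, sp$test$recording_id)),
                   sort(tab$recording_id))
})

test_that("cross-validation folds are stratified and deterministic", {
  y <- rep(c("immature", "mature"), each = 25)
  f1 <- cv_folds(y, 5, 42)
  f2 <- cv_folds(y, 5, 42)
  expect_identical(f1, f2)
  for (k in 1:5)
    expect_identical(as.integer(table(y[f1 == k])), c(5L, 5L))
  expect_error(cv_folds(rep(c("a", "b"), c(3, 40)), 5), "cannot populate")
})

test_that("the reference grid enumerates 1680 configurations", {
  g <- default_grid()
  expect_identical(nrow(g), 1680L)
  expect_identical(nrow(unique(g)), 1680L)
  expect_setequal(unique(g$C), seq(0.1, 1, by = 0.1))
  expect_setequal(unique(g$coef0), seq(0, 1, by = 0.05))
})

test_that("a one-point grid returns that configuration with its CV metrics", {
  xy <- test_xy(15, seed = 2)
  g1 <- data.frame(C = 0.5, kernel = "rbf", gamma = "scale", degree = 3,
                   coef0 = 0, stringsAsFactors = FALSE)
  res <- grid_search(xy$x, xy$y, grid = g1, seed = 3)
  expect_identical(nrow(res$trials), 1L)
  expect_equal(res$best_config$C, 0.5)
  expect_true(is.finite(res$best_score))
})

test_that("the grid winner equals an independent re-evaluation on the same folds", {
  xy <- test_xy(15, shift = 0.8, seed = 6)
  grid <- expand.grid(C = c(0.2, 1), kernel = c("rbf", "polynomial"),
                      gamma = "scale", degree = 2, coef0 = c(0, 0.5),
                      stringsAsFactors = FALSE)
  res <- grid_search(xy$x, xy$y, grid = grid, seed = 11)
  fold <- cv_folds(xy$y, 5, 11)
  ref <- vapply(seq_len(nrow(grid)), function(i) {
    cfg <- svm_config(C = grid$C[i], kernel = grid$kernel[i],
                      gamma = grid$gamma[i], degree = grid$degree[i],
                      coef0 = grid$coef0[i])
    accs <- vapply(1:5, function(f) {
      m <- train_svm(xy$x[fold != f, ], xy$y[fold != f], cfg)
      mean(predict(m, xy$x[fold == f, ]) == xy$y[fold == f])
    }, numeric(1))
    mean(accs)
  }, numeric(1))
  expect_equal(res$trials$cv_mean, ref, tolerance = 1e-12)
  expect_identical(res$best_index, which.max(ref))
})

test_that("random search is seed-stable, logs every trial, and returns the argmax", {
  xy <- test_xy(15, shift = 0.8, seed = 8)
  r1 <- random_search(xy$x, xy$y, n_iter = 12, seed = 5)
  r2 <- random_search(xy$x, xy$y, n_iter = 12, seed = 5)
  expect_identical(r1$trials, r2$trials)
  expect_identical(nrow(r1$trials), 12L)
  expect_gte(r1$best_score, max(r1$trials$cv_mean) - 1e-12)
  expect_true(all(r1$trials$C >= 0.1 & r1$trials$C <= 3))
  expect_true(all(r1$trials$coef0 >= 0 & r1$trials$coef0 <= 1))
  r3 <- random_search(xy$x, xy$y, n_iter = 1, seed = 5)
  expect_identical(nrow(r3$trials), 1L)
  expect_equal(r3$best_config$C, r3$trials$C[1])
})
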