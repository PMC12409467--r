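test_that("a perfect classifier scores 100 on every metric", {
  xy <- test_xy(20, shift = 3, seed = 1)
  m <- train_svm(xy$x, xy$y, svm_config(C = 1))
  ev <- evaluate(m, xy$x, xy$y)
  expect_equal(ev$metrics$mean_pct, rep(100, 4))
  expect_identical(sum(ev$confusion), length(xy$y))
})

test_that("metrics follow the textbook confusion-matrix definitions", {
  # TP=2, FP=0, FN=1, TN=2
  truth <- c("mature", "mature", "mature", "immature", "immature")
  pred <- c("mature", "mature", "immature", "immature", "immature")
  cm <- function(mt) 100 * cmmaturity:::classification_metric(
    truth, pred, mt, positive = "mature")
  expect_equal(cm("precision"), 100)
  expect_equal(cm("recall"), 200 / 3, tolerance = 1e-10)
  expect_equal(cm("f1"), 80)
  expect_equal(cm("accuracy"), 80)
})

test_that("fold aggregation uses the sample standard deviation", {
  accs <- c(1, 0.98, 1, 0.98, 1)
  expect_equal(100 * mean(accs), 99.2)
  expect_equal(100 * stats::sd(accs), 1.095445, tolerance = 1e-6)
  # cv_evaluate reports exactly these conventions
  xy <- test_xy(25, shift = 1.2, seed = 3)
  ev <- cv_evaluate(xy$x, xy$y, svm_config(C = 1), k = 5, seed = 2)
  acc <- ev$folds$accuracy
  expect_equal(ev$metrics$mean_pct[1], 100 * mean(acc))
  expect_equal(ev$metrics$sd_pct[1], 100 * stats::sd(acc))
  expect_identical(sum(ev$confusion), length(xy$y))
})

test_that("hold-out evaluation reports fold-model variability on one test set", {
  xy <- test_xy(30, shift = 1.2, seed = 4)
  tr_idx <- c(1:24, 31:54)
  ev <- holdout_evaluate(xy$x[tr_idx, ], xy$x[-tr_idx, ],
                         svm_config(C = 1), k = 5, seed = 9,
                         y_train = xy$y[tr_idx], y_test = xy$y[-tr_idx])
  expect_identical(nrow(ev$folds), 5L)
  expect_true(all(ev$metrics$mean_pct >= 0 & ev$metrics$mean_pct <= 100))
  expect_true(all(is.finite(ev$metrics$sd_pct)))
})

test_that("label mismatches are rejected", {
  xy <- test_xy(10)
  m <- train_svm(xy$x, xy$y)
  expect_error(evaluate(m, xy$x, rep(c("x", "y"), 10)), "do not match")
})

test_that("maturity scores are signed decision values with a geometric distance", {
  xy <- test_xy(20, shift = 2, seed = 5)
  cfg <- svm_config(C = 10, kernel = "polynomial", gamma = 1, degree = 1,
                    coef0 = 0)                      # linear-equivalent
  m <- train_svm(xy$x, xy$y, cfg)
  ms <- maturity_score(m, xy$x, groups = xy$y)
  # sign(score) is the predicted class for every sample
  expect_identical(ms$predicted,
                   ifelse(ms$score >= 0, "mature", "immature"))
  # closed form for the linear kernel: f(x) = w.x - rho, distance f/||w||
  w <- colSums(m$dual_coefs * m$support_vectors)
  f_lin <- as.vector(xy$x %*% w) - m$rho
  expect_equal(ms$score, f_lin, tolerance = 1e-8)
  expect_equal(ms$distance, f_lin / sqrt(sum(w^2)), tolerance = 1e-8)
  # a point on the hyperplane scores zero
  x0 <- xy$x[1, , drop = FALSE]
  x0 <- x0 - (sum(w * x0[1, ]) - m$rho) / sum(w^2) * matrix(w, 1)
  expect_equal(decision_function(m, x0), 0, tolerance = 1e-8)
  # density export carries the bandwidth and per-group curves
  expect_true(all(c("all", "immature", "mature") %in% names(ms$density)))
  expect_true(is.finite(ms$bandwidth))
})
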