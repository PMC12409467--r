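bg4 <- function(seed = 1, n = 12, p = 4) {
  withr::with_seed(seed, {
    m <- matrix(stats::rnorm(n * p), n, p)
    colnames(m) <- letters[seq_len(p)]
    m
  })
}

test_that("a feature the model ignores receives exactly zero attribution", {
  bg <- bg4()
  x <- bg[1, ] + 0.5
  f <- function(m) 2 * m[, 1] - m[, 3]            # features 2, 4 inert
  e <- exact_shap(NULL, x, bg, predict_fun = f)
  expect_identical(unname(e$phi[c(2, 4)]), c(0, 0))
})

test_that("linear models have the closed-form attribution a_j (x_j - mean(bg_j))", {
  bg <- bg4(2)
  a <- c(2, -1, 0.5, 0)
  x <- withr::with_seed(3, stats::rnorm(4))
  f <- function(m) m %*% a + 7
  e <- exact_shap(NULL, x, bg, predict_fun = f)
  expect_equal(unname(e$phi), unname(a * (x - colMeans(bg))),
               tolerance = 1e-12)
  expect_equal(e$base_value, mean(f(bg)), tolerance = 1e-12)
})

test_that("efficiency holds to 1e-8 on a real SVM explanation", {
  xy <- test_xy(20, seed = 6)
  m <- train_svm(xy$x, xy$y, svm_config(C = 0.5))
  e <- exact_shap(m, xy$x[3, , drop = FALSE], xy$x[1:25, ])
  expect_lt(abs(sum(e$phi) + e$base_value - e$model_output), 1e-8)
  expect_equal(e$model_output,
               decision_function(m, xy$x[3, , drop = FALSE]),
               tolerance = 1e-10)
})

test_that("two exchangeable features receive identical attributions", {
  bg <- bg4(4)
  bg[, 2] <- bg[, 1]                               # identical marginals
  x <- c(1.3, 1.3, -0.2, 0.4)
  f <- function(m) m[, 1] * m[, 2] + m[, 1] + m[, 2] + m[, 3]
  e <- exact_shap(NULL, x, bg, predict_fun = f)
  expect_equal(unname(e$phi[1]), unname(e$phi[2]), tolerance = 1e-12)
})

test_that("subset and permutation enumerations agree to 1e-10 for p <= 6", {
  for (p in c(3, 5, 6)) {
    bg <- bg4(10 + p, n = 8, p = p)
    x <- withr::with_seed(20 + p, stats::rnorm(p))
    f <- function(m) sin(m[, 1]) * m[, 2] + exp(0.2 * m[, p]) +
      if (p > 3) m[, 3] * m[, 4] else 0
    e1 <- exact_shap(NULL, x, bg, predict_fun = f)
    e2 <- permutation_shap(NULL, x, bg, predict_fun = f)
    expect_lt(max(abs(e1$phi - e2$phi)), 1e-10)
    expect_lt(abs(e1$base_value - e2$base_value), 1e-12)
  }
})

test_that("coalition weights sum to one for every feature count", {
  for (p in c(2, 5, 10, 16)) {
    w <- cmmaturity:::shap_weights(p)
    expect_equal(sum(w * choose(p - 1, 0:(p - 1))), 1, tolerance = 1e-12)
  }
})

test_that("the unit output scale squashes onto [0, 1] and keeps efficiency", {
  xy <- test_xy(15, seed = 8)
  m <- train_svm(xy$x, xy$y)
  e <- exact_shap(m, xy$x[1, , drop = FALSE], xy$x[1:20, ],
                  output_scale = "unit")
  expect_true(e$model_output >= 0 && e$model_output <= 1)
  expect_lt(abs(sum(e$phi) + e$base_value - e$model_output), 1e-8)
})

test_that("global importance ranks by mean absolute contribution with beeswarm export", {
  bg <- bg4(5)
  f <- function(m) 3 * m[, 2] + 0.5 * m[, 4]
  es <- lapply(1:6, function(i)
    exact_shap(NULL, bg[i, ] + 0.3, bg, predict_fun = f))
  names(es) <- paste0("s", 1:6)
  gi <- global_importance(es)
  expect_identical(gi$ranking$feature[1], "b")
  expect_identical(nrow(gi$points), 24L)
  expect_true(all(c("sample_id", "feature", "phi", "feature_value") %in%
                    names(gi$points)))
  # degenerate: all-zero attributions tie at zero
  es0 <- lapply(es, function(e) { e$phi[] <- 0; e })
  gi0 <- global_importance(es0)
  expect_true(all(gi0$ranking$mean_abs_phi == 0))
  # single dominant feature carries the whole output shift
  f1 <- function(m) 2 * m[, 1]
  e1 <- exact_shap(NULL, bg[2, ] + 1, bg, predict_fun = f1)
  gi1 <- global_importance(list(a = e1))
  expect_identical(gi1$ranking$feature[1], "a")
  expect_equal(gi1$ranking$mean_abs_phi[1],
               abs(e1$model_output - e1$base_value), tolerance = 1e-12)
})

test_that("waterfall data telescopes from the base value to the model output", {
  bg <- bg4(6)
  f <- function(m) m[, 1] - 0.5 * m[, 3] + 0.2 * m[, 4]
  e <- exact_shap(NULL, bg[3, ] + 0.7, bg, predict_fun = f)
  wf <- waterfall_data(e)
  expect_identical(wf$feature[1],
                   names(sort(abs(e$phi), decreasing = TRUE))[1])
  expect_equal(wf$cumulative[1], e$base_value + wf$phi[1])
  expect_lt(abs(wf$cumulative[nrow(wf)] - e$model_output), 1e-8)
  # the stated two-feature example: base 0.5, phi +0.3 / -0.1 -> 0.8, 0.7
  e2 <- e
  e2$phi <- c(a = 0.3, b = -0.1)
  e2$feature_values <- c(a = 1, b = 2)
  e2$base_value <- 0.5
  e2$model_output <- 0.7
  wf2 <- waterfall_data(e2)
  expect_equal(wf2$cumulative, c(0.8, 0.7))
})

test_that("mismatched explanations and oversized feature sets are rejected", {
  bg <- bg4(7)
  f <- function(m) m[, 1]
  e1 <- exact_shap(NULL, bg[1, ], bg, predict_fun = f)
  e2 <- e1; names(e2$phi) <- c("x", "y", "z", "w")
  expect_error(global_importance(list(e1, e2)), "inconsistent")
  big <- matrix(0, 2, 21)
  expect_error(exact_shap(NULL, big[1, ], big, predict_fun = f),
               "intractable")
})
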