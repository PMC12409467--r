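test_that("a symmetric separable pair puts the boundary at zero with unit margins", {
  # linear-equivalent kernel: polynomial of degree 1, gamma 1, coef0 0
  x <- matrix(c(-1, 1), ncol = 1)
  x <- cbind(x, 0)                       # 2-D to keep libsvm comfortable
  colnames(x) <- c("a", "b")
  y <- c("immature", "mature")
  cfg <- svm_config(C = 100, kernel = "polynomial", gamma = 1, degree = 1,
                    coef0 = 0)
  m <- train_svm(x, y, cfg)
  dec <- decision_function(m, x)
  expect_equal(dec, c(-1, 1), tolerance = 1e-6)
  expect_equal(decision_function(m, matrix(c(0, 0), 1,
                                           dimnames = list(NULL, c("a", "b")))),
               0, tolerance = 1e-6)
})

test_that("the XOR four-point set is separated by an rbf kernel", {
  x <- matrix(c(0, 0, 1, 1, 0, 1, 0, 1), 4,
              dimnames = list(NULL, c("a", "b")))
  y <- c("immature", "mature", "mature", "immature")
  m <- train_svm(x, y, svm_config(C = 1, kernel = "rbf", gamma = 1))
  expect_identical(unname(predict(m, x)), y)
})

test_that("the primal objective matches an independent quadratic-programming oracle", {
  skip_if_not_installed("kernlab")
  errs <- vapply(1:6, function(i) {
    x <- withr::with_seed(i, matrix(stats::rnorm(30), 10, 3))
    colnames(x) <- c("a", "b", "c")
    y_pm <- rep(c(-1, 1), each = 5)
    cfg <- svm_config(C = withr::with_seed(100 + i, stats::runif(1, 0.5, 2)),
                      kernel = "rbf", gamma = "auto")
    m <- train_svm(x, ifelse(y_pm > 0, "mature", "immature"), cfg,
                   tolerance = 1e-9)
    obj <- svm_objective(m, x, ifelse(y_pm > 0, "mature", "immature"))
    abs(obj - qp_primal_objective(x, y_pm, cfg))
  }, numeric(1))
  expect_lt(max(errs), 1e-6)
})

test_that("the trained model satisfies the Karush-Kuhn-Tucker conditions", {
  xy <- test_xy(20, shift = 1.0, seed = 9)
  for (cfg in list(svm_config(C = 0.5, kernel = "rbf"),
                   svm_config(C = 1, kernel = "polynomial", degree = 2,
                              coef0 = 0.5))) {
    m <- train_svm(xy$x, xy$y, cfg, tolerance = 1e-8)
    expect_true(check_kkt(m, xy$x, xy$y))
    # slack values are exactly the margin violations
    dec <- decision_function(m, xy$x)
    ypm <- ifelse(xy$y == "mature", 1, -1)
    expect_equal(m$xi, pmax(0, 1 - ypm * dec), tolerance = 1e-8)
  }
})

test_that("degenerate training inputs are rejected", {
  xy <- test_xy(5)
  expect_error(train_svm(xy$x[1:5, ], rep("mature", 5)), "2 classes")
  bad <- xy$x; bad[1, 1] <- NA
  expect_error(train_svm(bad, xy$y), "finite")
})

test_that("gamma conventions resolve as 1/p and 1/(p * var)", {
  x <- matrix(c(1, 2, 3, 4), 2)
  expect_equal(cmmaturity:::resolve_gamma("auto", x), 0.5)
  expect_equal(cmmaturity:::resolve_gamma("scale", x),
               1 / (2 * stats::var(c(1, 2, 3, 4))))
  expect_equal(cmmaturity:::resolve_gamma(0.3, x), 0.3)
})

test_that("a model survives a JSON round trip", {
  xy <- test_xy(15, seed = 4)
  m <- train_svm(xy$x, xy$y, svm_config(C = 0.7, kernel = "rbf"))
  stats <- list(mean = stats::setNames(rep(0, 10), colnames(xy$x)),
                sd = stats::setNames(rep(1, 10), colnames(xy$x)))
  f <- tempfile(fileext = ".json")
  write_svm_json(m, stats, f)
  back <- read_svm_json(f)
  expect_equal(decision_function(back$model, xy$x),
               decision_function(m, xy$x), tolerance = 1e-9)
  unlink(f)
})
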