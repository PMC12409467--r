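#' Soft-margin SVM configuration
#'
#' Hyperparameters of the C-classification soft-margin support vector
#' machine used for maturity classification.
#'
#' @param C Regularization weight (> 0): the cost of margin violations in
#'   the primal objective `0.5 * ||w||^2 + C * sum(xi_i)`.
#' @param kernel `"rbf"` (radial basis function, default), `"polynomial"`
#'   or `"sigmoid"`.
#' @param gamma `"auto"` (1 / p), `"scale"` (1 / (p * var(X)) with the
#'   total variance of the training matrix), or a positive number.
#' @param degree Polynomial degree (polynomial kernel only; default 3).
#' @param coef0 Kernel offset (polynomial and sigmoid kernels; default 0).
#' @return An object of class `svm_config`.
#' @export
svm_config <- function(C = 1, kernel = c("rbf", "polynomial", "sigmoid"),
                       gamma = "scale", degree = 3L, coef0 = 0) {
  kernel <- match.arg(kernel)
  assert_scalar_number(C, "C", 0, strict_lower = TRUE)
  if (is.character(gamma)) {
    if (!gamma %in% c("auto", "scale"))
      stop_("gamma must be 'auto', 'scale' or a positive number")
  } else {
    assert_scalar_number(gamma, "gamma", 0, strict_lower = TRUE)
  }
  assert_scalar_number(degree, "degree", 1)
  assert_scalar_number(coef0, "coef0", 0)
  structure(
    list(C = C, kernel = kernel, gamma = gamma,
         degree = as.integer(degree), coef0 = coef0),
    class = "svm_config"
  )
}

#' @export
print.svm_config <- function(x, ...) {
  cat(sprintf("SVM config: C = %g, kernel = %s, gamma = %s", x$C, x$kernel,
              if (is.character(x$gamma)) x$gamma else format(x$gamma)))
  if (x$kernel == "polynomial") cat(sprintf(", degree = %d", x$degree))
  if (x$kernel %in% c("polynomial", "sigmoid"))
    cat(sprintf(", coef0 = %g", x$coef0))
  cat("\n")
  invisible(x)
}

# Resolve a gamma specification against a training matrix.
resolve_gamma <- function(gamma, X) {
  p <- ncol(X)
  if (is.numeric(gamma)) return(gamma)
  if (gamma == "auto") return(1 / p)
  v <- stats::var(as.vector(X))        # total variance, "scale" convention
  if (!is.finite(v) || v <= 0) v <- 1
  1 / (p * v)
}

# Kernel matrix between rows of X and rows of Y.
kernel_matrix <- function(X, Y, kernel, gamma, degree, coef0) {
  switch(kernel,
    rbf = {
      d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
      exp(-gamma * pmax(d2, 0))
    },
    polynomial = (gamma * tcrossprod(X, Y) + coef0)^degree,
    sigmoid = tanh(gamma * tcrossprod(X, Y) + coef0),
    stop_("unknown kernel '%s'", kernel)
  )
}

#' Train a soft-margin SVM maturity classifier
#'
#' Solves the kernelized soft-margin problem
#' `min 0.5 * ||w||^2 + C * sum(xi_i)` subject to
#' `y_i (w . phi(x_i) + t) >= 1 - xi_i`, `xi_i >= 0` (libsvm via e1071).
#' The decision function is oriented so that positive values mean the
#' positive class (`"mature"` when present, otherwise the second factor
#' level).
#'
#' @param x Numeric feature matrix (or feature table data frame, from which
#'   the ten feature columns are taken), expected normalized.
#' @param y Class labels (two classes).
#' @param config An [svm_config()].
#' @param positive_class Label mapped to positive decision values (default
#'   `"mature"` when present).
#' @param tolerance Termination tolerance of the dual solver.
#' @return An object of class `trained_svm`: support vectors, signed dual
#'   coefficients (alpha_i * y_i), offset `rho` (decision = K alpha - rho),
#'   resolved gamma, slack variables `xi`, the primal objective value, and
#'   the label mapping.
#' @export
train_svm <- function(x, y, config = svm_config(),
                      positive_class = NULL, tolerance = 1e-6) {
  stopifnot(inherits(config, "svm_config"))
  if (is.data.frame(x)) x <- as.matrix(x[FEATURE_NAMES])
  y <- as.character(y)
  if (any(!is.finite(x))) stop_("features must be finite for SVM training")
  classes <- sort(unique(y))
  if (length(classes) != 2L)
    stop_("train_svm() needs exactly 2 classes, got %d", length(classes))
  if (is.null(positive_class))
    positive_class <- if ("mature" %in% classes) "mature" else classes[2L]
  if (!positive_class %in% classes)
    stop_("positive_class '%s' not among labels", positive_class)
  negative_class <- setdiff(classes, positive_class)

  gamma <- resolve_gamma(config$gamma, x)
  fit <- e1071::svm(
    x = x, y = factor(y, levels = c(negative_class, positive_class)),
    scale = FALSE, type = "C-classification",
    kernel = switch(config$kernel, rbf = "radial",
                    polynomial = "polynomial", sigmoid = "sigmoid"),
    cost = config$C, gamma = gamma, degree = config$degree,
    coef0 = config$coef0, tolerance = tolerance)

  sv <- fit$SV
  coefs <- as.vector(fit$coefs)        # alpha_i * y_i in libsvm order
  rho <- fit$rho
  model <- structure(
    list(config = config, gamma = gamma, support_vectors = sv,
         dual_coefs = coefs, rho = rho,
         positive_class = positive_class, negative_class = negative_class,
         feature_names = colnames(x) %||% paste0("f", seq_len(ncol(x)))),
    class = "trained_svm"
  )
  # orient: positive decision value = positive class
  dec <- decision_function(model, x)
  ypm <- ifelse(y == positive_class, 1, -1)
  if (stats::cor(dec, ypm) < 0) {
    model$dual_coefs <- -model$dual_coefs
    model$rho <- -model$rho
    dec <- -dec
  }
  model$xi <- pmax(0, 1 - ypm * dec)
  model$alpha <- abs(coefs)
  model$objective <- svm_objective(model, x, y)
  model$n_train <- nrow(x)
  model
}

#' Signed decision values of a trained SVM
#'
#' `f(x) = sum_i (alpha_i y_i) k(sv_i, x) - rho`; positive values indicate
#' the positive (mature) class.
#'
#' @param model A [train_svm()] model.
#' @param x Feature matrix or feature table data frame.
#' @return Numeric vector of decision values.
#' @export
decision_function <- function(model, x) {
  stopifnot(inherits(model, "trained_svm"))
  if (is.data.frame(x)) {
    cols <- if (all(model$feature_names %in% names(x))) model$feature_names
            else FEATURE_NAMES
    x <- as.matrix(x[cols])
  }
  K <- kernel_matrix(x, model$support_vectors, model$config$kernel,
                     model$gamma, model$config$degree, model$config$coef0)
  as.vector(K %*% model$dual_coefs) - model$rho
}

#' @export
predict.trained_svm <- function(object, newdata, ...) {
  dec <- decision_function(object, newdata)
  ifelse(dec >= 0, object$positive_class, object$negative_class)
}

#' @export
print.trained_svm <- function(x, ...) {
  cat("Trained soft-margin SVM\n")
  print(x$config)
  cat(sprintf("  %d support vectors | positive class: %s | objective %.6g\n",
              nrow(x$support_vectors), x$positive_class, x$objective))
  invisible(x)
}

#' Primal objective of a trained SVM on its training set
#'
#' `0.5 * ||w||^2 + C * sum(xi_i)` with `||w||^2 = a' K a` for the signed
#' dual coefficients `a` and the kernel Gram matrix of the support vectors.
#'
#' @param model A [train_svm()] model.
#' @param x,y The training data the model was fitted on.
#' @return The primal objective value.
#' @export
svm_objective <- function(model, x, y) {
  stopifnot(inherits(model, "trained_svm"))
  if (is.data.frame(x)) x <- as.matrix(x[FEATURE_NAMES])
  Ksv <- kernel_matrix(model$support_vectors, model$support_vectors,
                       model$config$kernel, model$gamma,
                       model$config$degree, model$config$coef0)
  w2 <- as.numeric(t(model$dual_coefs) %*% Ksv %*% model$dual_coefs)
  ypm <- ifelse(as.character(y) == model$positive_class, 1, -1)
  xi <- pmax(0, 1 - ypm * decision_function(model, x))
  0.5 * w2 + model$config$C * sum(xi)
}

#' Karush-Kuhn-Tucker consistency check of a trained SVM
#'
#' Verifies, within `tol`, that training samples with positive slack are
#' exactly those violating the unit margin, that free support vectors
#' (0 < alpha < C) sit on the margin, and that zero-alpha samples satisfy
#' it.
#'
#' @param model A [train_svm()] model.
#' @param x,y Training data.
#' @param tol Numeric tolerance.
#' @return `TRUE` (invisibly) if all conditions hold, otherwise an error.
#' @export
check_kkt <- function(model, x, y, tol = 1e-4) {
  stopifnot(inherits(model, "trained_svm"))
  if (is.data.frame(x)) xm <- as.matrix(x[FEATURE_NAMES]) else xm <- x
  dec <- decision_function(model, xm)
  ypm <- ifelse(as.character(y) == model$positive_class, 1, -1)
  marg <- ypm * dec
  xi <- pmax(0, 1 - marg)
  # slack is positive exactly on margin violations
  if (!all((xi > tol) == (marg < 1 - tol)))
    stop_("KKT violation: slack/margin mismatch")
  # support-vector conditions
  C <- model$config$C
  sv_idx <- match_support_rows(model$support_vectors, xm)
  alpha <- numeric(nrow(xm))
  alpha[sv_idx] <- model$alpha
  free <- alpha > tol & alpha < C - tol
  if (any(abs(marg[free] - 1) > 50 * tol))
    stop_("KKT violation: free support vector off the unit margin")
  atC <- abs(alpha - C) <= tol
  if (any(marg[atC] > 1 + 50 * tol))
    stop_("KKT violation: bound support vector beyond the margin")
  zero <- alpha <= tol
  if (any(marg[zero] < 1 - 50 * tol))
    stop_("KKT violation: non-support sample inside the margin")
  invisible(TRUE)
}

match_support_rows <- function(sv, x) {
  key <- function(m) apply(round(m, 10), 1L, paste, collapse = ",")
  match(key(sv), key(x))
}
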