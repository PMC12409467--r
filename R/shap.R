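#' Exact Shapley-value explanation of a classifier prediction
#'
#' Computes, by full enumeration of all `2^p` feature coalitions, the exact
#' Shapley value of every feature for one sample:
#' `phi_i = sum over S not containing i of |S|! (p - |S| - 1)! / p! *
#' (v(S + i) - v(S))`, where the value `v(S)` of a coalition is the mean
#' model output over the background set with the features outside `S`
#' replaced by the background rows (interventional marginalization). The
#' explained output is the signed decision value by default, or a logistic
#' squashing of it onto the 0 (immature) to 1 (mature) scale.
#'
#' Satisfies the efficiency axiom exactly: `base_value + sum(phi)` equals
#' the explained model output.
#'
#' @param model A [train_svm()] model (any model with a
#'   [decision_function()] method works through `predict_fun`).
#' @param sample A single row (vector, 1-row matrix or data frame) of
#'   normalized features.
#' @param background Background feature matrix or table (normalized; the
#'   training partition by default in higher-level wrappers).
#' @param output_scale `"decision"` (default) or `"unit"` (logistic
#'   squashing onto `[0, 1]`).
#' @param predict_fun Optional function `(matrix) -> numeric` overriding
#'   the model's decision function (used for testing axioms on constructed
#'   models).
#' @return List of class `shap_explanation`: `phi` (named numeric),
#'   `base_value`, `model_output`, `feature_values`, `output_scale`.
#' @export
exact_shap <- function(model, sample, background,
                       output_scale = c("decision", "unit"),
                       predict_fun = NULL) {
  output_scale <- match.arg(output_scale)
  bg <- shap_matrix(background)
  x <- shap_matrix(sample)
  if (nrow(x) != 1L) stop_("exact_shap() explains one sample at a time")
  if (ncol(bg) != ncol(x)) stop_("background and sample column mismatch")
  if (!is.null(colnames(bg)) && !is.null(colnames(x)) &&
        !identical(colnames(bg), colnames(x)))
    stop_("background and sample columns are ordered differently")
  p <- ncol(x)
  if (p > 20L)
    stop_(paste0("exact enumeration of 2^%d coalitions is intractable; ",
                 "reduce the feature set"), p)
  if (nrow(bg) == 0L) stop_("background set must be non-empty")
  f <- predict_fun %||% function(m) decision_function(model, m)
  if (output_scale == "unit") {
    f_raw <- f
    f <- function(m) stats::plogis(f_raw(m))
  }

  B <- nrow(bg)
  n_coal <- bitwShiftL(1L, p)
  masks <- 0:(n_coal - 1L)
  # coalition membership matrix (coalition x feature)
  member <- vapply(seq_len(p), function(i)
    bitwAnd(bitwShiftR(masks, i - 1L), 1L) == 1L, logical(n_coal))
  # value of every coalition: hybrids are background rows with coalition
  # features set to the sample's values; built in one shot, evaluated in
  # chunks to bound the kernel-matrix memory
  H <- bg[rep(seq_len(B), times = n_coal), , drop = FALSE]
  for (i in seq_len(p))
    H[rep(member[, i], each = B), i] <- x[1L, i]
  colnames(H) <- colnames(bg)
  out <- numeric(nrow(H))
  chunk <- 50000L
  for (start in seq(1L, nrow(H), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(H))
    out[idx] <- f(H[idx, , drop = FALSE])
  }
  v <- rowMeans(matrix(out, nrow = n_coal, byrow = TRUE))

  w <- shap_weights(p)                  # w[s+1] = s! (p-s-1)! / p!
  phi <- numeric(p)
  sizes <- as.integer(rowSums(member))
  for (i in seq_len(p)) {
    ibit <- bitwShiftL(1L, i - 1L)
    without <- masks[bitwAnd(masks, ibit) == 0L]
    s <- sizes[without + 1L]
    phi[i] <- sum(w[s + 1L] * (v[bitwOr(without, ibit) + 1L] - v[without + 1L]))
  }
  names(phi) <- colnames(x) %||% paste0("f", seq_len(p))
  structure(
    list(phi = phi, base_value = v[1L], model_output = v[n_coal],
         feature_values = stats::setNames(as.numeric(x[1L, ]), names(phi)),
         output_scale = output_scale),
    class = "shap_explanation"
  )
}

# Shapley coalition weights s!(p-s-1)!/p! for s = 0..p-1 (they sum to 1
# over all coalitions excluding a fixed player).
shap_weights <- function(p) {
  s <- 0:(p - 1)
  exp(lfactorial(s) + lfactorial(p - s - 1) - lfactorial(p))
}

bitcount <- function(m) {
  n <- 0L
  while (m > 0L) { n <- n + bitwAnd(m, 1L); m <- bitwShiftR(m, 1L) }
  n
}

shap_matrix <- function(x) {
  if (is.data.frame(x)) {
    feats <- intersect(FEATURE_NAMES, names(x))
    if (length(feats) == length(FEATURE_NAMES)) x <- x[FEATURE_NAMES]
    as.matrix(x)
  } else if (is.null(dim(x))) {
    matrix(x, nrow = 1L, dimnames = list(NULL, names(x)))
  } else as.matrix(x)
}

#' @export
print.shap_explanation <- function(x, ...) {
  cat(sprintf("Shapley explanation (%s scale): base %.4f -> output %.4f\n",
              x$output_scale, x$base_value, x$model_output))
  ord <- order(abs(x$phi), decreasing = TRUE)
  for (i in ord)
    cat(sprintf("  %-13s phi = %+0.4f (value %+.3f)\n", names(x$phi)[i],
                x$phi[i], x$feature_values[i]))
  invisible(x)
}

#' Permutation-form Shapley values (reference implementation)
#'
#' Averages each feature's marginal contribution over all `p!` orderings.
#' Mathematically identical to [exact_shap()]; kept as an independent
#' computational route for validation on small `p`.
#'
#' @inheritParams exact_shap
#' @return A `shap_explanation`.
#' @export
permutation_shap <- function(model, sample, background,
                             output_scale = c("decision", "unit"),
                             predict_fun = NULL) {
  output_scale <- match.arg(output_scale)
  bg <- shap_matrix(background)
  x <- shap_matrix(sample)
  p <- ncol(x)
  if (p > 8L) stop_("permutation enumeration is p! — keep p <= 8")
  f <- predict_fun %||% function(m) decision_function(model, m)
  if (output_scale == "unit") {
    f_raw <- f
    f <- function(m) stats::plogis(f_raw(m))
  }
  B <- nrow(bg)
  vcache <- new.env(parent = emptyenv())
  vfun <- function(mask) {
    key <- as.character(mask)
    if (!is.null(vcache[[key]])) return(vcache[[key]])
    hy <- bg
    for (i in seq_len(p))
      if (bitwAnd(bitwShiftR(mask, i - 1L), 1L) == 1L) hy[, i] <- x[1L, i]
    colnames(hy) <- colnames(bg)
    val <- mean(f(hy))
    vcache[[key]] <- val
    val
  }
  perms <- permutations_of(p)
  phi <- numeric(p)
  for (r in seq_len(nrow(perms))) {
    mask <- 0L
    for (i in perms[r, ]) {
      newmask <- bitwOr(mask, bitwShiftL(1L, i - 1L))
      phi[i] <- phi[i] + (vfun(newmask) - vfun(mask))
      mask <- newmask
    }
  }
  phi <- phi / nrow(perms)
  names(phi) <- colnames(x) %||% paste0("f", seq_len(p))
  structure(
    list(phi = phi, base_value = vfun(0L),
         model_output = vfun(bitwShiftL(1L, p) - 1L),
         feature_values = stats::setNames(as.numeric(x[1L, ]), names(phi)),
         output_scale = output_scale),
    class = "shap_explanation"
  )
}

permutations_of <- function(p) {
  if (p == 1L) return(matrix(1L, 1L))
  sub <- permutations_of(p - 1L)
  do.call(rbind, lapply(seq_len(p), function(pos) {
    left <- if (pos > 1L) sub[, 1:(pos - 1L), drop = FALSE]
    right <- if (pos <= p - 1L) sub[, pos:(p - 1L), drop = FALSE]
    cbind(left, p, right)
  }))
}

#' Explain many samples
#'
#' @param model A [train_svm()] model.
#' @param samples Feature matrix or table of samples to explain.
#' @param background Background matrix or table.
#' @param sample_ids Optional ids (defaults to `recording_id` or row
#'   numbers).
#' @inheritParams exact_shap
#' @return List of `shap_explanation` objects, named by sample id.
#' @export
explain_samples <- function(model, samples, background,
                            output_scale = c("decision", "unit"),
                            sample_ids = NULL) {
  output_scale <- match.arg(output_scale)
  ids <- sample_ids %||%
    (if (is.data.frame(samples) && "recording_id" %in% names(samples))
       samples$recording_id
     else as.character(seq_len(nrow(samples))))
  m <- shap_matrix(samples)
  out <- lapply(seq_len(nrow(m)), function(i)
    exact_shap(model, m[i, , drop = FALSE], background, output_scale))
  names(out) <- ids
  out
}

#' Global feature importance from Shapley explanations
#'
#' Ranks features by their mean absolute contribution and exports the
#' per-sample (contribution, feature value) pairs needed for a beeswarm
#' rendering.
#'
#' @param explanations List of `shap_explanation` objects.
#' @return List of class `shap_importance`: `ranking` (data frame with
#'   `feature`, `mean_abs_phi`, `rank`) and `points` (data frame with
#'   `sample_id`, `feature`, `phi`, `feature_value`).
#' @export
global_importance <- function(explanations) {
  if (!length(explanations)) stop_("need at least one explanation")
  feats <- names(explanations[[1L]]$phi)
  for (e in explanations)
    if (!identical(names(e$phi), feats))
      stop_("explanations have inconsistent feature sets")
  ids <- names(explanations) %||% as.character(seq_along(explanations))
  points <- do.call(rbind, lapply(seq_along(explanations), function(i) {
    e <- explanations[[i]]
    data.frame(sample_id = ids[i], feature = feats, phi = unname(e$phi),
               feature_value = unname(e$feature_values),
               stringsAsFactors = FALSE)
  }))
  agg <- tapply(abs(points$phi), points$feature, mean)
  ranking <- data.frame(feature = names(agg),
                        mean_abs_phi = as.numeric(agg),
                        stringsAsFactors = FALSE)
  ranking <- ranking[order(-ranking$mean_abs_phi, ranking$feature), ]
  ranking$rank <- seq_len(nrow(ranking))
  rownames(ranking) <- NULL
  structure(list(ranking = ranking, points = points),
            class = "shap_importance")
}

#' @export
print.shap_importance <- function(x, ...) {
  cat("Global Shapley importance (mean |phi|):\n")
  for (i in seq_len(nrow(x$ranking)))
    cat(sprintf("  %2d. %-13s %.4f\n", x$ranking$rank[i],
                x$ranking$feature[i], x$ranking$mean_abs_phi[i]))
  invisible(x)
}

#' Waterfall plot data for one explanation
#'
#' Orders features by decreasing absolute contribution and accumulates the
#' path from the base value to the model output; each row carries the
#' normalized feature value it corresponds to.
#'
#' @param explanation A `shap_explanation`.
#' @return Data frame with `feature`, `feature_value`, `phi`,
#'   `cumulative` (after adding this feature's contribution); attribute
#'   `base_value`.
#' @export
waterfall_data <- function(explanation) {
  stopifnot(inherits(explanation, "shap_explanation"))
  ord <- order(abs(explanation$phi), decreasing = TRUE)
  phi <- explanation$phi[ord]
  out <- data.frame(
    feature = names(phi),
    feature_value = unname(explanation$feature_values[ord]),
    phi = unname(phi),
    cumulative = explanation$base_value + cumsum(unname(phi)),
    stringsAsFactors = FALSE
  )
  attr(out, "base_value") <- explanation$base_value
  attr(out, "model_output") <- explanation$model_output
  out
}

#' Write explanations to CSV / JSON
#'
#' @param explanations List of `shap_explanation`s.
#' @param csv_path Per-feature contributions CSV
#'   (`sample_id,feature,phi,feature_value`).
#' @param json_path Per-sample base value and model output JSON.
#' @return Invisibly, the CSV path.
#' @export
write_explanations <- function(explanations, csv_path, json_path = NULL) {
  gi <- global_importance(explanations)
  utils::write.csv(gi$points, csv_path, row.names = FALSE, quote = FALSE)
  if (!is.null(json_path)) {
    meta <- lapply(explanations, function(e)
      list(base_value = e$base_value, model_output = e$model_output,
           output_scale = e$output_scale))
    jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(csv_path)
}
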