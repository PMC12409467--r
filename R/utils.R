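#' @keywords internal
"_PACKAGE"

# Canonical order of the ten beating features used everywhere in the package.
FEATURE_NAMES <- c(
  "max_c", "c_time", "max_r", "r_time", "cr_interval",
  "time_01", "c_rise_time", "r_rise_time", "beating_rate", "displacement"
)

# Non-feature columns of a feature table, in CSV order.
TABLE_ID_COLS <- c("recording_id", "cell_line", "class")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Names of the ten beating features, in canonical column order
#'
#' @return Character vector of length 10.
#' @export
feature_names <- function() FEATURE_NAMES

stop_ <- function(...) stop(sprintf(...), call. = FALSE)

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_("`%s` must be a single finite number", name)
  if (strict_lower && x <= lower)
    stop_("`%s` must be > %g (got %g)", name, lower, x)
  if (!strict_lower && x < lower)
    stop_("`%s` must be >= %g (got %g)", name, lower, x)
  if (x > upper)
    stop_("`%s` must be <= %g (got %g)", name, upper, x)
  invisible(x)
}

#' Derive a reproducible child seed from a parent seed
#'
#' Deterministic expansion of one global seed into per-stage or per-item
#' seeds, so pipeline stages can be re-run in isolation. The derivation is a
#' fixed affine-modular map kept strictly below 2^31 so the result is always
#' a valid R integer seed.
#'
#' @param seed Integer parent seed.
#' @param index Non-negative integer offset (stage or item number).
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, index) {
  seed <- as.double(seed) %% 2147483647
  idx <- as.double(index)
  as.integer((seed * 48271 + idx * 9973 + 1) %% 2147483647)
}

# Trapezoidal integral of linearly interpolated samples over [t0, t1],
# with fractional end segments.
trapz_interval <- function(time, values, t0, t1) {
  if (t1 <= t0) return(0)
  t0 <- max(t0, time[1L])
  t1 <- min(t1, time[length(time)])
  keep <- which(time > t0 & time < t1)
  v0 <- stats::approx(time, values, xout = t0)$y
  v1 <- stats::approx(time, values, xout = t1)$y
  tt <- c(t0, time[keep], t1)
  vv <- c(v0, values[keep], v1)
  sum(diff(tt) * (utils::head(vv, -1L) + utils::tail(vv, -1L)) / 2)
}

# Centred moving average with edge shrinkage (window truncated at the ends).
moving_average <- function(x, w) {
  if (w <= 1L) return(x)
  if (w %% 2L == 0L) w <- w + 1L
  n <- length(x)
  cs <- cumsum(c(0, x))
  h <- (w - 1L) %/% 2L
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
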