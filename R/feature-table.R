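#' Impute missing beating duration from phase durations and plateau time
#'
#' Rows with a missing `time_01` (beating duration) receive
#' `c_time + r_time + mean plateau time of the recording's cell line`, the
#' mean taken over recordings of that line with a known plateau time.
#' Non-missing rows are returned unchanged.
#'
#' @param table Feature table with `cell_line`, `c_time`, `r_time`,
#'   `time_01` and `plateau_time` columns.
#' @param by `"cell_line"` (default) or `"cell_line_class"`: the grouping
#'   over which the mean plateau time is taken.
#' @return The table with `time_01` completed.
#' @export
impute_time_01 <- function(table, by = c("cell_line", "cell_line_class")) {
  by <- match.arg(by)
  need <- c("cell_line", "c_time", "r_time", "time_01", "plateau_time")
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols))
    stop_("impute_time_01() needs columns: %s",
          paste(missing_cols, collapse = ", "))
  miss <- is.na(table$time_01)
  if (!any(miss)) return(table)
  grp <- if (by == "cell_line") table$cell_line
         else paste(table$cell_line, table$class, sep = "|")
  mp <- tapply(table$plateau_time, grp, mean, na.rm = TRUE)
  bad <- unique(grp[miss][!is.finite(mp[grp[miss]])])
  if (length(bad))
    stop_("no plateau information for cell line(s): %s",
          paste(bad, collapse = ", "))
  table$time_01[miss] <- table$c_time[miss] + table$r_time[miss] +
    as.numeric(mp[grp[miss]])
  table
}

#' Feature-wise z-normalization
#'
#' Replaces each of the ten feature columns by `(x - mean) / sd`. When
#' `stats` is omitted the mean and the sample SD (n - 1) are fitted on the
#' given table and returned for reuse on held-out data, the
#' leakage-avoiding default. Passing `stats` applies an existing
#' normalization (e.g. training-set statistics to a test set).
#'
#' @param table Feature table.
#' @param stats Optional list with numeric vectors `mean` and `sd` (named
#'   by feature).
#' @return List with `table` (normalized) and `stats`.
#' @export
znormalize <- function(table, stats = NULL) {
  feats <- intersect(FEATURE_NAMES, names(table))
  if (!length(feats)) stop_("no feature columns found")
  if (is.null(stats)) {
    mu <- vapply(table[feats], mean, numeric(1), na.rm = TRUE)
    sd_ <- vapply(table[feats], stats::sd, numeric(1), na.rm = TRUE)
    zero <- names(sd_)[!is.finite(sd_) | sd_ <= 0]
    if (length(zero))
      stop_("cannot z-normalize zero-variance feature(s): %s",
            paste(zero, collapse = ", "))
    stats <- list(mean = mu, sd = sd_)
  } else {
    if (!all(feats %in% names(stats$mean)) ||
          !all(feats %in% names(stats$sd)))
      stop_("normalization stats do not cover all features")
  }
  for (nm in feats)
    table[[nm]] <- (table[[nm]] - stats$mean[[nm]]) / stats$sd[[nm]]
  list(table = table, stats = stats)
}

#' Write or read normalization statistics as JSON
#'
#' @param stats A `list(mean =, sd =)` as returned by [znormalize()].
#' @param path File path.
#' @return `write_norm_stats()` returns `path` invisibly;
#'   `read_norm_stats()` the stats list.
#' @export
write_norm_stats <- function(stats, path) {
  jsonlite::write_json(
    list(mean = as.list(stats$mean), sd = as.list(stats$sd)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_norm_stats
#' @export
read_norm_stats <- function(path) {
  raw <- jsonlite::read_json(path)
  list(mean = unlist(raw$mean), sd = unlist(raw$sd))
}
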