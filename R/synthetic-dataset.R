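#' Phenotype preset for the synthetic study
#'
#' Bundles the mean beat-waveform morphology of a maturity phenotype with
#' its between-recording variability (per-field coefficient of variation)
#' and between-cell-line random effects (per-field log-normal SD).
#'
#' @param label One of `"immature"`, `"mature"`, `"intermediate"`.
#' @param params_mean A [beat_waveform_params()] with the phenotype means.
#' @param params_cv Named numeric: per-field coefficient of variation of the
#'   between-recording (log-normal) variability. Missing fields default to 0.
#' @param cell_line_effect_sd Named numeric: per-field SD of the
#'   multiplicative log-normal cell-line random effect. Missing fields
#'   default to 0.
#' @return An object of class `phenotype_preset`.
#' @export
phenotype_preset <- function(label = c("immature", "mature", "intermediate"),
                             params_mean, params_cv = numeric(),
                             cell_line_effect_sd = numeric()) {
  label <- match.arg(label)
  stopifnot(inherits(params_mean, "beat_waveform_params"))
  structure(
    list(label = label, params_mean = params_mean,
         params_cv = params_cv, cell_line_effect_sd = cell_line_effect_sd),
    class = "phenotype_preset"
  )
}

# Waveform fields subject to between-recording and between-line variation.
VARIABLE_FIELDS <- c("beating_rate", "max_c", "max_r", "c_rise_time",
                     "c_time", "r_rise_time", "r_time", "plateau_time",
                     "shape_q")

#' Default phenotype presets of the synthetic study
#'
#' Mean morphologies for immature (early after differentiation), mature
#' (maturation-medium) and intermediate (standard-medium, same age)
#' phenotypes. The mature preset differs from the immature one in the
#' directions reported for maturing iPSC-CM monolayers: higher peak
#' contraction and relaxation speed and displacement; longer contraction,
#' relaxation, contraction-relaxation interval, beating duration and
#' relaxation-rise time; shorter contraction-rise time; lower spontaneous
#' beating rate. The intermediate preset is the component-wise midpoint.
#' Magnitudes are package defaults chosen to give clear (> 1.5 SD)
#' separation on displacement, relaxation-rise time and beating duration;
#' they are not measured literature values.
#'
#' @return Named list of three [phenotype_preset()] objects.
#' @export
default_presets <- function() {
  cv <- c(beating_rate = 0.12, max_c = 0.11, max_r = 0.13,
          c_rise_time = 0.10, c_time = 0.09, r_rise_time = 0.10,
          r_time = 0.09, plateau_time = 0.15, shape_q = 0.10)
  line_sd <- c(beating_rate = 0.05, max_c = 0.06, max_r = 0.06,
               c_rise_time = 0.04, c_time = 0.04, r_rise_time = 0.04,
               r_time = 0.04, plateau_time = 0.05, shape_q = 0.03)
  # shape_q: mature pulses are fuller (more sustained speed for the same
  # peak and duration), which gives the per-beat displacement a signal
  # channel of its own on top of max_c * c_time
  imm <- beat_waveform_params(
    beating_rate = 46, max_c = 9, max_r = 5.5,
    c_rise_time = 0.175, c_time = 0.38,
    r_rise_time = 0.17, r_time = 0.50,
    plateau_time = 0.15, noise_sd = 0.8, rate_jitter_cv = 0.05,
    shape_q = 1.05)
  mat <- beat_waveform_params(
    beating_rate = 38, max_c = 12.5, max_r = 7.5,
    c_rise_time = 0.16, c_time = 0.43,
    r_rise_time = 0.27, r_time = 0.68,
    plateau_time = 0.18, noise_sd = 1.0, rate_jitter_cv = 0.05,
    shape_q = 0.78)
  mid_fields <- lapply(names(unclass(imm)), function(nm) {
    a <- imm[[nm]]; b <- mat[[nm]]
    if (is.numeric(a)) (a + b) / 2 else a
  })
  names(mid_fields) <- names(unclass(imm))
  mid <- do.call(beat_waveform_params, mid_fields[
    setdiff(names(mid_fields), "pulse_shape")])
  list(
    immature = phenotype_preset("immature", imm, cv, line_sd),
    mature = phenotype_preset("mature", mat, cv, line_sd),
    intermediate = phenotype_preset("intermediate", mid, cv, line_sd)
  )
}

#' Study configuration for the synthetic dataset generator
#'
#' @param n_per_class Recordings per phenotype class.
#' @param n_cell_lines Number of cell lines (default 4).
#' @param duration_s Recording duration, s (default 25).
#' @param fs Frame rate, frames/s (default 60).
#' @param seed Integer seed.
#' @param missing_time_01_rate Fraction of recordings whose beating duration
#'   (`time_01`) is masked as missing in the emitted table, emulating the
#'   missingness of the original feature-extraction software (default
#'   0.331).
#' @param features `"extracted"` (default; features measured from the
#'   generated motion traces by [detect_beats()] and [extract_features()])
#'   or `"annotated"` (ground-truth feature values).
#' @return An object of class `synthetic_study_config`.
#' @export
synthetic_study_config <- function(n_per_class, n_cell_lines = 4L,
                                   duration_s = 25, fs = 60, seed = 1L,
                                   missing_time_01_rate = 0.331,
                                   features = c("extracted", "annotated")) {
  features <- match.arg(features)
  assert_scalar_number(n_per_class, "n_per_class", 1)
  assert_scalar_number(n_cell_lines, "n_cell_lines", 1)
  if (n_per_class < n_cell_lines)
    stop_("n_per_class (%d) must be >= n_cell_lines (%d)",
          n_per_class, n_cell_lines)
  assert_scalar_number(duration_s, "duration_s", 0, strict_lower = TRUE)
  assert_scalar_number(fs, "fs", 0, strict_lower = TRUE)
  assert_scalar_number(missing_time_01_rate, "missing_time_01_rate", 0, 1)
  structure(
    list(n_per_class = as.integer(n_per_class),
         n_cell_lines = as.integer(n_cell_lines),
         duration_s = duration_s, fs = fs, seed = as.integer(seed),
         missing_time_01_rate = missing_time_01_rate, features = features),
    class = "synthetic_study_config"
  )
}

# Draw one recording's waveform parameters: preset mean x cell-line factor
# x log-normal recording-level variability, re-drawn (up to 50 times) until
# the waveform invariants hold, then clamped as a last resort.
draw_params <- function(preset, line_factors) {
  base <- unclass(preset$params_mean)
  cv <- preset$params_cv
  for (try in 1:50) {
    vals <- base
    for (nm in VARIABLE_FIELDS) {
      cvi <- if (nm %in% names(cv)) cv[[nm]] else 0
      fac <- if (nm %in% names(line_factors)) line_factors[[nm]] else 1
      vals[[nm]] <- base[[nm]] * fac *
        if (cvi > 0) exp(stats::rnorm(1, -cvi^2 / 2, cvi)) else 1
    }
    ok <- vals$c_rise_time < vals$c_time &&
      vals$r_rise_time < vals$r_time &&
      vals$shape_q >= 0.4 && vals$shape_q <= 2.5 &&
      (vals$c_time + vals$plateau_time + vals$r_time) < 60 / vals$beating_rate
    if (ok) break
  }
  if (!ok) {
    vals$c_rise_time <- min(vals$c_rise_time, 0.8 * vals$c_time)
    vals$r_rise_time <- min(vals$r_rise_time, 0.8 * vals$r_time)
    excess <- (vals$c_time + vals$plateau_time + vals$r_time) /
      (60 / vals$beating_rate)
    if (excess >= 1) vals$beating_rate <- vals$beating_rate / (1.05 * excess)
  }
  do.call(beat_waveform_params,
          vals[setdiff(names(vals), "pulse_shape")])
}

#' Generate a labelled synthetic feature dataset with traces
#'
#' Simulates the study design: `n_per_class` recordings per phenotype,
#' cell lines assigned round-robin within each class, one multiplicative
#' log-normal random effect per cell line and waveform field (drawn once
#' per line, shared across classes), log-normal between-recording
#' variability, and per-recording motion traces from [generate_trace()].
#' Features are either measured from the traces ([detect_beats()] +
#' [extract_features()]) or taken from the ground-truth annotation. A
#' seeded fraction of beating-duration (`time_01`) values is masked as
#' missing, to be restored by [impute_time_01()].
#'
#' @param config A [synthetic_study_config()].
#' @param presets List of [phenotype_preset()] objects (at least two).
#' @return A list with `table` (feature table data frame: `recording_id`,
#'   `cell_line`, `class`, the ten features, `plateau_time`), `traces`
#'   (named list of [motion_trace()]), and `annotations` (named list of
#'   ground-truth annotations).
#' @export
generate_dataset <- function(config, presets) {
  stopifnot(inherits(config, "synthetic_study_config"))
  if (!is.list(presets) || length(presets) < 2L)
    stop_("generate_dataset() needs at least two phenotype presets")
  for (p in presets) stopifnot(inherits(p, "phenotype_preset"))
  labels <- vapply(presets, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop_("preset labels must be unique")

  withr::with_seed(config$seed, {
    lines <- paste0("line", seq_len(config$n_cell_lines))
    # one set of line factors per field, shared by all classes: the line is
    # a biological identity, not a per-class nuisance
    line_factors <- lapply(seq_len(config$n_cell_lines), function(i) {
      sds <- presets[[1L]]$cell_line_effect_sd
      out <- lapply(VARIABLE_FIELDS, function(nm) {
        sdi <- if (nm %in% names(sds)) sds[[nm]] else 0
        if (sdi > 0) exp(stats::rnorm(1, -sdi^2 / 2, sdi)) else 1
      })
      names(out) <- VARIABLE_FIELDS
      out
    })
    names(line_factors) <- lines

    rows <- list(); traces <- list(); annotations <- list()
    rec <- 0L
    for (p in presets) {
      for (i in seq_len(config$n_per_class)) {
        rec <- rec + 1L
        line <- lines[((i - 1L) %% config$n_cell_lines) + 1L]
        params <- draw_params(p, line_factors[[line]])
        id <- sprintf("rec%03d_%s", rec, p$label)
        g <- generate_trace(params, config$duration_s, config$fs,
                            seed = derive_seed(config$seed, rec))
        feats <- if (config$features == "extracted") {
          cycles <- detect_beats(g$trace)
          if (nrow(cycles) == 0L) {
            as.data.frame(as.list(g$annotation$features))
          } else {
            extract_features(g$trace, cycles)[c(FEATURE_NAMES,
                                                "plateau_time")]
          }
        } else {
          cbind(as.data.frame(as.list(g$annotation$features)),
                plateau_time = g$annotation$plateau_time)
        }
        rows[[rec]] <- cbind(
          data.frame(recording_id = id, cell_line = line, class = p$label,
                     stringsAsFactors = FALSE),
          feats[c(FEATURE_NAMES, "plateau_time")]
        )
        traces[[id]] <- g$trace
        annotations[[id]] <- g$annotation
      }
    }
    table <- do.call(rbind, rows)
    rownames(table) <- NULL
    if (config$missing_time_01_rate > 0) {
      miss <- stats::runif(nrow(table)) < config$missing_time_01_rate
      table$time_01[miss] <- NA_real_
    }
    list(table = table, traces = traces, annotations = annotations)
  })
}

#' Write or read a feature table as CSV
#'
#' Column order is fixed: `recording_id,cell_line,class,` the ten features,
#' then auxiliary columns (`plateau_time`).
#'
#' @param table Feature table data frame.
#' @param path File path.
#' @return `write_feature_table()` returns `path` invisibly;
#'   `read_feature_table()` returns the data frame.
#' @export
write_feature_table <- function(table, path) {
  cols <- c(TABLE_ID_COLS, FEATURE_NAMES,
            intersect("plateau_time", names(table)))
  utils::write.csv(table[cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c(TABLE_ID_COLS, FEATURE_NAMES)
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    stop_("feature table is missing columns: %s",
          paste(missing_cols, collapse = ", "))
  tab
}

#' Write or read a motion trace as a two-column CSV (time_s, speed_um_s)
#'
#' @param trace A [motion_trace()].
#' @param path File path.
#' @param fs Sampling rate when reading (inferred from the time column if
#'   omitted).
#' @return `write_trace()` returns `path` invisibly; `read_trace()` a
#'   [motion_trace()].
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "motion_trace"))
  utils::write.csv(
    data.frame(time_s = trace$time_s, speed_um_s = trace$speed_um_s),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path, fs = NULL) {
  d <- utils::read.csv(path)
  if (!all(c("time_s", "speed_um_s") %in% names(d)))
    stop_("trace CSV must have columns time_s, speed_um_s")
  if (is.null(fs)) fs <- 1 / stats::median(diff(d$time_s))
  motion_trace(d$time_s, d$speed_um_s, fs,
               metadata = list(source = path))
}
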