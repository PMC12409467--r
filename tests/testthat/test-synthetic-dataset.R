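small_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_per_class = 8, seed = 21, duration_s = 15,
         features = "annotated"),
    list(...))
  do.call(synthetic_study_config, args)
}

test_that("the dataset has n_per_class rows per label with round-robin lines", {
  ds <- generate_dataset(small_cfg(), default_presets()[c("immature",
                                                          "mature")])
  expect_identical(nrow(ds$table), 16L)
  expect_true(all(table(ds$table$class) == 8L))
  expect_true(all(table(ds$table$cell_line, ds$table$class) == 2L))
  # n_per_class = n_cell_lines = 4: exactly one recording per line per class
  ds4 <- generate_dataset(small_cfg(n_per_class = 4),
                          default_presets()[c("immature", "mature")])
  expect_true(all(table(ds4$table$cell_line, ds4$table$class) == 1L))
})

test_that("identical configurations produce byte-identical tables and traces", {
  cfg <- small_cfg(missing_time_01_rate = 0.4)
  pr <- default_presets()[c("immature", "mature")]
  d1 <- generate_dataset(cfg, pr)
  d2 <- generate_dataset(cfg, pr)
  expect_identical(d1$table, d2$table)
  expect_identical(d1$traces, d2$traces)
  f1 <- tempfile(); f2 <- tempfile()
  write_feature_table(d1$table, f1); write_feature_table(d2$table, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  unlink(c(f1, f2))
})

test_that("beating-duration missingness matches the configured rate", {
  cfg <- small_cfg(n_per_class = 60, missing_time_01_rate = 0.331)
  ds <- generate_dataset(cfg, default_presets()[c("immature", "mature")])
  expect_gt(mean(is.na(ds$table$time_01)), 0.2)
  expect_lt(mean(is.na(ds$table$time_01)), 0.45)
  expect_false(anyNA(generate_dataset(
    small_cfg(missing_time_01_rate = 0),
    default_presets()[c("immature", "mature")])$table$time_01))
})

test_that("degenerate configurations are rejected", {
  expect_error(synthetic_study_config(n_per_class = 2, n_cell_lines = 4),
               "n_cell_lines")
  expect_error(generate_dataset(small_cfg(), list()), "two phenotype")
})

test_that("class means shift in the reported maturation directions", {
  # measured through the full trace -> detection -> extraction path
  cfg <- synthetic_study_config(n_per_class = 30, seed = 33,
                                missing_time_01_rate = 0)
  ds <- generate_dataset(cfg, default_presets()[c("immature", "mature")])
  mu <- aggregate(ds$table[cmmaturity:::FEATURE_NAMES],
                  list(class = ds$table$class), mean)
  imm <- mu[mu$class == "immature", ]
  mat <- mu[mu$class == "mature", ]
  up <- c("max_c", "max_r", "displacement", "c_time", "r_time",
          "cr_interval", "time_01", "r_rise_time")
  for (nm in up) expect_gt(mat[[nm]], imm[[nm]])
  for (nm in c("c_rise_time", "beating_rate"))
    expect_lt(mat[[nm]], imm[[nm]])
  # the calibrated strong separations: > 1.5 within-class SD on the
  # headline features
  for (nm in c("displacement", "r_rise_time", "time_01")) {
    v <- tapply(ds$table[[nm]], ds$table$class, stats::var)
    gap <- mat[[nm]] - imm[[nm]]
    expect_gt(gap / sqrt(mean(v)), 1.5)
  }
})

test_that("the intermediate preset lies between the two phenotypes component-wise", {
  pr <- default_presets()
  for (nm in cmmaturity:::VARIABLE_FIELDS) {
    lo <- min(pr$immature$params_mean[[nm]], pr$mature$params_mean[[nm]])
    hi <- max(pr$immature$params_mean[[nm]], pr$mature$params_mean[[nm]])
    expect_gte(pr$intermediate$params_mean[[nm]], lo)
    expect_lte(pr$intermediate$params_mean[[nm]], hi)
  }
})

test_that("traces survive a CSV round trip", {
  g <- generate_trace(test_params(), 5, 60, seed = 2)
  f <- tempfile(fileext = ".csv")
  write_trace(g$trace, f)
  back <- read_trace(f)
  expect_equal(back$speed_um_s, g$trace$speed_um_s, tolerance = 1e-9)
  expect_equal(back$fs, 60, tolerance = 1e-6)
  unlink(f)
})
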