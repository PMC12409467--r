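make_t01_table <- function() {
  data.frame(
    recording_id = paste0("r", 1:6),
    cell_line = c("a", "a", "a", "b", "b", "b"),
    class = "immature",
    c_time = c(0.4, 0.5, 0.4, 0.3, 0.35, 0.3),
    r_time = c(0.6, 0.7, 0.6, 0.5, 0.55, 0.5),
    time_01 = c(NA, 1.4, 1.2, NA, 1.1, 1.0),
    plateau_time = c(0.2, 0.2, 0.2, 0.1, 0.3, 0.2)
  )
}

test_that("beating duration is imputed as c_time + r_time + line mean plateau", {
  tab <- make_t01_table()
  out <- impute_time_01(tab)
  expect_equal(out$time_01[1], 0.4 + 0.6 + 0.2)     # line a mean plateau 0.2
  expect_equal(out$time_01[4], 0.3 + 0.5 + 0.2)     # line b mean of {0.1,0.3,0.2}
  # non-missing rows and row count untouched
  expect_identical(out$time_01[c(2, 3, 5, 6)], tab$time_01[c(2, 3, 5, 6)])
  expect_identical(nrow(out), nrow(tab))
})

test_that("a table without missing values is returned identically", {
  tab <- make_t01_table()
  tab$time_01 <- 1
  expect_identical(impute_time_01(tab), tab)
})

test_that("a line with no plateau information is reported by name", {
  tab <- make_t01_table()
  tab$plateau_time[tab$cell_line == "b"] <- NA
  expect_error(impute_time_01(tab), "b")
})

test_that("z-normalization standardizes with sample SD and round-trips stats", {
  tab <- test_table(20)
  zn <- znormalize(tab)
  for (nm in cmmaturity:::FEATURE_NAMES) {
    expect_equal(mean(zn$table[[nm]]), 0, tolerance = 1e-12)
    expect_equal(stats::sd(zn$table[[nm]]), 1, tolerance = 1e-12)
  }
  # {1,2,3} -> {-1,0,1} under the sample-SD convention
  small <- tab[1:3, ]
  small$max_c <- c(1, 2, 3)
  expect_equal(znormalize(small)$table$max_c, c(-1, 0, 1))
  # identity stats are the identity; refitting is not
  id_stats <- list(
    mean = stats::setNames(rep(0, 10), cmmaturity:::FEATURE_NAMES),
    sd = stats::setNames(rep(1, 10), cmmaturity:::FEATURE_NAMES))
  expect_equal(znormalize(tab, id_stats)$table, tab)
})

test_that("training statistics applied to a shifted test set leave the expected mean", {
  tab <- test_table(20)
  zn <- znormalize(tab)
  shifted <- tab
  shifted$max_c <- shifted$max_c + 2
  out <- znormalize(shifted, zn$stats)$table
  expect_equal(mean(out$max_c), 2 / zn$stats$sd[["max_c"]],
               tolerance = 1e-10)
})

test_that("zero-variance features are rejected by name", {
  tab <- test_table(10)
  tab$r_time <- 1
  expect_error(znormalize(tab), "r_time")
})

test_that("feature tables and normalization stats survive a file round trip", {
  tab <- test_table(8)
  f <- tempfile(fileext = ".csv")
  write_feature_table(tab, f)
  back <- read_feature_table(f)
  expect_equal(back$max_c, tab$max_c)
  expect_identical(names(back)[1:3], c("recording_id", "cell_line", "class"))
  zn <- znormalize(tab)
  sf <- tempfile(fileext = ".json")
  write_norm_stats(zn$stats, sf)
  expect_equal(read_norm_stats(sf), zn$stats, tolerance = 1e-12)
  unlink(c(f, sf))
})
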