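test_that("noise-free cycles are found with landmarks within one sample of truth", {
  p <- test_params()
  g <- generate_trace(p, 25, 60, seed = 7)
  cyc <- detect_beats(g$trace)
  truth <- g$annotation$cycles
  expect_identical(nrow(cyc), nrow(truth))
  for (nm in c("c_start", "c_peak", "c_end", "r_start", "r_peak", "r_end"))
    expect_true(all(abs(cyc[[nm]] - truth[[nm]]) <= 1L),
                info = nm)
})

test_that("an all-zero trace yields no cycles, not an error", {
  tr <- motion_trace((0:599) / 60, rep(0, 600), 60)
  expect_identical(nrow(detect_beats(tr)), 0L)
})

test_that("a trace truncated mid-relaxation drops the partial last cycle", {
  p <- test_params(rate_jitter_cv = 0)
  g <- generate_trace(p, 25, 60)
  full <- detect_beats(g$trace)
  # cut inside the last relaxation pulse
  cut <- full$r_peak[nrow(full)]
  tr2 <- motion_trace(g$trace$time_s[1:cut], g$trace$speed_um_s[1:cut], 60)
  part <- detect_beats(tr2)
  expect_identical(nrow(part), nrow(full) - 1L)
})

test_that("landmark ordering invariants hold on noisy traces", {
  p <- test_params(noise_sd = 1.2)
  for (s in 1:5) {
    g <- generate_trace(p, 25, 60, seed = s)
    cyc <- detect_beats(g$trace)
    expect_gt(nrow(cyc), 0)
    expect_true(all(cyc$c_start < cyc$c_peak & cyc$c_peak < cyc$c_end &
                      cyc$c_end <= cyc$r_start & cyc$r_start < cyc$r_peak &
                      cyc$r_peak < cyc$r_end))
  }
})

test_that("extracted features obey the feature-vector order invariants", {
  p <- test_params(noise_sd = 1.0)
  for (s in 1:5) {
    g <- generate_trace(p, 25, 60, seed = s)
    f <- extract_features(g$trace, detect_beats(g$trace))
    expect_true(all(unlist(f[cmmaturity:::FEATURE_NAMES]) >= 0))
    expect_lte(f$c_rise_time, f$c_time)
    expect_lte(f$r_rise_time, f$r_time)
    expect_gte(f$time_01, f$c_time + f$r_time)
  }
})

test_that("features are recovered within 2% on noise-free traces", {
  presets <- default_presets()
  for (lab in c("immature", "mature")) {
    p <- presets[[lab]]$params_mean
    p$noise_sd <- 0
    for (s in 1:10) {
      g <- generate_trace(p, 25, 60, seed = s)
      f <- extract_features(g$trace, detect_beats(g$trace))
      rel <- abs(unlist(f[cmmaturity:::FEATURE_NAMES]) -
                   g$annotation$features) / g$annotation$features
      expect_lt(max(rel), 0.02)
    }
  }
})

test_that("a single detected cycle yields no beating rate but all other features", {
  p <- test_params(rate_jitter_cv = 0)
  g <- generate_trace(p, 25, 60)
  cyc <- detect_beats(g$trace)[1, ]
  f <- extract_features(g$trace, cyc)
  expect_true(is.na(f$beating_rate))
  expect_true(all(is.finite(unlist(
    f[setdiff(cmmaturity:::FEATURE_NAMES, "beating_rate")]))))
})

test_that("extract_features rejects an empty cycle set and supports index-only cycles", {
  p <- test_params()
  g <- generate_trace(p, 25, 60)
  expect_error(extract_features(g$trace, data.frame()), "at least one")
  # plain integer landmarks (no refined times): grid-resolution features
  cyc <- g$annotation$cycles[
    c("c_start", "c_peak", "c_end", "r_start", "r_peak", "r_end")]
  f <- extract_features(g$trace, cyc)
  expect_equal(f$c_time, g$annotation$features[["c_time"]],
               tolerance = 0.05)
})
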