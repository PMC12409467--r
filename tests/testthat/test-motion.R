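test_that("matching a frame against itself gives zero displacement everywhere", {
  A <- withr::with_seed(1, matrix(stats::runif(64 * 64), 64))
  mf <- block_match(A, A)
  expect_true(all(mf$dx == 0 & mf$dy == 0))
  expect_true(all(mf$score == 0))
})

test_that("a pure translation is recovered on interior blocks", {
  A <- withr::with_seed(2, matrix(stats::runif(64 * 64), 64))
  B <- A * 0
  B[, 4:64] <- A[, 1:61]                      # content moved right by 3
  mf <- block_match(A, B)
  expect_true(all(mf$dx == 3 & mf$dy == 0))
})

test_that("displacements are clamped to the search radius", {
  # smooth texture: SAD decreases monotonically toward the true shift, so
  # an out-of-window shift of 9 px resolves to the window boundary
  A <- withr::with_seed(3, cmmaturity:::moving_average_2d(
    matrix(stats::runif(80 * 80), 80), 5))
  B <- A * 0
  B[, 10:80] <- A[, 1:71]                     # true shift 9 > max_shift 7
  mf <- block_match(A, B)
  expect_true(all(abs(mf$dx) <= 7 & abs(mf$dy) <= 7))
  expect_true(all(mf$dx == 7))                # lands on the search boundary
})

test_that("block_match equals the brute-force exhaustive SAD oracle", {
  cfg <- block_match_config(block_width_px = 8, max_shift_px = 4)
  for (s in 1:8) {
    dims <- withr::with_seed(100 + s, sample(32:64, 2))
    A <- withr::with_seed(s, matrix(stats::runif(prod(dims)), dims[1]))
    B <- withr::with_seed(s + 50, {
      b <- A + matrix(stats::rnorm(prod(dims), 0, 0.1), dims[1])
      dy <- sample(-3:3, 1); dx <- sample(-3:3, 1)
      br <- b * 0
      src_r <- max(1, 1 - dy):min(dims[1], dims[1] - dy)
      src_c <- max(1, 1 - dx):min(dims[2], dims[2] - dx)
      br[src_r + dy, src_c + dx] <- b[src_r, src_c]
      br
    })
    got <- block_match(A, B, cfg)
    got <- got[order(got$row, got$col), ]
    ref <- brute_force_block_match(A, B, cfg)
    ref <- ref[order(ref$row, ref$col), ]
    expect_equal(got$score, ref$score, tolerance = 1e-9)
    expect_identical(got$dx, ref$dx)
    expect_identical(got$dy, ref$dy)
  }
})

test_that("frame geometry errors are rejected", {
  A <- matrix(0, 20, 20)
  expect_error(block_match(A, matrix(0, 21, 20)), "identical dimensions")
  expect_error(block_match(matrix(0, 8, 8), matrix(0, 8, 8),
                           block_match_config()), "smaller than one block")
  expect_error(block_match_config(max_shift_px = 16), "max_shift_px")
})

test_that("a static video yields an identically zero trace with the physical metadata", {
  frames <- array(rep(withr::with_seed(4, matrix(stats::runif(64^2), 64)),
                      each = 1), c(64, 64, 8))
  frames <- aperm(frames, c(3, 1, 2))
  v <- video_stack(frames * 255)
  tr <- compute_motion_trace(v)
  expect_true(all(tr$speed_um_s == 0))
  expect_equal(tr$metadata$block_width_um, 10.4)
  expect_equal(tr$metadata$max_shift_um, 4.55)
  expect_identical(length(tr$time_s), 8L - 4L)
})

test_that("a constant 1 px / 4 frames drift reads out as 9.75 um/s", {
  canvas <- withr::with_seed(5, matrix(stats::runif(120 * 200), 120))
  n <- 24
  frames <- array(0, c(n, 96, 96))
  for (t in seq_len(n)) {
    o <- (t - 1) %/% 4                       # 1 px every 4 frames
    frames[t, , ] <- canvas[10 + seq_len(96), 10 + o + seq_len(96)]
  }
  tr <- compute_motion_trace(video_stack(frames * 255))
  expect_true(all(abs(tr$speed_um_s - 1 * 0.65 * 60 / 4) < 1e-9))
})

test_that("doubling the spatial resolution exactly doubles reported speeds", {
  p <- test_params(max_r = 9.12, r_time = 0.5526, r_rise_time = 0.22,
                   rate_jitter_cv = 0)
  g <- generate_trace(p, 3, 60)
  gv <- generate_video(g$trace, 96, texture_seed = 6,
                       annotation = g$annotation)
  t1 <- compute_motion_trace(gv$video, block_match_config())
  t2 <- compute_motion_trace(gv$video,
                             block_match_config(resolution_um_per_px = 1.3))
  expect_equal(t2$speed_um_s, 2 * t1$speed_um_s)
})

test_that("brightness adjustment follows the gain-and-clip rule", {
  frames <- array(128, c(2, 32, 32))
  v <- video_stack(frames)
  expect_identical(adjust_brightness(v, 1)$frames, v$frames)
  expect_true(all(adjust_brightness(v, 2)$frames == 255))
  v2 <- video_stack(array(60, c(2, 32, 32)))
  expect_true(all(adjust_brightness(v2, 2)$frames == 120))
  expect_error(adjust_brightness(v, 0), "positive")
})

test_that("increasing brightness does not lengthen the extracted contraction-rise time", {
  p <- test_params(max_c = 14, max_r = 9.8, r_time = 0.6,
                   c_time = 0.42, r_rise_time = 0.24,
                   plateau_time = 0.18, rate_jitter_cv = 0)
  g <- generate_trace(p, 6, 60)
  gv <- generate_video(g$trace, 96, texture_seed = 8,
                       annotation = g$annotation)
  crise <- vapply(c(1, 1.6, 2.4), function(gain) {
    tr <- compute_motion_trace(gv$video,
                               block_match_config(brightness_gain = gain))
    cyc <- detect_beats(tr)
    if (nrow(cyc) == 0) return(NA_real_)
    extract_features(tr, cyc)$c_rise_time
  }, numeric(1))
  crise <- crise[!is.na(crise)]
  expect_true(all(diff(crise) <= 1e-9 + 1e-6))
})
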