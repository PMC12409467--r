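#' Block-matching configuration
#'
#' Acquisition and analysis parameters of the exhaustive block-matching
#' motion estimator. The defaults correspond to a 0.65 um/pixel, 60
#' frames/s phase-contrast recording analysed with 16-pixel blocks
#' (10.4 um), a maximum shift of 7 pixels (4.55 um) and a frame offset of
#' 4 frames. Note the frame offset is specified in frames; the implied
#' interval in milliseconds (1000 * frame_offset / fs) is recorded in the
#' metadata of every trace computed with the configuration.
#'
#' @param block_width_px Block width, pixels (default 16).
#' @param max_shift_px Maximum search shift, pixels (default 7; must be
#'   smaller than the block width).
#' @param frame_offset_frames Frame offset between matched frames (default 4).
#' @param resolution_um_per_px Spatial resolution, um/pixel (default 0.65).
#' @param fs Frame rate, frames/s (default 60).
#' @param brightness_gain Multiplicative intensity gain applied before
#'   matching (default 1).
#' @return An object of class `block_match_config`.
#' @export
block_match_config <- function(block_width_px = 16L, max_shift_px = 7L,
                               frame_offset_frames = 4L,
                               resolution_um_per_px = 0.65, fs = 60,
                               brightness_gain = 1) {
  assert_scalar_number(block_width_px, "block_width_px", 2)
  assert_scalar_number(max_shift_px, "max_shift_px", 1)
  if (max_shift_px >= block_width_px)
    stop_("max_shift_px (%g) must be < block_width_px (%g)",
          max_shift_px, block_width_px)
  assert_scalar_number(frame_offset_frames, "frame_offset_frames", 1)
  assert_scalar_number(resolution_um_per_px, "resolution_um_per_px", 0,
                       strict_lower = TRUE)
  assert_scalar_number(fs, "fs", 0, strict_lower = TRUE)
  assert_scalar_number(brightness_gain, "brightness_gain", 0,
                       strict_lower = TRUE)
  structure(
    list(block_width_px = as.integer(block_width_px),
         max_shift_px = as.integer(max_shift_px),
         frame_offset_frames = as.integer(frame_offset_frames),
         resolution_um_per_px = resolution_um_per_px, fs = fs,
         brightness_gain = brightness_gain),
    class = "block_match_config"
  )
}

#' Construct a grayscale video stack
#'
#' @param frames 3-D numeric array, time x height x width.
#' @param resolution_um_per_px Spatial resolution, um/pixel.
#' @param fs Frame rate, frames/s.
#' @param bit_depth Intensity bit depth (default 8; intensities must lie in
#'   `[0, 2^bit_depth - 1]`).
#' @return An object of class `video_stack`.
#' @export
video_stack <- function(frames, resolution_um_per_px = 0.65, fs = 60,
                        bit_depth = 8L) {
  if (length(dim(frames)) != 3L)
    stop_("frames must be a 3-D array (time x height x width)")
  if (dim(frames)[1L] < 2L) stop_("a video needs at least 2 frames")
  vmax <- 2^bit_depth - 1
  if (min(frames) < 0 || max(frames) > vmax)
    stop_("intensities must lie within [0, %g] for bit depth %d",
          vmax, bit_depth)
  structure(
    list(frames = frames, resolution_um_per_px = resolution_um_per_px,
         fs = fs, bit_depth = as.integer(bit_depth)),
    class = "video_stack"
  )
}

#' @export
print.video_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("Video stack: %d frames of %d x %d px (%.3g um/px, %g fps)\n",
              d[1L], d[2L], d[3L], x$resolution_um_per_px, x$fs))
  invisible(x)
}

#' Adjust the brightness of a video stack
#'
#' Scales intensities by `gain` and clips to the declared bit-depth range,
#' the digital equivalent of the brightness adjustment offered by
#' interactive motion-analysis software before matching.
#'
#' @param video A [video_stack()].
#' @param gain Multiplicative gain (> 0).
#' @return A [video_stack()] of identical dimensions.
#' @export
adjust_brightness <- function(video, gain) {
  stopifnot(inherits(video, "video_stack"))
  if (!is.numeric(gain) || length(gain) != 1L || !is.finite(gain) ||
        gain <= 0)
    stop_("gain must be a single positive number")
  vmax <- 2^video$bit_depth - 1
  out <- video
  out$frames <- pmin(pmax(video$frames * gain, 0), vmax)
  out
}

#' Estimate the motion field between two frames by exhaustive block matching
#'
#' Tiles `frame_a` with non-overlapping blocks anchored at the top-left
#' corner and, for each block whose full search window lies inside the
#' frame, finds the integer shift within `+/- max_shift_px` minimizing the
#' sum of absolute differences (SAD) against `frame_b`. Ties are broken
#' towards the smallest shift magnitude, then in row-major order of the
#' search enumeration, biasing ambiguous matches towards zero motion.
#'
#' @param frame_a,frame_b Numeric matrices of identical dimensions.
#' @param config A [block_match_config()].
#' @return A data frame of class `motion_field`: block indices (`bi`, `bj`),
#'   top-left corner (`row`, `col`), integer displacement (`dy`, `dx`) and
#'   SAD `score`.
#' @export
block_match <- function(frame_a, frame_b, config = block_match_config()) {
  stopifnot(inherits(config, "block_match_config"))
  if (!is.matrix(frame_a) || !is.matrix(frame_b))
    stop_("frames must be matrices")
  if (!all(dim(frame_a) == dim(frame_b)))
    stop_("frames must have identical dimensions")
  bw <- config$block_width_px
  ms <- config$max_shift_px
  h <- nrow(frame_a); w <- ncol(frame_a)
  if (h < bw || w < bw)
    stop_("frame (%d x %d) is smaller than one block (%d px)", h, w, bw)

  # block grid anchored at (1, 1); keep blocks whose search window stays
  # inside the frame
  r0 <- seq(1L, h - bw + 1L, by = bw)
  c0 <- seq(1L, w - bw + 1L, by = bw)
  r0 <- r0[r0 - ms >= 1L & r0 + bw - 1L + ms <= h]
  c0 <- c0[c0 - ms >= 1L & c0 + bw - 1L + ms <= w]
  if (!length(r0) || !length(c0))
    stop_("no block has a complete +/-%d px search window inside a %d x %d frame",
          ms, h, w)
  nbr <- length(r0); nbc <- length(c0)
  nb <- nbr * nbc

  # shift enumeration ordered by (magnitude, dy, dx): with strict
  # improvement this realizes the tie rule
  shifts <- expand.grid(dx = -ms:ms, dy = -ms:ms)
  shifts <- shifts[order(shifts$dx^2 + shifts$dy^2, shifts$dy, shifts$dx), ]

  # per-shift SAD for all blocks at once: abs-difference image, then block
  # sums via indicator matrices
  Ri <- matrix(0, h, nbr); Ci <- matrix(0, w, nbc)
  for (i in seq_len(nbr)) Ri[r0[i]:(r0[i] + bw - 1L), i] <- 1
  for (j in seq_len(nbc)) Ci[c0[j]:(c0[j] + bw - 1L), j] <- 1
  best <- matrix(Inf, nbr, nbc)
  bdy <- matrix(0L, nbr, nbc); bdx <- matrix(0L, nbr, nbc)
  for (k in seq_len(nrow(shifts))) {
    dy <- shifts$dy[k]; dx <- shifts$dx[k]
    # frame_b shifted so that index (r, c) holds frame_b[r + dy, c + dx]
    bsh <- frame_b[(1L + max(dy, 0)):(h + min(dy, 0)),
                   (1L + max(dx, 0)):(w + min(dx, 0)), drop = FALSE]
    ad <- matrix(0, h, w)
    ad[(1L - min(dy, 0)):(h - max(dy, 0)),
       (1L - min(dx, 0)):(w - max(dx, 0))] <-
      abs(frame_a[(1L - min(dy, 0)):(h - max(dy, 0)),
                  (1L - min(dx, 0)):(w - max(dx, 0)), drop = FALSE] - bsh)
    sad <- t(Ri) %*% ad %*% Ci
    upd <- sad < best
    best[upd] <- sad[upd]
    bdy[upd] <- dy; bdx[upd] <- dx
  }
  out <- data.frame(
    bi = rep(seq_len(nbr), times = nbc),
    bj = rep(seq_len(nbc), each = nbr),
    row = rep(r0, times = nbc),
    col = rep(c0, each = nbr),
    dy = as.vector(bdy), dx = as.vector(bdx),
    score = as.vector(best)
  )
  class(out) <- c("motion_field", "data.frame")
  out
}

#' Compute a motion-speed trace from a video by block matching
#'
#' Applies the brightness gain, then matches frame `t` against frame
#' `t + frame_offset_frames` for every valid `t` and converts the spatial
#' mean of the block displacement magnitudes to a speed in um/s:
#' `speed = mean(|d|) * resolution * fs / frame_offset`. Averaging
#' magnitudes (not the mean vector) prevents opposing local motions from
#' cancelling.
#'
#' @param video A [video_stack()].
#' @param config A [block_match_config()].
#' @return A [motion_trace()] whose metadata records the configuration, the
#'   physical block width (`block_width_um`) and the implied frame-offset
#'   interval in ms.
#' @export
compute_motion_trace <- function(video, config = block_match_config()) {
  stopifnot(inherits(video, "video_stack"), inherits(config, "block_match_config"))
  off <- config$frame_offset_frames
  nf <- dim(video$frames)[1L]
  if (nf <= off)
    stop_("video has %d frames; need more than the frame offset (%d)",
          nf, off)
  if (config$brightness_gain != 1)
    video <- adjust_brightness(video, config$brightness_gain)
  n_out <- nf - off
  speed <- numeric(n_out)
  for (t in seq_len(n_out)) {
    mf <- block_match(video$frames[t, , ], video$frames[t + off, , ], config)
    mag <- sqrt(mf$dx^2 + mf$dy^2)
    speed[t] <- mean(mag) * config$resolution_um_per_px * config$fs / off
  }
  motion_trace(
    (seq_len(n_out) - 1L) / config$fs, speed, config$fs,
    metadata = list(
      config = unclass(config),
      block_width_um = config$block_width_px * config$resolution_um_per_px,
      max_shift_um = config$max_shift_px * config$resolution_um_per_px,
      frame_offset_ms = 1000 * config$frame_offset_frames / config$fs,
      n_frames = nf
    )
  )
}

#' Read or write a video stack as multi-page TIFF
#'
#' Grayscale; color pages are converted by the BT.601 luma weights.
#' Requires the `tiff` package.
#'
#' @param video A [video_stack()].
#' @param path File path.
#' @param resolution_um_per_px,fs Acquisition metadata to attach on read.
#' @return `write_video_tiff()` returns `path` invisibly;
#'   `read_video_tiff()` a [video_stack()].
#' @export
write_video_tiff <- function(video, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop_("the 'tiff' package is required to write TIFF videos")
  vmax <- 2^video$bit_depth - 1
  pages <- lapply(seq_len(dim(video$frames)[1L]), function(t)
    video$frames[t, , ] / vmax)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_video_tiff
#' @export
read_video_tiff <- function(path, resolution_um_per_px = 0.65, fs = 60) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop_("the 'tiff' package is required to read TIFF videos")
  pages <- tiff::readTIFF(path, all = TRUE)
  to_gray <- function(p) {
    if (length(dim(p)) == 3L)
      p <- 0.299 * p[, , 1L] + 0.587 * p[, , 2L] + 0.114 * p[, , 3L]
    p
  }
  pages <- lapply(pages, to_gray)
  frames <- array(0, c(length(pages), nrow(pages[[1L]]), ncol(pages[[1L]])))
  for (t in seq_along(pages)) frames[t, , ] <- pages[[t]] * 255
  video_stack(frames, resolution_um_per_px, fs, bit_depth = 8L)
}
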