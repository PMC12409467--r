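#' Render a synthetic beating video from a motion trace
#'
#' Builds a band-limited random texture on a canvas larger than the frame
#' and crops a window that slides along one axis according to the
#' integer-rounded cumulative displacement implied by the motion trace.
#' During the contraction phase the window moves forward, during
#' relaxation it moves back (displacement is the time integral of signed
#' speed). Displacement is rendered in whole pixels only, so the emitted
#' per-frame ground truth is exact for block matching.
#'
#' The signed velocity is derived from the trace and its annotation when
#' supplied (contraction positive, relaxation negative); without an
#' annotation the speed is integrated with alternating sign at each
#' zero-speed gap, which reproduces the contraction/relaxation alternation
#' of traces generated by [generate_trace()].
#'
#' @param trace A [motion_trace()].
#' @param frame_size_px Frame side length, pixels (square frames).
#' @param texture_seed Integer seed for the random texture.
#' @param annotation Optional annotation from [generate_trace()] used to
#'   sign the speed by phase.
#' @param config A [block_match_config()] supplying the resolution and the
#'   bit depth context; the frame must be at least 4 block widths wide.
#' @param axis `"x"` or `"y"`: the motion axis.
#' @return A list: `video` (a [video_stack()]), `displacement_px` (integer
#'   per-frame ground-truth displacement along the axis), `velocity_px`
#'   (unrounded displacement).
#' @export
generate_video <- function(trace, frame_size_px = 96L, texture_seed = 1L,
                           annotation = NULL,
                           config = block_match_config(),
                           axis = c("x", "y")) {
  stopifnot(inherits(trace, "motion_trace"))
  axis <- match.arg(axis)
  if (frame_size_px < 4L * config$block_width_px)
    stop_("frame_size_px (%d) must be at least 4 block widths (%d px)",
          frame_size_px, 4L * config$block_width_px)

  speed <- trace$speed_um_s
  n <- length(speed)
  sign_vec <- signed_phase(trace, annotation)
  # cumulative displacement in pixels (displacement = integral of velocity)
  vel_px <- cumsum(sign_vec * speed / trace$fs) / config$resolution_um_per_px
  disp_px <- as.integer(round(vel_px))
  margin <- max(abs(disp_px)) + config$max_shift_px + 1L
  if (margin > frame_size_px)
    stop_(paste0("implied displacement (%d px) exceeds the frame margin; ",
                 "use a larger frame or a lower-amplitude trace"),
          max(abs(disp_px)))

  canvas <- withr::with_seed(texture_seed, {
    big <- matrix(stats::runif((frame_size_px + 2L * margin)^2),
                  frame_size_px + 2L * margin)
    sm <- moving_average_2d(big, 3L)
    # normalize to mid-range 8-bit intensities with headroom
    lo <- min(sm); hi <- max(sm)
    40 + (sm - lo) / (hi - lo) * 150
  })

  frames <- array(0, c(n, frame_size_px, frame_size_px))
  for (t in seq_len(n)) {
    o <- disp_px[t]
    if (axis == "x") {
      frames[t, , ] <- canvas[margin + seq_len(frame_size_px),
                              margin + o + seq_len(frame_size_px)]
    } else {
      frames[t, , ] <- canvas[margin + o + seq_len(frame_size_px),
                              margin + seq_len(frame_size_px)]
    }
  }
  list(
    video = video_stack(frames, config$resolution_um_per_px, trace$fs),
    displacement_px = disp_px,
    velocity_px = vel_px
  )
}

# Sign of the tissue velocity per sample: +1 in contraction, -1 in
# relaxation. With an annotation the phases are taken from it; otherwise
# active segments (speed > 0) alternate sign.
signed_phase <- function(trace, annotation) {
  n <- length(trace$speed_um_s)
  sgn <- numeric(n)
  if (!is.null(annotation)) {
    cyc <- annotation$cycles
    for (k in seq_len(nrow(cyc))) {
      sgn[cyc$c_start[k]:cyc$c_end[k]] <- 1
      sgn[cyc$r_start[k]:cyc$r_end[k]] <- -1
    }
  } else {
    active <- trace$speed_um_s > 1e-12
    r <- rle(active)
    sign_next <- 1
    pos <- 1L
    for (i in seq_along(r$lengths)) {
      if (r$values[i]) {
        sgn[pos:(pos + r$lengths[i] - 1L)] <- sign_next
        sign_next <- -sign_next
      }
      pos <- pos + r$lengths[i]
    }
  }
  sgn
}

# Separable moving-average blur with reflected edges (band-limits a white
# noise texture so block matching has structure at the block scale).
moving_average_2d <- function(x, w) {
  for (pass in 1:2) {
    x <- apply(x, 2L, moving_average, w = w)
    x <- t(apply(x, 1L, moving_average, w = w))
  }
  x
}
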