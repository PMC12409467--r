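#' Beat waveform parameters
#'
#' Parameter set describing the motion-speed morphology of a single beating
#' cycle of a cardiomyocyte monolayer: a contraction speed pulse, a plateau
#' with no motion, and a relaxation speed pulse. Speed lobes are raised-cosine
#' (Hann) by default; a triangular option gives closed-form feature values
#' that are convenient for analytic checks.
#'
#' @param beating_rate Spontaneous beating rate, beats/min.
#' @param max_c Peak contraction speed, um/s.
#' @param max_r Peak relaxation speed, um/s.
#' @param c_rise_time Contraction onset-to-peak duration, s.
#' @param c_time Total contraction duration, s.
#' @param r_rise_time Relaxation onset-to-peak duration, s.
#' @param r_time Total relaxation duration, s.
#' @param plateau_time Gap between contraction end and relaxation start, s.
#' @param noise_sd Standard deviation of additive Gaussian speed noise, um/s.
#'   The generated speed is clipped at zero, as a rectified speed signal is.
#' @param rate_jitter_cv Coefficient of variation of the cycle-to-cycle
#'   period (dimensionless).
#' @param shape_q Pulse fullness exponent (default 1): the speed lobe is
#'   the base pulse raised to `shape_q`, so values below 1 give fuller
#'   (more sustained) waveforms with a larger area for the same peak and
#'   duration, and values above 1 give spikier ones. This is the waveform
#'   property that lets the per-beat displacement vary independently of
#'   peak speed and duration.
#' @param pulse_shape `"hann"` (default) or `"triangular"`.
#' @return An object of class `beat_waveform_params`.
#' @export
beat_waveform_params <- function(beating_rate, max_c, max_r,
                                 c_rise_time, c_time,
                                 r_rise_time, r_time,
                                 plateau_time,
                                 noise_sd = 0, rate_jitter_cv = 0,
                                 shape_q = 1,
                                 pulse_shape = c("hann", "triangular")) {
  pulse_shape <- match.arg(pulse_shape)
  assert_scalar_number(shape_q, "shape_q", 0.2, 5)
  assert_scalar_number(beating_rate, "beating_rate", 0, strict_lower = TRUE)
  assert_scalar_number(max_c, "max_c", 0, strict_lower = TRUE)
  assert_scalar_number(max_r, "max_r", 0, strict_lower = TRUE)
  for (nm in c("c_rise_time", "c_time", "r_rise_time", "r_time",
               "plateau_time")) {
    assert_scalar_number(get(nm), nm, 0, strict_lower = nm != "plateau_time")
  }
  assert_scalar_number(noise_sd, "noise_sd", 0)
  assert_scalar_number(rate_jitter_cv, "rate_jitter_cv", 0)
  if (c_rise_time >= c_time)
    stop_("c_rise_time (%g) must be < c_time (%g)", c_rise_time, c_time)
  if (r_rise_time >= r_time)
    stop_("r_rise_time (%g) must be < r_time (%g)", r_rise_time, r_time)
  period <- 60 / beating_rate
  active <- c_time + plateau_time + r_time
  if (active >= period)
    stop_(paste0("beating cycle (c_time + plateau_time + r_time = %.3f s) ",
                 "must be shorter than the beat period (60/beating_rate = ",
                 "%.3f s)"), active, period)
  structure(
    list(beating_rate = beating_rate, max_c = max_c, max_r = max_r,
         c_rise_time = c_rise_time, c_time = c_time,
         r_rise_time = r_rise_time, r_time = r_time,
         plateau_time = plateau_time, noise_sd = noise_sd,
         rate_jitter_cv = rate_jitter_cv, shape_q = shape_q,
         pulse_shape = pulse_shape),
    class = "beat_waveform_params"
  )
}

#' @export
print.beat_waveform_params <- function(x, ...) {
  cat("Beat waveform parameters (", x$pulse_shape, " pulses)\n", sep = "")
  cat(sprintf("  rate %.1f bpm | contraction %.1f um/s peak, %.3g s (rise %.3g s)\n",
              x$beating_rate, x$max_c, x$c_time, x$c_rise_time))
  cat(sprintf("  plateau %.3g s | relaxation %.1f um/s peak, %.3g s (rise %.3g s)\n",
              x$plateau_time, x$max_r, x$r_time, x$r_rise_time))
  cat(sprintf("  noise sd %.3g um/s | period jitter CV %.3g\n",
              x$noise_sd, x$rate_jitter_cv))
  invisible(x)
}

# Speed of one unimodal pulse at time u after pulse onset, raised to the
# fullness exponent q. Hann: two half-cosine lobes joined at the peak;
# triangular: two linear ramps. Analytic areas: amp * duration * B with
# B = gamma(q + 1/2) / (sqrt(pi) gamma(q + 1)) for the raised-cosine lobe
# and B = 1 / (q + 1) for the triangle (both 1/2 at q = 1).
pulse_speed <- function(u, amp, rise, duration, shape, q = 1) {
  v <- numeric(length(u))
  fall <- duration - rise
  up <- u >= 0 & u <= rise
  dn <- u > rise & u <= duration
  if (shape == "hann") {
    v[up] <- 0.5 * (1 - cos(pi * u[up] / rise))
    v[dn] <- 0.5 * (1 + cos(pi * (u[dn] - rise) / fall))
  } else {
    v[up] <- u[up] / rise
    v[dn] <- 1 - (u[dn] - rise) / fall
  }
  if (q != 1) v <- v^q
  amp * v
}

# Area of a unit-peak, unit-duration pulse with fullness exponent q.
pulse_area_factor <- function(shape, q) {
  if (shape == "hann") exp(lgamma(q + 0.5) - lgamma(q + 1)) / sqrt(pi)
  else 1 / (q + 1)
}

#' Construct a motion-speed trace object
#'
#' A uniformly sampled time series of spatially averaged tissue motion speed,
#' with acquisition metadata. This container is shared by the synthetic
#' generator and the block-matching motion analysis.
#'
#' @param time_s Sample times, s (uniform grid).
#' @param speed_um_s Motion speed, um/s (non-negative).
#' @param fs Sampling rate, frames/s.
#' @param metadata Named list of provenance (acquisition and analysis
#'   parameters).
#' @return An object of class `motion_trace`.
#' @export
motion_trace <- function(time_s, speed_um_s, fs, metadata = list()) {
  if (length(time_s) != length(speed_um_s))
    stop_("time_s and speed_um_s must have equal length")
  if (length(time_s) >= 2L) {
    dt <- diff(time_s)
    if (max(abs(dt - dt[1L])) > 1e-9 * max(dt[1L], 1e-12))
      stop_("motion trace requires a uniform time grid")
  }
  if (any(speed_um_s < -1e-9))
    stop_("motion speed must be non-negative")
  structure(
    list(time_s = as.numeric(time_s),
         speed_um_s = pmax(as.numeric(speed_um_s), 0),
         fs = fs, metadata = metadata),
    class = "motion_trace"
  )
}

#' @export
print.motion_trace <- function(x, ...) {
  cat(sprintf("Motion trace: %d samples at %.5g frames/s (%.4g s)\n",
              length(x$time_s), x$fs,
              if (length(x$time_s)) max(x$time_s) else 0))
  cat(sprintf("  speed range %.3g-%.3g um/s\n",
              min(x$speed_um_s), max(x$speed_um_s)))
  invisible(x)
}

#' Generate a synthetic beating motion-speed trace with ground truth
#'
#' Synthesizes the motion-speed signal of a spontaneously beating
#' cardiomyocyte monolayer: per cycle, a contraction speed pulse, a zero-speed
#' plateau and a relaxation speed pulse, with optional cycle-period jitter and
#' additive rectified Gaussian noise. Alongside the trace, an annotation
#' records the true phase landmarks of every complete cycle and the true
#' values of the ten beating features, so downstream beat detection and
#' feature extraction can be validated against exact ground truth.
#'
#' @param params A [beat_waveform_params()] object.
#' @param duration_s Trace duration, s.
#' @param fs Sampling rate, frames/s.
#' @param seed Integer seed for noise and jitter (`NULL` for the current RNG
#'   state).
#' @return A list with elements `trace` (a [motion_trace()]) and `annotation`
#'   (list with `cycles`, a data frame of per-cycle landmark times and sample
#'   indices, and `features`, the named vector of true trace-level features;
#'   the true displacement is the analytic integral of the contraction pulse,
#'   `max_c * c_time / 2` for both pulse shapes).
#' @export
generate_trace <- function(params, duration_s, fs, seed = NULL) {
  stopifnot(inherits(params, "beat_waveform_params"))
  assert_scalar_number(duration_s, "duration_s", 0, strict_lower = TRUE)
  assert_scalar_number(fs, "fs", 0, strict_lower = TRUE)
  p <- params
  period <- 60 / p$beating_rate
  active <- p$c_time + p$plateau_time + p$r_time
  if (fs <= 2 * p$beating_rate / 60)
    stop_("fs = %g frames/s is too low to sample a %g bpm beat", fs,
          p$beating_rate)
  if (fs * min(p$c_rise_time, p$r_rise_time) < 2)
    stop_("fs = %g frames/s cannot resolve rise times of %g s", fs,
          min(p$c_rise_time, p$r_rise_time))

  gen <- function() {
    n_max <- ceiling(duration_s / (active * 1.0)) + 2L
    jitter <- if (p$rate_jitter_cv > 0) {
      pmax(pmin(stats::rnorm(n_max, 0, p$rate_jitter_cv), 3 * p$rate_jitter_cv),
           -3 * p$rate_jitter_cv)
    } else numeric(n_max)
    periods <- pmax(period * (1 + jitter), active * 1.02)
    pad <- (period - active) / 2
    starts <- pad + c(0, cumsum(periods))
    starts <- starts[starts + active <= duration_s]
    n_cyc <- length(starts)

    n <- floor(duration_s * fs)
    tgrid <- (seq_len(n) - 1L) / fs
    speed <- numeric(n)
    for (s0 in starts) {
      # contraction pulse
      i <- which(tgrid >= s0 & tgrid <= s0 + p$c_time)
      speed[i] <- speed[i] +
        pulse_speed(tgrid[i] - s0, p$max_c, p$c_rise_time, p$c_time,
                    p$pulse_shape, p$shape_q)
      # relaxation pulse
      r0 <- s0 + p$c_time + p$plateau_time
      i <- which(tgrid >= r0 & tgrid <= r0 + p$r_time)
      speed[i] <- speed[i] +
        pulse_speed(tgrid[i] - r0, p$max_r, p$r_rise_time, p$r_time,
                    p$pulse_shape, p$shape_q)
    }
    if (p$noise_sd > 0)
      speed <- pmax(speed + stats::rnorm(n, 0, p$noise_sd), 0)

    idx_of <- function(tt) pmin(pmax(round(tt * fs) + 1L, 1L), n)
    cyc <- data.frame(
      c_start_time = starts,
      c_peak_time  = starts + p$c_rise_time,
      c_end_time   = starts + p$c_time,
      r_start_time = starts + p$c_time + p$plateau_time,
      r_peak_time  = starts + p$c_time + p$plateau_time + p$r_rise_time,
      r_end_time   = starts + active
    )
    for (nm in c("c_start", "c_peak", "c_end", "r_start", "r_peak", "r_end"))
      cyc[[nm]] <- idx_of(cyc[[paste0(nm, "_time")]])
    true_rate <- if (n_cyc >= 2L)
      60 / mean(diff(cyc$c_peak_time)) else NA_real_
    feats <- c(
      max_c = p$max_c,
      c_time = p$c_time,
      max_r = p$max_r,
      r_time = p$r_time,
      cr_interval = p$c_time + p$plateau_time + p$r_rise_time - p$c_rise_time,
      time_01 = active,
      c_rise_time = p$c_rise_time,
      r_rise_time = p$r_rise_time,
      beating_rate = true_rate,
      displacement = p$max_c * p$c_time *
        pulse_area_factor(p$pulse_shape, p$shape_q)
    )
    list(
      trace = motion_trace(
        tgrid, speed, fs,
        metadata = list(source = "synthetic", params = unclass(p),
                        duration_s = duration_s, seed = seed)),
      annotation = list(cycles = cyc, features = feats,
                        plateau_time = p$plateau_time)
    )
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}
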