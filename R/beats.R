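#' Detect complete beating cycles in a motion-speed trace
#'
#' Automated stand-in for the manual landmark adjustment used with
#' interactive motion-analysis software. The trace is lightly smoothed and
#' baseline-corrected, candidate peaks above `min_peak_fraction` of the
#' global maximum are paired into contraction/relaxation pulses by their
#' alternation and relative amplitude, and each phase boundary is located by
#' walking outward from the peak to the `boundary_fraction` crossing and then
#' on to the local speed minimum at the pulse base. Peak positions are
#' refined to sub-sample precision by local quadratic interpolation, and
#' boundaries by extrapolating the square-root of the speed (linear near the
#' base of a smooth pulse) to zero.
#'
#' Only complete cycles are returned: a contraction peak followed by a
#' relaxation peak, with all six landmarks inside the trace. A trace with no
#' peak above threshold yields an empty set, not an error.
#'
#' @param trace A [motion_trace()].
#' @param min_peak_fraction Candidate peaks must exceed this fraction of the
#'   global corrected maximum (default 0.3).
#' @param boundary_fraction Fraction of the phase-peak speed at which the
#'   outward boundary search switches from thresholding to base refinement
#'   (default 0.1).
#' @return A data frame of class `beat_cycles` with one row per complete
#'   cycle: integer sample indices `c_start, c_peak, c_end, r_start, r_peak,
#'   r_end`, refined landmark times `*_time` (s), and refined peak speeds
#'   `c_peak_speed`, `r_peak_speed` (um/s).
#' @export
detect_beats <- function(trace, min_peak_fraction = 0.3,
                         boundary_fraction = 0.1) {
  stopifnot(inherits(trace, "motion_trace"))
  if (min_peak_fraction <= 0 || min_peak_fraction >= 1)
    stop_("min_peak_fraction must be in (0, 1)")
  if (boundary_fraction <= 0 || boundary_fraction >= 1)
    stop_("boundary_fraction must be in (0, 1)")
  fs <- trace$fs
  n <- length(trace$speed_um_s)
  if (n < 2 * fs)
    stop_("trace must be at least 2 s long (%d samples at %g frames/s)",
          n, fs)

  raw <- trace$speed_um_s
  # two smoothing scales: a light one that preserves pulse edges for
  # boundary placement, and a heavy one that suppresses noise maxima on
  # broad pulses for peak detection and pairing
  w1 <- max(3L, as.integer(round(fs / 12)))
  if (w1 %% 2L == 0L) w1 <- w1 + 1L
  w2 <- max(w1, as.integer(round(fs / 4)))
  if (w2 %% 2L == 0L) w2 <- w2 + 1L
  sm <- moving_average(raw, w1)
  baseline <- as.numeric(stats::quantile(sm, 0.1))
  s <- pmax(sm - baseline, 0)
  s2 <- pmax(moving_average(raw, w2) - baseline, 0)
  # intermediate scale for crossing localization: light enough to keep the
  # mid-limb shape, heavy enough that noise rarely dips across a level
  wc <- max(w1, 7L)
  if (wc %% 2L == 0L) wc <- wc + 1L
  smc <- moving_average(raw, wc)
  sc <- pmax(smc - baseline, 0)
  # leave-center-out companion: selecting limb samples by a smoothed value
  # that *contains* the sample correlates selection with the sample noise
  # and inflates values at the selection edges; removing the centre sample
  # makes selection independent of the fitted value
  sc_loo <- pmax((wc * smc - raw) / (wc - 1) - baseline, 0)

  empty <- structure(
    data.frame(c_start = integer(), c_peak = integer(), c_end = integer(),
               r_start = integer(), r_peak = integer(), r_end = integer()),
    class = c("beat_cycles", "data.frame"))
  M <- max(s2)
  if (M <= 0) return(empty)

  peaks <- find_local_maxima(s2, height = min_peak_fraction * M,
                             min_sep = max(3L, as.integer(round(0.15 * fs))))
  if (length(peaks) < 2L) return(empty)
  # re-locate each peak on the lightly smoothed trace
  h2 <- (w2 - 1L) %/% 2L
  peaks <- vapply(peaks, function(p) {
    win <- max(p - h2, 1L):min(p + h2, n)
    win[which.max(s[win])]
  }, integer(1))
  peaks <- sort(unique(peaks))

  # Pair peaks into (contraction, relaxation) pulses. Within a beating
  # cycle the contraction pulse is faster than the relaxation pulse, so a
  # local greedy rule — pair a peak with its successor when the first is
  # the larger — recovers the alternation and, unlike a global parity
  # assignment, re-synchronizes after a missed or spurious peak.
  cp <- integer(); rp <- integer()
  i <- 1L
  while (i < length(peaks)) {
    if (s[peaks[i]] >= s[peaks[i + 1L]]) {
      cp <- c(cp, peaks[i]); rp <- c(rp, peaks[i + 1L])
      i <- i + 2L
    } else i <- i + 1L                  # leading/stray relaxation peak
  }
  if (!length(cp)) return(empty)

  n_cyc <- length(cp)
  tgrid <- trace$time_s
  dt <- 1 / fs

  # Per-cycle peak estimates (sub-sample height via a curvature-corrected
  # parabola on the lightly smoothed trace; see refine_peak).
  pk_c <- lapply(cp, function(p) refine_peak(raw, sm, w1, p, tgrid))
  pk_r <- lapply(rp, function(p) refine_peak(raw, sm, w1, p, tgrid))
  # bootstrap amplitudes from the smoothed peaks (attenuated a few percent,
  # refined below by regressing on the fitted lobe shape)
  amp_c <- stats::median(s[cp]) + baseline
  amp_r <- stats::median(s[rp]) + baseline

  # Search limits per cycle: previous/next peaks and the inter-pulse valley.
  mids <- vapply(seq_len(n_cyc), function(k) {
    cp[k] + which.min(s[cp[k]:rp[k]]) - 1L
  }, integer(1))
  lo_c <- c(1L, rp[-n_cyc])
  hi_r <- c(cp[-1L], n)

  # The four limb families; beat morphology is constant within a recording,
  # so limb samples are pooled across cycles (shared slope, per-cycle
  # offset), which makes the boundary estimates robust to per-cycle noise.
  run_limb_fits <- function(vals, ac, ar) {
    list(
      cl = pooled_limb_fit(sc, sc_loo, vals, cp, -1L, lo_c,
                           boundary_fraction, ac, tgrid, dt, sigma_hat),
      cr = pooled_limb_fit(sc, sc_loo, vals, cp, +1L, mids,
                           boundary_fraction, ac, tgrid, dt, sigma_hat),
      rl = pooled_limb_fit(sc, sc_loo, vals, rp, -1L, mids,
                           boundary_fraction, ar, tgrid, dt, sigma_hat),
      rr = pooled_limb_fit(sc, sc_loo, vals, rp, +1L, hi_r,
                           boundary_fraction, ar, tgrid, dt, sigma_hat)
    )
  }
  # high-frequency noise level, estimated on actively moving samples only
  # (in the rest segments the zero-rectification compresses the noise);
  # the limb-fit selection floor must clear it so that rectified samples
  # near the pulse base cannot bias the fitted tail
  active <- s2 > 0.3 * M
  sigma_hat <- if (sum(active) > 20L) {
    stats::sd((raw - sm)[active]) / sqrt(1 - 1 / w1)
  } else stats::sd(raw - sm) / sqrt(1 - 1 / w1)

  fits <- run_limb_fits(raw, amp_c, amp_r)
  speeds_c <- vapply(pk_c, `[[`, numeric(1), "speed")
  speeds_r <- vapply(pk_r, `[[`, numeric(1), "speed")

  # Refine the amplitudes from the pulse-top samples implied by the limb
  # fits (ratio of means, unbiased because the noise is mean-zero and
  # unrectified at the top), then redo the limb fits once with them.
  for (pass in 1:2) {
    pf_c <- pulse_amplitude_fit(raw, tgrid, fits$cl, fits$cr)
    pf_r <- pulse_amplitude_fit(raw, tgrid, fits$rl, fits$rr)
    if (is.null(pf_c) || is.null(pf_r)) break
    amp_c <- pf_c$A; amp_r <- pf_r$A
    speeds_c <- rep(amp_c, n_cyc); speeds_r <- rep(amp_r, n_cyc)
    if (pass < 2) fits <- run_limb_fits(raw, amp_c, amp_r)
  }

  peak_time <- function(left, right, pk, k) {
    cands <- c(left$peak_time[k], right$peak_time[k])
    cands <- cands[is.finite(cands)]
    if (length(cands)) mean(cands) else pk[[k]]$time
  }
  clamp_idx <- function(tt, lo, hi)
    pmin(pmax(as.integer(round(tt * fs)) + 1L, lo), hi)

  cyc <- data.frame(
    c_start_time = fits$cl$boundary, c_end_time = fits$cr$boundary,
    r_start_time = fits$rl$boundary, r_end_time = fits$rr$boundary,
    c_peak_time = vapply(seq_len(n_cyc), function(k)
      peak_time(fits$cl, fits$cr, pk_c, k), numeric(1)),
    r_peak_time = vapply(seq_len(n_cyc), function(k)
      peak_time(fits$rl, fits$rr, pk_r, k), numeric(1)),
    c_peak_speed = speeds_c,
    r_peak_speed = speeds_r
  )

  # Final refinement: fit the full two-pulse model in speed space, where
  # the noise is additive Gaussian, with the exact censored-Gaussian
  # (Tobit) likelihood of the zero-rectified signal. Both pulse families
  # share one lobe-fullness exponent q (beat morphology is one waveform
  # per recording), which keeps q identifiable; the linearized limb fits
  # serve as initial values. Exact on noise-free data.
  ref <- refine_pulses(
    raw, tgrid, dt, sigma_hat,
    fam_c = list(s0 = cyc$c_start_time,
                 r0 = cyc$c_peak_time - cyc$c_start_time,
                 f0 = cyc$c_end_time - cyc$c_peak_time, A0 = amp_c),
    fam_r = list(s0 = cyc$r_start_time,
                 r0 = cyc$r_peak_time - cyc$r_start_time,
                 f0 = cyc$r_end_time - cyc$r_peak_time, A0 = amp_r))
  if (!is.null(ref)) {
    cyc$c_start_time <- ref$c$s
    cyc$c_peak_time <- ref$c$s + ref$c$r
    cyc$c_end_time <- ref$c$s + ref$c$r + ref$c$f
    cyc$c_peak_speed <- rep(ref$c$A, n_cyc)
    cyc$r_start_time <- ref$r$s
    cyc$r_peak_time <- ref$r$s + ref$r$r
    cyc$r_end_time <- ref$r$s + ref$r$r + ref$r$f
    cyc$r_peak_speed <- rep(ref$r$A, n_cyc)
  }
  cyc$c_start <- clamp_idx(cyc$c_start_time, pmax(lo_c, 1L), cp)
  cyc$c_peak <- cp
  cyc$c_end <- clamp_idx(cyc$c_end_time, cp, mids)
  cyc$r_start <- clamp_idx(cyc$r_start_time, mids, rp)
  cyc$r_peak <- rp
  cyc$r_end <- clamp_idx(cyc$r_end_time, rp, pmin(hi_r, n))
  # Enforce landmark ordering; drop cycles that violate it (noise artefacts).
  ok <- with(cyc, c_start < c_peak & c_peak < c_end & c_end <= r_start &
                  r_start < r_peak & r_peak < r_end)
  cyc <- cyc[ok, , drop = FALSE]
  rownames(cyc) <- NULL
  class(cyc) <- c("beat_cycles", "data.frame")
  cyc
}

# Local maxima above `height`, separated by at least `min_sep` samples
# (closer peaks are merged, keeping the higher one).
find_local_maxima <- function(x, height, min_sep) {
  n <- length(x)
  if (n < 3L) return(integer())
  d <- diff(x)
  cand <- which(d[-length(d)] > 0 & d[-1L] <= 0) + 1L
  cand <- cand[x[cand] >= height]
  if (!length(cand)) return(integer())
  keep <- integer()
  for (i in cand) {
    if (length(keep) && i - keep[length(keep)] < min_sep) {
      if (x[i] > x[keep[length(keep)]]) keep[length(keep)] <- i
    } else keep <- c(keep, i)
  }
  keep
}

# Pooled limb fit: estimate one boundary family (e.g. every contraction
# onset) jointly across all cycles of a recording.
#
# Integer localization follows an outward threshold-crossing search from
# each pulse peak at `bf * amplitude` (two consecutive sub-threshold
# samples stop the walk, so a single noise dip on a flat limb does not
# truncate it). Sub-sample refinement works in linearized limb
# coordinates: for a raised-cosine speed lobe v = A sin^2(pi u / (2 r)),
# y = asin(sqrt(v / A)) is exactly linear in time along the limb, so the
# pulse onset is the root of a straight-line fit, with no dependence on the
# (asymmetry-biased) discrete argmax. Because beat morphology is constant
# within a recording, all cycles share the limb slope (one fixed effect per
# cycle absorbs the timing of each beat), which makes the fit robust to
# per-cycle noise. Mid-limb samples are selected by their *smoothed* value
# (stable selection) while the fitted values are raw (the moving average
# would bias short limbs).
pooled_limb_fit <- function(sc, sc_sel, raw, pks, d, lims, bf, amp, tgrid,
                            dt, sigma = 0) {
  n_cyc <- length(pks)
  thr <- bf * amp
  # The selection band must clear (a) the rest floor of the smoothed trace
  # (rectified noise lifts it above zero) and (b) ~2 sigma of the noise
  # itself, below which zero-clipping biases the observed speed upward;
  # otherwise flat off-pulse or rectified samples masquerade as limb tail
  # and drag the extrapolated root outward.
  fl <- as.numeric(stats::quantile(sc, 0.15))
  sel_lo <- max(fl + 0.12 * max(amp - fl, 0), 1.5 * sigma)
  sel_hi <- 0.85 * amp
  walk <- function(p, lim) {
    idx <- integer()
    i <- p
    while (i != lim && i + d != lim &&
             (sc[i + d] > thr || sc[i + 2 * d] > thr)) {
      i <- i + d
      idx <- c(idx, i)
    }
    list(idx = idx, t_bf = tgrid[i])
  }
  walks <- lapply(seq_len(n_cyc), function(k) walk(pks[k], lims[k]))
  t_bf <- vapply(walks, `[[`, numeric(1), "t_bf")

  pts <- lapply(seq_len(n_cyc), function(k) {
    idx <- walks[[k]]$idx
    # selection floor 0.12: the moving average smears a steep limb a few
    # samples past its base, and those outside samples would otherwise
    # drag the extrapolated root outward
    keep <- idx[sc_sel[idx] >= sel_lo & sc_sel[idx] <= sel_hi]
    if (!length(keep)) return(NULL)
    v <- pmin(pmax(raw[keep] / amp, 0.01), 0.97)
    vs <- pmin(pmax(sc[keep] / amp, 0.08), 0.92)
    # second-order (Jensen) correction of E[asin(sqrt(v + noise))],
    # evaluated at the stable smoothed value; vanishes for sigma = 0
    sv2 <- (sigma / amp)^2
    jb <- (2 * vs - 1) / (4 * (vs * (1 - vs))^1.5) * sv2 / 2
    data.frame(k = k, t = tgrid[keep], y = asin(sqrt(v)) - jb,
               w = vs * (1 - vs))   # inverse-variance weight of y
  })
  pts <- do.call(rbind, pts)

  boundary <- t_bf
  peak_time <- rep(NA_real_, n_cyc)
  # weighted least squares with per-cycle intercepts: demean within cycle
  wls_slope <- function(pp) {
    wm <- function(x, w, g) {
      s <- rowsum(x * w, g); n <- rowsum(w, g)
      (s / n)[match(g, rownames(s)), 1L]
    }
    tt <- pp$t - wm(pp$t, pp$w, pp$k)
    yy <- pp$y - wm(pp$y, pp$w, pp$k)
    sxx <- sum(pp$w * tt^2)
    if (sxx <= 0) return(NULL)
    beta <- sum(pp$w * tt * yy) / sxx
    if (!is.finite(beta)) return(NULL)
    list(beta = beta, resid = yy - beta * tt)
  }
  if (!is.null(pts) && nrow(pts) >= 5L) {
    fit <- wls_slope(pts)
    # one robust pass: drop gross outlier points and refit
    if (!is.null(fit) && nrow(pts) >= 10L) {
      sdr <- stats::mad(fit$resid, center = 0)
      if (is.finite(sdr) && sdr > 0) {
        keep <- abs(fit$resid) <= 3 * sdr
        if (sum(keep) >= 5L && any(!keep)) {
          fit2 <- wls_slope(pts[keep, , drop = FALSE])
          if (!is.null(fit2)) { pts <- pts[keep, , drop = FALSE]; fit <- fit2 }
        }
      }
    }
    if (!is.null(fit)) {
      beta <- fit$beta
      if (beta * d < 0 && abs(beta) > 1e-9) {
        limb <- (pi / 2) / abs(beta)      # boundary-to-peak duration
        for (k in unique(pts$k)) {
          sub <- pts[pts$k == k, ]
          alpha <- sum(sub$w * (sub$y - beta * sub$t)) / sum(sub$w)
          root <- -alpha / beta
          if (abs(root - t_bf[k]) <= 10 * dt) {
            boundary[k] <- root
            peak_time[k] <- root - d * limb
          }
        }
      }
    }
  }
  list(boundary = boundary, peak_time = peak_time, t_bf = t_bf)
}

# Pooled pulse-amplitude estimate: given the limb fits of one pulse
# family, average the raw samples near the pulse top (implied lobe shape
# m >= min_m) across all cycles and divide by the mean lobe value there.
# Near the top the additive noise is mean-zero and unrectified and the
# lobe is flat, so the ratio is unbiased and insensitive to small boundary
# errors; for a noise-free raised-cosine pulse it is exact.
pulse_amplitude_fit <- function(raw, tgrid, left, right, min_m = 0.85) {
  r_limb <- stats::median(left$peak_time - left$boundary, na.rm = TRUE)
  f_limb <- stats::median(right$boundary - right$peak_time, na.rm = TRUE)
  if (!is.finite(r_limb) || !is.finite(f_limb) ||
        r_limb <= 0 || f_limb <= 0) return(NULL)
  ok <- is.finite(left$peak_time) & is.finite(right$peak_time)
  if (!any(ok)) return(NULL)
  vv <- numeric(); mm <- numeric()
  for (k in which(ok)) {
    s_k <- left$boundary[k]; e_k <- right$boundary[k]
    if (!(e_k > s_k)) next
    t_pk <- ((s_k + r_limb) + (e_k - f_limb)) / 2
    if (!(t_pk > s_k && t_pk < e_k)) next
    idx <- which(tgrid > s_k & tgrid < e_k)
    if (!length(idx)) next
    tt <- tgrid[idx]
    m <- ifelse(tt <= t_pk,
                sin(pi * (tt - s_k) / (2 * (t_pk - s_k)))^2,
                sin(pi * (e_k - tt) / (2 * (e_k - t_pk)))^2)
    sel <- m >= min_m
    vv <- c(vv, raw[idx][sel]); mm <- c(mm, m[sel])
  }
  if (length(vv) < 4L) return(NULL)
  A <- mean(vv) / mean(mm)
  if (!is.finite(A) || A <= 0) return(NULL)
  list(A = A)
}

# Joint censored-Gaussian refinement of both pulse families. The speed
# trace is a zero-rectified noisy pulse train, so the exact likelihood is
# Tobit: quadratic misfit where the observed speed is positive, censoring
# mass log(pnorm(-mu/sigma)) where it is exactly zero. Parameters: per
# family an amplitude, rise and fall duration and per-cycle onsets, plus
# one lobe-fullness exponent q shared by both families (the generator of
# this package and, physiologically, a beat, have one waveform per
# recording). L-BFGS-B with analytic gradients, initialized from the
# linearized limb fits; returns NULL when the initialization is unusable.
refine_pulses <- function(raw, tgrid, dt, sigma, fam_c, fam_r) {
  prep <- function(fam) {
    K <- length(fam$s0)
    r_init <- stats::median(fam$r0[is.finite(fam$r0) & fam$r0 > 0])
    f_init <- stats::median(fam$f0[is.finite(fam$f0) & fam$f0 > 0])
    if (!is.finite(r_init) || !is.finite(f_init) ||
          !is.finite(fam$A0) || fam$A0 <= 0 || any(!is.finite(fam$s0)))
      return(NULL)
    dur <- r_init + f_init
    idx <- lapply(seq_len(K), function(k) {
      which(tgrid >= fam$s0[k] - 3 * dt & tgrid <= fam$s0[k] + dur + 3 * dt)
    })
    if (sum(lengths(idx)) < 8 * K) return(NULL)
    list(K = K, r_init = r_init, f_init = f_init, A0 = fam$A0,
         s0 = fam$s0, cyc_id = rep(seq_len(K), lengths(idx)),
         ii = unlist(idx))
  }
  pc <- prep(fam_c); pr <- prep(fam_r)
  if (is.null(pc) || is.null(pr)) return(NULL)
  noisy <- sigma > 1e-9

  # family block: given (A, r, f, q, s) return mu and partials at its
  # sample positions
  fam_eval <- function(fp, A, r, f, q, s) {
    u <- tgrid[fp$ii] - s[fp$cyc_id]
    n <- length(u)
    m0 <- numeric(n); dm_du <- numeric(n)
    dm_dr <- numeric(n); dm_df <- numeric(n)
    up <- u >= 0 & u <= r
    dn <- u > r & u <= r + f
    au <- pi * u[up] / (2 * r)
    m0[up] <- sin(au)^2
    dm_du[up] <- (pi / (2 * r)) * sin(2 * au)
    dm_dr[up] <- -(pi * u[up] / (2 * r^2)) * sin(2 * au)
    w <- r + f - u[dn]
    bw <- pi * w / (2 * f)
    sbw <- sin(2 * bw)
    m0[dn] <- sin(bw)^2
    dm_du[dn] <- -(pi / (2 * f)) * sbw
    dm_dr[dn] <- (pi / (2 * f)) * sbw
    dm_df[dn] <- (pi / (2 * f)) * sbw - (pi * w / (2 * f^2)) * sbw
    inp <- m0 > 0
    m <- m0
    qfac <- numeric(n)
    dm_dq <- numeric(n)
    m[inp] <- m0[inp]^q
    qfac[inp] <- q * m0[inp]^(q - 1)
    dm_dq[inp] <- m[inp] * log(m0[inp])
    list(m = m, qfac = qfac, dm_du = dm_du, dm_dr = dm_dr,
         dm_df = dm_df, dm_dq = dm_dq)
  }

  # parameter layout: A_c, r_c, f_c, A_r, r_r, f_r, q, s_c (K_c), s_r (K_r)
  Kc <- pc$K; Kr <- pr$K
  obj <- function(par) {
    q <- par[7L]
    ec <- fam_eval(pc, par[1L], par[2L], par[3L], q,
                   par[7L + seq_len(Kc)])
    er <- fam_eval(pr, par[4L], par[5L], par[6L], q,
                   par[7L + Kc + seq_len(Kr)])
    val <- 0
    grad <- numeric(length(par))
    for (b in 1:2) {
      fe <- if (b == 1) ec else er
      fp <- if (b == 1) pc else pr
      A <- par[if (b == 1) 1L else 4L]
      vv <- raw[fp$ii]
      mu <- A * fe$m
      if (noisy) {
        pos <- vv > 0
        z <- mu / sigma
        e <- vv - mu
        val <- val + sum(e[pos]^2) / 2 -
          sigma^2 * sum(stats::pnorm(-z[!pos], log.p = TRUE))
        dmu <- numeric(length(mu))
        dmu[pos] <- -e[pos]
        dmu[!pos] <- sigma * exp(stats::dnorm(z[!pos], log = TRUE) -
                                   stats::pnorm(-z[!pos], log.p = TRUE))
      } else {
        e <- vv - mu
        val <- val + sum(e^2) / 2
        dmu <- -e
      }
      base <- if (b == 1) 0L else 3L
      grad[base + 1L] <- sum(dmu * fe$m)
      grad[base + 2L] <- sum(dmu * A * fe$qfac * fe$dm_dr)
      grad[base + 3L] <- sum(dmu * A * fe$qfac * fe$dm_df)
      grad[7L] <- grad[7L] + sum(dmu * A * fe$dm_dq)
      s_off <- 7L + (if (b == 1) 0L else Kc)
      grad[s_off + seq_len(fp$K)] <-
        rowsum(dmu * A * fe$qfac * -fe$dm_du, fp$cyc_id)[, 1L]
    }
    list(value = val, grad = grad)
  }
  par0 <- c(pc$A0, pc$r_init, pc$f_init, pr$A0, pr$r_init, pr$f_init, 1,
            pc$s0, pr$s0)
  lower <- c(0.5 * pc$A0, pmax(0.4 * pc$r_init, 2 * dt),
             pmax(0.4 * pc$f_init, 2 * dt),
             0.5 * pr$A0, pmax(0.4 * pr$r_init, 2 * dt),
             pmax(0.4 * pr$f_init, 2 * dt),
             0.4, pc$s0 - 6 * dt, pr$s0 - 6 * dt)
  upper <- c(2 * pc$A0, 2 * pc$r_init, 2 * pc$f_init,
             2 * pr$A0, 2 * pr$r_init, 2 * pr$f_init,
             2.5, pc$s0 + 6 * dt, pr$s0 + 6 * dt)
  pscale <- c(pc$A0, pc$r_init, pc$f_init, pr$A0, pr$r_init, pr$f_init,
              0.3, rep(5 * dt, Kc + Kr))
  fit <- tryCatch(
    stats::optim(par0, fn = function(p) obj(p)$value,
                 gr = function(p) obj(p)$grad,
                 method = "L-BFGS-B", lower = lower, upper = upper,
                 control = list(maxit = 200, parscale = pscale)),
    error = function(e) NULL)
  if (is.null(fit) || !all(is.finite(fit$par))) return(NULL)
  p_ <- fit$par
  list(
    c = list(A = p_[1L], r = p_[2L], f = p_[3L],
             s = p_[7L + seq_len(Kc)]),
    r = list(A = p_[4L], r = p_[5L], f = p_[6L],
             s = p_[7L + Kc + seq_len(Kr)]),
    q = p_[7L]
  )
}

# Sub-sample pulse-peak estimate. The peak time falls back to the raw
# argmax near the smoothed peak (grid quantization averages out across
# period-jittered cycles; the limb fits usually supply a better estimate).
# The peak speed is the vertex of a least-squares parabola on the *lightly
# smoothed* trace plus an explicit curvature correction var_w * |a2| for
# the moving-average attenuation: unlike a raw-sample maximum it neither
# selects nor chases single up-noise samples.
refine_peak <- function(raw, sm, w1, p, tgrid) {
  n <- length(raw)
  win <- max(p - 3L, 1L):min(p + 3L, n)
  p0 <- win[which.max(raw[win])]
  dt <- tgrid[2L] - tgrid[1L]
  fwin <- max(p - 4L, 1L):min(p + 4L, n)
  tt <- tgrid[fwin] - tgrid[p]
  vv <- sm[fwin]
  speed <- max(raw[max(p0 - 1L, 1L):min(p0 + 1L, n)])
  if (length(fwin) >= 5L) {
    fit <- stats::lm.fit(cbind(1, tt, tt^2), vv)
    a <- fit$coefficients
    if (is.finite(a[3L]) && a[3L] < 0) {
      var_w <- (w1^2 - 1) / 12 * dt^2
      corr <- min(var_w * abs(a[3L]), 0.12 * max(vv))
      vtx <- a[1L] - a[2L]^2 / (4 * a[3L]) + corr
      smax <- max(vv)
      if (vtx >= 0.75 * smax && vtx <= 1.25 * smax) speed <- vtx
    }
  }
  list(time = tgrid[p0], speed = speed)
}

#' Extract the ten beating features from detected cycles
#'
#' Computes the per-cycle feature values and averages them across all
#' complete cycles of the recording: peak contraction and relaxation speed
#' (`max_c`, `max_r`), phase durations (`c_time`, `r_time`), onset-to-peak
#' rise times (`c_rise_time`, `r_rise_time`), the peak-to-peak
#' contraction-relaxation interval (`cr_interval`), the beating duration
#' `time_01` from contraction onset to relaxation end, the spontaneous
#' `beating_rate` from the mean interval between successive contraction
#' peaks (requires at least two cycles, otherwise `NA`), and `displacement`,
#' the time integral of motion speed over the contraction phase.
#'
#' @param trace A [motion_trace()].
#' @param cycles A `beat_cycles` data frame from [detect_beats()], or any
#'   data frame with the six landmark index columns.
#' @return A one-row data frame with the ten features plus `plateau_time`
#'   (mean gap between contraction end and relaxation start, used by the
#'   beating-duration imputation) and `n_cycles`.
#' @export
extract_features <- function(trace, cycles) {
  stopifnot(inherits(trace, "motion_trace"))
  if (!is.data.frame(cycles) || nrow(cycles) == 0L)
    stop_("extract_features() requires at least one complete beating cycle")
  need <- c("c_start", "c_peak", "c_end", "r_start", "r_peak", "r_end")
  if (!all(need %in% names(cycles)))
    stop_("cycles must contain columns %s", paste(need, collapse = ", "))
  tgrid <- trace$time_s
  # Use refined landmark times when available, otherwise grid times.
  tm <- function(col) {
    tc <- paste0(col, "_time")
    if (tc %in% names(cycles)) cycles[[tc]] else tgrid[cycles[[col]]]
  }
  spd <- function(col, idx_col) {
    if (col %in% names(cycles)) cycles[[col]]
    else trace$speed_um_s[cycles[[idx_col]]]
  }
  c_start <- tm("c_start"); c_peak <- tm("c_peak"); c_end <- tm("c_end")
  r_start <- tm("r_start"); r_peak <- tm("r_peak"); r_end <- tm("r_end")
  max_c <- spd("c_peak_speed", "c_peak")
  max_r <- spd("r_peak_speed", "r_peak")
  disp <- vapply(seq_len(nrow(cycles)), function(k) {
    trapz_interval(tgrid, trace$speed_um_s, c_start[k], c_end[k])
  }, numeric(1))
  # mean over inter-peak intervals, excluding double-length gaps left by a
  # skipped cycle
  rate <- if (nrow(cycles) >= 2L) {
    iv <- diff(c_peak)
    iv <- iv[iv <= 1.6 * stats::median(iv)]
    60 / mean(iv)
  } else NA_real_
  data.frame(
    max_c = mean(max_c),
    c_time = mean(c_end - c_start),
    max_r = mean(max_r),
    r_time = mean(r_end - r_start),
    cr_interval = mean(r_peak - c_peak),
    time_01 = mean(r_end - c_start),
    c_rise_time = mean(c_peak - c_start),
    r_rise_time = mean(r_peak - r_start),
    beating_rate = rate,
    displacement = mean(disp),
    plateau_time = mean(r_start - c_end),
    n_cycles = nrow(cycles)
  )
}
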