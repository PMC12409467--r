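# Shared fixtures: all synthetic, built in code.

# A representative mature-like waveform with optional overrides.
test_params <- function(...) {
  args <- utils::modifyList(
    list(beating_rate = 40, max_c = 12, max_r = 7.5,
         c_rise_time = 0.15, c_time = 0.42,
         r_rise_time = 0.27, r_time = 0.68,
         plateau_time = 0.18, noise_sd = 0, rate_jitter_cv = 0.04),
    list(...))
  do.call(beat_waveform_params, args)
}

# Separable two-class feature matrix for classifier tests.
test_xy <- function(n_per_class = 40, shift = 1.5, seed = 1) {
  withr::with_seed(seed, {
    x <- matrix(stats::rnorm(2 * n_per_class * 10), 2 * n_per_class, 10)
    colnames(x) <- cmmaturity:::FEATURE_NAMES
    y <- rep(c("immature", "mature"), each = n_per_class)
    x[y == "mature", ] <- x[y == "mature", ] + shift
    list(x = x, y = y)
  })
}

# Small labelled feature table with cell lines.
test_table <- function(n_per_class = 16, seed = 3, lines = 4) {
  xy <- test_xy(n_per_class, seed = seed)
  tab <- as.data.frame(xy$x)
  tab$recording_id <- sprintf("r%03d", seq_len(nrow(tab)))
  tab$class <- xy$y
  tab$cell_line <- paste0("line", rep_len(seq_len(lines), nrow(tab)))
  tab$plateau_time <- 0.2
  tab
}

# Plain-loop brute-force exhaustive SAD block matcher (independent oracle).
brute_force_block_match <- function(frame_a, frame_b, config) {
  bw <- config$block_width_px; ms <- config$max_shift_px
  h <- nrow(frame_a); w <- ncol(frame_a)
  r0 <- seq(1, h - bw + 1, by = bw)
  c0 <- seq(1, w - bw + 1, by = bw)
  r0 <- r0[r0 - ms >= 1 & r0 + bw - 1 + ms <= h]
  c0 <- c0[c0 - ms >= 1 & c0 + bw - 1 + ms <= w]
  out <- NULL
  for (r in r0) for (cc in c0) {
    blk <- frame_a[r:(r + bw - 1), cc:(cc + bw - 1)]
    best <- Inf; bdx <- 0L; bdy <- 0L
    cand <- expand.grid(dx = -ms:ms, dy = -ms:ms)
    cand <- cand[order(cand$dx^2 + cand$dy^2, cand$dy, cand$dx), ]
    for (k in seq_len(nrow(cand))) {
      dy <- cand$dy[k]; dx <- cand$dx[k]
      sad <- sum(abs(blk - frame_b[(r + dy):(r + dy + bw - 1),
                                   (cc + dx):(cc + dx + bw - 1)]))
      if (sad < best) { best <- sad; bdy <- dy; bdx <- dx }
    }
    out <- rbind(out, data.frame(row = r, col = cc, dy = bdy, dx = bdx,
                                 score = best))
  }
  out
}

# Dual-QP oracle for the soft-margin objective (kernlab interior point).
qp_primal_objective <- function(x, y_pm, config) {
  gamma <- cmmaturity:::resolve_gamma(config$gamma, x)
  K <- cmmaturity:::kernel_matrix(x, x, config$kernel, gamma,
                                  config$degree, config$coef0)
  Q <- (y_pm %o% y_pm) * K
  n <- length(y_pm)
  sol <- kernlab::ipop(c = rep(-1, n), H = Q + diag(1e-7, n),
                       A = matrix(y_pm, 1), b = 0, l = rep(0, n),
                       u = rep(config$C, n), r = 0, sigf = 8,
                       maxiter = 400)
  a <- kernlab::primal(sol)
  # by strong duality the optimal primal objective equals the dual
  # objective sum(alpha) - 0.5 alpha' Q alpha (no offset recovery needed)
  sum(a) - 0.5 * as.numeric(t(a) %*% Q %*% a)
}
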