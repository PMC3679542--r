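# Shared fixture builders: everything is generated in code at test time.

quick_cfg <- function(...) {
  args <- utils::modifyList(
    list(duration = 40, flagellum_length = 8,
         injection_rate_antero = 0.6, injection_rate_retro = 0.8,
         seed = 42L),
    list(...))
  do.call(sim_config, args)
}

# Hand-constructed ground truth carrying only pause events, for controlled
# gliding scenarios.
truth_with_pauses <- function(config, pauses) {
  structure(list(
    trains = tibble::tibble(train_id = integer(), flagellum = integer(),
                            direction = character(), v = numeric(),
                            t_inject = numeric(), t_exit = numeric()),
    track = tibble::tibble(train_id = integer(), flagellum = integer(),
                           direction = character(), t = numeric(),
                           s = numeric()),
    pauses = pauses, bead = NULL, body = NULL, config = config,
    n_dropped_pauses = 0L
  ), class = "ift_truth")
}

pause_row <- function(position, t_start, t_end, direction = "retrograde",
                      flagellum = 1L, train_id = 1L) {
  tibble::tibble(pause_id = 1L, train_id = train_id, flagellum = flagellum,
                 position = position, t_start = t_start, t_end = t_end,
                 direction = direction)
}

# Synthetic kymograph with Gaussian-profile ridges: each ridge starts at
# arc s0 (um) at time t0 and moves at v um/s. Constructed directly (no FFT,
# no renderer) so it can serve as an oracle for FSDA.
make_ridge_kymo <- function(velocities, s0 = NULL, t0 = NULL,
                            n_t = 100, n_s = 96, pixel_size = 0.106,
                            frame_interval = 0.2, amp = 100, width_px = 1.2,
                            noise_sd = 0, seed = 1) {
  m <- length(velocities)
  s0 <- s0 %||% rep(n_s * pixel_size / 2, m)
  t0 <- t0 %||% rep(0, m)
  K <- matrix(0, n_t, n_s)
  tt <- (seq_len(n_t) - 1) * frame_interval
  cols <- seq_len(n_s)
  for (i in seq_len(m)) {
    pos_um <- s0[i] + velocities[i] * (tt - t0[i])
    pos_px <- pos_um / pixel_size + 1
    for (r in seq_len(n_t)) {
      if (pos_px[r] < -4 || pos_px[r] > n_s + 4) next
      K[r, ] <- K[r, ] + amp * exp(-(cols - pos_px[r])^2 / (2 * width_px^2))
    }
  }
  if (noise_sd > 0) {
    K <- K + withr::with_seed(seed, matrix(rnorm(n_t * n_s, 0, noise_sd),
                                           n_t, n_s))
  }
  kymograph(K, pixel_size, frame_interval)
}

# Render simulated ground-truth tracks straight into a kymograph at a given
# peak signal-to-noise ratio (bypasses the movie stage for speed). The
# camera integrates over the frame interval, so each frame draws several
# sub-frame positions (motion blur); without it a PSF-wide ridge moving
# several px per frame is temporally aliased.
truth_kymo <- function(truth, config, snr = 5, amp = 100, width_px = 1.2,
                       seed = 1, n_sub = 4) {
  n_t <- length(seq(0, config$duration, by = config$frame_interval))
  n_s <- ceiling(config$flagellum_length / config$pixel_size) + 1L
  K <- matrix(0, n_t, n_s)
  cols <- seq_len(n_s)
  tr <- truth$track
  for (id in unique(tr$train_id)) {
    g <- tr[tr$train_id == id, ]
    for (i in seq_len(nrow(g))) {
      r <- round(g$t[i] / config$frame_interval) + 1L
      s1 <- g$s[i]
      s2 <- if (i < nrow(g)) g$s[i + 1L] else g$s[i]
      for (u in (seq_len(n_sub) - 1) / n_sub) {
        pos_px <- (s1 + u * (s2 - s1)) / config$pixel_size + 1
        K[r, ] <- K[r, ] +
          (amp / n_sub) * exp(-(cols - pos_px)^2 / (2 * width_px^2))
      }
    }
  }
  # SNR is defined against the typical on-ridge intensity of a single train
  # (overlaps of several trains must not inflate the noise floor)
  ridge_rows <- round(tr$t / config$frame_interval) + 1L
  ridge_cols <- pmin(pmax(round(tr$s / config$pixel_size) + 1L, 1L), n_s)
  signal_ref <- if (nrow(tr)) median(K[cbind(ridge_rows, ridge_cols)]) else amp
  K <- K + withr::with_seed(seed, matrix(rnorm(n_t * n_s, 0, signal_ref / snr),
                                         n_t, n_s))
  kymograph(K, config$pixel_size, config$frame_interval)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
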