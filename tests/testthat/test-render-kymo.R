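static_truth <- function(cfg, s_um) {
  structure(list(
    trains = tibble::tibble(train_id = 1L, flagellum = 1L,
                            direction = "anterograde", v = 0,
                            t_inject = 0, t_exit = Inf),
    track = tibble::tibble(train_id = 1L, flagellum = 1L,
                           direction = "anterograde",
                           t = seq(0, cfg$duration, by = cfg$frame_interval),
                           s = s_um),
    pauses = tibble::tibble(), bead = NULL, body = NULL, config = cfg,
    n_dropped_pauses = 0L
  ), class = "ift_truth")
}

test_that("zero signal and zero noise give an all-zero movie", {
  cfg <- sim_config(duration = 2, photon_rate = 0, background_rate = 0,
                    read_noise = 0, injection_rate_antero = 0,
                    injection_rate_retro = 0, seed = 1)
  mv <- render_movie(simulate_ift(cfg), cfg)
  expect_true(all(unclass(mv) == 0))
})

test_that("a static emitter renders at the same pixel in every frame", {
  cfg <- sim_config(duration = 4, background_rate = 0, read_noise = 0,
                    seed = 1)
  truth <- static_truth(cfg, 5.13)
  mv <- render_movie(truth, cfg, noise = FALSE)
  peaks <- apply(unclass(mv), 1, which.max)
  expect_length(unique(peaks), 1L)
})

test_that("rendered emitters are recovered by Gaussian localization within 20 nm", {
  cfg <- sim_config(duration = 1, frame_interval = 0.5, psf_sigma = 0.13,
                    photon_rate = 400, background_rate = 16, read_noise = 2,
                    seed = 9)
  truth <- static_truth(cfg, 4.27)
  mv <- render_movie(truth, cfg)   # SNR ~ 400 / sqrt(416) ~ 20
  frame <- unclass(mv)[1, , ]
  peak <- which(frame == max(frame), arr.ind = TRUE)[1, ]
  loc <- localize_gaussian(frame, peak, roi_halfwidth = 5)
  # ground truth: straight path at row 8, col 8 + s / px (0-based coords)
  true_col <- 8 + 4.27 / cfg$pixel_size + 1   # 1-based
  err_nm <- sqrt((loc$row - 9)^2 + (loc$col - true_col)^2) *
    cfg$pixel_size * 1000
  expect_lt(err_nm, 20)
})

test_that("a uniform movie samples to a constant kymograph", {
  mv <- array(7, dim = c(5, 20, 40))
  pl <- cbind(rep(10, 30), seq(3, 32))
  k <- sample_kymograph(mv, pl, linewidth_px = 3, pixel_size = 0.106,
                        frame_interval = 0.2)
  expect_true(all(abs(unclass(k) - 7) < 1e-12))
})

test_that("kymograph sampling is linear in the movie", {
  set.seed(11)
  m1 <- array(runif(5 * 20 * 40), dim = c(5, 20, 40))
  m2 <- array(runif(5 * 20 * 40), dim = c(5, 20, 40))
  pl <- cbind(rep(9, 30), seq(4, 33))
  k1 <- sample_kymograph(m1, pl, pixel_size = 0.106, frame_interval = 0.2)
  k2 <- sample_kymograph(m2, pl, pixel_size = 0.106, frame_interval = 0.2)
  k12 <- sample_kymograph(2 * m1 + 3 * m2, pl, pixel_size = 0.106,
                          frame_interval = 0.2)
  expect_equal(unclass(k12), 2 * unclass(k1) + 3 * unclass(k2),
               tolerance = 1e-12)
})

test_that("a moving emitter leaves a ridge whose slope is the velocity", {
  v <- 1.5
  cfg <- sim_config(duration = 10, background_rate = 0, read_noise = 0,
                    flagellum_length = 8, seed = 2)
  tt <- seq(0, cfg$duration, by = cfg$frame_interval)
  truth <- static_truth(cfg, pmin(0.5 + v * tt, 8))
  mv <- render_movie(truth, cfg, noise = FALSE)
  pl <- iftmotion:::straight_path(cfg$flagellum_length, cfg$pixel_size, 8, 8)
  k <- sample_kymograph(mv, pl)
  # follow the per-row argmax while the emitter is inside the path
  rows <- which(0.5 + v * tt < 7.5)
  pos_um <- (apply(unclass(k)[rows, ], 1, which.max) - 1) * cfg$pixel_size
  fit <- lm(pos_um ~ tt[rows])
  expect_equal(unname(coef(fit)[2]), v, tolerance = 0.05 * v)
})

test_that("anchor stacking keeps a static anchor emitter in a fixed column", {
  # path rotates 40 degrees about the anchor; emitter sits at the anchor
  anchor <- c(16, 16)
  rotpl <- function(theta) {
    t(sapply(seq(0, 14), function(d) anchor + d * c(sin(theta), cos(theta))))
  }
  p <- flagellar_path(list(list(frame = 0L, polyline = rotpl(0)),
                           list(frame = 9L, polyline = rotpl(0.7))),
                      anchor_um = 0, pixel_size = 0.106)
  frames <- interpolate_paths(p, 10)
  mv <- array(0, dim = c(10, 32, 32))
  for (f in 1:10) {
    rr <- 1:32
    g <- exp(-outer((rr - anchor[1] - 1)^2, (rr - anchor[2] - 1)^2, "+") / 2)
    mv[f, , ] <- 100 * g
  }
  k <- sample_kymograph(mv, frames, pixel_size = 0.106, frame_interval = 0.1)
  peaks <- apply(unclass(k), 1, which.max)
  expect_length(unique(peaks), 1L)
  expect_equal(unique(peaks), attr(frames, "anchor_index"))
})

test_that("a path shorter than the flagellum is rejected", {
  cfg <- sim_config(duration = 1, seed = 1)
  truth <- simulate_ift(cfg)
  short <- cbind(rep(8, 10), seq(1, 10))
  expect_error(render_movie(truth, cfg, paths = short), "shorter")
  expect_error(sample_kymograph(array(0, c(2, 8, 8)), short, linewidth_px = 0),
               "linewidth")
})
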