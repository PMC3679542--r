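test_that("with no attachment the bead diffuses with MSD ~ 2 D tau", {
  # brute-force MSD over replicate seeds, short lags (before boundaries bite)
  D <- 0.02
  msd_at_lag <- function(s, lag_steps, dt) {
    d <- s[(1 + lag_steps):length(s)] - s[seq_len(length(s) - lag_steps)]
    mean(d^2)
  }
  lags <- c(1L, 2L, 4L)
  acc <- matrix(0, 50, length(lags))
  for (k in 1:50) {
    cfg <- sim_config(duration = 20, flagellum_length = 12,
                      bead_diffusion_coeff = D, bead_attach_rate = 0,
                      injection_rate_antero = 0.2, injection_rate_retro = 0.2,
                      seed = k)
    truth <- simulate_bead(cfg, simulate_ift(cfg))
    expect_true(all(is.na(truth$bead$coupled_train)))
    dt <- cfg$frame_interval
    acc[k, ] <- vapply(lags, function(l) msd_at_lag(truth$bead$s, l, dt),
                       numeric(1))
  }
  for (j in seq_along(lags)) {
    tau <- lags[j] * 0.2
    expect_equal(mean(acc[, j]), 2 * D * tau, tolerance = 0.15)
  }
})

test_that("a permanently coupled bead moves at speed factor times the train", {
  cfg <- sim_config(duration = 30, v_retro = 3, v_retro_sd = 0,
                    injection_rate_antero = 0, injection_rate_retro = 0.001,
                    bead_detach_rate = 0, bead_speed_factor = 0.7,
                    pause_rate_max = 0, pause_rate_residual = 0, seed = 7)
  truth <- simulate_ift(cfg)
  # guarantee one train alive at t = 0
  truth$trains <- tibble::tibble(train_id = 1L, flagellum = 1L,
                                 direction = "retrograde", v = 3,
                                 t_inject = 0, t_exit = 10 / 3)
  truth$track <- tibble::tibble(train_id = 1L, flagellum = 1L,
                                direction = "retrograde",
                                t = seq(0, 10 / 3, by = 0.2),
                                s = 10 - 3 * seq(0, 10 / 3, by = 0.2))
  truth$pauses <- truth$pauses[0, ]
  out <- simulate_bead(cfg, truth, start_coupled = TRUE)
  seg <- out$bead[!is.na(out$bead$coupled_train), ]
  expect_gt(nrow(seg), 10)
  fit <- lm(s ~ t, data = seg)
  expect_equal(unname(coef(fit)[2]), -0.7 * 3, tolerance = 0.01)

  # with speed factor 1 the bead matches the train position exactly
  cfg1 <- sim_config(duration = 30, v_retro = 3, v_retro_sd = 0,
                     injection_rate_antero = 0, injection_rate_retro = 0.001,
                     bead_detach_rate = 0, bead_speed_factor = 1,
                     pause_rate_max = 0, pause_rate_residual = 0, seed = 7)
  out1 <- simulate_bead(cfg1, truth)
  # force coupling from the start for the exactness check
  out1 <- simulate_bead(cfg1, truth, start_coupled = TRUE)
  seg1 <- out1$bead[!is.na(out1$bead$coupled_train), ]
  train_pos <- approx(truth$track$t, truth$track$s, xout = seg1$t)$y
  expect_equal(seg1$s, train_pos, tolerance = 1e-8)
})

test_that("calcium-deprived beads never couple", {
  cfg <- quick_cfg(ca_free = 0, bead_attach_rate = 2)
  truth <- simulate_bead(cfg, simulate_ift(cfg))
  expect_true(all(is.na(truth$bead$coupled_train)))
})

test_that("bead simulation requires a train list", {
  cfg <- quick_cfg()
  expect_error(simulate_bead(cfg, list()), "ift_truth")
})
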