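test_that("identical config and seed reproduce bit-identical ground truth", {
  cfg <- quick_cfg()
  expect_identical(simulate_ift(cfg), simulate_ift(cfg))
  cfg2 <- quick_cfg(seed = 43L)
  expect_false(identical(simulate_ift(cfg)$track, simulate_ift(cfg2)$track))
})

test_that("pause counts follow the configured Poisson rate", {
  # closed-form expectation: 0.125 /s x 400 s = 50 pauses per cell
  counts <- vapply(1:30, function(s) {
    cfg <- sim_config(duration = 400, pause_rate_max = 0.125,
                      ca_free = 0.34e-3, seed = s)
    nrow(simulate_ift(cfg)$pauses)
  }, numeric(1))
  se_mean <- sqrt(50 / 30)
  expect_lt(abs(mean(counts) - 50), 3 * se_mean)
})

test_that("calcium map gives residual pausing at zero calcium and saturates", {
  cfg <- quick_cfg()
  expect_equal(ca_pause_rate(0, cfg), cfg$pause_rate_residual)
  expect_equal(ca_pause_rate(0.34e-3, cfg), cfg$pause_rate_max,
               tolerance = 0.01)
  expect_true(ca_pause_rate(1e-7, cfg) < ca_pause_rate(1e-6, cfg))
  # no residual pausing configured and no calcium: no pauses at all
  cfg0 <- quick_cfg(ca_free = 0, pause_rate_residual = 0)
  expect_equal(nrow(simulate_ift(cfg0)$pauses), 0L)
})

test_that("zero injection rates give an empty train list", {
  cfg <- quick_cfg(injection_rate_antero = 0, injection_rate_retro = 0)
  truth <- simulate_ift(cfg)
  expect_equal(nrow(truth$trains), 0L)
  expect_equal(nrow(truth$track), 0L)
})

test_that("train positions stay on the flagellum and pauses lie in lifetimes", {
  for (s in 1:5) {
    truth <- simulate_ift(quick_cfg(seed = s))
    expect_true(all(truth$track$s >= 0 & truth$track$s <= 8))
    if (nrow(truth$pauses)) {
      m <- match(truth$pauses$train_id, truth$trains$train_id)
      expect_true(all(truth$pauses$t_start >= truth$trains$t_inject[m]))
      expect_true(all(truth$pauses$t_start <= truth$trains$t_exit[m]))
      expect_true(all(truth$pauses$position >= 0 &
                        truth$pauses$position <= 8))
    }
    # anterograde trains move tip-ward, retrograde base-ward
    tr <- truth$track
    for (id in unique(tr$train_id)) {
      g <- tr[tr$train_id == id, ]
      if (nrow(g) < 2) next
      drift <- g$s[nrow(g)] - g$s[1]
      if (g$direction[1] == "anterograde") expect_gte(drift, 0)
      if (g$direction[1] == "retrograde") expect_lte(drift, 0)
    }
  }
})

test_that("invalid kinetic parameters are rejected", {
  expect_error(sim_config(v_antero = -1), "v_antero")
  expect_error(sim_config(frame_interval = 0), "frame_interval")
  expect_error(sim_config(injection_rate_antero = NaN), "injection_rate")
  expect_error(sim_config(bead_speed_factor = 0), "bead_speed_factor")
  expect_error(sim_config(bead_speed_factor = 1.5), "bead_speed_factor")
  expect_error(simulate_ift(list()), "sim_config")
})
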