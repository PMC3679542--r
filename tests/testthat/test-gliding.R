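cfg_glide <- sim_config(duration = 30, glide_speed = 0.86, seed = 1)

test_that("a long retrograde pause moves the body by glide_speed x duration", {
  # pause lasts 5 s, anchor 10 um away: displacement = 0.86 * 5 = 4.3 um
  truth <- truth_with_pauses(
    sim_config(duration = 30, flagellum_length = 12, glide_speed = 0.86,
               seed = 1),
    pause_row(position = 10, t_start = 5, t_end = 10))
  out <- simulate_gliding(truth$config, truth)
  expect_equal(max(out$body$position), 0.86 * 5, tolerance = 1e-9)
  # motion starts at the pause and stops at its end
  expect_equal(out$body$position[out$body$t <= 5], rep(0, sum(out$body$t <= 5)))
  expect_equal(out$body$position[out$body$t >= 10],
               rep(0.86 * 5, sum(out$body$t >= 10)))
})

test_that("the body never glides past the paused train", {
  # anchor 2 um away, pause long enough to cover 8.6 um: displacement = 2
  truth <- truth_with_pauses(cfg_glide,
                             pause_row(position = 2, t_start = 2, t_end = 12))
  out <- simulate_gliding(cfg_glide, truth)
  expect_equal(max(out$body$position), 2, tolerance = 1e-9)
})

test_that("equal simultaneous anchors in both flagella cancel", {
  cfg2 <- sim_config(duration = 30, n_flagella = 2L, seed = 1)
  pauses <- dplyr::bind_rows(
    pause_row(position = 4, t_start = 2, t_end = 10, flagellum = 1L),
    pause_row(position = 5, t_start = 2, t_end = 10, flagellum = 2L))
  out <- simulate_gliding(cfg2, truth_with_pauses(cfg2, pauses))
  expect_equal(out$body$position, rep(0, nrow(out$body)))
  # but an unbalanced window moves the body toward the majority flagellum
  pauses2 <- dplyr::bind_rows(
    pauses,
    pause_row(position = 6, t_start = 12, t_end = 14, flagellum = 1L))
  out2 <- simulate_gliding(cfg2, truth_with_pauses(cfg2, pauses2))
  expect_gt(max(out2$body$position), 0)
})

test_that("anterograde pauses never initiate gliding", {
  truth <- truth_with_pauses(cfg_glide,
                             pause_row(position = 5, t_start = 2, t_end = 10,
                                       direction = "anterograde"))
  out <- simulate_gliding(cfg_glide, truth)
  expect_equal(out$body$position, rep(0, nrow(out$body)))
})

test_that("displacement per pause never exceeds the anchor distance", {
  n_checked <- 0L
  for (s in 1:8) {
    cfg <- sim_config(duration = 60, seed = s, pause_rate_max = 0.2)
    truth <- simulate_gliding(cfg, simulate_ift(cfg))
    retro <- truth$pauses[truth$pauses$direction == "retrograde", ]
    if (!nrow(retro)) next
    b_at <- function(t) approx(truth$body$t, truth$body$position, xout = t,
                               rule = 2)$y
    for (j in seq_len(nrow(retro))) {
      moved <- b_at(min(retro$t_end[j], 60)) - b_at(retro$t_start[j])
      # motion toward a flagellum-1 anchor is positive and bounded by the
      # anchor's distance at the start of its pause
      expect_lte(moved, retro$position[j] + 1e-9)
      n_checked <- n_checked + 1L
    }
    # gliding is toward the anchor: opposite to retrograde transport
    expect_true(all(truth$body$position >= -1e-12))
  }
  expect_gt(n_checked, 10)
})
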