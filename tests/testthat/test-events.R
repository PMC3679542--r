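test_that("steadily moving and fully immotile tracks yield no pause events", {
  tt <- seq(0, 20, by = 0.2)
  mover <- tibble::tibble(train_id = 1L, t = tt, s = 3 * tt)
  res <- detect_pauses(mover, acquisition_time = 20)
  expect_equal(nrow(res$events), 0L)

  still <- tibble::tibble(train_id = 1L, t = tt, s = rep(4, length(tt)))
  res2 <- detect_pauses(still, acquisition_time = 20)
  expect_equal(nrow(res2$events), 0L)
  expect_equal(res2$n_excluded_immotile, 1L)
})

test_that("a pause inside a moving track is detected with its prior direction", {
  tt <- seq(0, 20, by = 0.2)
  s <- ifelse(tt < 8, 2 * tt, ifelse(tt < 12, 16, 16 + 2 * (tt - 12)))
  tr <- tibble::tibble(train_id = 1L, t = tt, s = s)
  res <- detect_pauses(tr, acquisition_time = 20)
  expect_equal(nrow(res$events), 1L)
  ev <- res$events
  expect_equal(ev$prior_direction, "anterograde")
  expect_lt(abs(ev$t_start - 8), 0.5)
  expect_lt(abs(ev$t_end - 12), 0.5)
  expect_equal(ev$position, 16, tolerance = 0.1)

  retro <- tibble::tibble(train_id = 1L, t = tt, s = rev(s))
  res_r <- detect_pauses(retro, acquisition_time = 20)
  expect_equal(res_r$events$prior_direction, "retrograde")
})

test_that("pause frequency recovers the configured rate on simulated cells", {
  rates <- vapply(1:25, function(s) {
    cfg <- sim_config(duration = 200, pause_rate_max = 0.125, seed = 400 + s)
    truth <- simulate_ift(cfg)
    detect_pauses(truth$track, acquisition_time = 200)$frequency_corrected
  }, numeric(1))
  # Poisson SE of the mean rate over 25 x 200 s
  se <- sqrt(0.125 / (25 * 200))
  expect_lt(abs(mean(rates) - 0.125), 3 * se)
})

test_that("gliding onsets report time, speed and direction", {
  tt <- seq(0, 20, by = 0.2)
  still <- tibble::tibble(t = tt, position = rep(0, length(tt)))
  expect_equal(nrow(detect_gliding_onset(still)), 0L)

  pos <- ifelse(tt < 10, 0, ifelse(tt < 14, 1.5 * (tt - 10), 6))
  body <- tibble::tibble(t = tt, position = pos)
  ev <- detect_gliding_onset(body)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$onset, 10, tolerance = 0.41)
  expect_equal(ev$speed, 1.5, tolerance = 0.1)
  expect_equal(ev$direction, 1)
})

test_that("lag times are measured to the latest retrograde pause", {
  pauses <- dplyr::bind_rows(
    pause_row(5, 10.0, 11.5, "retrograde"),
    pause_row(5, 3.0, 4.0, "anterograde"))
  glides <- tibble::tibble(onset = 10.5, t_end = 12, speed = 1,
                           direction = 1, run_um = 1)
  fit <- lag_time_analysis(pauses, glides)
  expect_equal(fit$lags$lag, 0.5)
  expect_equal(fit$tau, 0.5)

  # onset preceded only by an anterograde pause: flagged and excluded
  glides2 <- tibble::tibble(onset = c(5, 10.5), t_end = c(6, 12),
                            speed = 1, direction = 1, run_um = 1)
  fit2 <- lag_time_analysis(pauses, glides2)
  expect_equal(fit2$n_excluded, 1L)
  expect_true(fit2$lags$excluded[1])
  expect_error(lag_time_analysis(pauses, glides[0, ]), "glide")
})

test_that("exponential lag fit is unbiased across tau values", {
  for (tau in c(0.25, 0.5, 1, 2)) {
    est <- withr::with_seed(round(1000 * tau), {
      vapply(1:200, function(i) {
        lags <- rexp(36, 1 / tau)
        p_starts <- seq(50, by = 50, length.out = 36)
        pauses <- tibble::tibble(t_start = p_starts, t_end = p_starts + 40,
                                 direction = "retrograde")
        glides <- tibble::tibble(onset = p_starts + lags)
        lag_time_analysis(pauses, glides)$tau
      }, numeric(1))
    })
    expect_lt(abs(mean(est) - tau) / tau, 0.1)
  }
})

test_that("the Monte-Carlo independence test is calibrated at its extremes", {
  # observed mean equal to the null mean: p near 0.5
  p_mid <- independence_test(8.25, 36, 8.25, n_mc = 2e4, seed = 3)$p_value
  expect_gt(p_mid, 0.4); expect_lt(p_mid, 0.6)
  # observed mean far above the null mean: p near 1
  p_hi <- independence_test(8.25 * 3, 36, 8.25, n_mc = 2e4, seed = 3)$p_value
  expect_gt(p_hi, 0.999)
  expect_error(independence_test(-1, 36, 8, 1e4), "mean_lag")
  expect_error(independence_test(1, 36, 8, n_mc = 100), "n_mc")
  expect_error(independence_test(1, 1, 8, 1e4), "n")
})

test_that("pause profiles reflect where pausing intensity sits", {
  # uniform coverage: flat profile
  K <- matrix(10, 50, 80)
  K[, seq(1, 80, by = 4)] <- 100    # regular paused ridges
  prof <- pause_profile(kymograph(K, 0.106, 0.2), flagellum_length = 8.4,
                        n_bins = 10)
  expect_lt(diff(range(prof$intensity)) / mean(prof$intensity), 0.2)

  # calcium-deprived regime: pauses only near the base
  K2 <- matrix(10, 50, 80)
  K2[, 1:12] <- 120
  prof2 <- pause_profile(kymograph(K2, 0.106, 0.2), flagellum_length = 8.4,
                         n_bins = 10)
  basal <- sum(prof2$intensity[prof2$position < 0.2] * prof2$n_px[prof2$position < 0.2])
  total <- sum(prof2$intensity * prof2$n_px)
  expect_gt(basal / total, 0.8)

  # zero component: all-zero profile
  prof3 <- pause_profile(kymograph(matrix(0, 20, 20), 0.106, 0.2), 2)
  expect_true(all(prof3$intensity == 0))
  expect_error(pause_profile(kymograph(K, 0.106, 0.2), 0), "positive")
})
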