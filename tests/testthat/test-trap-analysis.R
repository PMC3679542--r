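# Deterministic excursion builder: ramp to a plateau, dwell, exponential
# recoil; thresholds can then be applied by hand as the oracle.
build_excursion <- function(plateau_nm, dwell_s, rate_hz = 2000,
                            ramp_speed = 2000, tau = 0.02, pad_s = 1,
                            jitter_sd = 0.5, seed = 1) {
  dt <- 1 / rate_hz
  ramp <- seq(0, plateau_nm, by = ramp_speed * dt)
  dwell <- rep(plateau_nm, round(dwell_s / dt))
  tdec <- seq(dt, 6 * tau, by = dt)
  dec <- plateau_nm * exp(-tdec / tau)
  pad <- rep(0, round(pad_s / dt))
  x <- c(pad, ramp, dwell, dec, pad)
  x <- x + withr::with_seed(seed, rnorm(length(x), 0, jitter_sd))
  tibble::tibble(t = (seq_along(x) - 1) * dt, x = x)
}

test_that("equipartition calibration recovers the simulated stiffness", {
  tc <- trap_sim_config(run_rate = 0, seed = 31)
  tr <- simulate_trap_trace(tc, duration = 30)
  cal <- calibrate_stiffness(tr)
  expect_equal(cal$kappa, 0.4, tolerance = 0.05)
  # doubling the variance halves the stiffness estimate
  d2 <- tibble::tibble(t = tr$data$t, x = tr$data$x * sqrt(2))
  cal2 <- calibrate_stiffness(d2, kT = 4.11)
  expect_equal(cal2$kappa, cal$kappa / 2, tolerance = 1e-9)
})

test_that("a drifting segment fails the stationarity check", {
  tt <- seq(0, 5, by = 5e-4)
  drift <- tibble::tibble(t = tt, x = 20 * tt +
                            withr::with_seed(1, rnorm(length(tt), 0, 3)))
  expect_error(calibrate_stiffness(drift, kT = 4.11), "stationary")
  expect_error(calibrate_stiffness(drift[1:100, ], kT = 4.11), "1 s")
})

test_that("hand-built excursions classify as stall, release and escape", {
  # 150 ms dwell at 63 nm with kappa 0.4: a stall of ~25.2 pN
  d <- build_excursion(63, 0.15)
  ev <- classify_events(d, kappa = 0.4)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$type, "stall")
  expect_equal(ev$peak_force, 25.2, tolerance = 0.05)
  expect_gte(ev$stall_duration, 0.1)

  # 50 ms dwell: a release
  d2 <- build_excursion(63, 0.05)
  ev2 <- classify_events(d2, kappa = 0.4)
  expect_equal(ev2$type, "release")

  # monotone crossing of the 200 nm linear range: an escape
  d3 <- build_excursion(240, 0.05)
  ev3 <- classify_events(d3, kappa = 0.4)
  expect_equal(ev3$type, "escape")

  expect_error(classify_events(d, kappa = 0.4, v_window = 0.2), "v_window")
  expect_error(classify_events(tibble::tibble(t = 1, x = 1)), "kappa")
})

test_that("classification agrees with simulator labels", {
  tc <- trap_sim_config(run_rate = 1, escape_fraction = 0.1, seed = 11)
  tr <- simulate_trap_trace(tc, duration = 120)
  ev <- classify_events(tr)
  tru <- tr$events
  hits <- vapply(seq_len(nrow(tru)), function(i) {
    ov <- which(ev$t_start < tru$t_end[i] & ev$t_end > tru$t_start[i])
    if (length(ov)) ev$type[ov[1]] == tru$type[i] else FALSE
  }, logical(1))
  expect_gt(mean(hits), 0.9)
  # direction comes from the excursion sign plus orientation metadata
  dirs <- vapply(seq_len(nrow(tru)), function(i) {
    ov <- which(ev$t_start < tru$t_end[i] & ev$t_end > tru$t_start[i])
    if (length(ov)) ev$direction[ov[1]] == tru$direction[i] else FALSE
  }, logical(1))
  expect_gt(mean(dirs), 0.95)
})

test_that("peak-force statistics summarise events per direction and type", {
  ev <- tibble::tibble(type = "stall", direction = "retrograde",
                       t_start = 1:4, t_end = 2:5,
                       peak_force = rep(20, 4), stall_duration = 0.2)
  fs <- peak_force_stats(ev)
  expect_equal(fs$summary$mean, 20)
  expect_equal(fs$summary$sem, 0)
  # single event: SEM undefined
  fs1 <- peak_force_stats(ev[1, ])
  expect_true(is.na(fs1$summary$sem))
  expect_error(peak_force_stats(ev[0, ]), "Empty")
  # normal recovery: n = 100 draws from N(25.2, 5)
  draws <- withr::with_seed(5, rnorm(100, 25.2, 5))
  ev2 <- tibble::tibble(type = "stall", direction = "retrograde",
                        t_start = seq_len(100), t_end = seq_len(100) + 0.5,
                        peak_force = draws, stall_duration = 0.2)
  fs2 <- peak_force_stats(ev2)
  expect_lt(abs(fs2$summary$mean - 25.2), 2 * fs2$summary$sem + 1e-9)
})

test_that("recoil fits return gamma = kappa tau exactly on noiseless decays", {
  tau <- 0.02
  tt <- seq(0, 0.15, by = 5e-4)
  seg <- tibble::tibble(t = tt, x = 80 * exp(-tt / tau))
  f <- fit_recoil(seg, kappa = 0.4)
  expect_equal(f$gamma, 8.0, tolerance = 1e-6)
  expect_equal(f$tau, tau, tolerance = 1e-8)
  # doubling tau doubles gamma
  seg2 <- tibble::tibble(t = tt, x = 80 * exp(-tt / (2 * tau)))
  expect_equal(fit_recoil(seg2, kappa = 0.4)$gamma, 16, tolerance = 1e-6)
  # failure modes
  expect_error(fit_recoil(seg[1:5, ], kappa = 0.4), "few samples")
  grow <- tibble::tibble(t = tt, x = 80 * exp(tt / tau))
  expect_error(fit_recoil(grow, kappa = 0.4), "decay|rejected")
})

test_that("oscillation protocol recovers the drag constant", {
  tr <- simulate_trap_oscillation(gamma = 8.4, kappa = 0.07, duration = 30,
                                  seed = 7)
  fit <- oscillation_drag(tr)
  expect_equal(fit$gamma_mean, 8.4, tolerance = 0.1)
  expect_equal(mean(fit$fits$tau), 8.4 / 1000 / 0.07, tolerance = 0.1)
  # a trace without steps is rejected
  flat <- structure(list(data = tibble::tibble(t = seq(0, 1, 5e-4),
                                               x = rnorm(2001)),
                         schedule = NULL),
                    kappa = 0.07, class = "trap_trace")
  expect_error(oscillation_drag(flat), "schedule")
})

test_that("recoil and oscillation drag estimates agree on a common gamma", {
  g <- 8.0
  recoils <- vapply(1:40, function(s) {
    tc <- trap_sim_config(run_rate = 0, drag = g, seed = 5000 + s)
    tr <- simulate_trap_trace(tc, duration = 0.25, x0 = 100)
    fit_recoil(tr$data, kappa = 0.4)$gamma
  }, numeric(1))
  osc <- oscillation_drag(simulate_trap_oscillation(gamma = g, duration = 30,
                                                    seed = 9))
  expect_lt(abs(mean(recoils) - osc$gamma_mean) / g, 0.15)
})

test_that("motor counts and drag forces follow their closed forms", {
  expect_equal(motor_count(25.2, 7), 4L)
  expect_equal(motor_count(6.99, 7), 1L)
  expect_equal(motor_count(21.4, 6), 4L)
  # monotone non-decreasing in the peak force
  ff <- seq(1, 60, by = 0.5)
  expect_true(all(diff(motor_count(ff, 7)) >= 0))
  expect_error(motor_count(10, 0), "f_single")

  expect_equal(drag_force(8, 3), 24)
  expect_equal(drag_force(8, 2), 16)
  expect_equal(drag_force(8, 0), 0)
  expect_equal(drag_force(2 * 8, 3), 2 * drag_force(8, 3))
  expect_error(drag_force(-1, 3), "gamma")
  expect_equal(trap_force(0.4, 200), 80)
})
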