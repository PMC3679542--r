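#' Simulate a bead-in-trap displacement trace with motor events
#'
#' Integrates the overdamped Langevin dynamics of a bead in a harmonic trap,
#' `x(t+dt) = x + dt (F_motor - kappa x) / gamma + N(0, 2 kT dt / gamma)`,
#' while IFT motors execute runs: the motor force ramps at
#' `kappa * motor_velocity` until a drawn stall force is reached, holds
#' through a drawn dwell, then detaches (exponential recoil to the trap
#' centre) - or, for an escape run, keeps ramping past the detector's linear
#' range. Ground-truth labels record every stall, release and escape with its
#' true peak force.
#'
#' Runs whose drawn dwell is shorter than 0.1 s are releases by the stall
#' definition (velocity zero for at least 100 ms); premature detachment
#' during a ramp also yields a release.
#'
#' @param config A [trap_sim_config()].
#' @param duration Trace duration, s.
#' @param x0 Initial displacement, nm (for controlled relaxation tests).
#' @return A `trap_trace`: list with `data` (tibble `t`, `x` in nm), `events`
#'   (tibble `type`, `direction`, `t_start`, `t_end`, `peak_force` pN,
#'   `stall_duration` s), and `config`; attributes `kappa`, `kT`,
#'   `sampling_rate`, `range_nm`, `orientation` (`"retro_positive"`).
#' @export
simulate_trap_trace <- function(config, duration = 10, x0 = 0) {
  if (!inherits(config, "trap_sim_config")) {
    abort("`config` must be a trap_sim_config.")
  }
  dt <- 1 / config$sampling_rate
  gamma_nm <- config$drag / 1000         # pN s/nm
  kappa <- config$stiffness
  if (dt * kappa / gamma_nm >= 1) {
    abort("Unstable integration: dt * kappa / gamma >= 1.")
  }
  n <- floor(duration / dt) + 1L
  noise_sd <- sqrt(2 * config$kT * dt / gamma_nm)
  ramp_rate <- kappa * config$motor_velocity * 1000  # pN/s
  sigma_th <- if (config$kT > 0) sqrt(config$kT / kappa) else 0

  x <- numeric(n)
  x[1] <- x0
  events <- list()

  with_seed(config$seed, {
    noise <- if (noise_sd > 0) rnorm(n, 0, noise_sd) else numeric(n)
    state <- "idle"
    f <- 0; dir <- 0
    f_stall <- NA_real_; dwell <- NA_real_; dwell_left <- NA_real_
    is_escape <- FALSE; t_run_start <- NA_real_; peak <- 0
    next_run <- if (config$run_rate > 0) rexp(1, config$run_rate) else Inf

    finish_run <- function(t_now, type) {
      events[[length(events) + 1L]] <<- tibble(
        type = type,
        direction = if (dir > 0) "retrograde" else "anterograde",
        t_start = t_run_start, t_end = t_now,
        peak_force = peak,
        stall_duration = if (type == "stall") dwell else
          if (type == "release" && !is.na(dwell)) dwell else 0
      )
    }

    for (k in seq_len(n - 1L)) {
      t_now <- (k - 1) * dt
      if (state == "idle" && t_now >= next_run) {
        state <- "ramp"
        dir <- if (runif(1) < config$p_retrograde) 1 else -1
        f_stall <- max(1, rnorm(1, config$stall_force_mean,
                                config$stall_force_sd))
        is_escape <- runif(1) < config$escape_fraction
        dwell <- rexp(1, 1 / config$stall_dwell_mean)
        dwell_left <- dwell
        t_run_start <- t_now
        f <- 0; peak <- 0
      }
      if (state == "ramp") {
        f <- f + ramp_rate * dt
        peak <- f  # true motor force; the trap force follows with lag tau
        if (is_escape) {
          if (abs(x[k]) > 1.3 * config$range_nm) {
            finish_run(t_now, "escape")
            state <- "recoil"; f <- 0
          }
        } else if (f >= f_stall) {
          f <- f_stall
          peak <- f_stall
          state <- "stall"
        } else if (config$detach_probability > 0 &&
                   runif(1) < config$detach_probability) {
          dwell <- 0
          finish_run(t_now, "release")
          state <- "recoil"; f <- 0
        }
      } else if (state == "stall") {
        dwell_left <- dwell_left - dt
        if (dwell_left <= 0) {
          finish_run(t_now, if (dwell >= 0.1) "stall" else "release")
          state <- "recoil"; f <- 0
        }
      } else if (state == "recoil") {
        if (abs(x[k]) < max(2 * sigma_th, 1)) {
          state <- "idle"
          next_run <- t_now +
            if (config$run_rate > 0) rexp(1, config$run_rate) else Inf
        }
      }
      drift <- dt * (dir * f - kappa * x[k]) / gamma_nm
      x[k + 1L] <- x[k] + drift + noise[k]
    }
  })

  ev <- if (length(events)) dplyr::bind_rows(events) else
    tibble(type = character(), direction = character(), t_start = numeric(),
           t_end = numeric(), peak_force = numeric(),
           stall_duration = numeric())
  structure(list(data = tibble(t = (seq_len(n) - 1) * dt, x = x),
                 events = ev, config = config),
            kappa = kappa, kT = config$kT,
            sampling_rate = config$sampling_rate,
            range_nm = config$range_nm, orientation = "retro_positive",
            class = "trap_trace")
}

#' Simulate a square-wave trap-oscillation trace
#'
#' The trap centre jumps between `+amplitude` and `-amplitude` nm at
#' `2 * frequency` steps per second while the bead, coupled to the membrane
#' but not to transport, relaxes toward each new centre with time constant
#' `gamma / kappa`.
#'
#' @param gamma Drag constant, pN s/um.
#' @param kappa Trap stiffness, pN/nm (0.07 in the oscillation assay).
#' @param amplitude Square-wave amplitude, nm (trap centre alternates between
#'   `+amplitude` and `-amplitude`).
#' @param frequency Square-wave frequency, Hz.
#' @param duration Trace duration, s.
#' @param kT Thermal energy, pN nm.
#' @param sampling_rate Hz.
#' @param seed Integer seed.
#' @return A `trap_trace` whose `schedule` element gives the step times and
#'   centres.
#' @export
simulate_trap_oscillation <- function(gamma = 8.4, kappa = 0.07,
                                      amplitude = 500, frequency = 0.2,
                                      duration = 30, kT = 4.11,
                                      sampling_rate = 2000, seed = 1) {
  dt <- 1 / sampling_rate
  gamma_nm <- gamma / 1000
  if (dt * kappa / gamma_nm >= 1) abort("Unstable integration step.")
  n <- floor(duration / dt) + 1L
  t <- (seq_len(n) - 1) * dt
  half <- 1 / (2 * frequency)
  centre <- ifelse((t %/% half) %% 2 == 0, -amplitude, amplitude)
  noise_sd <- sqrt(2 * kT * dt / gamma_nm)
  x <- numeric(n)
  x[1] <- centre[1]
  with_seed(seed, {
    noise <- if (noise_sd > 0) rnorm(n, 0, noise_sd) else numeric(n)
    for (k in seq_len(n - 1L)) {
      x[k + 1L] <- x[k] + dt * kappa * (centre[k] - x[k]) / gamma_nm + noise[k]
    }
  })
  steps <- which(diff(centre) != 0)
  schedule <- tibble(t_step = t[steps + 1L], centre = centre[steps + 1L])
  structure(list(data = tibble(t = t, x = x), events = NULL,
                 schedule = schedule,
                 config = list(gamma = gamma, kappa = kappa,
                               amplitude = amplitude, frequency = frequency,
                               kT = kT, sampling_rate = sampling_rate,
                               seed = seed)),
            kappa = kappa, kT = kT, sampling_rate = sampling_rate,
            range_nm = Inf, orientation = "retro_positive",
            class = "trap_trace")
}

#' @export
print.trap_trace <- function(x, ...) {
  cat(sprintf("<trap_trace> %.1f s at %g Hz, kappa = %g pN/nm",
              max(x$data$t), attr(x, "sampling_rate"), attr(x, "kappa")))
  if (!is.null(x$events) && nrow(x$events)) {
    cat(sprintf(", %d labelled events", nrow(x$events)))
  }
  cat("\n")
  invisible(x)
}

#' @export
autoplot.trap_trace <- function(object, ...) {
  kappa <- attr(object, "kappa")
  p <- ggplot2::ggplot(object$data, ggplot2::aes(x = .data$t, y = .data$x)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::labs(x = "time (s)", y = "displacement (nm)") +
    ggplot2::scale_y_continuous(
      sec.axis = ggplot2::sec_axis(~ . * kappa, name = "force (pN)")) +
    ggplot2::theme_minimal()
  if (!is.null(object$events) && nrow(object$events)) {
    p <- p + ggplot2::geom_rect(
      data = object$events, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$t_start, xmax = .data$t_end,
                   ymin = -Inf, ymax = Inf, fill = .data$type),
      alpha = 0.15)
  }
  p
}
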