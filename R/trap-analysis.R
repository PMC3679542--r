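#' Calibrate trap stiffness by equipartition
#'
#' `kappa = kT / var(x)` over a motor-free segment. Stationarity is checked
#' by the split-half variance ratio, which must lie in `[0.5, 2]`.
#'
#' @param trace A `trap_trace`, or a tibble with `t` (s) and `x` (nm).
#' @param kT Thermal energy, pN nm (default: trace metadata, else 4.11).
#' @return A one-row tibble: `kappa` (pN/nm), `variance` (nm^2), `n`,
#'   `variance_ratio`.
#' @export
calibrate_stiffness <- function(trace, kT = NULL) {
  d <- trace_data(trace)
  kT <- kT %||% attr(trace, "kT") %||% 4.11
  if (diff(range(d$t)) < 1) abort("Calibration segment must be at least 1 s.")
  x <- d$x - mean(d$x)
  half <- floor(length(x) / 2)
  x1 <- x[seq_len(half)]; x2 <- x[(half + 1):length(x)]
  ratio <- var(x1) / var(x2)
  if (ratio < 0.5 || ratio > 2) {
    abort(sprintf("Non-stationary segment: split-half variance ratio %.2f outside [0.5, 2].",
                  ratio))
  }
  # a drifting baseline can keep the variance ratio near 1: also require the
  # split-half means to agree within one within-half sd
  shift <- abs(mean(x1) - mean(x2)) / sqrt((var(x1) + var(x2)) / 2)
  if (shift > 1) {
    abort(sprintf("Non-stationary segment: split-half mean shift of %.1f sd suggests drift.",
                  shift))
  }
  v <- var(x)
  tibble(kappa = kT / v, variance = v, n = length(x), variance_ratio = ratio)
}

trace_data <- function(trace) {
  if (inherits(trace, "trap_trace")) return(trace$data)
  if (is.data.frame(trace) && all(c("t", "x") %in% names(trace))) return(trace)
  abort("`trace` must be a trap_trace or a tibble with columns t, x.")
}

#' Force at a given trap displacement
#'
#' @param kappa Trap stiffness, pN/nm.
#' @param x_nm Displacement, nm.
#' @return Force in pN (`kappa * x_nm`).
#' @export
trap_force <- function(kappa, x_nm) {
  if (any(kappa <= 0)) abort("`kappa` must be positive.")
  kappa * x_nm
}

#' Classify stall, release and escape events in a trap trace
#'
#' Excursions from the trap-centre baseline are segmented with hysteresis;
#' within each, the sliding mean velocity identifies the plateau at the
#' excursion peak. A plateau of at least `stall_min` is a stall; a peak
#' reached and returned with a shorter plateau is a release; displacement
#' beyond the detector's linear range (`range_nm`, equivalently a force above
#' `force_cap`) is an escape. Peak force is `kappa * max |x - baseline|`
#' within the event.
#'
#' @param trace A `trap_trace` (calibrated: `kappa` attribute or argument).
#' @param kappa Trap stiffness, pN/nm (default: trace metadata).
#' @param stall_min Minimum plateau duration for a stall, s (0.1 = 100 ms).
#' @param v_window Sliding velocity window, s (must be < `stall_min`).
#' @param range_nm Detector linear range, nm.
#' @param force_cap Escape force threshold, pN (with the reference stiffness
#'   0.4 pN/nm, 80 pN corresponds to 200 nm).
#' @param start_sd,stop_sd Excursion hysteresis thresholds in units of the
#'   thermal displacement sd.
#' @return A tibble of events: `type`, `direction`, `t_start`, `t_end`,
#'   `peak_force` (pN), `stall_duration` (s).
#' @export
classify_events <- function(trace, kappa = NULL, stall_min = 0.1,
                            v_window = 0.02, range_nm = 200, force_cap = 80,
                            start_sd = 5, stop_sd = 2.5) {
  kappa <- kappa %||% attr(trace, "kappa")
  if (is.null(kappa)) abort("Uncalibrated trace: supply `kappa`.")
  if (v_window >= stall_min) abort("`v_window` must be smaller than `stall_min`.")
  d <- trace_data(trace)
  kT <- attr(trace, "kT") %||% 4.11
  orientation <- attr(trace, "orientation") %||% NA_character_
  dt <- median(diff(d$t))
  sigma <- sqrt(kT / kappa)

  # Baseline: mode of the trace within +/- 2 thermal sd of the median.
  core <- d$x[abs(d$x - median(d$x)) < 2 * sigma]
  if (length(core) < 10) core <- d$x
  dens <- density(core)
  baseline <- dens$x[which.max(dens$y)]
  y <- d$x - baseline

  hi <- abs(y) > start_sd * sigma
  lo <- abs(y) > stop_sd * sigma
  n <- length(y)

  # Hysteresis segmentation: an excursion spans from where |y| last rose
  # through the stop threshold to where it falls back below it, and must
  # cross the start threshold in between.
  events <- list()
  k <- 1L
  while (k <= n) {
    if (!hi[k]) { k <- k + 1L; next }
    i0 <- k
    while (i0 > 1L && lo[i0 - 1L]) i0 <- i0 - 1L
    i1 <- k
    while (i1 < n && lo[i1 + 1L]) i1 <- i1 + 1L
    seg <- y[i0:i1]
    peak_idx <- which.max(abs(seg))
    peak_x <- abs(seg[peak_idx])
    dir_sign <- sign(seg[peak_idx])
    plateau <- 0
    force <- kappa * min(peak_x, range_nm)
    if (peak_x >= range_nm || kappa * peak_x >= force_cap) {
      type <- "escape"
    } else {
      w <- max(2L, round(v_window / dt))
      h <- max(1L, w %/% 2)
      sm <- running_mean(seg, w)
      ns <- length(sm)
      # centred sliding mean velocity over ~v_window
      v <- (sm[pmin(seq_len(ns) + h, ns)] - sm[pmax(seq_len(ns) - h, 1L)]) /
        ((pmin(seq_len(ns) + h, ns) - pmax(seq_len(ns) - h, 1L)) * dt)
      # thermal velocity floor of the windowed difference estimator
      v_floor <- 2 * sqrt(2) * sigma / (2 * h * dt)
      slow <- abs(v) < v_floor
      # merge brief noise-induced gaps so one plateau is one run
      slow <- fill_gaps(slow, max_gap = max(1L, round(0.25 * stall_min / dt)))
      runs <- rle(slow)
      ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
      hit <- which(runs$values & starts <= peak_idx & ends >= peak_idx)
      if (length(hit)) {
        pi0 <- starts[hit[1]]; pi1 <- ends[hit[1]]
        plateau <- (pi1 - pi0 + 1L) * dt
        # stall force = trap force at zero mean velocity (plateau level);
        # less biased than the running max under thermal noise
        level <- abs(mean(seg[pi0:pi1]))
        force <- kappa * level
        # The cargo approaches the plateau with the trap relaxation time, so
        # the velocity criterion starts the clock ~tau * ln(v_entry/v_floor)
        # after the motor actually stalled; estimate tau from this
        # excursion's own recoil and add the entry lag back.
        ns_seg <- length(seg)
        if (pi1 < ns_seg) {
          rec_idx <- which(abs(seg[pi1:ns_seg]) <= level / exp(1))[1]
          if (!is.na(rec_idx) && rec_idx > 1) {
            tau_hat <- (rec_idx - 1L) * dt
            pre <- max(1L, pi0 - 2L * h):max(1L, pi0 - 1L)
            v_entry <- max(abs(v[pre]))
            if (is.finite(v_entry) && v_entry > v_floor) {
              plateau <- plateau + tau_hat * log(v_entry / v_floor)
            }
          }
        }
      }
      type <- if (plateau >= stall_min) "stall" else "release"
    }
    direction <- if (is.na(orientation)) {
      "unknown"
    } else if (orientation == "retro_positive") {
      if (dir_sign > 0) "retrograde" else "anterograde"
    } else {
      if (dir_sign > 0) "anterograde" else "retrograde"
    }
    events[[length(events) + 1L]] <- tibble(
      type = type, direction = direction,
      t_start = d$t[i0], t_end = d$t[i1],
      peak_force = force,
      stall_duration = if (type == "stall") plateau else
        if (type == "release") plateau else NA_real_
    )
    k <- i1 + 1L
  }
  if (length(events)) dplyr::bind_rows(events) else
    tibble(type = character(), direction = character(), t_start = numeric(),
           t_end = numeric(), peak_force = numeric(),
           stall_duration = numeric())
}

# Set FALSE runs of length <= max_gap between TRUE runs to TRUE.
fill_gaps <- function(x, max_gap) {
  runs <- rle(x)
  n <- length(runs$values)
  for (i in seq_len(n)) {
    if (!runs$values[i] && runs$lengths[i] <= max_gap && i > 1 && i < n) {
      runs$values[i] <- TRUE
    }
  }
  inverse.rle(runs)
}

running_mean <- function(x, w) {
  if (w <= 1L) return(x)
  cs <- cumsum(c(0, x))
  n <- length(x)
  i0 <- pmax(1L, seq_len(n) - w + 1L)
  (cs[seq_len(n) + 1L] - cs[i0]) / (seq_len(n) - i0 + 1L)
}

#' Peak-force statistics per direction and event type
#'
#' @param events Event tibble from [classify_events()] or simulator labels.
#' @param bin_width Histogram bin width, pN (default 2.5).
#' @return A `force_stats` (list): `summary` tibble (`direction`, `type`,
#'   `n`, `mean`, `sem`), `fractions` tibble (`direction`, `type`,
#'   `fraction`), `histogram` tibble (`direction`, `type`, `bin_mid`,
#'   `count`), `bin_width`.
#' @export
peak_force_stats <- function(events, bin_width = 2.5) {
  if (!nrow(events)) abort("Empty event list.")
  summary <- events |>
    dplyr::group_by(.data$direction, .data$type) |>
    dplyr::summarise(
      n = dplyr::n(), mean = mean(.data$peak_force),
      sem = if (dplyr::n() > 1) sd(.data$peak_force) / sqrt(dplyr::n()) else NA_real_,
      .groups = "drop")
  fractions <- events |>
    dplyr::group_by(.data$direction) |>
    dplyr::count(.data$type) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::select("direction", "type", "fraction")
  histogram <- events |>
    dplyr::mutate(bin_mid = (floor(.data$peak_force / bin_width) + 0.5) * bin_width) |>
    dplyr::count(.data$direction, .data$type, .data$bin_mid, name = "count")
  structure(list(summary = summary, fractions = fractions,
                 histogram = histogram, bin_width = bin_width),
            class = "force_stats")
}

#' @export
print.force_stats <- function(x, ...) {
  cat("<force_stats>\n")
  print(as.data.frame(x$summary), row.names = FALSE)
  invisible(x)
}

#' @export
tidy.force_stats <- function(x, ...) x$summary

#' @export
autoplot.force_stats <- function(object, ...) {
  ggplot2::ggplot(object$histogram,
                  ggplot2::aes(x = .data$bin_mid, y = .data$count,
                               fill = .data$type)) +
    ggplot2::geom_col(width = object$bin_width * 0.9) +
    ggplot2::facet_wrap(~direction) +
    ggplot2::labs(x = "peak force (pN)", y = "events", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Fit an exponential recoil and estimate the drag constant
#'
#' After motor detachment the bead relaxes to the trap centre as
#' `x(t) = x0 exp(-t / tau) + baseline` with `tau = gamma / kappa`; the fit
#' therefore yields the drag constant `gamma = kappa * tau` (in pN s/um with
#' kappa in pN/nm and tau in s, via a factor 1000).
#'
#' @param segment Tibble with `t` (s) and `x` (nm), starting at the event
#'   end with `|x|` decaying toward baseline.
#' @param kappa Trap stiffness, pN/nm.
#' @param min_r_squared Fits below this R^2 are rejected (default 0.8).
#' @return A `drag_fit` (list): `gamma` (pN s/um), `tau` (s), `r_squared`,
#'   `x0`, `baseline`, `n`, `kappa`.
#' @export
fit_recoil <- function(segment, kappa, min_r_squared = 0.8) {
  d <- trace_data(segment)
  if (nrow(d) < 10) abort("Too few samples for a recoil fit (need >= 10).")
  check_number(kappa, "kappa", min = 0, strict_min = TRUE)
  t0 <- d$t[1]
  tt <- d$t - t0
  b0 <- mean(tail(d$x, max(3, nrow(d) %/% 10)))
  a0 <- d$x[1] - b0
  if (abs(a0) < 1e-9) abort("Segment does not decay: zero initial amplitude.")
  if (abs(d$x[1] - b0) < abs(d$x[nrow(d)] - b0)) {
    abort("Segment does not decay toward baseline.")
  }
  # initial tau: time to reach 1/e of the initial amplitude
  idx <- which(abs(d$x - b0) <= abs(a0) / exp(1))[1]
  tau0 <- if (!is.na(idx) && tt[idx] > 0) tt[idx] else max(tt) / 3
  fit <- tryCatch(
    minpack.lm::nlsLM(x ~ b + a * exp(-tt / tau),
                      data = tibble(x = d$x, tt = tt),
                      start = list(a = a0, b = b0, tau = tau0),
                      lower = c(a = -Inf, b = -Inf, tau = 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) abort(paste0("Recoil fit failed: ", conditionMessage(e)))
  )
  p <- coef(fit)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((d$x - mean(d$x))^2)
  r2 <- if (tss > 0) 1 - rss / tss else 1
  if (r2 < min_r_squared) {
    abort(sprintf("Recoil fit rejected: R^2 = %.3f < %.2f.", r2, min_r_squared))
  }
  structure(list(gamma = 1000 * kappa * p[["tau"]], tau = p[["tau"]],
                 r_squared = r2, x0 = p[["a"]], baseline = p[["b"]],
                 n = nrow(d), kappa = kappa),
            class = "drag_fit")
}

#' @export
print.drag_fit <- function(x, ...) {
  cat(sprintf("<drag_fit> gamma = %.2f pN s/um (tau = %.1f ms, R^2 = %.3f, n = %d)\n",
              x$gamma, 1000 * x$tau, x$r_squared, x$n))
  invisible(x)
}

#' @export
glance.drag_fit <- function(x, ...) {
  tibble(gamma = x$gamma, tau = x$tau, r_squared = x$r_squared, n = x$n,
         kappa = x$kappa)
}

#' Drag constant from a square-wave trap-oscillation trace
#'
#' After each square-wave step the bead relaxes toward the new trap centre
#' with time constant `gamma / kappa`; per-step exponential fits are pooled
#' into a mean and SD of the drag constant.
#'
#' @param trace A `trap_trace` from [simulate_trap_oscillation()] (or any
#'   trace with a `schedule` tibble of `t_step`, `centre`).
#' @param kappa Trap stiffness, pN/nm (default: trace metadata).
#' @param min_r_squared Per-step fit quality threshold.
#' @return An `oscillation_fit` (list): `gamma_mean`, `gamma_sd`,
#'   `gamma_sem`, `n_steps`, `fits` tibble.
#' @export
oscillation_drag <- function(trace, kappa = NULL, min_r_squared = 0.8) {
  kappa <- kappa %||% attr(trace, "kappa")
  if (is.null(kappa)) abort("Supply `kappa`.")
  sched <- trace$schedule
  if (is.null(sched) || !nrow(sched)) abort("Trace has no square-wave schedule.")
  d <- trace_data(trace)
  dt <- median(diff(d$t))
  step_bounds <- c(sched$t_step, max(d$t) + dt)
  fits <- list()
  for (i in seq_len(nrow(sched))) {
    t0 <- sched$t_step[i]
    t1 <- step_bounds[i + 1L]
    seg <- d[d$t >= t0 & d$t < t1, , drop = FALSE]
    if (nrow(seg) < 10) next
    f <- tryCatch(fit_recoil(tibble(t = seg$t, x = seg$x - sched$centre[i]),
                             kappa, min_r_squared),
                  error = function(e) NULL)
    if (is.null(f)) next
    if ((t1 - t0) < 3 * f$tau) {
      abort("Square-wave steps are shorter than 3 relaxation times; gamma is not identifiable.")
    }
    fits[[length(fits) + 1L]] <- tibble(step = i, gamma = f$gamma,
                                        tau = f$tau, r_squared = f$r_squared)
  }
  if (!length(fits)) abort("No usable relaxation steps found.")
  ft <- dplyr::bind_rows(fits)
  structure(list(gamma_mean = mean(ft$gamma), gamma_sd = sd(ft$gamma),
                 gamma_sem = sd(ft$gamma) / sqrt(nrow(ft)),
                 n_steps = nrow(ft), fits = ft, kappa = kappa),
            class = "oscillation_fit")
}

#' @export
print.oscillation_fit <- function(x, ...) {
  cat(sprintf("<oscillation_fit> gamma = %.2f +/- %.2f (SD) pN s/um over %d steps\n",
              x$gamma_mean, x$gamma_sd, x$n_steps))
  invisible(x)
}

#' @export
glance.oscillation_fit <- function(x, ...) {
  tibble(gamma_mean = x$gamma_mean, gamma_sd = x$gamma_sd,
         gamma_sem = x$gamma_sem, n_steps = x$n_steps)
}

#' Minimum motor count from a peak force
#'
#' `ceiling(F_peak / f_single)`: the smallest number of motors, each
#' producing at most `f_single`, able to generate `F_peak`.
#'
#' @param F_peak Peak force, pN.
#' @param f_single Single-motor stall force, pN (kinesin-2 / dynein: 6-7).
#' @return Integer motor count (vectorized).
#' @export
motor_count <- function(F_peak, f_single) {
  if (any(f_single <= 0)) abort("`f_single` must be positive.")
  as.integer(ceiling(F_peak / f_single))
}

#' Viscous drag force at a transport velocity
#'
#' @param gamma Drag constant, pN s/um.
#' @param v Velocity, um/s.
#' @return Force in pN (`gamma * v`).
#' @export
drag_force <- function(gamma, v) {
  if (any(gamma < 0)) abort("`gamma` must be non-negative.")
  gamma * v
}
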