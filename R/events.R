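#' Bead-train colocalization test against a randomized null
#'
#' For each bead sample, the observed statistic is the distance to the
#' nearest train moving in the same direction at that time. The null
#' distribution is built by circularly resampling each train track's start
#' time uniformly in the acquisition window (geometry and speed preserved,
#' temporal registration destroyed) `n_null` times. A two-sample
#' Kolmogorov-Smirnov test compares observed distances with the pooled null.
#'
#' @param bead Tibble with `t`, `s` and a `direction` column giving the
#'   bead's direction of motion at each sample (`"anterograde"`,
#'   `"retrograde"`, or `NA` to match any train). A bead track from
#'   [simulate_bead()] is accepted: direction is derived from the coupled
#'   train when available, otherwise from the local sign of motion.
#' @param track Train track tibble (`train_id`, `direction`, `t`, `s`), e.g.
#'   `truth$track`.
#' @param n_null Number of track randomizations (>= 10).
#' @param seed Integer seed for the randomization.
#' @param duration Acquisition window, s (default: span of the track times).
#' @param stride_s Spacing between evaluated bead samples, s (default 1).
#'   Consecutive frames give strongly autocorrelated distances; the KS test
#'   assumes independent samples, so bead samples are decimated to roughly
#'   the distance decorrelation time (a train at ~2.5 um/s changes the
#'   nearest-distance field on the ~1 s scale). Set to 0 to use every frame.
#' @return A `coloc_test` (list): `statistic` (KS D), `p_value`, `observed`
#'   and `null` distance vectors, `n_obs`, `n_null`, `seed`.
#' @export
colocalization_test <- function(bead, track, n_null = 100, seed = 1,
                                duration = NULL, stride_s = 1) {
  if (n_null < 10) abort("`n_null` must be at least 10.")
  if (!nrow(track)) abort("No train samples supplied.")
  duration <- duration %||% max(track$t)

  bead <- infer_bead_direction(bead, track)
  if (stride_s > 0 && nrow(bead) > 2) {
    dt_b <- median(diff(bead$t))
    step <- max(1L, round(stride_s / dt_b))
    bead <- bead[seq(1, nrow(bead), by = step), , drop = FALSE]
  }

  obs <- nearest_same_direction_distance(bead, track)
  if (!length(obs)) abort("No evaluable bead samples (no same-direction train).")

  # Circular time-shifts are drawn on the frame grid so the shifted tracks
  # remain sampled at the same time points as the data.
  dt <- median(diff(sort(unique(track$t))))
  n_steps <- ceiling(duration / dt)
  period <- n_steps * dt
  null_reps <- with_seed(seed, {
    ids <- unique(track$train_id)
    lapply(seq_len(n_null), function(rep) {
      shifts <- setNames(sample.int(n_steps, length(ids), replace = TRUE) * dt,
                         as.character(ids))
      shifted <- track
      shifted$t <- round(((track$t + shifts[as.character(track$train_id)]) %%
                            period) / dt) * dt
      nearest_same_direction_distance(bead, shifted, tol = dt / 2)
    })
  })
  null_d <- unlist(null_reps)

  # The KS distance of the observed distances to the pooled null is the test
  # statistic; its significance is computed by the Monte-Carlo rank among the
  # same statistic evaluated for each null replicate (exchangeable under the
  # null, so the p-value is calibrated even with a finite, mixed null pool).
  ks_d <- function(x, pool) {
    suppressWarnings(unname(ks.test(x, pool)$statistic))
  }
  d_obs <- ks_d(obs, null_d)
  d_null <- vapply(seq_len(n_null), function(i) {
    ks_d(null_reps[[i]], unlist(null_reps[-i]))
  }, numeric(1))
  p <- (1 + sum(d_null >= d_obs)) / (n_null + 1)

  structure(list(statistic = d_obs, p_value = p,
                 observed = obs, null = null_d, null_statistics = d_null,
                 n_obs = length(obs), n_null = n_null, seed = seed),
            class = "coloc_test")
}

# Distance from each bead sample to the nearest same-direction train at the
# same (within tol) time point. Vectorized: track samples are matched to bead
# samples through a shared time grid, then distances are min-aggregated per
# bead sample and direction.
nearest_same_direction_distance <- function(bead, track, tol = NULL) {
  dt <- median(diff(sort(unique(track$t))))
  tol <- tol %||% (dt / 2 + 1e-9)
  grid <- round(bead$t / tol)
  # map each track sample to the bead sample sharing its time cell
  key <- match(round(track$t / tol), grid)
  ok <- !is.na(key)
  min_by_bead <- function(rows) {
    out <- rep(Inf, nrow(bead))
    if (!any(rows)) return(out)
    d <- abs(track$s[rows] - bead$s[key[rows]])
    agg <- tapply(d, key[rows], min)
    out[as.integer(names(agg))] <- agg
    out
  }
  d_ant <- min_by_bead(ok & track$direction == "anterograde")
  d_ret <- min_by_bead(ok & track$direction == "retrograde")
  res <- ifelse(is.na(bead$direction), pmin(d_ant, d_ret),
                ifelse(bead$direction == "anterograde", d_ant, d_ret))
  res[is.finite(res)]
}

infer_bead_direction <- function(bead, track) {
  if ("direction" %in% names(bead)) return(bead)
  dir <- rep(NA_character_, nrow(bead))
  if ("coupled_train" %in% names(bead)) {
    m <- match(bead$coupled_train,
               track$train_id[!duplicated(track$train_id)])
    dirs_by_id <- track$direction[!duplicated(track$train_id)]
    dir <- ifelse(is.na(bead$coupled_train), NA_character_, dirs_by_id[m])
  }
  bead$direction <- dir
  bead
}

#' @export
print.coloc_test <- function(x, ...) {
  cat(sprintf("<coloc_test> KS D = %.4f, p = %.3g (%d obs vs %d pooled null)\n",
              x$statistic, x$p_value, x$n_obs, length(x$null)))
  invisible(x)
}

#' @export
glance.coloc_test <- function(x, ...) {
  tibble(statistic = x$statistic, p_value = x$p_value, n_obs = x$n_obs,
         n_null = x$n_null, seed = x$seed)
}

#' Detect pauses in position tracks and estimate the pausing frequency
#'
#' A pause is a maximal interval in which the speed stays below `v_thresh`
#' for at least `min_duration`, within a track that moves before or after
#' the interval; the interval boundaries come from single-frame
#' displacements (whose phase error is symmetric, keeping the duration
#' estimate unbiased), while the prior direction uses the smoother central
#' difference. Tracks that never move during the whole acquisition are
#' excluded. The pausing frequency is the number of events divided by the
#' acquisition time; because pauses shorter than `min_duration` are
#' censored, a corrected frequency is also reported assuming exponentially
#' distributed pause durations (mean estimated from the detected durations
#' minus the threshold).
#'
#' @param tracks Track tibble with `t`, `s` and a grouping column
#'   (`train_id` or `track_id`); or a list of such tibbles.
#' @param v_thresh Pause speed threshold, um/s (default 0.2).
#' @param min_duration Minimum pause duration, s (default 0.4 = 2 frames at
#'   5 fps).
#' @param acquisition_time Acquisition time, s (default: span of `t`).
#' @param n_flagella Number of flagella pooled in `tracks` (for the
#'   per-flagellum frequency).
#' @return A `pause_set` (list): `events` tibble (`track`, `position`,
#'   `t_start`, `t_end`, `duration`, `prior_direction`), `frequency`
#'   (events/s, raw), `frequency_corrected` (censoring-corrected),
#'   `frequency_per_flagellum`, `acquisition_time`, `n_excluded_immotile`.
#' @export
detect_pauses <- function(tracks, v_thresh = 0.2, min_duration = 0.4,
                          acquisition_time = NULL, n_flagella = 1) {
  if (v_thresh <= 0) abort("`v_thresh` must be positive.")
  if (inherits(tracks, "kymograph")) {
    abort("Pass tracks; for a pause-component kymograph use extract_tracks() with a wide gate, or pause_profile() for intensity profiles.")
  }
  if (is.data.frame(tracks)) {
    key <- intersect(c("train_id", "track_id"), names(tracks))
    tracks <- if (length(key)) split(tracks, tracks[[key[1]]]) else list(tracks)
  }
  acquisition_time <- acquisition_time %||%
    diff(range(unlist(lapply(tracks, function(x) x$t))))

  events <- list()
  n_immotile <- 0L
  for (nm in seq_along(tracks)) {
    tr <- tracks[[nm]]
    tr <- tr[order(tr$t), ]
    n <- nrow(tr)
    if (n < 3) next
    v <- central_velocity(tr$t, tr$s)     # for the prior-direction call
    dt_tr <- median(diff(tr$t))
    # pause intervals from single-frame displacements: a frame-to-frame gap
    # is sub-threshold only when it lies inside the pause, so the interval
    # estimate [t_first_gap, t_last_gap+1] + one frame has a phase error
    # that is symmetric about zero (unlike the two-frame central window,
    # whose censoring is one-sided)
    gv <- diff(tr$s) / diff(tr$t)
    slow <- abs(gv) < v_thresh
    if (all(slow)) {          # immotile for the whole acquisition: excluded
      n_immotile <- n_immotile + 1L
      next
    }
    runs <- rle(slow)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (k in which(runs$values)) {
      g0 <- starts[k]; g1 <- ends[k]     # gap indices: samples g0 .. g1+1
      dur <- tr$t[g1 + 1L] - tr$t[g0] + dt_tr
      if (dur < min_duration) next
      prior <- if (g0 > 1) {
        dir_from_sign(mean(v[max(1, g0 - 3):max(1, g0 - 1)]))
      } else {
        "unknown"
      }
      if (prior == "unknown" && "direction" %in% names(tr)) {
        prior <- tr$direction[1]
      }
      events[[length(events) + 1L]] <- tibble(
        track = nm, position = mean(tr$s[g0:(g1 + 1L)]),
        t_start = tr$t[g0], t_end = tr$t[g1 + 1L], duration = dur,
        prior_direction = prior
      )
    }
  }
  ev <- if (length(events)) dplyr::bind_rows(events) else
    tibble(track = integer(), position = numeric(), t_start = numeric(),
           t_end = numeric(), duration = numeric(),
           prior_direction = character())

  freq <- nrow(ev) / acquisition_time
  # Censoring correction for exponential pause durations: pauses shorter
  # than min_duration are missed, so a fraction exp(-min_duration / m) of
  # all pauses is detected; m follows from the truncated-exponential
  # identity E[detected duration] = min_duration + m.
  corr <- freq
  if (nrow(ev) >= 5) {
    m_hat <- max(mean(ev$duration) - min_duration, 1e-6)
    corr <- freq / exp(-min_duration / m_hat)
  }
  structure(list(events = ev, frequency = freq, frequency_corrected = corr,
                 frequency_per_flagellum = corr / n_flagella,
                 acquisition_time = acquisition_time,
                 n_excluded_immotile = n_immotile,
                 v_thresh = v_thresh, min_duration = min_duration),
            class = "pause_set")
}

central_velocity <- function(t, s) {
  n <- length(s)
  v <- numeric(n)
  if (n >= 3) {
    v[2:(n - 1)] <- (s[3:n] - s[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
  }
  v[1] <- (s[2] - s[1]) / (t[2] - t[1])
  v[n] <- (s[n] - s[n - 1]) / (t[n] - t[n - 1])
  v
}

dir_from_sign <- function(v) {
  if (!is.finite(v) || v == 0) return("unknown")
  if (v > 0) "anterograde" else "retrograde"
}

#' @export
print.pause_set <- function(x, ...) {
  cat(sprintf("<pause_set> %d pauses in %.1f s: %.4f s^-1 raw, %.4f corrected (%d immotile tracks excluded)\n",
              nrow(x$events), x$acquisition_time, x$frequency,
              x$frequency_corrected, x$n_excluded_immotile))
  invisible(x)
}

#' @export
glance.pause_set <- function(x, ...) {
  tibble(n_events = nrow(x$events), frequency = x$frequency,
         frequency_corrected = x$frequency_corrected,
         frequency_per_flagellum = x$frequency_per_flagellum,
         acquisition_time = x$acquisition_time,
         n_excluded_immotile = x$n_excluded_immotile)
}

#' Detect gliding onsets in a cell-body track
#'
#' An onset is the first sample of a maximal interval in which the body speed
#' stays at or above `v_thresh` and the run covers at least `min_run`. The
#' speed is the slope of a line fit over the interval; the direction is its
#' sign.
#'
#' @param body Tibble with `t` and `position` (um, signed).
#' @param v_thresh Speed threshold, um/s.
#' @param min_run Minimum run length, um.
#' @return Tibble of glide events: `onset`, `t_end`, `speed`, `direction`
#'   (+1 / -1), `run_um`.
#' @export
detect_gliding_onset <- function(body, v_thresh = 0.2, min_run = 0.2) {
  body <- body[order(body$t), ]
  n <- nrow(body)
  if (n < 3) return(empty_glides())
  v <- central_velocity(body$t, body$position)
  fast <- abs(v) >= v_thresh
  runs <- rle(fast)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  out <- list()
  for (k in which(runs$values)) {
    i0 <- starts[k]; i1 <- ends[k]
    run <- abs(body$position[i1] - body$position[i0])
    if (run < min_run || i1 - i0 < 1) next
    fit <- lm(position ~ t, data = body[i0:i1, ])
    sl <- unname(coef(fit)[2])
    out[[length(out) + 1L]] <- tibble(
      onset = body$t[i0], t_end = body$t[i1], speed = abs(sl),
      direction = sign(sl), run_um = run
    )
  }
  if (length(out)) dplyr::bind_rows(out) else empty_glides()
}

empty_glides <- function() {
  tibble(onset = numeric(), t_end = numeric(), speed = numeric(),
         direction = numeric(), run_um = numeric())
}

#' Lag time between retrograde pausing and gliding onset
#'
#' For each gliding onset, the lag is the onset time minus the start of the
#' most recent retrograde-direction pause. The lags are fitted to a single
#' exponential by maximum likelihood (for which the fitted mean equals the
#' sample mean); onsets with no preceding retrograde pause are flagged and
#' excluded from the fit.
#'
#' @param pauses Pause events tibble (needs `t_start` and `prior_direction`
#'   or `direction`), e.g. `detect_pauses(...)$events` or `truth$pauses`.
#' @param glides Glide events from [detect_gliding_onset()] (needs `onset`).
#' @return A `lag_fit` (list): `lags` tibble (`onset`, `lag`, `excluded`),
#'   `tau` (ML exponential mean), `mean`, `sem`, `n`.
#' @export
lag_time_analysis <- function(pauses, glides) {
  if (!nrow(glides)) abort("At least one glide event is required.")
  dir_col <- if ("prior_direction" %in% names(pauses)) "prior_direction" else "direction"
  retro <- pauses[pauses[[dir_col]] == "retrograde", , drop = FALSE]
  lags <- purrr::map_dfr(seq_len(nrow(glides)), function(i) {
    t_on <- glides$onset[i]
    prev <- retro$t_start[retro$t_start <= t_on]
    if (!length(prev)) {
      tibble(onset = t_on, lag = NA_real_, excluded = TRUE)
    } else {
      tibble(onset = t_on, lag = t_on - max(prev), excluded = FALSE)
    }
  })
  val <- lags$lag[!lags$excluded]
  if (!length(val)) abort("No onset had a preceding retrograde pause.")
  structure(list(lags = lags, tau = mean(val), mean = mean(val),
                 sem = sd(val) / sqrt(length(val)), n = length(val),
                 n_excluded = sum(lags$excluded)),
            class = "lag_fit")
}

#' @export
print.lag_fit <- function(x, ...) {
  cat(sprintf("<lag_fit> tau = %.3f s (mean %.3f +/- %.3f SEM, n = %d, %d excluded)\n",
              x$tau, x$mean, x$sem, x$n, x$n_excluded))
  invisible(x)
}

#' @export
tidy.lag_fit <- function(x, ...) x$lags

#' @export
glance.lag_fit <- function(x, ...) {
  tibble(tau = x$tau, mean = x$mean, sem = x$sem, n = x$n,
         n_excluded = x$n_excluded)
}

#' Monte-Carlo test of pause / gliding-onset independence
#'
#' Under the null hypothesis that gliding onsets are independent of pausing,
#' a lag is distributed like the waiting time to the most recent pause:
#' exponential with the mean inter-pause interval. The test simulates `n_mc`
#' means of `n` such exponential lags and reports the one-sided fraction at
#' or below the observed mean lag (with plus-one correction).
#'
#' @param mean_lag Observed mean lag, s.
#' @param n Number of observed lags.
#' @param mean_interpause Mean interval between pausing events, s.
#' @param n_mc Number of Monte-Carlo replicates (>= 1e4).
#' @param seed Integer seed.
#' @return A one-row tibble: `p_value`, `mean_lag`, `mean_interpause`, `n`,
#'   `n_mc`, `seed`.
#' @export
independence_test <- function(mean_lag, n, mean_interpause, n_mc = 1e6,
                              seed = 1) {
  check_number(mean_lag, "mean_lag", min = 0, strict_min = TRUE)
  check_number(mean_interpause, "mean_interpause", min = 0, strict_min = TRUE)
  if (n < 2) abort("`n` must be at least 2.")
  if (n_mc < 1e4) abort("`n_mc` must be at least 1e4.")
  # The mean of n iid exponentials with mean m is Gamma(n, rate n/m).
  p <- with_seed(seed, {
    sims <- rgamma(n_mc, shape = n, rate = n / mean_interpause)
    (1 + sum(sims <= mean_lag)) / (n_mc + 1)
  })
  tibble(p_value = p, mean_lag = mean_lag, mean_interpause = mean_interpause,
         n = as.integer(n), n_mc = as.integer(n_mc), seed = as.integer(seed))
}

#' Pause-intensity profile along the flagellum
#'
#' Time-averages the pause-component intensity of a kymograph into bins of
#' normalized arc length, excluding background pixels (values below a
#' percentile of the component).
#'
#' @param pause_component A [kymograph()] (the paused FSDA component).
#' @param flagellum_length Flagellum length, um (> 0).
#' @param n_bins Number of arc-length bins.
#' @param background_percentile Pixels at or below this percentile are
#'   treated as background and excluded (default 0.5).
#' @return A tibble: `bin`, `position` (normalized 0-1 bin centre),
#'   `intensity` (mean above-background intensity), `n_px`.
#' @export
pause_profile <- function(pause_component, flagellum_length, n_bins = 20,
                          background_percentile = 0.5) {
  if (flagellum_length <= 0) abort("`flagellum_length` must be positive.")
  K <- unclass(pause_component)
  px <- attr(pause_component, "pixel_size")
  s <- (seq_len(ncol(K)) - 1L) * px / flagellum_length
  thresh <- quantile(K, background_percentile)
  bins <- pmin(pmax(ceiling(s * n_bins), 1L), n_bins)
  out <- purrr::map_dfr(seq_len(n_bins), function(b) {
    cols <- which(bins == b & s <= 1 + 1e-9)
    vals <- K[, cols, drop = FALSE]
    vals <- vals[vals > thresh]
    tibble(bin = b, position = (b - 0.5) / n_bins,
           intensity = if (length(vals)) mean(vals) else 0,
           n_px = length(vals))
  })
  out
}
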