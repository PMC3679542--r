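#' Simulate intraflagellar transport with calcium-dependent pausing
#'
#' Generates ground-truth IFT train kinetics for one cell: anterograde trains
#' are injected at the flagellar base as a Poisson process and move tip-ward,
#' retrograde trains are injected at the tip and move base-ward. Pausing
#' events occur as a Poisson process whose rate saturates with free calcium
#' (see [ca_pause_rate()]); each event anchors a randomly chosen moving train
#' for an exponentially distributed duration, after which the train resumes
#' its prior direction. Trains vanish on reaching the opposite end.
#'
#' @param config A [sim_config()].
#' @return An `ift_truth` object: a list with
#'   \describe{
#'     \item{trains}{tibble: `train_id`, `flagellum`, `direction`
#'       (`"anterograde"`/`"retrograde"`), `v` (um/s, unsigned),
#'       `t_inject`, `t_exit` (s).}
#'     \item{track}{tibble of frame-sampled positions: `train_id`,
#'       `flagellum`, `direction`, `t` (s), `s` (um from base).}
#'     \item{pauses}{tibble: `pause_id`, `train_id`, `flagellum`, `position`
#'       (um), `t_start`, `t_end` (s), `direction` (prior direction).}
#'     \item{config}{the input config.}
#'     \item{n_dropped_pauses}{pausing events that found no moving train.}
#'   }
#' @examples
#' truth <- simulate_ift(sim_config(duration = 60, seed = 7))
#' nrow(truth$pauses)
#' @export
simulate_ift <- function(config) {
  if (!inherits(config, "sim_config")) {
    abort("`config` must be a sim_config object.")
  }
  L <- config$flagellum_length
  dur <- config$duration

  trains <- with_seed(config$seed, {
    per_flagellum <- lapply(seq_len(config$n_flagella), function(fl) {
      inject_trains(config, fl)
    })
    dplyr::bind_rows(per_flagellum)
  })
  if (nrow(trains) == 0) {
    trains <- tibble(flagellum = integer(), direction = character(),
                     t_inject = numeric(), train_id = integer(),
                     v = numeric())
  }
  if (nrow(trains) > 0) {
    trains$train_id <- seq_len(nrow(trains))
    # Per-train speed draws from entity sub-streams: reproducible under
    # reordering of the injection list.
    trains$v <- vapply(seq_len(nrow(trains)), function(i) {
      mu <- if (trains$direction[i] == "anterograde") config$v_antero else config$v_retro
      s0 <- if (trains$direction[i] == "anterograde") config$v_antero_sd else config$v_retro_sd
      with_seed(child_seed(config$seed, trains$train_id[i]),
                max(0.05 * mu + 1e-6, rnorm(1, mu, s0)))
    }, numeric(1))
  }

  # Hot loops below work on plain vectors; tibble slicing is too slow here.
  n_tr <- nrow(trains)
  t_inj <- trains$t_inject
  v_tr <- trains$v
  is_ant <- trains$direction == "anterograde"
  pause_lists <- vector("list", n_tr)   # per train: matrix of (t_start, dur)
  pause_total <- numeric(n_tr)          # accrued pause time per train

  n_dropped <- 0L
  p_train <- integer(0); p_time <- numeric(0); p_dur <- numeric(0)
  p_pos <- numeric(0)
  lambda <- ca_pause_rate(config$ca_free, config)
  with_seed(child_seed(config$seed, 0L), {
    n_pauses <- rpois(1, lambda * dur)
    if (n_pauses > 0 && n_tr > 0) {
      p_times <- sort(runif(n_pauses, 0, dur))
      for (tp in p_times) {
        # candidate trains: injected, not yet arrived (transit + accrued
        # pauses), and not inside one of their own pauses
        cand <- which(t_inj <= tp & t_inj + L / v_tr + pause_total > tp)
        if (length(cand)) {
          inside <- vapply(cand, function(i) {
            pl <- pause_lists[[i]]
            !is.null(pl) && any(tp >= pl[, 1] & tp < pl[, 1] + pl[, 2])
          }, logical(1))
          cand <- cand[!inside]
        }
        if (!length(cand)) {
          n_dropped <- n_dropped + 1L
          next
        }
        i <- if (length(cand) == 1L) cand else sample(cand, 1)
        dur_p <- rexp(1, rate = 1 / config$pause_duration_mean)
        pause_lists[[i]] <- rbind(pause_lists[[i]], c(tp, dur_p))
        pause_total[i] <- pause_total[i] + dur_p
        d <- v_tr[i] * (tp - t_inj[i] -
                          sum(pmax(0, pmin(tp, pause_lists[[i]][, 1] +
                                             pause_lists[[i]][, 2]) -
                                     pause_lists[[i]][, 1])))
        pos <- if (is_ant[i]) min(d, L) else max(L - d, 0)
        p_train <- c(p_train, i)
        p_time <- c(p_time, tp)
        p_dur <- c(p_dur, dur_p)
        p_pos <- c(p_pos, pos)
      }
    } else if (n_pauses > 0) {
      n_dropped <- n_pauses
    }
  })

  pauses <- if (length(p_train)) {
    tibble(pause_id = seq_along(p_train),
           train_id = trains$train_id[p_train],
           flagellum = trains$flagellum[p_train],
           position = p_pos, t_start = p_time, t_end = p_time + p_dur,
           direction = trains$direction[p_train])
  } else {
    empty_pauses()
  }

  # Exit times with pauses applied, then frame-sampled tracks.
  frame_times <- seq(0, dur, by = config$frame_interval)
  if (n_tr) {
    trains$t_exit <- vapply(seq_len(n_tr), function(i) {
      t_exit <- t_inj[i] + L / v_tr[i]
      pl <- pause_lists[[i]]
      if (!is.null(pl)) {
        for (k in order(pl[, 1])) {
          if (pl[k, 1] < t_exit) t_exit <- t_exit + pl[k, 2]
        }
      }
      t_exit
    }, numeric(1))
    track_parts <- vector("list", n_tr)
    for (i in seq_len(n_tr)) {
      tt <- frame_times[frame_times >= t_inj[i] &
                          frame_times <= min(trains$t_exit[i], dur)]
      if (!length(tt)) next
      moving <- tt - t_inj[i]
      pl <- pause_lists[[i]]
      if (!is.null(pl)) {
        for (k in seq_len(nrow(pl))) {
          moving <- moving -
            pmax(0, pmin(tt, pl[k, 1] + pl[k, 2]) - pmax(t_inj[i], pl[k, 1]))
        }
      }
      d <- v_tr[i] * moving
      s <- if (is_ant[i]) pmin(d, L) else pmax(L - d, 0)
      track_parts[[i]] <- tibble(
        train_id = trains$train_id[i], flagellum = trains$flagellum[i],
        direction = trains$direction[i], t = tt, s = s
      )
    }
    track <- dplyr::bind_rows(track_parts)
    if (!nrow(track)) track <- empty_track_samples()
  } else {
    trains$t_exit <- numeric(0)
    track <- empty_track_samples()
  }

  structure(list(trains = trains, track = track, pauses = pauses,
                 bead = NULL, body = NULL, config = config,
                 n_dropped_pauses = n_dropped),
            class = "ift_truth")
}

empty_pauses <- function() {
  tibble(pause_id = integer(), train_id = integer(), flagellum = integer(),
         position = numeric(), t_start = numeric(), t_end = numeric(),
         direction = character())
}

empty_track_samples <- function() {
  tibble(train_id = integer(), flagellum = integer(),
         direction = character(), t = numeric(), s = numeric())
}

inject_trains <- function(config, fl) {
  dur <- config$duration
  n_a <- rpois(1, config$injection_rate_antero * dur)
  n_r <- rpois(1, config$injection_rate_retro * dur)
  tibble(
    flagellum = fl,
    direction = rep(c("anterograde", "retrograde"), c(n_a, n_r)),
    t_inject = c(sort(runif(n_a, 0, dur)), sort(runif(n_r, 0, dur)))
  )
}

# Position of a train at time t (scalars), given its pause matrix of
# (t_start, dur). Anterograde: s = v * moving_time from 0; retrograde:
# s = L - v * moving_time.
train_position_at <- function(t_inject, v, anterograde, pauses, t, L) {
  if (t < t_inject) return(NA_real_)
  moving <- t - t_inject
  if (!is.null(pauses) && nrow(pauses)) {
    overlap <- pmin(t, pauses[, 1] + pauses[, 2]) - pmax(t_inject, pauses[, 1])
    moving <- moving - sum(pmax(0, overlap))
  }
  d <- v * moving
  if (anterograde) min(d, L) else max(L - d, 0)
}

#' @export
print.ift_truth <- function(x, ...) {
  cat("<ift_truth>\n")
  cat(sprintf("  %d trains (%d pauses, %d dropped), %g s, %d flagella\n",
              nrow(x$trains), nrow(x$pauses), x$n_dropped_pauses,
              x$config$duration, x$config$n_flagella))
  if (!is.null(x$bead)) cat(sprintf("  bead track: %d samples\n", nrow(x$bead)))
  if (!is.null(x$body)) cat(sprintf("  cell-body track: %d samples\n", nrow(x$body)))
  invisible(x)
}
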