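#' Simulate a membrane-coupled bead riding IFT trains
#'
#' Adds a bead track to a ground truth from [simulate_ift()]. The bead
#' alternates between free 1D diffusion on the flagellar membrane (reflecting
#' at both ends) and coupled segments in which it rides a train at
#' `bead_speed_factor` times the train's velocity. Attachment and detachment
#' are Poisson processes; the effective attachment rate is scaled by the same
#' calcium saturation map as pausing, so calcium-deprived beads only diffuse.
#'
#' @param config A [sim_config()].
#' @param truth An `ift_truth` from [simulate_ift()] (must contain trains).
#' @param bead_start Initial bead position, um from base (default mid-length).
#' @param start_coupled If `TRUE`, the bead starts coupled to the train alive
#'   at t = 0 nearest to `bead_start` (error if none).
#' @param capture_radius Maximum bead-train distance (um) at which an
#'   attachment event can couple the bead; an attachment is only physical
#'   when a train passes within reach of the bead's membrane tether.
#' @param dt Integration step, s (default: a fifth of the frame interval).
#' @return The `ift_truth` with a `bead` tibble added: `t` (s), `s` (um),
#'   `coupled_train` (train id or `NA` while diffusing).
#' @export
simulate_bead <- function(config, truth, bead_start = NULL,
                          start_coupled = FALSE, capture_radius = 0.25,
                          dt = NULL) {
  if (!inherits(truth, "ift_truth")) abort("`truth` must be an ift_truth.")
  if (is.null(truth$trains)) abort("`truth` is missing its train list.")
  L <- config$flagellum_length
  bead_start <- bead_start %||% (L / 2)
  dt <- dt %||% (config$frame_interval / 5)

  trains <- truth$trains
  pauses_by_train <- split_pause_matrices(truth$pauses, trains$train_id)

  h <- config$ca_free / (config$ca_free + config$ca_half)
  ka <- config$bead_attach_rate * h
  kd <- config$bead_detach_rate
  sd_step <- sqrt(2 * config$bead_diffusion_coeff * dt)

  times <- seq(0, config$duration, by = dt)
  n <- length(times)
  s <- numeric(n)
  coupled <- rep(NA_integer_, n)
  s[1] <- bead_start

  # Train position helper in the fine grid (plain vectors for speed).
  t_inj <- trains$t_inject
  v_tr <- trains$v
  is_ant <- trains$direction == "anterograde"
  t_exit <- trains$t_exit
  pos_of <- function(id, t) {
    i <- match(id, trains$train_id)
    train_position_at(t_inj[i], v_tr[i], is_ant[i],
                      pauses_by_train[[as.character(id)]], t, L)
  }
  alive_at <- function(t) {
    trains$train_id[t_inj <= t & t_exit > t]
  }

  with_seed(child_seed(config$seed, 1000003L), {
    cur <- NA_integer_
    if (start_coupled) {
      cand <- alive_at(0)
      if (!length(cand)) abort("start_coupled = TRUE but no train alive at t = 0.")
      d0 <- vapply(cand, pos_of, numeric(1), t = 0)
      cur <- cand[which.min(abs(d0 - bead_start))]
      s[1] <- pos_of(cur, 0)
    }
    coupled[1] <- cur
    for (k in seq_len(n - 1L)) {
      t0 <- times[k]; t1 <- times[k + 1L]
      if (!is.na(cur)) {
        i <- match(cur, trains$train_id)
        if (trains$t_exit[i] <= t1) {
          # train reached its destination: bead released where it is
          cur <- NA_integer_
          s[k + 1L] <- s[k]
        } else if (kd > 0 && runif(1) < 1 - exp(-kd * dt)) {
          cur <- NA_integer_
          s[k + 1L] <- s[k]
        } else {
          v_train <- (pos_of(cur, t1) - pos_of(cur, t0)) / dt
          s[k + 1L] <- s[k] + config$bead_speed_factor * v_train * dt
        }
      } else {
        if (ka > 0 && runif(1) < 1 - exp(-ka * dt)) {
          cand <- alive_at(t0)
          if (length(cand)) {
            d0 <- vapply(cand, pos_of, numeric(1), t = t0)
            j <- which.min(abs(d0 - s[k]))
            if (abs(d0[j] - s[k]) <= capture_radius) {
              cur <- cand[j]
            }
          }
        }
        if (!is.na(cur)) {
          # bead binds the captured train and rides it from its position
          s[k + 1L] <- pos_of(cur, t1)
        } else {
          s[k + 1L] <- reflect_into(s[k] + rnorm(1, 0, sd_step), 0, L)
        }
      }
      s[k + 1L] <- min(max(s[k + 1L], 0), L)
      coupled[k + 1L] <- cur
    }
  })

  # Record at frame times.
  frame_times <- seq(0, config$duration, by = config$frame_interval)
  idx <- round(frame_times / dt) + 1L
  idx <- idx[idx <= n]
  truth$bead <- tibble(t = times[idx], s = s[idx], coupled_train = coupled[idx])
  truth
}

# Reflecting boundary map onto [lo, hi].
reflect_into <- function(x, lo, hi) {
  span <- hi - lo
  y <- (x - lo) %% (2 * span)
  y <- ifelse(y > span, 2 * span - y, y)
  lo + y
}

# Split the pauses tibble into per-train matrices of (t_start, duration),
# keyed by train id, as consumed by train_position_at().
split_pause_matrices <- function(pauses, train_ids) {
  out <- stats::setNames(vector("list", length(train_ids)),
                         as.character(train_ids))
  if (!is.null(pauses) && nrow(pauses)) {
    for (id in unique(pauses$train_id)) {
      p <- pauses[pauses$train_id == id, ]
      out[[as.character(id)]] <- cbind(p$t_start, p$t_end - p$t_start)
    }
  }
  out
}
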