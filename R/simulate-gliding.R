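#' Simulate gliding of the cell body driven by paused retrograde trains
#'
#' Adds a cell-body track to a ground truth. While at least one
#' retrograde-origin pause is surface-anchored and the anchored forces are
#' unbalanced, the body glides at `glide_speed` toward the flagellum holding
#' more anchors, but never beyond the nearest anchored train: motion stops
#' when the pause ends or the body reaches the anchor. Anterograde-origin
#' pauses never initiate motion, and equal anchor counts in the two flagella
#' cancel.
#'
#' Positive displacement is toward the tip of flagellum 1; flagellum 2 points
#' the other way in the lab frame.
#'
#' @param config A [sim_config()].
#' @param truth An `ift_truth` (its `pauses` tibble drives the motion; it may
#'   be hand-constructed for controlled scenarios).
#' @return The `ift_truth` with a `body` tibble added: `t` (s), `position`
#'   (um, signed lab-frame displacement).
#' @export
simulate_gliding <- function(config, truth) {
  if (!inherits(truth, "ift_truth")) abort("`truth` must be an ift_truth.")
  dur <- config$duration
  v <- config$glide_speed

  anchors <- truth$pauses
  anchors <- anchors[anchors$direction == "retrograde" &
                       anchors$t_start < dur, , drop = FALSE]

  # Event-driven integration: between anchor starts/ends the active set is
  # constant, so the body moves at a constant (possibly zero) velocity until
  # the segment ends or it reaches the nearest pulling anchor.
  breaks_t <- c(0)
  breaks_b <- c(0)
  if (nrow(anchors)) {
    ev <- sort(unique(pmin(pmax(c(0, anchors$t_start, anchors$t_end, dur), 0), dur)))
    remaining <- anchors$position          # um between body base and anchor
    sign_fl <- ifelse(anchors$flagellum == 1L, 1, -1)
    b <- 0
    for (k in seq_len(length(ev) - 1L)) {
      ta <- ev[k]; tb <- ev[k + 1L]
      act <- which(anchors$t_start <= ta & anchors$t_end > ta)
      if (length(act)) {
        n1 <- sum(sign_fl[act] > 0)
        n2 <- sum(sign_fl[act] < 0)
        dir <- sign(n1 - n2)
        if (dir != 0) {
          pulling <- act[sign_fl[act] == dir]
          cap <- max(0, min(remaining[pulling]))
          dist <- min(v * (tb - ta), cap)
          if (dist > 0) {
            t_arrive <- ta + dist / v
            b <- b + dir * dist
            breaks_t <- c(breaks_t, t_arrive)
            breaks_b <- c(breaks_b, b)
            # pulling-side anchors get closer, opposite-side recede
            remaining[act] <- remaining[act] - dist * (sign_fl[act] == dir) +
              dist * (sign_fl[act] != dir)
          }
        }
      }
      breaks_t <- c(breaks_t, tb)
      breaks_b <- c(breaks_b, b)
    }
  } else {
    breaks_t <- c(0, dur)
    breaks_b <- c(0, 0)
  }

  frame_times <- seq(0, dur, by = config$frame_interval)
  pos <- approx(breaks_t, breaks_b, xout = frame_times, ties = "ordered",
                rule = 2)$y
  truth$body <- tibble(t = frame_times, position = pos)
  truth
}
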