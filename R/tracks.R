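#' Extract train tracks from a directional kymograph component
#'
#' Detects per-row local intensity maxima above a threshold, links them
#' across rows by nearest-neighbour gating, and fits a least-squares line to
#' each linked ridge; the slope is the train velocity. Ridges shorter than
#' `min_length` or `min_duration` are discarded.
#'
#' @param component A [kymograph()] (typically one directional component from
#'   [fsda_decompose()]).
#' @param min_length Minimum ridge extent, um.
#' @param min_duration Minimum ridge duration, s.
#' @param threshold Detection threshold (intensity). Default: median plus 4
#'   median absolute deviations of the component.
#' @param gate_px Maximum per-frame jump when linking, px. Default: the
#'   displacement of a 4 um/s train per frame plus 2 px.
#' @param max_gap Rows a track may go undetected before being closed.
#' @return A tibble with one row per track: `track_id`, `n`, `t_start`,
#'   `t_end`, `length_um`, `velocity` (um/s, signed), `intercept`,
#'   `r_squared`, `mean_intensity`, and a `samples` list-column of
#'   `(t, s, intensity)` tibbles.
#' @export
extract_tracks <- function(component, min_length = 0.5, min_duration = 0.6,
                           threshold = NULL, gate_px = NULL, max_gap = 2L) {
  K <- unclass(component)
  if (!length(K) || all(K == 0)) {
    if (!length(K)) abort("Empty component.")
  }
  px <- attr(component, "pixel_size")
  dt <- attr(component, "frame_interval")
  threshold <- threshold %||%
    (median(K) + 4 * stats::mad(K, constant = 1.4826))
  gate_px <- gate_px %||% (4 * dt / px + 2)

  n_t <- nrow(K); n_s <- ncol(K)
  # Per-row local maxima above threshold (interior columns).
  detections <- vector("list", n_t)
  for (r in seq_len(n_t)) {
    v <- K[r, ]
    if (n_s >= 3) {
      is_peak <- c(FALSE, v[2:(n_s - 1)] >= v[1:(n_s - 2)] &
                     v[2:(n_s - 1)] > v[3:n_s], FALSE) & v >= threshold
    } else {
      is_peak <- v >= threshold & v == max(v)
    }
    cols <- which(is_peak)
    if (length(cols)) {
      # subpixel refinement by parabolic interpolation of the peak
      sub <- vapply(cols, function(j) {
        if (j <= 1 || j >= n_s) return(as.numeric(j))
        denom <- v[j - 1] - 2 * v[j] + v[j + 1]
        if (denom >= 0) return(as.numeric(j))
        j + 0.5 * (v[j - 1] - v[j + 1]) / denom
      }, numeric(1))
      detections[[r]] <- cbind(col = sub, intensity = v[cols])
    }
  }

  # Greedy linking with constant-velocity prediction: once a track has two
  # points, candidates are gated around the extrapolated position, not the
  # last one (a fast ridge advances several px per frame, and linking to the
  # last position systematically prefers lagging noise peaks).
  predict_col <- function(tr, r) {
    n <- length(tr$rows)
    if (n < 2L) return(tr$last_col)
    drow <- tr$rows[n] - tr$rows[1]
    slope <- if (drow > 0) (tr$cols[n] - tr$cols[1]) / drow else 0
    tr$last_col + slope * (r - tr$last_row)
  }
  active <- list()   # each: list(cols, rows, ints, last_col, last_row)
  done <- list()
  for (r in seq_len(n_t)) {
    det <- detections[[r]]
    used <- if (is.null(det)) logical(0) else rep(FALSE, nrow(det))
    if (length(active)) {
      if (!is.null(det) && nrow(det)) {
        preds <- vapply(active, predict_col, numeric(1), r = r)
        # established tracks (tight prediction gate) link first
        ord <- order(-vapply(active, function(tr) length(tr$rows), numeric(1)))
        for (i in ord) {
          tr <- active[[i]]
          cand <- which(!used)
          if (!length(cand)) break
          gate_i <- if (length(tr$rows) >= 2L) max(3, gate_px / 2) else gate_px
          d <- abs(det[cand, "col"] - preds[i])
          j <- cand[which.min(d)]
          if (min(d) <= gate_i) {
            used[j] <- TRUE
            tr$cols <- c(tr$cols, det[j, "col"])
            tr$rows <- c(tr$rows, r)
            tr$ints <- c(tr$ints, det[j, "intensity"])
            tr$last_col <- det[j, "col"]
            tr$last_row <- r
            active[[i]] <- tr
          }
        }
      }
      # close stale tracks
      stale <- vapply(active, function(tr) r - tr$last_row > max_gap, logical(1))
      done <- c(done, active[stale])
      active <- active[!stale]
    }
    if (!is.null(det) && any(!used)) {
      for (j in which(!used)) {
        active[[length(active) + 1L]] <- list(
          cols = det[j, "col"], rows = r, ints = det[j, "intensity"],
          last_col = det[j, "col"], last_row = r)
      }
    }
  }
  done <- c(done, active)

  if (!length(done)) return(empty_track_table())

  rows_out <- purrr::map(done, function(tr) {
    if (length(tr$rows) < 2) return(NULL)
    t <- (tr$rows - 1) * dt
    s <- (tr$cols - 1) * px
    dur <- diff(range(t))
    len <- diff(range(s))
    if (dur < min_duration || len < min_length) return(NULL)
    fit <- lm(s ~ t)
    r2 <- summary(fit)$r.squared
    tibble(
      n = length(t), t_start = min(t), t_end = max(t), length_um = len,
      velocity = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
      r_squared = if (is.nan(r2)) 1 else r2,
      mean_intensity = mean(tr$ints),
      samples = list(tibble(t = t, s = s, intensity = tr$ints))
    )
  })
  out <- dplyr::bind_rows(rows_out)
  if (!nrow(out)) return(empty_track_table())
  dplyr::mutate(out, track_id = dplyr::row_number(), .before = 1)
}

empty_track_table <- function() {
  tibble(track_id = integer(), n = integer(), t_start = numeric(),
         t_end = numeric(), length_um = numeric(), velocity = numeric(),
         intercept = numeric(), r_squared = numeric(),
         mean_intensity = numeric(), samples = list())
}
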