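#' Render a ground truth to a noisy TIRF-like movie
#'
#' Draws every train (and the bead, if present) as a symmetric 2D Gaussian of
#' width `psf_sigma` along a flagellar path, integrating each emitter's
#' motion across the frame interval (`n_sub` sub-frame positions, as a real
#' camera exposure does), then applies shot noise
#' (`Poisson(signal + background)`) and Gaussian read noise. Deterministic
#' under the config seed.
#'
#' @param truth An `ift_truth` from the simulators.
#' @param config The [sim_config()] used to build `truth`.
#' @param paths Optional `path_frames` from [interpolate_paths()] (or a single
#'   polyline matrix) mapping arc length to pixel coordinates. Default: a
#'   straight horizontal path with an 8 px margin.
#' @param n_rows Image height in px (default 16, or enough to contain the
#'   path).
#' @param include Entities to draw, subset of `c("trains", "bead")`.
#' @param amplitude Peak signal per emitter, camera counts (default
#'   `config$photon_rate`).
#' @param noise If `FALSE`, skip shot and read noise and return the expected
#'   signal plus background (for identity checks).
#' @param n_sub Sub-frame positions integrated per frame (motion blur;
#'   1 = instantaneous sampling).
#' @return An `ift_movie`: numeric array `(frame, row, col)` with attributes
#'   `pixel_size` (um), `frame_interval` (s) and `seed`.
#' @export
render_movie <- function(truth, config, paths = NULL, n_rows = NULL,
                         include = c("trains", "bead"), amplitude = NULL,
                         noise = TRUE, n_sub = 4L) {
  if (!inherits(truth, "ift_truth")) abort("`truth` must be an ift_truth.")
  amplitude <- amplitude %||% config$photon_rate
  frame_times <- seq(0, config$duration, by = config$frame_interval)
  n_frames <- length(frame_times)
  px <- config$pixel_size

  if (is.null(paths)) {
    n_rows <- n_rows %||% 16L
    pl <- straight_path(config$flagellum_length, px, n_rows / 2, 8)
    paths <- structure(rep(list(pl), n_frames),
                       arc_px = seq(0, nrow(pl) - 1L), anchor_index = 1L,
                       base_end = "start", pixel_size = px,
                       class = "path_frames")
  } else if (is.matrix(paths)) {
    paths <- structure(rep(list(paths), n_frames),
                       arc_px = polyline_arcs(paths), anchor_index = 1L,
                       base_end = "start", pixel_size = px,
                       class = "path_frames")
  }
  if (length(paths) < n_frames) {
    abort("`paths` has fewer frames than the movie.")
  }
  path_len_um <- max(attr(paths, "arc_px")) * px -
    min(attr(paths, "arc_px")) * px
  if (path_len_um < config$flagellum_length - 1e-9) {
    abort("Path is shorter than the flagellum.")
  }

  all_rc <- do.call(rbind, paths[seq_len(n_frames)])
  n_rows <- n_rows %||% as.integer(ceiling(max(all_rc[, 1]) + 8))
  n_cols <- as.integer(ceiling(max(all_rc[, 2]) + 8))
  n_rows <- max(n_rows, as.integer(ceiling(max(all_rc[, 1]) + 4)))

  sigma_px <- config$psf_sigma / px
  win <- ceiling(4 * sigma_px)

  movie <- array(0, dim = c(n_frames, n_rows, n_cols))
  track <- if ("trains" %in% include) truth$track else NULL
  bead <- if ("bead" %in% include) truth$bead else NULL
  n_sub <- max(1L, as.integer(n_sub))

  # Position of each emitter at the NEXT frame, for sub-frame integration.
  with_next <- function(d, id_col = NULL) {
    if (is.null(d) || !nrow(d)) return(d)
    if (!is.null(id_col)) d <- d[order(d[[id_col]], d$t), ]
    nxt <- c(d$s[-1], NA)
    same <- if (is.null(id_col)) {
      c(abs(diff(d$t) - config$frame_interval) < 1e-9, FALSE)
    } else {
      c(d[[id_col]][-1] == d[[id_col]][-nrow(d)] &
          abs(diff(d$t) - config$frame_interval) < 1e-9, FALSE)
    }
    d$s_next <- ifelse(same, nxt, d$s)
    d
  }
  track <- with_next(track, "train_id")
  bead <- with_next(bead)

  sub_u <- (seq_len(n_sub) - 1) / n_sub
  for (f in seq_len(n_frames)) {
    t <- frame_times[f]
    ss <- numeric(0); ss2 <- numeric(0)
    if (!is.null(track) && nrow(track)) {
      rows <- abs(track$t - t) < config$frame_interval / 2
      ss <- track$s[rows]; ss2 <- track$s_next[rows]
    }
    if (!is.null(bead) && nrow(bead)) {
      rows <- which(abs(bead$t - t) < config$frame_interval / 2)
      if (length(rows)) {
        ss <- c(ss, bead$s[rows[1]])
        ss2 <- c(ss2, bead$s_next[rows[1]])
      }
    }
    if (!length(ss)) next
    img <- matrix(0, n_rows, n_cols)
    pl <- paths[[f]]
    arcs <- attr(paths, "arc_px") - min(attr(paths, "arc_px"))  # from base
    for (i in seq_along(ss)) {
      for (u in sub_u) {
        a <- (ss[i] + u * (ss2[i] - ss[i])) / px
        rc <- c(approx(arcs, pl[, 1], xout = a, rule = 2)$y,
                approx(arcs, pl[, 2], xout = a, rule = 2)$y)
        r0 <- max(1L, floor(rc[1] - win)); r1 <- min(n_rows, ceiling(rc[1] + win))
        c0 <- max(1L, floor(rc[2] - win)); c1 <- min(n_cols, ceiling(rc[2] + win))
        if (r0 > r1 || c0 > c1) next
        rr <- r0:r1; cc <- c0:c1
        # rc is in 0-based pixel coordinates; matrix indices are 1-based
        g <- exp(-outer((rr - 1 - rc[1])^2, (cc - 1 - rc[2])^2, "+") /
                   (2 * sigma_px^2))
        img[rr, cc] <- img[rr, cc] + (amplitude / n_sub) * g
      }
    }
    movie[f, , ] <- img
  }

  if (noise) {
    with_seed(child_seed(config$seed, 2000003L), {
      lambda <- movie + config$background_rate
      if (any(lambda > 0)) {
        movie[] <- rpois(length(lambda), lambda)
      }
      if (config$read_noise > 0) {
        movie[] <- movie + rnorm(length(movie), 0, config$read_noise)
      }
    })
    movie[movie < 0] <- 0
  } else {
    movie <- movie + config$background_rate
  }

  structure(movie, pixel_size = px, frame_interval = config$frame_interval,
            seed = config$seed, class = "ift_movie")
}

#' @export
print.ift_movie <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<ift_movie> %d frames, %d x %d px, %g um/px, %g s/frame\n",
              d[1], d[2], d[3], attr(x, "pixel_size"),
              attr(x, "frame_interval")))
  invisible(x)
}
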