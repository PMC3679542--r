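#' Kymograph container
#'
#' A 2D intensity image with time down the rows and arc length from the
#' flagellar base across the columns.
#'
#' @param intensity Numeric matrix, rows = frames, cols = arc-length samples.
#' @param pixel_size Arc-length sampling step, um per column.
#' @param frame_interval Time step, s per row.
#' @param arc_origin_um Arc coordinate of the first column (um from base).
#' @return A `kymograph` object.
#' @export
kymograph <- function(intensity, pixel_size, frame_interval,
                      arc_origin_um = 0) {
  if (!is.matrix(intensity)) abort("`intensity` must be a matrix.")
  structure(intensity, pixel_size = pixel_size,
            frame_interval = frame_interval, arc_origin_um = arc_origin_um,
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("<kymograph> %d frames x %d positions (%g s, %g um)\n",
              nrow(x), ncol(x), nrow(x) * attr(x, "frame_interval"),
              ncol(x) * attr(x, "pixel_size")))
  invisible(x)
}

#' Kymograph as a tidy tibble
#'
#' @param x A `kymograph`.
#' @param ... Unused.
#' @return A tibble with columns `t` (s), `s` (um from base), `intensity`.
#' @export
tidy.kymograph <- function(x, ...) {
  dt <- attr(x, "frame_interval"); dp <- attr(x, "pixel_size")
  tibble(
    t = rep((seq_len(nrow(x)) - 1L) * dt, times = ncol(x)),
    s = rep(attr(x, "arc_origin_um") + (seq_len(ncol(x)) - 1L) * dp,
            each = nrow(x)),
    intensity = as.vector(unclass(x))
  )
}

# Bilinear interpolation with edge clamping; r, c are 1-based fractional
# pixel coordinates (vectors of equal length).
bilinear_sample <- function(img, r, c) {
  nr <- nrow(img); nc <- ncol(img)
  r <- pmin(pmax(r, 1), nr)
  c <- pmin(pmax(c, 1), nc)
  r0 <- pmin(floor(r), nr - 1L); c0 <- pmin(floor(c), nc - 1L)
  fr <- r - r0; fc <- c - c0
  img[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    img[cbind(r0 + 1L, c0)] * fr * (1 - fc) +
    img[cbind(r0, c0 + 1L)] * (1 - fr) * fc +
    img[cbind(r0 + 1L, c0 + 1L)] * fr * fc
}

#' Sample a kymograph from a movie along per-frame flagellar paths
#'
#' Each kymograph row is the bilinear interpolation of the corresponding
#' frame along the arc-length-resampled polyline, averaged over
#' `linewidth_px` samples taken perpendicular to the local tangent.
#' Out-of-bounds samples use edge padding. With evolving paths the rows are
#' stacked so the anchor point keeps a fixed arc-length coordinate.
#'
#' @param movie An `ift_movie` (or plain 3D array `(frame, row, col)`).
#' @param paths A `path_frames` from [interpolate_paths()], or a single
#'   polyline matrix of (row, col) pixel coordinates used for every frame.
#' @param linewidth_px Number of perpendicular samples to average (>= 1).
#' @param pixel_size,frame_interval Metadata overrides when `movie` is a
#'   plain array.
#' @return A [kymograph()].
#' @export
sample_kymograph <- function(movie, paths, linewidth_px = 3,
                             pixel_size = NULL, frame_interval = NULL) {
  if (linewidth_px < 1) abort("`linewidth_px` must be >= 1.")
  d <- dim(movie)
  if (length(d) != 3) abort("`movie` must be a 3D (frame, row, col) array.")
  n_frames <- d[1]
  pixel_size <- pixel_size %||% attr(movie, "pixel_size") %||% 0.106
  frame_interval <- frame_interval %||% attr(movie, "frame_interval") %||% 1

  if (is.matrix(paths)) {
    pl <- resample_polyline(paths, 1)
    paths <- structure(rep(list(pl), n_frames),
                       arc_px = polyline_arcs(pl), anchor_index = 1L,
                       base_end = "start", pixel_size = pixel_size,
                       class = "path_frames")
  }
  if (length(paths) < n_frames) abort("`paths` covers fewer frames than the movie.")
  arc <- attr(paths, "arc_px")
  base_end <- attr(paths, "base_end") %||% "start"
  n_pos <- length(arc)

  offs <- seq_len(linewidth_px) - (linewidth_px + 1) / 2
  out <- matrix(0, n_frames, n_pos)
  for (f in seq_len(n_frames)) {
    pl <- paths[[f]]
    tang <- path_tangents(pl)
    normal <- cbind(-tang[, 2], tang[, 1])
    img <- movie[f, , ]
    acc <- numeric(n_pos)
    for (o in offs) {
      acc <- acc + bilinear_sample(img, pl[, 1] + o * normal[, 1] + 1,
                                   pl[, 2] + o * normal[, 2] + 1)
    }
    out[f, ] <- acc / linewidth_px
  }
  if (base_end == "end") {
    out <- out[, rev(seq_len(n_pos)), drop = FALSE]
    arc <- rev(max(arc) - arc)
  }
  kymograph(out, pixel_size = pixel_size, frame_interval = frame_interval,
            arc_origin_um = 0)
}

# Unit tangents along a polyline (central differences, one-sided at ends).
path_tangents <- function(pl) {
  n <- nrow(pl)
  d <- rbind(pl[2, ] - pl[1, ],
             (pl[3:n, , drop = FALSE] - pl[1:(n - 2), , drop = FALSE]) / 2,
             pl[n, ] - pl[n - 1, ])
  if (n == 2) d <- rbind(pl[2, ] - pl[1, ], pl[2, ] - pl[1, ])
  len <- sqrt(rowSums(d^2))
  d / pmax(len, 1e-12)
}

# Resample a polyline at equal arc-length spacing (px).
resample_polyline <- function(pl, step_px = 1) {
  arcs <- polyline_arcs(pl)
  u <- seq(0, arcs[length(arcs)], by = step_px)
  cbind(approx(arcs, pl[, 1], xout = u)$y,
        approx(arcs, pl[, 2], xout = u)$y)
}

#' @export
autoplot.kymograph <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$s, y = .data$t,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "intensity") +
    ggplot2::labs(x = "arc length from base (µm)", y = "time (s)") +
    ggplot2::theme_minimal()
}
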