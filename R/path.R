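#' Flagellar path with keyframed curves and a fixed anchor point
#'
#' Describes the curve along which a kymograph is sampled. For a stationary
#' flagellum a single keyframe suffices; for cells that reorient their
#' flagella while gliding, several keyframe curves are assigned at chosen
#' frames, consecutive curves sharing at least one common point (the anchor),
#' and intermediate frames are obtained by interpolation. Kymograph rows are
#' stacked so the anchor maps to the same arc-length coordinate in every
#' frame.
#'
#' @param keyframes A list of elements `list(frame = <0-based frame index>,
#'   polyline = <n x 2 matrix of (row, col) pixel coordinates>)`, frames
#'   strictly increasing. A bare matrix is accepted as a single keyframe at
#'   frame 0.
#' @param anchor_um Arc-length position (um from the first vertex) of the
#'   fixed common point on the first keyframe.
#' @param pixel_size Pixel size in um.
#' @param base_end Which polyline end is the flagellar base: `"start"` (first
#'   vertex) or `"end"`.
#' @param tol_px Tolerance (px) for validating that consecutive keyframes
#'   share the anchor point.
#' @return A `flagellar_path` object.
#' @export
flagellar_path <- function(keyframes, anchor_um = 0, pixel_size = 0.106,
                           base_end = c("start", "end"), tol_px = 2) {
  base_end <- match.arg(base_end)
  if (is.matrix(keyframes)) {
    keyframes <- list(list(frame = 0L, polyline = keyframes))
  }
  if (!length(keyframes)) abort("At least one keyframe is required.")
  frames <- vapply(keyframes, function(k) as.integer(k$frame), integer(1))
  if (is.unsorted(frames, strictly = TRUE)) {
    abort("Keyframe frame indices must be strictly increasing.")
  }
  for (k in keyframes) {
    pl <- k$polyline
    if (!is.matrix(pl) || ncol(pl) != 2 || nrow(pl) < 2) {
      abort("Each keyframe polyline must be an n x 2 matrix with n >= 2.")
    }
    if (any(!is.finite(pl))) abort("Polyline coordinates must be finite.")
    if (any(sqrt(rowSums(diff(pl)^2)) == 0)) {
      abort("Polyline has repeated consecutive vertices.")
    }
    if (polyline_self_intersects(pl)) abort("Polyline is self-intersecting.")
  }
  path <- structure(list(keyframes = keyframes, anchor_um = anchor_um,
                         pixel_size = pixel_size, base_end = base_end,
                         tol_px = tol_px),
                    class = "flagellar_path")
  # Validate the common-point chain now so failures surface early.
  anchor_chain(path)
  path
}

# Cumulative arc length (px) along a polyline.
polyline_arcs <- function(pl) {
  c(0, cumsum(sqrt(rowSums(diff(pl)^2))))
}

# Point at arc position a (px) along a polyline, linear interpolation.
polyline_point <- function(pl, a) {
  arcs <- polyline_arcs(pl)
  a <- min(max(a, 0), arcs[length(arcs)])
  cbind(approx(arcs, pl[, 1], xout = a)$y, approx(arcs, pl[, 2], xout = a)$y)
}

# Arc parameter of the point on the polyline closest to xy = c(row, col),
# by exact orthogonal projection onto each segment.
polyline_nearest_arc <- function(pl, xy) {
  arcs <- polyline_arcs(pl)
  best_arc <- 0; best_d2 <- Inf
  for (i in seq_len(nrow(pl) - 1L)) {
    a <- pl[i, ]; b <- pl[i + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    u <- if (len2 > 0) sum((xy - a) * ab) / len2 else 0
    u <- min(max(u, 0), 1)
    p <- a + u * ab
    d2 <- sum((xy - p)^2)
    if (d2 < best_d2) {
      best_d2 <- d2
      best_arc <- arcs[i] + u * sqrt(len2)
    }
  }
  list(arc = best_arc, dist = sqrt(best_d2))
}

polyline_self_intersects <- function(pl) {
  n <- nrow(pl) - 1L
  if (n < 3L) return(FALSE)
  for (i in seq_len(n - 2L)) {
    for (j in seq(i + 2L, n)) {
      if (segments_cross(pl[i, ], pl[i + 1L, ], pl[j, ], pl[j + 1L, ])) {
        return(TRUE)
      }
    }
  }
  FALSE
}

segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

# Arc position (px) of the anchor on each keyframe, chained through the
# common point: keyframe 1 uses anchor_um, later keyframes take the point
# nearest the previous keyframe's anchor location (must lie within tol_px).
anchor_chain <- function(path) {
  kf <- path$keyframes
  a <- numeric(length(kf))
  a[1] <- path$anchor_um / path$pixel_size
  arcs1 <- polyline_arcs(kf[[1]]$polyline)
  if (a[1] < 0 || a[1] > arcs1[length(arcs1)]) {
    abort("anchor_um lies outside the first keyframe polyline.")
  }
  xy <- polyline_point(kf[[1]]$polyline, a[1])
  if (length(kf) > 1) {
    for (k in 2:length(kf)) {
      hit <- polyline_nearest_arc(kf[[k]]$polyline, xy)
      if (hit$dist > path$tol_px) {
        abort(sprintf(
          "Keyframes %d and %d share no common point within %g px (nearest %.2f px).",
          k - 1L, k, path$tol_px, hit$dist))
      }
      a[k] <- hit$arc
      xy <- polyline_point(kf[[k]]$polyline, a[k])
    }
  }
  a
}

#' Interpolate keyframed flagellar curves to every frame
#'
#' Both bounding keyframe polylines are resampled at equal arc-length spacing
#' relative to the anchor, then blended vertex-wise linearly; frames before
#' the first or after the last keyframe reuse the nearest keyframe. The
#' anchor maps to the same arc-length coordinate (the same vertex index) in
#' every frame.
#'
#' @param path A [flagellar_path()].
#' @param n_frames Number of movie frames.
#' @param step_px Resampling step along the curve, px (default 1).
#' @return A `path_frames` object: list of `n_frames` polyline matrices, with
#'   attributes `arc_px` (anchor-relative arc coordinate of each vertex),
#'   `anchor_index`, `base_end` and `pixel_size`.
#' @export
interpolate_paths <- function(path, n_frames, step_px = 1) {
  if (!inherits(path, "flagellar_path")) abort("`path` must be a flagellar_path.")
  if (n_frames < 1) abort("`n_frames` must be positive.")
  kf <- path$keyframes
  frames <- vapply(kf, function(k) as.integer(k$frame), integer(1))
  if (any(frames < 0) || any(frames >= n_frames)) {
    abort("Keyframe frames must lie within [0, n_frames).")
  }
  anchors <- anchor_chain(path)
  lens <- vapply(kf, function(k) {
    arcs <- polyline_arcs(k$polyline); arcs[length(arcs)]
  }, numeric(1))

  # Anchor-relative common arc range covered by every keyframe.
  u_min <- -min(anchors)
  u_max <- min(lens - anchors)
  u <- seq(u_min, u_max, by = step_px)
  anchor_index <- which.min(abs(u))

  resampled <- lapply(seq_along(kf), function(k) {
    arcs <- polyline_arcs(kf[[k]]$polyline)
    pl <- kf[[k]]$polyline
    cbind(approx(arcs, pl[, 1], xout = u + anchors[k])$y,
          approx(arcs, pl[, 2], xout = u + anchors[k])$y)
  })

  out <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    f0 <- f - 1L
    if (f0 <= frames[1]) {
      out[[f]] <- resampled[[1]]
    } else if (f0 >= frames[length(frames)]) {
      out[[f]] <- resampled[[length(frames)]]
    } else {
      k <- max(which(frames <= f0))
      w <- (f0 - frames[k]) / (frames[k + 1L] - frames[k])
      out[[f]] <- (1 - w) * resampled[[k]] + w * resampled[[k + 1L]]
    }
  }
  structure(out, arc_px = u, anchor_index = anchor_index,
            base_end = path$base_end, pixel_size = path$pixel_size,
            class = "path_frames")
}

# Straight horizontal path helper used by the renderer and tests: maps arc
# s = 0..length_um onto a row of pixels starting at (row0, col0).
straight_path <- function(length_um, pixel_size, row0, col0) {
  n <- ceiling(length_um / pixel_size) + 1L
  cbind(rep(row0, n), col0 + seq(0, n - 1L))
}
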