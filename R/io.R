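# Readers/writers for the standard on-disk forms: multi-page TIFF movies and
# kymographs with JSON sidecars, CSV tracks/traces. Sidecars carry enough
# metadata (pixel size, frame interval, seed, scale) to restore the objects.

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

write_sidecar <- function(path, meta) {
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
}

read_sidecar <- function(path) {
  jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
}

#' Write / read a movie as a multi-page 16-bit TIFF with a JSON sidecar
#'
#' Counts are stored as 16-bit samples scaled by the sidecar's `scale`
#' (rounded to integers), so a written movie reads back bit-identically after
#' rounding.
#'
#' @param movie An `ift_movie`.
#' @param path Output `.tif` path (sidecar written alongside).
#' @param extra Optional named list merged into the sidecar (e.g. config
#'   echo).
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path, extra = list()) {
  d <- dim(movie)
  scale <- 65535
  vals <- pmin(pmax(round(unclass(movie)), 0), scale)
  pages <- lapply(seq_len(d[1]), function(f) vals[f, , ] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
  write_sidecar(path, c(list(
    kind = "movie", pixel_size_um = attr(movie, "pixel_size"),
    frame_interval_s = attr(movie, "frame_interval"),
    seed = attr(movie, "seed"), n_frames = d[1], scale = scale
  ), extra))
  invisible(path)
}

#' @rdname write_movie
#' @export
read_movie <- function(path) {
  meta <- read_sidecar(path)
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, dim = c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (f in seq_along(pages)) arr[f, , ] <- round(pages[[f]] * meta$scale)
  structure(arr, pixel_size = meta$pixel_size_um,
            frame_interval = meta$frame_interval_s, seed = meta$seed,
            class = "ift_movie")
}

#' Write / read a kymograph as TIFF + JSON sidecar
#'
#' Intensities are min-max normalized into the TIFF and restored from the
#' sidecar's `offset`/`scale` (32-bit float precision).
#'
#' @param kymo A [kymograph()].
#' @param path Output `.tif` path.
#' @param extra Optional named list merged into the sidecar.
#' @return `path`, invisibly.
#' @export
write_kymograph <- function(kymo, path, extra = list()) {
  K <- unclass(kymo)
  off <- min(K)
  scale <- max(K) - off
  if (scale == 0) scale <- 1
  tiff::writeTIFF((K - off) / scale, path, bits.per.sample = 32,
                  compression = "none")
  write_sidecar(path, c(list(
    kind = "kymograph", pixel_size_um = attr(kymo, "pixel_size"),
    frame_interval_s = attr(kymo, "frame_interval"),
    arc_origin_um = attr(kymo, "arc_origin_um"),
    offset = off, scale = scale
  ), extra))
  invisible(path)
}

#' @rdname write_kymograph
#' @export
read_kymograph <- function(path) {
  meta <- read_sidecar(path)
  K <- tiff::readTIFF(path)
  kymograph(K * meta$scale + meta$offset, meta$pixel_size_um,
            meta$frame_interval_s, meta$arc_origin_um %||% 0)
}

#' Write / read tabular results as CSV
#'
#' Thin readr wrappers so every table (tracks, pauses, glide events, traces)
#' round-trips with documented headers.
#'
#' @param x A data frame (list-columns are dropped with a warning).
#' @param path Output `.csv` path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(x, path) {
  is_list <- vapply(x, is.list, logical(1))
  if (any(is_list)) {
    warn(sprintf("Dropping list-columns: %s",
                 paste(names(x)[is_list], collapse = ", ")))
    x <- x[!is_list]
  }
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Write / read a trap trace as CSV plus JSON header
#'
#' The CSV holds `t_s, x_nm`; the JSON sidecar holds stiffness, sampling
#' rate, detector range and flagellar orientation.
#'
#' @param trace A `trap_trace`.
#' @param path Output `.csv` path.
#' @return `path`, invisibly.
#' @export
write_trap_trace <- function(trace, path) {
  d <- trace_data(trace)
  readr::write_csv(tibble(t_s = d$t, x_nm = d$x), path)
  write_sidecar(path, list(
    kind = "trap_trace",
    kappa_pN_per_nm = attr(trace, "kappa"),
    rate_hz = attr(trace, "sampling_rate"),
    kT_pN_nm = attr(trace, "kT"),
    range_nm = attr(trace, "range_nm"),
    orientation = attr(trace, "orientation")
  ))
  invisible(path)
}

#' @rdname write_trap_trace
#' @export
read_trap_trace <- function(path) {
  meta <- read_sidecar(path)
  d <- readr::read_csv(path, show_col_types = FALSE)
  structure(list(data = tibble(t = d$t_s, x = d$x_nm), events = NULL,
                 config = NULL),
            kappa = meta$kappa_pN_per_nm, kT = meta$kT_pN_nm,
            sampling_rate = meta$rate_hz,
            range_nm = if (is.null(meta$range_nm)) Inf else meta$range_nm,
            orientation = meta$orientation, class = "trap_trace")
}

#' Write / read flagellar path keyframes as CSV + JSON header
#'
#' CSV columns: `frame`, `vertex_index`, `row_px`, `col_px`; the header holds
#' `anchor_um` and `base_end`.
#'
#' @param path_obj A [flagellar_path()].
#' @param path Output `.csv` path.
#' @return `path`, invisibly.
#' @export
write_path_csv <- function(path_obj, path) {
  df <- purrr::map_dfr(path_obj$keyframes, function(k) {
    tibble(frame = k$frame, vertex_index = seq_len(nrow(k$polyline)) - 1L,
           row_px = k$polyline[, 1], col_px = k$polyline[, 2])
  })
  readr::write_csv(df, path)
  write_sidecar(path, list(kind = "flagellar_path",
                           anchor_um = path_obj$anchor_um,
                           pixel_size_um = path_obj$pixel_size,
                           base_end = path_obj$base_end))
  invisible(path)
}

#' @rdname write_path_csv
#' @export
read_path_csv <- function(path) {
  meta <- read_sidecar(path)
  df <- readr::read_csv(path, show_col_types = FALSE)
  kfs <- lapply(split(df, df$frame), function(g) {
    g <- g[order(g$vertex_index), ]
    list(frame = g$frame[1], polyline = cbind(g$row_px, g$col_px))
  })
  kfs <- kfs[order(vapply(kfs, function(k) k$frame, numeric(1)))]
  flagellar_path(unname(kfs), anchor_um = meta$anchor_um,
                 pixel_size = meta$pixel_size_um, base_end = meta$base_end)
}
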