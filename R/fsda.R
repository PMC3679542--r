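#' Velocity bins for Fourier-space direction analysis
#'
#' Partitions the signed velocity axis into labelled bins. The default is the
#' three-way split used throughout: retrograde `(-Inf, -v_min)`, paused
#' `[-v_min, +v_min]`, anterograde `(+v_min, Inf)`. Anterograde is positive
#' velocity, i.e. motion toward increasing arc length (the tip).
#'
#' @param v_min Pause threshold, um/s: trajectories slower than this in
#'   magnitude count as paused (default 0.2, an order of magnitude below
#'   train speeds).
#' @param breaks Optional full vector of velocity break points
#'   `c(-Inf, ..., Inf)` for custom binning (overrides `v_min`).
#' @param labels Bin labels, `length(breaks) - 1` of them.
#' @param softness Raised-cosine transition width at wedge edges, as a
#'   fraction of the smaller adjacent wedge angle (default 0.1; 0 = hard
#'   edges).
#' @return A `velocity_bins` object.
#' @export
velocity_bins <- function(v_min = 0.2, breaks = NULL, labels = NULL,
                          softness = 0.1) {
  if (is.null(breaks)) {
    check_number(v_min, "v_min", min = 0, strict_min = TRUE)
    breaks <- c(-Inf, -v_min, v_min, Inf)
    labels <- labels %||% c("retrograde", "paused", "anterograde")
  }
  if (breaks[1] != -Inf || breaks[length(breaks)] != Inf ||
      is.unsorted(breaks, strictly = TRUE)) {
    abort("`breaks` must be strictly increasing from -Inf to Inf.")
  }
  labels <- labels %||% paste0("bin", seq_len(length(breaks) - 1L))
  if (length(labels) != length(breaks) - 1L) {
    abort("`labels` must have one entry per bin.")
  }
  check_number(softness, "softness", min = 0, max = 0.49)
  structure(list(breaks = breaks, labels = labels, softness = softness),
            class = "velocity_bins")
}

# Map the velocity circle onto wedge angles. A ridge of velocity v (um/s)
# concentrates spectral energy on f_t = -v * f_s; the wedge angle is
# alpha = atan(v) in physical frequency units, with anterograde and
# retrograde meeting (wrapping) at +/- pi/2 on the f_s = 0 axis.
bin_edges_alpha <- function(bins) {
  atan(bins$breaks[-c(1, length(bins$breaks))])
}

# Circular signed distance on the velocity-angle circle (period pi).
alpha_dist <- function(a, b) {
  d <- (a - b + pi / 2) %% pi - pi / 2
  d
}

#' Build slope-selective spectral masks
#'
#' For each velocity bin, the mask selects the wedge of 2D frequency space
#' whose implied velocity `-f_t / f_s` falls in the bin, with raised-cosine
#' edges. Masks are Hermitian-symmetric, sum to 1 at every non-DC frequency,
#' and the DC term goes to a separate background mask.
#'
#' @param bins A [velocity_bins()].
#' @param shape `c(n_rows, n_cols)` of the kymograph (time x arc length),
#'   both at least 8.
#' @param pixel_size Arc-length step, um.
#' @param frame_interval Time step, s.
#' @return Named list of numeric mask matrices (one per bin label, plus
#'   `"background"`), each of dimension `shape`.
#' @export
build_masks <- function(bins, shape, pixel_size, frame_interval) {
  if (!inherits(bins, "velocity_bins")) abort("`bins` must be velocity_bins.")
  if (length(shape) != 2 || any(shape < 8)) {
    abort("`shape` must be (rows, cols) with both >= 8.")
  }
  n_t <- shape[1]; n_s <- shape[2]
  f_t <- fft_freq(n_t, frame_interval)   # cycles/s, along rows
  f_s <- fft_freq(n_s, pixel_size)       # cycles/um, along cols

  FT <- matrix(f_t, n_t, n_s)
  FS <- matrix(f_s, n_t, n_s, byrow = TRUE)

  n_bins <- length(bins$labels)
  edges <- bin_edges_alpha(bins)                       # interior edges
  widths <- diff(c(-pi / 2, edges, pi / 2))            # per-bin wedge angles
  # wrap wedge (retro lower edge ~ antero upper edge) has combined width
  wrap_width <- widths[1] + widths[n_bins]

  # Smooth step "above edge e" with circular distance; transition half-width
  # is softness x the smaller adjacent wedge angle (clamped to stay
  # non-overlapping).
  smooth_step <- function(a, edge, w) {
    d <- alpha_dist(a, edge)
    if (w <= 0) return((d >= 0) * 1)
    out <- 0.5 * (1 + sin(pi * d / (2 * w)))
    out[d <= -w] <- 0
    out[d >= w] <- 1
    out
  }

  masks_for <- function(FT, FS) {
    # Canonicalize to the f_s > 0 half-plane (Hermitian symmetry: a
    # frequency and its negation carry the same implied velocity).
    flip <- FS < 0 | (FS == 0 & FT < 0)
    FSc <- ifelse(flip, -FS, FS)
    FTc <- ifelse(flip, -FT, FT)
    alpha <- atan2(-FTc, FSc)  # in (-pi/2, pi/2]; f_s = 0 axis -> -pi/2

    U <- vector("list", n_bins - 1L)
    for (j in seq_len(n_bins - 1L)) {
      U[[j]] <- smooth_step(alpha, edges[j],
                            bins$softness * min(widths[j], widths[j + 1L]))
    }
    w_wrap <- bins$softness * min(widths[1], widths[n_bins])
    U_wrap <- smooth_step(alpha, pi / 2, w_wrap)  # 1 just above -pi/2 wrap

    # Bin b lies between its lower and upper edges; the first and last bins
    # share the wrap edge at +/- pi/2 (the f_s = 0 axis).
    lapply(seq_len(n_bins), function(b) {
      lower <- if (b == 1L) U_wrap else U[[b - 1L]]
      upper <- if (b == n_bins) U_wrap else U[[b]]
      lower * (1 - upper)
    })
  }

  # For even dimensions the Nyquist row/column represents +f and -f at once;
  # average the masks over both sign readings there so that the masks stay
  # Hermitian and the components stay real.
  ft_variants <- list(FT)
  if (n_t %% 2 == 0) {
    FT2 <- FT; FT2[n_t / 2 + 1L, ] <- -FT2[n_t / 2 + 1L, ]
    ft_variants <- c(ft_variants, list(FT2))
  }
  fs_variants <- list(FS)
  if (n_s %% 2 == 0) {
    FS2 <- FS; FS2[, n_s / 2 + 1L] <- -FS2[, n_s / 2 + 1L]
    fs_variants <- c(fs_variants, list(FS2))
  }
  combos <- list()
  for (ftv in ft_variants) for (fsv in fs_variants) {
    combos[[length(combos) + 1L]] <- masks_for(ftv, fsv)
  }
  masks <- lapply(seq_len(n_bins), function(b) {
    Reduce(`+`, lapply(combos, `[[`, b)) / length(combos)
  })
  names(masks) <- bins$labels

  # DC -> background only.
  bg <- matrix(0, n_t, n_s)
  bg[1, 1] <- 1
  for (b in seq_len(n_bins)) masks[[b]][1, 1] <- 0
  masks$background <- bg
  masks
}

#' Decompose a kymograph into directional components (FSDA)
#'
#' Applies a 2D Tukey window, takes the 2D FFT, multiplies the spectrum by
#' each velocity-wedge mask, and inverse-transforms each product. Components
#' are real and sum (with background) to the windowed input; per-bin energy
#' fractions follow Parseval's theorem.
#'
#' @param kymo A [kymograph()] (finite-valued).
#' @param bins A [velocity_bins()].
#' @param window_alpha Tukey taper fraction applied on both axes
#'   (default 0.25; 0 disables windowing).
#' @param dewindow If `TRUE`, divide components by the window where it
#'   exceeds `dewindow_floor` (zero elsewhere) to restore input scale away
#'   from the borders.
#' @param dewindow_floor Window value below which de-windowing is suppressed.
#' @param pre_smooth_px Sigma (px) of a Gaussian anti-alias filter applied
#'   along the arc-length axis before windowing. For fast objects at low
#'   frame rates (a 3 um/s train at 5 fps), the ridge's spectral line
#'   crosses the temporal Nyquist frequency and wraps into the
#'   opposite-direction wedge; a ~1 px spatial pre-filter suppresses the
#'   wrapped content. 0 (default) disables it.
#' @return An `fsda_result`: list with `components` (named list of
#'   [kymograph()]s, one per bin plus background), `energy` (tibble of bin,
#'   fraction), `window`, and `bins`.
#' @export
fsda_decompose <- function(kymo, bins = velocity_bins(), window_alpha = 0.25,
                           dewindow = FALSE, dewindow_floor = 0.05,
                           pre_smooth_px = 0) {
  if (any(!is.finite(kymo))) abort("Kymograph contains non-finite values.")
  K <- unclass(kymo)
  if (pre_smooth_px > 0) {
    K <- t(apply(K, 1, smooth_vector, sigma = pre_smooth_px))
  }
  n_t <- nrow(K); n_s <- ncol(K)
  px <- attr(kymo, "pixel_size"); dt <- attr(kymo, "frame_interval")

  W <- outer(tukey_window(n_t, window_alpha), tukey_window(n_s, window_alpha))
  Kw <- K * W
  Z <- fft(Kw)
  masks <- build_masks(bins, c(n_t, n_s), px, dt)

  total_energy <- sum(Mod(Z)^2)
  comps <- vector("list", length(masks))
  energy <- numeric(length(masks))
  for (i in seq_along(masks)) {
    Zi <- Z * masks[[i]]
    ci <- Re(fft(Zi, inverse = TRUE)) / (n_t * n_s)
    if (dewindow) {
      ci <- ifelse(W > dewindow_floor, ci / W, 0)
    }
    comps[[i]] <- kymograph(ci, px, dt, attr(kymo, "arc_origin_um"))
    # Energy accounting applies the mask to the power spectrum so that the
    # soft-edged fractions still sum to exactly 1.
    energy[i] <- sum(masks[[i]] * Mod(Z)^2)
  }
  names(comps) <- names(masks)
  energy <- if (total_energy > 0) energy / total_energy else energy

  structure(list(
    components = comps,
    energy = tibble(bin = names(masks), fraction = energy),
    window = W, bins = bins, windowed_input = kymograph(Kw, px, dt),
    dewindow = dewindow
  ), class = "fsda_result")
}

#' @export
print.fsda_result <- function(x, ...) {
  cat("<fsda_result>\n")
  e <- x$energy
  for (i in seq_len(nrow(e))) {
    cat(sprintf("  %-12s energy fraction %.4f\n", e$bin[i], e$fraction[i]))
  }
  invisible(x)
}

# 1D Gaussian smoothing with edge clamping.
smooth_vector <- function(v, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2)); k <- k / sum(k)
  n <- length(v)
  idx <- outer(seq_len(n), -r:r, "+")
  idx[idx < 1] <- 1; idx[idx > n] <- n
  as.vector(matrix(v[idx], n) %*% k)
}

# Separable Gaussian blur with edge clamping (small kernels).
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2)); k <- k / sum(k)
  blur1 <- function(v) {
    n <- length(v)
    idx <- outer(seq_len(n), -r:r, "+")
    idx[idx < 1] <- 1; idx[idx > n] <- n
    as.vector(matrix(v[idx], n) %*% k)
  }
  m <- apply(m, 2, blur1)
  t(apply(m, 1, blur1))
}

#' Pseudo-color a kymograph by per-pixel velocity class
#'
#' Runs [fsda_decompose()] and labels each pixel with the bin whose local
#' component magnitude (after Gaussian envelope smoothing) is largest. Pixels
#' where every component is (tied at) zero get the background label.
#'
#' @param kymo A [kymograph()].
#' @param bins A [velocity_bins()].
#' @param envelope_sigma Envelope smoothing sigma in px.
#' @param ... Passed to [fsda_decompose()].
#' @return A `velocity_map`: integer matrix of bin indices with a `labels`
#'   attribute (`levels = c(bins$labels, "background")`).
#' @export
velocity_colormap <- function(kymo, bins = velocity_bins(),
                              envelope_sigma = 2, ...) {
  res <- fsda_decompose(kymo, bins, ...)
  lab_names <- c(bins$labels, "background")
  env <- lapply(bins$labels, function(b) {
    gaussian_blur(abs(unclass(res$components[[b]])), envelope_sigma)
  })
  n_t <- nrow(kymo); n_s <- ncol(kymo)
  stack <- array(unlist(env), dim = c(n_t, n_s, length(env)))
  best <- apply(stack, c(1, 2), function(v) {
    m <- max(v)
    if (m <= 0 || sum(v == m) > 1) length(lab_names) else which.max(v)
  })
  structure(best, labels = lab_names,
            pixel_size = attr(kymo, "pixel_size"),
            frame_interval = attr(kymo, "frame_interval"),
            class = "velocity_map")
}

#' @export
tidy.velocity_map <- function(x, ...) {
  dt <- attr(x, "frame_interval"); dp <- attr(x, "pixel_size")
  labs <- attr(x, "labels")
  tibble(
    t = rep((seq_len(nrow(x)) - 1L) * dt, times = ncol(x)),
    s = rep((seq_len(ncol(x)) - 1L) * dp, each = nrow(x)),
    label = factor(labs[as.vector(unclass(x))], levels = labs)
  )
}

#' @export
autoplot.velocity_map <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$s, y = .data$t,
                                   fill = .data$label)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_manual(values = c(anterograde = "#2ca02c",
                                          retrograde = "#d62728",
                                          paused = "#1f77b4",
                                          background = "grey20"),
                               na.value = "grey20", name = NULL) +
    ggplot2::labs(x = "arc length from base (µm)", y = "time (s)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.fsda_result <- function(object, ...) {
  dfs <- purrr::imap_dfr(object$components, function(k, nm) {
    dplyr::mutate(tidy(k), component = nm)
  })
  ggplot2::ggplot(dfs, ggplot2::aes(x = .data$s, y = .data$t,
                                    fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::facet_wrap(~component) +
    ggplot2::scale_fill_viridis_c(name = "intensity") +
    ggplot2::labs(x = "arc length from base (µm)", y = "time (s)") +
    ggplot2::theme_minimal()
}
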