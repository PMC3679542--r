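#' Subpixel localization by 2D Gaussian fitting
#'
#' Fits a symmetric two-dimensional Gaussian plus a constant offset to a
#' region of interest by Levenberg-Marquardt least squares, returning the
#' subpixel centre, width and amplitude. Fit failures raise an error rather
#' than returning NaN silently.
#'
#' @param frame 2D numeric matrix (one movie frame).
#' @param roi_center `(row, col)` pixel coordinates (1-based) of the ROI
#'   centre; must contain one dominant spot.
#' @param roi_halfwidth ROI half-width in px.
#' @return A one-row tibble: `row`, `col` (subpixel, 1-based), `sigma`,
#'   `amplitude`, `offset`, `rss`, `converged`.
#' @export
localize_gaussian <- function(frame, roi_center, roi_halfwidth = 5) {
  if (!is.matrix(frame)) abort("`frame` must be a matrix.")
  r0 <- round(roi_center[1]); c0 <- round(roi_center[2])
  hw <- as.integer(roi_halfwidth)
  if (r0 - hw < 1 || r0 + hw > nrow(frame) ||
      c0 - hw < 1 || c0 + hw > ncol(frame)) {
    abort("ROI extends outside the frame.")
  }
  rr <- (r0 - hw):(r0 + hw)
  cc <- (c0 - hw):(c0 + hw)
  z <- frame[rr, cc]
  df <- tibble(
    r = rep(rr, times = length(cc)),
    c = rep(cc, each = length(rr)),
    z = as.vector(z)
  )

  off0 <- min(z)
  amp0 <- max(z) - off0
  if (amp0 <= 0) abort("ROI amplitude does not exceed background.")
  peak <- which(z == max(z), arr.ind = TRUE)[1, ]
  start <- list(amp = amp0, mr = rr[peak[1]], mc = cc[peak[2]],
                sigma = hw / 2.5, off = off0)

  fit <- tryCatch(
    minpack.lm::nlsLM(
      z ~ off + amp * exp(-((r - mr)^2 + (c - mc)^2) / (2 * sigma^2)),
      data = df, start = start,
      lower = c(amp = 0, mr = min(rr) - 1, mc = min(cc) - 1,
                sigma = 0.3, off = -Inf),
      upper = c(amp = Inf, mr = max(rr) + 1, mc = max(cc) + 1,
                sigma = 4 * hw, off = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 100)
    ),
    error = function(e) abort(paste0("Gaussian fit failed: ", conditionMessage(e)))
  )
  p <- coef(fit)
  if (p[["amp"]] <= 0) abort("Fitted amplitude does not exceed background.")
  tibble(row = p[["mr"]], col = p[["mc"]], sigma = abs(p[["sigma"]]),
         amplitude = p[["amp"]], offset = p[["off"]],
         rss = sum(stats::residuals(fit)^2),
         converged = fit$convInfo$isConv %||% TRUE)
}

#' Correlate two position tracks over their temporal overlap
#'
#' Pairs samples by nearest time (within half the median frame interval) and
#' returns the Pearson correlation of the paired positions, as used to show
#' that bead and train movements track each other during processive runs.
#'
#' @param a,b Tibbles with columns `t` and a position column (`s`, or
#'   `position`).
#' @param min_overlap Minimum number of paired samples (default 5).
#' @return A one-row tibble: `r`, `n_overlap`.
#' @export
correlate_tracks <- function(a, b, min_overlap = 5) {
  pa <- track_position_col(a)
  pb <- track_position_col(b)
  dt <- median(diff(sort(unique(c(a$t, b$t)))))
  tol <- dt / 2 + 1e-12
  idx <- vapply(a$t, function(t) {
    j <- which.min(abs(b$t - t))
    if (abs(b$t[j] - t) <= tol) j else NA_integer_
  }, integer(1))
  keep <- !is.na(idx)
  x <- a[[pa]][keep]
  y <- b[[pb]][idx[keep]]
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < min_overlap) {
    abort(sprintf("Only %d overlapping samples (need >= %d).",
                  length(x), min_overlap))
  }
  if (sd(x) == 0 || sd(y) == 0) abort("Zero variance in one of the tracks.")
  tibble(r = stats::cor(x, y), n_overlap = length(x))
}

track_position_col <- function(x) {
  for (nm in c("s", "position", "x")) if (nm %in% names(x)) return(nm)
  abort("Track needs an `s`, `position` or `x` column.")
}
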