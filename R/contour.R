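#' Planar bundle contour
#'
#' Constructs a traced bundle centerline: an ordered list of (x, y) points in
#' micrometres for one bundle at one video frame, together with the cumulative
#' arc length along the polyline. This is the raw input of the shape pipeline,
#' as produced by filament-tracing tools.
#'
#' @param x,y numeric vectors of point coordinates in um, in tracing order.
#' @param bundle_id identifier of the bundle the contour belongs to.
#' @param frame integer frame index.
#' @param time acquisition time in seconds (defaults to `frame`, i.e. 1 Hz).
#' @return An object of class `planar_contour`: a list with elements
#'   `bundle_id`, `frame`, `time`, `points` (n x 2 matrix) and `arclength`
#'   (cumulative arc length in um, starting at 0).
#' @examples
#' pc <- planar_contour(x = c(0, 1, 2), y = c(0, 0, 0))
#' contour_length(pc)
#' @export
planar_contour <- function(x, y, bundle_id = "bundle", frame = 1L,
                           time = NULL) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) {
    stop("`x` and `y` must have the same length", call. = FALSE)
  }
  if (length(x) < 3) {
    stop("a contour needs at least 3 points", call. = FALSE)
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("contour coordinates must be finite", call. = FALSE)
  }
  dx <- diff(x)
  dy <- diff(y)
  seg <- sqrt(dx^2 + dy^2)
  if (any(seg == 0)) {
    stop("consecutive contour points must be distinct", call. = FALSE)
  }
  structure(
    list(
      bundle_id = bundle_id,
      frame = as.integer(frame),
      time = if (is.null(time)) as.numeric(frame) else as.numeric(time),
      points = cbind(x = x, y = y),
      arclength = c(0, cumsum(seg))
    ),
    class = "planar_contour"
  )
}

#' @export
print.planar_contour <- function(x, ...) {
  cat(sprintf(
    "Planar contour: bundle '%s', frame %d, %d points, L = %.3f um\n",
    x$bundle_id, x$frame, nrow(x$points), contour_length(x)
  ))
  invisible(x)
}

#' Total arc length of a contour
#'
#' @param contour a [planar_contour()].
#' @return Total polyline arc length in um.
#' @export
contour_length <- function(contour) {
  stopifnot(inherits(contour, "planar_contour"))
  contour$arclength[length(contour$arclength)]
}

#' Resample a contour at equal arc-length spacing
#'
#' Places `n_samples` points on the input polyline at equal arc-length
#' intervals from 0 to the total length. The resampled points lie exactly on
#' the original polyline and the total arc length is preserved.
#'
#' @param contour a [planar_contour()].
#' @param n_samples number of output points (>= 3).
#' @return A [planar_contour()] with `n_samples` equally spaced points.
#' @export
arclength_resample <- function(contour, n_samples) {
  stopifnot(inherits(contour, "planar_contour"))
  if (n_samples < 3) stop("`n_samples` must be >= 3", call. = FALSE)
  L <- contour_length(contour)
  s_new <- seq(0, L, length.out = n_samples)
  xy <- polyline_point_at(contour$points, contour$arclength, s_new)
  planar_contour(xy[, 1], xy[, 2],
    bundle_id = contour$bundle_id,
    frame = contour$frame, time = contour$time
  )
}

#' Smooth a traced contour
#'
#' Centered moving average of the point coordinates along the tracing
#' order, with a symmetrically shrinking window at the contour ends. Raw
#' point-wise tracing noise inflates the cumulative polyline arc length and
#' makes the arc-length coordinate of each point wander, which distorts
#' arc-length-matched spline fits; a light smoothing pass (as snake-style
#' tracers apply internally) restores a reliable arc-length parameterization
#' while attenuating curvature only at scales below `window` point
#' spacings.
#'
#' @param contour a [planar_contour()].
#' @param window odd window size in points (default 5).
#' @return A smoothed [planar_contour()].
#' @export
smooth_contour <- function(contour, window = 5L) {
  stopifnot(inherits(contour, "planar_contour"))
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) {
    stop("`window` must be a positive odd integer", call. = FALSE)
  }
  if (window == 1L) return(contour)
  p <- contour$points
  n <- nrow(p)
  h <- window %/% 2L
  sm <- vapply(seq_len(n), function(i) {
    hi <- min(h, i - 1L, n - i)
    colMeans(p[(i - hi):(i + hi), , drop = FALSE])
  }, numeric(2))
  planar_contour(sm[1, ], sm[2, ],
    bundle_id = contour$bundle_id,
    frame = contour$frame, time = contour$time
  )
}

## Linear interpolation of a polyline at arc lengths s (vectorized).
polyline_point_at <- function(points, arclength, s) {
  x <- stats::approx(arclength, points[, 1], xout = s, rule = 2)$y
  y <- stats::approx(arclength, points[, 2], xout = s, rule = 2)$y
  cbind(x, y)
}

## Tangent angle of a polyline, evaluated at segment midpoints, unwrapped so
## consecutive values never jump by more than pi. Returns a list with the
## midpoint arc lengths, the angles and the segment lengths (weights).
polyline_tangent_angles <- function(contour) {
  p <- contour$points
  dx <- diff(p[, 1])
  dy <- diff(p[, 2])
  theta <- unwrap_angles(atan2(dy, dx))
  s <- contour$arclength
  list(
    s_mid = (s[-1] + s[-length(s)]) / 2,
    theta = theta,
    ds = diff(s)
  )
}

unwrap_angles <- function(theta) {
  if (length(theta) < 2) return(theta)
  d <- diff(theta)
  jump <- round(d / (2 * pi))
  theta - c(0, cumsum(jump)) * 2 * pi
}
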