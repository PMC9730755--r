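## Boltzmann constant in pN um / K (1.380649e-23 J/K).
.kB <- 1.380649e-5

#' Tangent-tangent correlation function
#'
#' Computes \eqn{C_{tt}(s) = \langle \cos(\phi(s_0+s) - \phi(s_0))\rangle},
#' the mean cosine of the tangent-angle difference between contour points
#' separated by arc length `s`. The average runs both along the contour
#' (uniform `s0` grid of spacing `ds`) and over the supplied video frames.
#' Its half-decay length characterizes the length scale of active bending.
#'
#' @param shapes a list of [clothoid_spline()] or [planar_contour()] objects,
#'   the frames of one bundle over time (a single object is also accepted).
#' @param ds arc-length grid spacing in um; defaults to `L_min / 200` where
#'   `L_min` is the shortest contour length.
#' @param s_max largest separation to report, um; capped at `L_min`.
#' @return An object of class `correlation_function`: a data frame with
#'   columns `separation` (um), `value` and `n_pairs`, plus attributes `kind`
#'   and `ds`.
#' @seealso [curvature_correlation()], [half_decay_length()]
#' @export
tangent_correlation <- function(shapes, ds = NULL, s_max = NULL) {
  shapes <- as_shape_list(shapes)
  corr_by_lag(shapes, ds, s_max, kind = "tangent")
}

#' Curvature-curvature correlation function
#'
#' Computes \eqn{C_{KK}(s) = \langle K(s_0+s)K(s_0)\rangle / \langle
#' K^2\rangle}, the normalized autocorrelation of the signed curvature,
#' averaged along the contour and over frames, so that `C_KK(0) = 1`. Its
#' half-decay length measures the arc-length scale of curvature variation.
#'
#' @inheritParams tangent_correlation
#' @return A `correlation_function` of kind `"curvature"`.
#' @export
curvature_correlation <- function(shapes, ds = NULL, s_max = NULL) {
  shapes <- as_shape_list(shapes)
  if (!all(vapply(shapes, inherits, TRUE, "clothoid_spline"))) {
    stop("curvature correlation requires fitted clothoid splines", call. = FALSE)
  }
  corr_by_lag(shapes, ds, s_max, kind = "curvature")
}

as_shape_list <- function(shapes) {
  if (inherits(shapes, c("clothoid_spline", "planar_contour"))) {
    shapes <- list(shapes)
  }
  if (length(shapes) == 0) stop("empty list of shapes", call. = FALSE)
  ok <- vapply(
    shapes, function(s) inherits(s, c("clothoid_spline", "planar_contour")),
    TRUE
  )
  if (!all(ok)) {
    stop("shapes must be clothoid splines or planar contours", call. = FALSE)
  }
  shapes
}

shape_length <- function(shape) {
  if (inherits(shape, "clothoid_spline")) shape$length else contour_length(shape)
}

## Tangent angle (or curvature) of one shape sampled on a uniform grid of
## spacing ds from 0 to its length.
shape_profile <- function(shape, ds, what) {
  L <- shape_length(shape)
  s <- seq(0, L, by = ds)
  if (inherits(shape, "clothoid_spline")) {
    if (what == "tangent") clothoid_phi(shape, s) else curvature_at(shape, s)
  } else {
    ta <- polyline_tangent_angles(shape)
    stats::approx(ta$s_mid, ta$theta, xout = s, rule = 2)$y
  }
}

corr_by_lag <- function(shapes, ds, s_max, kind) {
  L_min <- min(vapply(shapes, shape_length, numeric(1)))
  if (is.null(ds)) ds <- L_min / 200
  if (ds <= 0) stop("`ds` must be > 0", call. = FALSE)
  smax <- if (is.null(s_max)) L_min else min(s_max, L_min)
  n_lags <- floor(smax / ds + 1e-9)
  what <- if (kind == "tangent") "tangent" else "curvature"
  profiles <- lapply(shapes, shape_profile, ds = ds, what = what)

  sums <- numeric(n_lags + 1)
  counts <- integer(n_lags + 1)
  for (p in profiles) {
    n <- length(p)
    for (k in 0:min(n_lags, n - 1)) {
      i <- seq_len(n - k)
      if (kind == "tangent") {
        sums[k + 1] <- sums[k + 1] + sum(cos(p[i + k] - p[i]))
      } else {
        sums[k + 1] <- sums[k + 1] + sum(p[i + k] * p[i])
      }
      counts[k + 1] <- counts[k + 1] + length(i)
    }
  }
  keep <- counts >= 1
  vals <- sums[keep] / counts[keep]
  if (kind == "curvature") {
    if (vals[1] <= 0) {
      stop("degenerate input: curvature is identically zero", call. = FALSE)
    }
    vals <- vals / vals[1]
  }
  out <- data.frame(
    separation = (which(keep) - 1) * ds,
    value = vals,
    n_pairs = counts[keep]
  )
  structure(out, kind = kind, ds = ds, class = c("correlation_function", "data.frame"))
}

#' @export
print.correlation_function <- function(x, ...) {
  hd <- half_decay_length(x)
  cat(sprintf(
    "%s correlation: %d bins, ds = %.3f um, half-decay length %s\n",
    attr(x, "kind"), nrow(x), attr(x, "ds"),
    if (is.na(hd)) "not reached" else sprintf("%.2f um", hd)
  ))
  invisible(x)
}

#' @export
plot.correlation_function <- function(x, ...) {
  graphics::plot(x$separation, x$value,
    type = "l", xlab = "separation s [um]",
    ylab = sprintf("C_%s(s)", if (attr(x, "kind") == "tangent") "tt" else "KK"),
    ...
  )
  graphics::abline(h = 0.5, lty = 3)
  invisible(x)
}

#' Average correlation functions across bundles
#'
#' Unweighted mean of per-bundle correlation functions, reported on the
#' common separation grid (all inputs must share the same `ds`); bins are
#' kept up to the shortest curve.
#'
#' @param corrs a list of `correlation_function` objects of the same kind.
#' @return A `correlation_function` holding the across-bundle mean; its
#'   `n_pairs` column carries the summed pair counts.
#' @export
pool_correlations <- function(corrs) {
  stopifnot(length(corrs) >= 1)
  kinds <- vapply(corrs, attr, "", "kind")
  dss <- vapply(corrs, attr, numeric(1), "ds")
  if (length(unique(kinds)) != 1 || max(dss) - min(dss) > 1e-9) {
    stop("correlation functions must share kind and ds", call. = FALSE)
  }
  n <- min(vapply(corrs, nrow, integer(1)))
  vals <- rowMeans(vapply(corrs, function(cc) cc$value[seq_len(n)], numeric(n)))
  cnts <- rowSums(vapply(corrs, function(cc) cc$n_pairs[seq_len(n)], numeric(n)))
  out <- data.frame(
    separation = corrs[[1]]$separation[seq_len(n)],
    value = vals, n_pairs = as.integer(cnts)
  )
  structure(out,
    kind = kinds[1], ds = dss[1],
    class = c("correlation_function", "data.frame")
  )
}

#' Half-decay characteristic length
#'
#' The smallest separation at which a correlation function first crosses
#' 0.5, located by linear interpolation between the bracketing bins. Used as
#' the characteristic length of both tangent and curvature correlations.
#'
#' @param corr a `correlation_function` (must start at `C(0) = 1`).
#' @return The crossing arc length in um, or `NA` if the curve never
#'   reaches 0.5 over the reported range.
#' @export
half_decay_length <- function(corr) {
  v <- corr$value
  s <- corr$separation
  below <- which(v < 0.5)
  if (length(below) == 0) return(NA_real_)
  i <- below[1]
  if (i == 1) return(s[1])
  s[i - 1] + (0.5 - v[i - 1]) * (s[i] - s[i - 1]) / (v[i] - v[i - 1])
}

#' Cosine-mode amplitudes of the tangent angle
#'
#' Decomposes the tangent angle of each contour on the cosine basis
#' \eqn{\theta(s) = \sqrt{2/L}\sum_n a_n \cos(n\pi s/L)} (free-end boundary
#' conditions); the integrals are evaluated as sums over the polyline
#' segments. Mode 0 (rigid rotation) is not part of the basis.
#'
#' @param contours a list of [planar_contour()] frames of one filament.
#' @param n_modes number of modes to return.
#' @return An `n_frames` x `n_modes` matrix of amplitudes `a_n` (units
#'   sqrt(um)), with the common contour length as attribute `L`.
#' @export
thermal_mode_amplitudes <- function(contours, n_modes = 3L) {
  contours <- as_shape_list(contours)
  Ls <- vapply(contours, shape_length, numeric(1))
  L <- mean(Ls)
  amps <- t(vapply(contours, function(pc) {
    ta <- polyline_tangent_angles(pc)
    vapply(seq_len(n_modes), function(n) {
      sqrt(2 / L) * sum(ta$theta * cos(n * pi * ta$s_mid / L) * ta$ds)
    }, numeric(1))
  }, numeric(n_modes)))
  if (n_modes == 1L) amps <- matrix(amps, ncol = 1L)
  structure(amps, L = L)
}

#' Flexural rigidity from thermal shape fluctuations
#'
#' Estimates the flexural rigidity `EI` of a freely fluctuating filament or
#' bundle (no motor activity) from the variance of its tangent-angle cosine
#' modes. By equipartition each mode carries
#' \eqn{\mathrm{var}(a_n) = k_B T L^2 / (EI\, n^2 \pi^2)}; the per-mode
#' estimates are combined by inverse-variance weighting over modes
#' `1..n_modes`.
#'
#' @param contours a list of at least 50 [planar_contour()] frames of the
#'   same filament; the contour length may vary by at most 5% across frames.
#' @param temperature bath temperature in kelvin (default 298).
#' @param n_modes number of modes used (default 3).
#' @return An object of class `rigidity_estimate` with elements `EI` and
#'   `stderr` (pN um^2), `per_mode` (per-mode estimates), `n_modes_used`,
#'   `n_frames`, `L` and `temperature`.
#' @export
estimate_EI_thermal <- function(contours, temperature = 298, n_modes = 3L) {
  contours <- as_shape_list(contours)
  n_frames <- length(contours)
  if (n_frames < 50) {
    stop("need at least 50 frames of thermal fluctuations", call. = FALSE)
  }
  Ls <- vapply(contours, shape_length, numeric(1))
  L <- mean(Ls)
  if ((max(Ls) - min(Ls)) / L > 0.05) {
    stop("contour length varies by more than 5% across frames", call. = FALSE)
  }
  amps <- thermal_mode_amplitudes(contours, n_modes = n_modes)
  v_n <- apply(amps, 2, stats::var)
  n <- seq_len(n_modes)
  EI_n <- .kB * temperature * L^2 / (v_n * n^2 * pi^2)
  ## var(EI_n) ~ EI_n^2 * 2/(F-1) from the chi-squared sampling error of v_n
  var_n <- EI_n^2 * 2 / (n_frames - 1)
  w <- 1 / var_n
  EI <- sum(w * EI_n) / sum(w)
  structure(
    list(
      EI = EI,
      stderr = sqrt(1 / sum(w)),
      per_mode = EI_n,
      n_modes_used = n_modes,
      n_frames = n_frames,
      L = L,
      temperature = temperature
    ),
    class = "rigidity_estimate"
  )
}

#' @export
print.rigidity_estimate <- function(x, ...) {
  cat(sprintf(
    "Flexural rigidity: EI = %.3f +/- %.3f pN um^2 (%.2g N m^2)\n",
    x$EI, x$stderr, x$EI * 1e-24
  ))
  cat(sprintf(
    "  from %d frames, modes 1-%d, L = %.2f um, T = %.0f K\n",
    x$n_frames, x$n_modes_used, x$L, x$temperature
  ))
  invisible(x)
}
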