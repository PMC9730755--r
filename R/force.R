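#' Curvature derivative of a fitted spline
#'
#' Finite difference of the node curvatures, `(K_{j+1} - K_j) / (s_{j+1} -
#' s_j)`, one value per inter-node span. This is the quantity that carries
#' the motor force signal in an internally driven bundle.
#'
#' @param spline a [clothoid_spline()].
#' @return Numeric vector of length `N_p - 1`, units 1/um^2.
#' @export
curvature_derivative <- function(spline) {
  stopifnot(inherits(spline, "clothoid_spline"))
  diff(spline$node_K) / diff(spline$node_s)
}

#' Motor shear force and force density from curvature
#'
#' For a free bundle (no external moments) bent only by internal motor
#' shear, the bending moment balance gives `EI * K = F * d`, with `F` the
#' shear force between filaments and `d` their effective separation. The
#' force density per unit length, `f = dF/ds`, is then directly proportional
#' to the curvature derivative: `f = (EI / d) * dK/ds`, evaluated per span of
#' the fitted spline. The shear force at the nodes is `F = EI * K / d`, and
#' `f` is exactly the finite difference of `F` across each span.
#'
#' @param spline a [clothoid_spline()] fitted to one frame of a bundle.
#' @param EI flexural rigidity in pN um^2 (default 7, the thermally measured
#'   bundle value, i.e. 0.7e-23 N m^2).
#' @param d effective inter-filament distance in um (default 0.075, the
#'   average kinesin-cluster size separating microtubules).
#' @param bundle_id,frame identifiers stored in the profile.
#' @return An object of class `force_profile`: a list with `segment_midpoints`
#'   (um), `force_density` (pN/um per span), `node_s`, `shear_force`
#'   (pN at the nodes), `EI`, `d`, `M_ext` (0, the free-bundle assumption)
#'   and the identifiers.
#' @export
force_density <- function(spline, EI = 7, d = 0.075, bundle_id = "bundle",
                          frame = 1L) {
  stopifnot(inherits(spline, "clothoid_spline"))
  if (!is.numeric(EI) || EI <= 0) stop("`EI` must be > 0", call. = FALSE)
  if (!is.numeric(d) || d <= 0) stop("`d` must be > 0", call. = FALSE)
  ns <- spline$node_s
  structure(
    list(
      bundle_id = bundle_id,
      frame = as.integer(frame),
      segment_midpoints = (ns[-1] + ns[-length(ns)]) / 2,
      force_density = (EI / d) * curvature_derivative(spline),
      node_s = ns,
      shear_force = EI * spline$node_K / d,
      EI = EI,
      d = d,
      M_ext = 0
    ),
    class = "force_profile"
  )
}

#' @export
print.force_profile <- function(x, ...) {
  cat(sprintf(
    "Force profile: bundle '%s' frame %d, %d spans, |f| up to %.2f pN/um\n",
    x$bundle_id, x$frame, length(x$force_density), max(abs(x$force_density))
  ))
  invisible(x)
}

#' @export
plot.force_profile <- function(x, ...) {
  graphics::plot(x$segment_midpoints, x$force_density,
    type = "h", lwd = 3,
    xlab = "arc length s [um]", ylab = "f [pN/um]", ...
  )
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Pooled force-density distribution across bundles and frames
#'
#' Pools the absolute force densities of many per-frame profiles, builds a
#' histogram, and reports the maximum force density of each bundle as the
#' 95th percentile of its own pooled distribution (linear interpolation
#' between closest order statistics).
#'
#' @param profiles a list of [force_density()] profiles.
#' @param bin_width histogram bin width in pN/um (default 0.5).
#' @return An object of class `force_density_summary` with elements
#'   `pooled_values` (all |f|), `breaks` and `counts` (histogram), and
#'   `per_bundle_p95` (named vector, pN/um).
#' @export
summarize_force_densities <- function(profiles, bin_width = 0.5) {
  if (inherits(profiles, "force_profile")) profiles <- list(profiles)
  if (length(profiles) == 0) stop("no force profiles supplied", call. = FALSE)
  stopifnot(all(vapply(profiles, inherits, TRUE, "force_profile")))
  ids <- vapply(profiles, function(p) as.character(p$bundle_id), "")
  vals <- lapply(profiles, function(p) abs(p$force_density))
  pooled <- unlist(vals, use.names = FALSE)
  breaks <- seq(0, max(pooled) + bin_width, by = bin_width)
  h <- graphics::hist(pooled, breaks = breaks, plot = FALSE)
  p95 <- vapply(
    split(vals, ids),
    function(v) stats::quantile(unlist(v), 0.95, names = FALSE, type = 7),
    numeric(1)
  )
  structure(
    list(
      pooled_values = pooled,
      breaks = h$breaks,
      counts = h$counts,
      per_bundle_p95 = p95
    ),
    class = "force_density_summary"
  )
}

#' @export
print.force_density_summary <- function(x, ...) {
  cat(sprintf(
    "Force densities: %d pooled values, median %.2f pN/um\n",
    length(x$pooled_values), stats::median(x$pooled_values)
  ))
  cat("  per-bundle 95th percentile [pN/um]:\n")
  print(round(x$per_bundle_p95, 2))
  invisible(x)
}
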