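# shared fixtures, all generated in code

# contour on a circle of radius R covering `arc` radians, n points
circle_contour <- function(R = 20, arc = pi / 2, n = 100, noise = 0,
                           center = c(0, R)) {
  ang <- seq(-pi / 2, -pi / 2 + arc, length.out = n)
  x <- center[1] + R * cos(ang) + rnorm(n, 0, noise)
  y <- center[2] + R * sin(ang) + rnorm(n, 0, noise)
  planar_contour(x, y)
}

# independent fine-step trapezoid integrator for the spline position oracle:
# works directly from the node-curvature definition, sharing no code with
# the package's quadrature
oracle_spline_xy <- function(node_K, L, s_target, phi0 = 0, base = c(0, 0),
                             n_steps = 2e5) {
  s <- seq(0, s_target, length.out = n_steps + 1)
  node_s <- seq(0, L, length.out = length(node_K))
  K <- approx(node_s, node_K, xout = s)$y
  h <- s[2] - s[1]
  phi <- phi0 + c(0, cumsum((K[-1] + K[-length(K)]) * h / 2))
  c(
    base[1] + sum((cos(phi)[-1] + cos(phi)[-length(phi)]) * h / 2),
    base[2] + sum((sin(phi)[-1] + sin(phi)[-length(phi)]) * h / 2)
  )
}

# bare correlation_function object for half-decay tests
make_corr <- function(separation, value, kind = "tangent") {
  structure(
    data.frame(separation = separation, value = value, n_pairs = 1L),
    kind = kind, ds = separation[2] - separation[1],
    class = c("correlation_function", "data.frame")
  )
}

# straight-axis motor track from 1D positions sampled at 1 Hz
axis_track <- function(p, id = "t", dt = 1) {
  t <- seq(0, by = dt, length.out = length(p))
  motor_track(t, p, rep(0, length(p)), track_id = id, projected = p)
}
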