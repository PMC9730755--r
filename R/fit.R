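#' Fit a clothoid spline to a traced contour
#'
#' Represents the bundle centerline by signed curvature at `n_nodes` equally
#' spaced arc-length nodes (linear in between, so each span is an Euler
#' spiral) plus a free base pose, and minimizes the sum of squared distances
#' between the spline evaluated at the contour's arc-length samples and the
#' observed points. Clothoid splines avoid the noise amplification that comes
#' with differentiating the traced shape directly.
#'
#' The total length L is taken from the observed polyline and held fixed.
#' Fitting is a two-stage procedure: a linear least-squares fit of
#' `(phi0, K_1..K_Np)` to the unwrapped polyline tangent angles (in which the
#' tangent angle is exactly linear), followed by derivative-free Nelder-Mead
#' simplex refinement of the full position objective with seeded randomized
#' restarts. The residual is the point-to-corresponding-point distance at
#' matched arc lengths, adequate for densely traced contours.
#'
#' @param contour a [planar_contour()].
#' @param n_nodes number of curvature nodes `N_p` (default 7).
#' @param n_restarts number of randomized simplex restarts (default 5).
#' @param seed integer seed making the randomized restarts reproducible.
#' @param maxit maximum simplex iterations per start.
#' @return An object of class `clothoid_fit`: a list with elements `spline`
#'   (the fitted [clothoid_spline()]), `rms_residual` (um), `converged`,
#'   `n_restarts_used`, and the fitted/observed points for the methods.
#' @seealso [predict.clothoid_spline()], [force_density()],
#'   [tangent_correlation()]
#' @examples
#' sp <- clothoid_spline(c(0, 0.02, 0.04, 0.02, 0, -0.02, -0.03), length = 80)
#' fit <- fit_clothoid(spline_contour(sp, 120), seed = 1)
#' coef(fit)
#' @export
fit_clothoid <- function(contour, n_nodes = 7L, n_restarts = 5L, seed = NULL,
                         maxit = 4000L) {
  stopifnot(inherits(contour, "planar_contour"))
  if (n_nodes < 2) stop("`n_nodes` must be >= 2", call. = FALSE)
  obs <- contour$points
  s_obs <- contour$arclength
  L <- contour_length(contour)
  n <- nrow(obs)

  ## --- stage 1: linear LS on unwrapped tangent angles ------------------
  ta <- polyline_tangent_angles(contour)
  A <- angle_basis(L, n_nodes, ta$s_mid)
  X <- cbind(1, A)
  w <- sqrt(ta$ds)
  beta <- tryCatch(
    qr.solve(X * w, ta$theta * w),
    error = function(e) c(ta$theta[1], rep(0, n_nodes))
  )
  p0 <- c(obs[1, 1], obs[1, 2], beta)

  obj <- make_position_objective(L, n_nodes, s_obs, obs)

  ## --- stage 2: simplex exploration from randomized starts, then one
  ## tight polish of the best candidate ----------------------------------
  explore <- function(start) {
    stats::optim(start, obj,
      method = "Nelder-Mead",
      control = list(maxit = 800L, reltol = 1e-9)
    )
  }
  best <- explore(p0)
  used <- 0L
  scale <- c(0.2, 0.2, 0.05, rep(0.01, n_nodes))
  with_seed(seed, {
    while (used < n_restarts) {
      used <- used + 1L
      start <- p0 + stats::rnorm(length(p0)) * scale
      cand <- explore(start)
      if (cand$value < best$value) best <- cand
    }
  })
  converged <- FALSE
  for (k in 1:4) {
    prev <- best$value
    best <- stats::optim(best$par, obj,
      method = "Nelder-Mead",
      control = list(maxit = maxit, reltol = 1e-13)
    )
    ## reltol met (0), or stagnation in either relative or absolute terms
    ## (near-zero residuals make the simplex degenerate, code 10, while the
    ## objective still creeps by amounts far below any meaningful scale)
    if (best$convergence == 0L ||
      prev - best$value <= max(1e-7 * prev, 1e-10)) {
      converged <- TRUE
      break
    }
  }

  p <- best$par
  spline <- clothoid_spline(p[-(1:3)], L,
    base_point = p[1:2],
    base_angle = p[3]
  )
  structure(
    list(
      spline = spline,
      rms_residual = sqrt(best$value / n),
      converged = converged,
      n_restarts_used = used,
      contour = contour,
      objective = best$value
    ),
    class = "clothoid_fit"
  )
}

## Fast position objective for the simplex stage. The tangent angle is
## linear in (phi0, K), so the angle at every quadrature point is a single
## matrix-vector product with a precomputed integrated-basis matrix; only
## the trigonometric integration is repeated per evaluation. Quadrature
## matches clothoid_xy (fixed step L/1024, 2-point Gauss-Legendre).
make_position_objective <- function(L, n_nodes, s_obs, obs, n_steps = 1024L) {
  h <- L / n_steps
  g <- seq(0, L, by = h)
  off <- h / 2 / sqrt(3)
  mid <- g[-length(g)] + h / 2
  Bq <- angle_basis(L, n_nodes, c(mid - off, mid + off))
  i <- findInterval(s_obs, g, rightmost.closed = TRUE)
  i[i < 1] <- 1L
  i[i > n_steps] <- n_steps
  w <- s_obs - g[i]
  pm <- g[i] + w / 2
  po <- w / 2 / sqrt(3)
  Bp <- angle_basis(L, n_nodes, c(pm - po, pm + po))
  m <- length(s_obs)
  half <- h / 2
  function(p) {
    phi_q <- p[3] + Bq %*% p[-(1:3)]
    ca <- cos(phi_q)
    sa <- sin(phi_q)
    cx <- c(0, cumsum((ca[1:n_steps] + ca[n_steps + 1:n_steps]) * half))
    cy <- c(0, cumsum((sa[1:n_steps] + sa[n_steps + 1:n_steps]) * half))
    phi_p <- p[3] + Bp %*% p[-(1:3)]
    x <- p[1] + cx[i] + (cos(phi_p[1:m]) + cos(phi_p[m + 1:m])) * w / 2
    y <- p[2] + cy[i] + (sin(phi_p[1:m]) + sin(phi_p[m + 1:m])) * w / 2
    sum((x - obs[, 1])^2) + sum((y - obs[, 2])^2)
  }
}

## Integrated hat basis: column j is the integral from 0 to s of the linear
## hat function centred on node j, so that phi(s) = phi0 + A %*% K.
angle_basis <- function(L, n_nodes, s) {
  vapply(seq_len(n_nodes), function(j) {
    K <- numeric(n_nodes)
    K[j] <- 1
    sp <- clothoid_spline(K, L)
    clothoid_phi(sp, s)
  }, numeric(length(s)))
}

#' @export
print.clothoid_fit <- function(x, ...) {
  cat(sprintf(
    "Clothoid fit: %d nodes over L = %.2f um, rms residual %.4f um%s\n",
    length(x$spline$node_K), x$spline$length, x$rms_residual,
    if (x$converged) "" else " (NOT converged)"
  ))
  invisible(x)
}

#' @export
summary.clothoid_fit <- function(object, ...) {
  s <- object$spline
  out <- list(
    n_nodes = length(s$node_K),
    length = s$length,
    node_s = s$node_s,
    node_K = s$node_K,
    base_point = s$base_point,
    base_angle = s$base_angle,
    rms_residual = object$rms_residual,
    converged = object$converged,
    n_restarts_used = object$n_restarts_used
  )
  class(out) <- "summary.clothoid_fit"
  out
}

#' @export
print.summary.clothoid_fit <- function(x, ...) {
  cat(sprintf("Clothoid spline fit (N_p = %d, L = %.2f um)\n", x$n_nodes, x$length))
  cat(sprintf(
    "  base point (%.3f, %.3f) um, base angle %.4f rad\n",
    x$base_point[1], x$base_point[2], x$base_angle
  ))
  cat("  node curvatures [1/um]:\n")
  tab <- rbind(s_um = x$node_s, K = x$node_K)
  print(round(tab, 5))
  cat(sprintf(
    "  rms residual %.4f um; converged: %s; restarts used: %d\n",
    x$rms_residual, x$converged, x$n_restarts_used
  ))
  invisible(x)
}

#' @export
coef.clothoid_fit <- function(object, ...) {
  k <- object$spline$node_K
  names(k) <- paste0("K", seq_along(k))
  k
}

#' @export
predict.clothoid_fit <- function(object, s = NULL, what = "xy", ...) {
  predict(object$spline, s = s, what = what, ...)
}

#' @export
fitted.clothoid_fit <- function(object, ...) {
  clothoid_xy(object$spline, object$contour$arclength)
}

#' @export
residuals.clothoid_fit <- function(object, ...) {
  object$contour$points - fitted(object)
}

#' @export
plot.clothoid_fit <- function(x, ...) {
  obs <- x$contour$points
  fit <- clothoid_xy(x$spline, seq(0, x$spline$length, length.out = 400))
  graphics::plot(obs,
    asp = 1, pch = 16, cex = 0.4, col = "grey50",
    xlab = "x [um]", ylab = "y [um]", ...
  )
  graphics::lines(fit, col = "red", lwd = 2)
  invisible(x)
}

## Evaluate `expr` under a temporary RNG state seeded with `seed`; the
## caller's RNG state is restored afterwards. With seed = NULL the global
## stream is used as-is.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
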