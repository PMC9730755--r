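#' Simulate a population of motor-cluster tracks
#'
#' Draws motor trajectories from the two-rate Markov model: each motor's
#' attachment lifetime is exponential with rate `k_d`, reversal events form
#' a Poisson process of rate `k_r` within the lifetime, and the motor moves
#' at speed `v` along a straight reference axis, flipping sign at each
#' reversal. Positions are sampled at interval `dt` with isotropic Gaussian
#' localization noise; the `projected` coordinate of each track is the noisy
#' axial position. The exact segment list, reversal count and run length of
#' every motor are recorded as ground truth (also for motors whose lifetime
#' is too short to yield a 2-sample track).
#'
#' @param model a [motor_model()].
#' @param n_tracks number of motors to simulate.
#' @param dt sampling interval, s (default 1, i.e. 1 Hz acquisition).
#' @param noise_sigma localization noise s.d. per coordinate, um
#'   (default 0.05).
#' @param seed integer seed; identical seeds give identical populations.
#' @return An object of class `motor_population`: a list with `tracks`
#'   (list of [motor_track()] with at least 2 samples), `truth` (data frame
#'   `track_id`, `lifetime`, `n_reversals`, `run_length`, `reversing` for
#'   all `n_tracks` motors), `segments` (list of signed ground-truth
#'   segments) and `params`.
#' @export
simulate_motor_population <- function(model, n_tracks, dt = 1,
                                      noise_sigma = 0.05, seed = NULL) {
  stopifnot(inherits(model, "motor_model"))
  if (n_tracks < 1) stop("`n_tracks` must be >= 1", call. = FALSE)
  if (dt <= 0) stop("`dt` must be > 0", call. = FALSE)
  with_seed(seed, {
    lifetime <- stats::rexp(n_tracks, rate = model$k_d)
    n_rev <- if (model$k_r > 0) {
      stats::rpois(n_tracks, model$k_r * lifetime)
    } else {
      integer(n_tracks)
    }
    tracks <- vector("list", n_tracks)
    segs <- vector("list", n_tracks)
    for (i in seq_len(n_tracks)) {
      t_rev <- if (n_rev[i] > 0) sort(stats::runif(n_rev[i], 0, lifetime[i])) else numeric(0)
      brk <- c(0, t_rev, lifetime[i])
      dirs <- (-1)^(seq_len(length(brk) - 1L) - 1L)
      seg <- model$v * diff(brk) * dirs
      segs[[i]] <- seg
      pos_brk <- c(0, cumsum(seg))
      t_samp <- seq(0, lifetime[i], by = dt)
      if (length(t_samp) >= 2) {
        x_true <- stats::approx(brk, pos_brk, xout = t_samp)$y
        x <- x_true + stats::rnorm(length(t_samp), 0, noise_sigma)
        y <- stats::rnorm(length(t_samp), 0, noise_sigma)
        tracks[[i]] <- motor_track(t_samp, x, y,
          track_id = paste0("sim", i),
          projected = x
        )
      }
    }
    truth <- data.frame(
      track_id = paste0("sim", seq_len(n_tracks)),
      lifetime = lifetime,
      n_reversals = n_rev,
      run_length = model$v * lifetime,
      reversing = n_rev >= 1L
    )
    structure(
      list(
        tracks = Filter(Negate(is.null), tracks),
        truth = truth,
        segments = segs,
        params = list(
          k_d = model$k_d, k_r = model$k_r, v = model$v,
          n_tracks = n_tracks, dt = dt, noise_sigma = noise_sigma, seed = seed
        )
      ),
      class = "motor_population"
    )
  })
}

#' @export
print.motor_population <- function(x, ...) {
  cat(sprintf(
    "Simulated motor population: %d motors (%d tracked >= 2 samples), %.1f%% reversing (truth)\n",
    nrow(x$truth), length(x$tracks), 100 * mean(x$truth$reversing)
  ))
  invisible(x)
}

#' @describeIn simulate_motor_population `simulate()` method; `nsim` is the
#'   number of tracks.
#' @param object a [motor_model()].
#' @param nsim number of tracks.
#' @param ... passed to `simulate_motor_population()`.
#' @export
simulate.motor_model <- function(object, nsim = 1, seed = NULL, ...) {
  simulate_motor_population(object, n_tracks = nsim, seed = seed, ...)
}

#' Simulate an actively bending bundle with known force ground truth
#'
#' Prescribes node-curvature paths over time, renders each frame's contour
#' from the implied clothoid spline (plus rigid drift and point noise), and
#' records the implied shear force density per span, `f = (EI/d) dK/ds`, as
#' ground truth. The default prescription makes each span's force density
#' oscillate sinusoidally in time with a span-specific phase and peak
#' amplitude `f_peak`, mimicking motor-driven bending while avoiding any
#' choice of elastic boundary conditions.
#'
#' @param n_frames number of video frames.
#' @param L bundle length, um (bundles in this system are 100-300 um; the
#'   short default keeps the implied bending radii physiological at the
#'   default `f_peak`).
#' @param n_nodes number of curvature nodes of the underlying spline.
#' @param n_points points per rendered contour.
#' @param f_peak peak force density of the prescription, pN/um.
#' @param EI,d rigidity (pN um^2) and inter-filament distance (um) used to
#'   convert curvature slopes to force densities.
#' @param period oscillation period of the span forces, frames.
#' @param noise_sigma tracing noise s.d. per point coordinate, um.
#' @param drift_sigma per-frame rigid translation random-walk step, um.
#' @param rot_sigma per-frame rigid rotation random-walk step, radians.
#' @param node_paths optional `n_frames x n_nodes` matrix of prescribed node
#'   curvatures overriding the sinusoidal prescription.
#' @param seed integer seed.
#' @return An object of class `bundle_simulation`: `contours` (list of
#'   [planar_contour()]), `true_splines`, `true_force` (list of
#'   [force_density()] profiles of the prescription) and `params`.
#' @export
simulate_bending_bundle <- function(n_frames = 24L, L = 150, n_nodes = 7L,
                                    n_points = 200L, f_peak = 5, EI = 7,
                                    d = 0.075, period = n_frames,
                                    noise_sigma = 0.1, drift_sigma = 0.2,
                                    rot_sigma = 0.005, node_paths = NULL,
                                    seed = NULL) {
  with_seed(seed, {
    node_s <- seq(0, L, length.out = n_nodes)
    ds <- diff(node_s)
    if (is.null(node_paths)) {
      ## span curvature slopes oscillate in time; adjacent spans are paired
      ## with opposite signs and a shared pair phase, so the accumulated
      ## curvature stays bounded by one span increment while every span's
      ## |f| sweeps 0..f_peak over a period
      n_span <- n_nodes - 1L
      pair <- ceiling(seq_len(n_span) / 2)
      phases <- stats::runif(max(pair), 0, 2 * pi)[pair]
      signs <- (-1)^(seq_len(n_span) - 1L)
      slope_peak <- f_peak * d / EI
      node_paths <- t(vapply(seq_len(n_frames), function(fr) {
        slopes <- slope_peak * signs * sin(2 * pi * fr / period + phases)
        K <- c(0, cumsum(slopes * ds))
        K - mean(K)
      }, numeric(n_nodes)))
    } else {
      node_paths <- as.matrix(node_paths)
      stopifnot(nrow(node_paths) == n_frames, ncol(node_paths) == n_nodes)
    }
    drift <- matrix(0, n_frames, 2)
    rot <- numeric(n_frames)
    if (n_frames > 1) {
      drift <- apply(matrix(stats::rnorm(2 * n_frames, 0, drift_sigma), ncol = 2), 2, cumsum)
      rot <- cumsum(stats::rnorm(n_frames, 0, rot_sigma))
    }
    contours <- vector("list", n_frames)
    splines <- vector("list", n_frames)
    forces <- vector("list", n_frames)
    for (fr in seq_len(n_frames)) {
      sp <- clothoid_spline(node_paths[fr, ], L,
        base_point = drift[fr, ],
        base_angle = rot[fr]
      )
      splines[[fr]] <- sp
      forces[[fr]] <- force_density(sp, EI = EI, d = d, frame = fr)
      s <- seq(0, L, length.out = n_points)
      xy <- clothoid_xy(sp, s) + matrix(stats::rnorm(2 * n_points, 0, noise_sigma), ncol = 2)
      contours[[fr]] <- planar_contour(xy[, 1], xy[, 2], frame = fr)
    }
    structure(
      list(
        contours = contours,
        true_splines = splines,
        true_force = forces,
        params = list(
          n_frames = n_frames, L = L, n_nodes = n_nodes,
          n_points = n_points, f_peak = f_peak, EI = EI, d = d,
          period = period, noise_sigma = noise_sigma,
          drift_sigma = drift_sigma, rot_sigma = rot_sigma, seed = seed
        )
      ),
      class = "bundle_simulation"
    )
  })
}

#' @export
print.bundle_simulation <- function(x, ...) {
  cat(sprintf(
    "Simulated bending bundle: %d frames, L = %.0f um, peak |f| = %.2f pN/um\n",
    x$params$n_frames, x$params$L,
    max(abs(unlist(lapply(x$true_force, function(p) p$force_density))))
  ))
  invisible(x)
}

#' Simulate a thermally fluctuating filament
#'
#' Draws independent equipartition frames of a freely fluctuating filament
#' of known flexural rigidity: cosine-mode amplitudes
#' \eqn{a_n \sim N(0, k_B T L^2 / (EI\,n^2\pi^2))}, tangent angle
#' synthesized from the cosine basis, contour integrated from the angle,
#' plus point localization noise. This is the input expected by
#' [estimate_EI_thermal()].
#'
#' @param EI flexural rigidity, pN um^2 (4 for a single Taxol-stabilized
#'   microtubule, 7 for a PEG-bundled pair of values measured thermally).
#' @param L filament length, um (default 17, a typical microtubule length).
#' @param temperature bath temperature, K.
#' @param n_frames number of independent frames.
#' @param n_modes number of cosine modes synthesized.
#' @param n_points points per traced contour.
#' @param noise_sigma tracing noise s.d. per coordinate, um (default 0.01,
#'   subpixel snake-tracing precision).
#' @param seed integer seed.
#' @return An object of class `thermal_simulation`: `contours` (list of
#'   [planar_contour()]) and `params` (the ground truth).
#' @export
simulate_thermal_filament <- function(EI = 4, L = 17, temperature = 298,
                                      n_frames = 1000L, n_modes = 20L,
                                      n_points = 25L, noise_sigma = 0.01,
                                      seed = NULL) {
  stopifnot(EI > 0, L > 0, temperature >= 0)
  with_seed(seed, {
    n <- seq_len(n_modes)
    sd_n <- if (temperature > 0) {
      sqrt(.kB * temperature * L^2 / (EI * n^2 * pi^2))
    } else {
      rep(0, n_modes)
    }
    ## fine grid for the angle-to-position integration, subsampled to the
    ## traced resolution
    oversample <- 8L
    s_fine <- seq(0, L, length.out = (n_points - 1L) * oversample + 1L)
    basis <- sqrt(2 / L) * cos(outer(s_fine, n * pi / L))
    keep <- seq(1, length(s_fine), by = oversample)
    h <- s_fine[2] - s_fine[1]
    contours <- vector("list", n_frames)
    for (fr in seq_len(n_frames)) {
      a <- stats::rnorm(n_modes, 0, sd_n)
      theta <- as.numeric(basis %*% a)
      cx <- cumsum_trapezoid(cos(theta), h)
      cy <- cumsum_trapezoid(sin(theta), h)
      x <- cx[keep] + stats::rnorm(n_points, 0, noise_sigma)
      y <- cy[keep] + stats::rnorm(n_points, 0, noise_sigma)
      contours[[fr]] <- planar_contour(x, y, frame = fr)
    }
    structure(
      list(
        contours = contours,
        params = list(
          EI = EI, L = L, temperature = temperature, n_frames = n_frames,
          n_modes = n_modes, n_points = n_points,
          noise_sigma = noise_sigma, seed = seed
        )
      ),
      class = "thermal_simulation"
    )
  })
}

#' @export
print.thermal_simulation <- function(x, ...) {
  cat(sprintf(
    "Simulated thermal filament: %d frames, EI = %.2f pN um^2, L = %.1f um\n",
    x$params$n_frames, x$params$EI, x$params$L
  ))
  invisible(x)
}

cumsum_trapezoid <- function(v, h) {
  c(0, cumsum((v[-1] + v[-length(v)]) * h / 2))
}
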