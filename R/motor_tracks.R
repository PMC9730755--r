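#' Motor-cluster trajectory
#'
#' A time-ordered point trajectory of one tracked kinesin cluster, as
#' produced by a spot tracker.
#'
#' @param t sample times in seconds, strictly increasing.
#' @param x,y positions in um.
#' @param track_id identifier.
#' @param projected optional 1D arc-length coordinate per sample (um), e.g.
#'   from [project_track()] or when the trajectory already lives on a known
#'   straight reference axis.
#' @return An object of class `motor_track` with elements `track_id`,
#'   `samples` (data frame `t`, `x`, `y`), `projected` and `discarded`.
#' @export
motor_track <- function(t, x, y, track_id = "track", projected = NULL) {
  t <- as.numeric(t)
  if (length(t) < 2) stop("a track needs at least 2 samples", call. = FALSE)
  if (any(diff(t) <= 0)) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }
  if (length(x) != length(t) || length(y) != length(t)) {
    stop("`t`, `x`, `y` must have equal length", call. = FALSE)
  }
  structure(
    list(
      track_id = track_id,
      samples = data.frame(t = t, x = as.numeric(x), y = as.numeric(y)),
      projected = if (is.null(projected)) NULL else as.numeric(projected),
      discarded = FALSE,
      discard_reason = NULL
    ),
    class = "motor_track"
  )
}

#' @export
print.motor_track <- function(x, ...) {
  cat(sprintf(
    "Motor track '%s': %d samples over %.1f s%s\n",
    x$track_id, nrow(x$samples), diff(range(x$samples$t)),
    if (x$discarded) sprintf(" [discarded: %s]", x$discard_reason) else ""
  ))
  invisible(x)
}

#' Project a motor track onto a bundle centerline
#'
#' Maps every sample to the arc length of its nearest point on the spline
#' (nearest-point projection onto a finely sampled polyline with local
#' segment refinement). Tracks with samples farther than `capture_distance`
#' from the spline, or whose projected coordinate jumps by more than
#' `max_jump` between consecutive samples, are flagged as discarded rather
#' than raising an error.
#'
#' @param track a [motor_track()].
#' @param spline a [clothoid_spline()] for the bundle the motor walks on.
#' @param capture_distance maximum allowed point-to-spline distance, um.
#' @param max_jump maximum allowed jump of the projected coordinate between
#'   consecutive samples, um.
#' @param step arc-length discretization of the spline used for the
#'   projection, um.
#' @return The track with `projected` filled in (or `discarded` set).
#' @export
project_track <- function(track, spline, capture_distance = 1,
                          max_jump = 2, step = 0.02) {
  stopifnot(inherits(track, "motor_track"), inherits(spline, "clothoid_spline"))
  s_grid <- seq(0, spline$length, by = step)
  ref <- clothoid_xy(spline, s_grid)
  p <- as.matrix(track$samples[, c("x", "y")])
  n_ref <- nrow(ref)
  proj <- numeric(nrow(p))
  dist <- numeric(nrow(p))
  for (i in seq_len(nrow(p))) {
    d2 <- (ref[, 1] - p[i, 1])^2 + (ref[, 2] - p[i, 2])^2
    k <- which.min(d2)
    ## refine on the two segments adjacent to the nearest vertex
    best_s <- s_grid[k]
    best_d2 <- d2[k]
    for (a in c(k - 1L, k)) {
      if (a < 1L || a >= n_ref) next
      v <- ref[a + 1L, ] - ref[a, ]
      w <- p[i, ] - ref[a, ]
      tt <- min(max(sum(v * w) / sum(v * v), 0), 1)
      q <- ref[a, ] + tt * v
      dd <- sum((p[i, ] - q)^2)
      if (dd < best_d2) {
        best_d2 <- dd
        best_s <- s_grid[a] + tt * step
      }
    }
    proj[i] <- best_s
    dist[i] <- sqrt(best_d2)
  }
  if (any(dist > capture_distance)) {
    track$discarded <- TRUE
    track$discard_reason <- "beyond capture distance"
  } else if (any(abs(diff(proj)) > max_jump)) {
    track$discarded <- TRUE
    track$discard_reason <- "projection jump"
  }
  track$projected <- proj
  track
}

#' Decompose a projected track into unidirectional run segments
#'
#' Reduces the 1D motion of a motor to signed unidirectional segments `d_i`
#' using a hysteresis rule: a direction change is accepted only once the
#' excursion in the new direction reaches `min_segment` (the minimum
#' detectable segment); sub-threshold wiggles from localization noise merge
#' into the enclosing segment. The run length is the sum of the absolute
#' segment lengths. Short pauses (net displacement below `pause_eps` over
#' `pause_window` inter-frame intervals) accumulate into `paused_time` and
#' are excluded from the moving time used for velocities.
#'
#' Tracks that never move by `min_segment`, nonreversing tracks shorter than
#' `min_segment`, reversing tracks shorter than `2 * min_segment` (the
#' detection floor: a reversal needs two detectable segments), and tracks
#' already flagged by [project_track()] are classified `"discarded"`.
#'
#' @param track a [motor_track()] with projected coordinates.
#' @param min_segment minimum detectable unidirectional segment, um
#'   (default 0.2).
#' @param pause_eps pause displacement threshold, um (default 0.05).
#' @param pause_window pause detection window in inter-frame intervals
#'   (default 3).
#' @return An object of class `run_decomposition`: `track_id`, `segments`
#'   (signed, um), `run_length` (um), `n_reversals`, `moving_time` and
#'   `paused_time` (s), and `classification` (`"nonreversing"`,
#'   `"reversing"` or `"discarded"`).
#' @export
decompose_runs <- function(track, min_segment = 0.2, pause_eps = 0.05,
                           pause_window = 3L) {
  stopifnot(inherits(track, "motor_track"))
  if (is.null(track$projected)) {
    stop("track has no projected coordinates; run project_track() first",
      call. = FALSE
    )
  }
  p <- track$projected
  t <- track$samples$t
  out <- list(
    track_id = track$track_id, segments = numeric(0), run_length = 0,
    n_reversals = 0L, moving_time = 0, paused_time = 0,
    classification = "discarded"
  )
  class(out) <- "run_decomposition"
  if (track$discarded) return(out)

  ## pause detection on inter-frame intervals
  n <- length(p)
  paused <- rep(FALSE, n - 1L)
  w <- as.integer(pause_window)
  if (w >= 1L && n > w) {
    for (i in seq_len(n - w)) {
      if (abs(p[i + w] - p[i]) < pause_eps) {
        paused[i:(i + w - 1L)] <- TRUE
      }
    }
  }
  dt <- diff(t)
  out$paused_time <- sum(dt[paused])
  out$moving_time <- sum(dt[!paused])

  ## hysteresis segmentation
  segments <- numeric(0)
  pivot <- p[1]
  extreme <- p[1]
  dir <- 0
  for (pi in p[-1]) {
    if (dir == 0) {
      if (abs(pi - pivot) >= min_segment) {
        dir <- sign(pi - pivot)
        extreme <- pi
      }
    } else if (dir > 0) {
      if (pi > extreme) {
        extreme <- pi
      } else if (extreme - pi >= min_segment) {
        segments <- c(segments, extreme - pivot)
        pivot <- extreme
        extreme <- pi
        dir <- -1
      }
    } else {
      if (pi < extreme) {
        extreme <- pi
      } else if (pi - extreme >= min_segment) {
        segments <- c(segments, extreme - pivot)
        pivot <- extreme
        extreme <- pi
        dir <- 1
      }
    }
  }
  if (dir != 0) segments <- c(segments, extreme - pivot)
  if (length(segments) == 0) return(out)

  out$segments <- segments
  out$run_length <- sum(abs(segments))
  out$n_reversals <- length(segments) - 1L
  out$classification <- if (out$n_reversals >= 1L) "reversing" else "nonreversing"
  ## detection floor
  floor_l <- if (out$n_reversals >= 1L) 2 * min_segment else min_segment
  if (out$run_length < floor_l) out$classification <- "discarded"
  out
}

#' @export
print.run_decomposition <- function(x, ...) {
  cat(sprintf(
    "Run decomposition '%s': %s, l = %.2f um, %d reversal(s), moving %.1f s, paused %.1f s\n",
    x$track_id, x$classification, x$run_length, x$n_reversals,
    x$moving_time, x$paused_time
  ))
  if (length(x$segments)) {
    cat("  segments [um]:", paste(sprintf("%+.2f", x$segments), collapse = " "), "\n")
  }
  invisible(x)
}

#' Population statistics of motor run decompositions
#'
#' Summarizes a tracked motor population: the reversing fraction
#' `eta_hat = N_R / N` over non-discarded tracks, the mean run length of each
#' class with the exponential standard error `mean / sqrt(count)`, and the
#' per-class median velocity (run length over moving time, pauses excluded)
#' with its interquartile range.
#'
#' @param decomps a list of [decompose_runs()] results.
#' @return An object of class `population_stats` with elements `N`, `N_R`,
#'   `N_discarded`, `eta_hat`, `lambda_nr_hat`, `lambda_nr_se`,
#'   `lambda_r_hat`, `lambda_r_se`, `velocity_nonrev`, `velocity_rev`
#'   (each a named vector `median`, `iqr`, in um/s; `NA` when a class is
#'   empty).
#' @export
population_stats <- function(decomps) {
  if (inherits(decomps, "run_decomposition")) decomps <- list(decomps)
  stopifnot(all(vapply(decomps, inherits, TRUE, "run_decomposition")))
  cls <- vapply(decomps, function(d) d$classification, "")
  keep <- cls != "discarded"
  if (!any(keep)) stop("no analyzable (non-discarded) tracks", call. = FALSE)
  dk <- decomps[keep]
  cls <- cls[keep]
  l <- vapply(dk, function(d) d$run_length, numeric(1))
  mt <- vapply(dk, function(d) d$moving_time, numeric(1))
  vel <- ifelse(mt > 0, l / mt, NA_real_)
  N <- length(dk)
  N_R <- sum(cls == "reversing")

  class_mean <- function(x) {
    if (length(x) == 0) c(mean = NA_real_, se = NA_real_)
    else c(mean = mean(x), se = mean(x) / sqrt(length(x)))
  }
  class_vel <- function(v) {
    v <- v[is.finite(v)]
    if (length(v) == 0) c(median = NA_real_, iqr = NA_real_)
    else c(median = stats::median(v), iqr = stats::IQR(v))
  }
  m_nr <- class_mean(l[cls == "nonreversing"])
  m_r <- class_mean(l[cls == "reversing"])
  structure(
    list(
      N = N,
      N_R = N_R,
      N_discarded = sum(!keep),
      eta_hat = N_R / N,
      lambda_nr_hat = unname(m_nr["mean"]),
      lambda_nr_se = unname(m_nr["se"]),
      lambda_r_hat = unname(m_r["mean"]),
      lambda_r_se = unname(m_r["se"]),
      velocity_nonrev = class_vel(vel[cls == "nonreversing"]),
      velocity_rev = class_vel(vel[cls == "reversing"])
    ),
    class = "population_stats"
  )
}

#' @export
print.population_stats <- function(x, ...) {
  cat(sprintf(
    "Motor population: N = %d analyzed (%d discarded), N_R = %d reversing (eta = %.3g)\n",
    x$N, x$N_discarded, x$N_R, x$eta_hat
  ))
  cat(sprintf(
    "  run length: nonreversing %.3f +/- %.3f um; reversing %s\n",
    x$lambda_nr_hat, x$lambda_nr_se,
    if (is.na(x$lambda_r_hat)) "n/a"
    else sprintf("%.3f +/- %.3f um", x$lambda_r_hat, x$lambda_r_se)
  ))
  cat(sprintf(
    "  velocity median (IQR): nonreversing %.3f (%.3f), reversing %s um/s\n",
    x$velocity_nonrev["median"], x$velocity_nonrev["iqr"],
    if (is.na(x$velocity_rev["median"])) "n/a"
    else sprintf("%.3f (%.3f)", x$velocity_rev["median"], x$velocity_rev["iqr"])
  ))
  invisible(x)
}
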