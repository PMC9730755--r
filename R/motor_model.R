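#' Two-rate Markov detachment/reversal model for motor clusters
#'
#' A walking motor cluster detaches from the bundle with rate `k_d` and
#' reverses its direction (switching to a microtubule of opposite polarity)
#' with rate `k_r`, while moving at constant speed `v`. The fraction of
#' motors that reverse at least once before detaching is
#' `eta_r = k_r / (k_r + k_d)`, the mean run length of nonreversing motors
#' is `lambda_nr = v / (k_d + k_r)`, and the mean distance per reversal
#' event is `Lambda_r = v / k_r`. The model can be built either from the
#' rates or from the two observables `(eta, lambda_nr)` — no fitting
#' parameters are involved.
#'
#' @param k_d detachment rate, 1/s.
#' @param k_r reversal rate, 1/s (>= 0).
#' @param v walking speed, um/s (default 0.4, within the observed range).
#' @return An object of class `motor_model` with elements `k_d`, `k_r`, `v`,
#'   `eta_r`, `lambda_nr` and `Lambda_r` (`Inf` when `k_r = 0`).
#' @seealso [rates_from_observables()], [drun()], [prun()],
#'   [mean_run_reversing()], [reversal_distance()],
#'   [simulate.motor_model()]
#' @examples
#' m <- rates_from_observables(eta = 0.07, lambda_nr = 0.68, v = 0.4)
#' reversal_distance(m)
#' mean_run_reversing(m)
#' @export
motor_model <- function(k_d, k_r, v = 0.4) {
  k_d <- unname(k_d)
  k_r <- unname(k_r)
  v <- unname(v)
  if (!is.numeric(k_d) || k_d <= 0) stop("`k_d` must be > 0", call. = FALSE)
  if (!is.numeric(k_r) || k_r < 0) stop("`k_r` must be >= 0", call. = FALSE)
  if (!is.numeric(v) || v <= 0) stop("`v` must be > 0", call. = FALSE)
  structure(
    list(
      k_d = k_d,
      k_r = k_r,
      v = v,
      eta_r = k_r / (k_r + k_d),
      lambda_nr = v / (k_d + k_r),
      Lambda_r = if (k_r > 0) v / k_r else Inf
    ),
    class = "motor_model"
  )
}

#' Build the motor model from the observed population parameters
#'
#' Inverts the pair of relations `eta = k_r / (k_r + k_d)` and
#' `lambda_nr = v / (k_d + k_r)` so the two rates follow directly from the
#' observed reversing fraction and nonreversing mean run length.
#'
#' @param eta observed reversing fraction, in (0, 1).
#' @param lambda_nr observed mean run length of nonreversing motors, um.
#' @param v walking speed, um/s; sets the time scale only — all run-length
#'   results depend on `(eta, lambda_nr)` alone.
#' @return A [motor_model()].
#' @export
rates_from_observables <- function(eta, lambda_nr, v = 0.4) {
  eta <- unname(eta)
  lambda_nr <- unname(lambda_nr)
  v <- unname(v)
  if (!is.numeric(eta) || eta <= 0 || eta >= 1) {
    stop("`eta` must be inside (0, 1)", call. = FALSE)
  }
  if (!is.numeric(lambda_nr) || lambda_nr <= 0) {
    stop("`lambda_nr` must be > 0", call. = FALSE)
  }
  k_tot <- v / lambda_nr
  motor_model(k_d = (1 - eta) * k_tot, k_r = eta * k_tot, v = v)
}

#' Observables implied by a motor model
#'
#' @param model a [motor_model()].
#' @return Named vector `eta`, `lambda_nr` (um), `v` (um/s); the exact
#'   inverse of [rates_from_observables()].
#' @export
observables <- function(model) {
  stopifnot(inherits(model, "motor_model"))
  c(eta = model$eta_r, lambda_nr = model$lambda_nr, v = model$v)
}

#' @export
print.motor_model <- function(x, ...) {
  cat("Two-rate Markov detachment/reversal model\n")
  cat(sprintf("  k_d = %.4g 1/s, k_r = %.4g 1/s, v = %.3g um/s\n", x$k_d, x$k_r, x$v))
  cat(sprintf(
    "  eta_r = %.4g, lambda_nr = %.4g um, Lambda_r = %.4g um\n",
    x$eta_r, x$lambda_nr, x$Lambda_r
  ))
  invisible(x)
}

#' @export
summary.motor_model <- function(object, floor_rev = 0.4, ...) {
  out <- list(
    model = object,
    mean_run_reversing = if (object$k_r > 0) mean_run_reversing(object) else NA_real_,
    mean_above_floor = if (object$k_r > 0) {
      mean_excess_above(object, floor_rev)
    } else {
      NA_real_
    },
    floor_rev = floor_rev
  )
  class(out) <- "summary.motor_model"
  out
}

#' @export
print.summary.motor_model <- function(x, ...) {
  print(x$model)
  if (!is.na(x$mean_run_reversing)) {
    cat(sprintf(
      "  reversing population: mean run %.3f um; mean excess above %.2f um floor: %.3f um\n",
      x$mean_run_reversing, x$floor_rev, x$mean_above_floor
    ))
  }
  invisible(x)
}

## internal: per-um rates a = k_d/v, b = k_r/v
.ab <- function(model) c(a = model$k_d / model$v, b = model$k_r / model$v)

check_l <- function(l) {
  if (any(!is.finite(l) & !is.infinite(l)) || any(l < 0)) {
    stop("run length `l` must be >= 0", call. = FALSE)
  }
}

check_reversing <- function(model) {
  if (model$k_r <= 0) {
    stop("reversing-population distribution undefined for k_r = 0", call. = FALSE)
  }
}

#' Run-length density of the Markov motor model
#'
#' Closed-form probability density of the total run length `l` for the two
#' observable populations. Nonreversing motors are exponential with mean
#' `lambda_nr`. For motors with at least one reversal the density is
#' \eqn{p_r(l) = (k_d / (v\,\eta_r))\, e^{-k_d l / v}(1 - e^{-k_r l / v})},
#' which vanishes at `l = 0` and integrates to 1.
#'
#' @param l run lengths, um (>= 0).
#' @param model a [motor_model()].
#' @param population `"nonreversing"` or `"reversing"`.
#' @return Density values, per um.
#' @export
drun <- function(l, model, population = c("nonreversing", "reversing")) {
  stopifnot(inherits(model, "motor_model"))
  population <- match.arg(population)
  check_l(l)
  ab <- .ab(model)
  a <- ab[["a"]]
  b <- ab[["b"]]
  if (population == "nonreversing") {
    (a + b) * exp(-(a + b) * l)
  } else {
    check_reversing(model)
    (a / model$eta_r) * exp(-a * l) * (-expm1(-b * l))
  }
}

#' Run-length cumulative distribution of the Markov motor model
#'
#' Closed-form CDF of the run length for either population, optionally
#' stretched to account for the minimum detectable distance (see
#' [stretched_cdf()]).
#'
#' @inheritParams drun
#' @param floor minimum detectable run length, um: the theoretical curve is
#'   shifted so it starts at `floor` (support shift `F(l - floor)`);
#'   default 0 (no stretch).
#' @return Probabilities in `[0, 1]`.
#' @export
prun <- function(l, model, population = c("nonreversing", "reversing"),
                 floor = 0) {
  stopifnot(inherits(model, "motor_model"))
  population <- match.arg(population)
  check_l(l)
  if (floor < 0) stop("`floor` must be >= 0", call. = FALSE)
  ls <- pmax(l - floor, 0)
  ab <- .ab(model)
  a <- ab[["a"]]
  b <- ab[["b"]]
  if (population == "nonreversing") {
    -expm1(-(a + b) * ls)
  } else {
    check_reversing(model)
    (-expm1(-a * ls) - (a / (a + b)) * (-expm1(-(a + b) * ls))) / model$eta_r
  }
}

#' Stretched theoretical CDF accounting for the detection floor
#'
#' Experimental run lengths below the minimum detectable distance (0.2 um
#' without reversal — one detectable segment — and 0.4 um with reversal —
#' two segments) are absent from the data. For overlaying the theory on
#' experimental cumulative distributions, the theoretical CDF is stretched
#' by a support shift so it starts at the population's floor:
#' `F~(l) = F(l - l_min)` for `l >= l_min`, else 0.
#'
#' @param model a [motor_model()].
#' @param population `"nonreversing"` or `"reversing"`.
#' @param floor the population's minimum detectable distance in um; defaults
#'   to 0.2 for nonreversing and 0.4 for reversing motors.
#' @return A function of `l` evaluating the stretched CDF.
#' @export
stretched_cdf <- function(model, population = c("nonreversing", "reversing"),
                          floor = NULL) {
  population <- match.arg(population)
  if (is.null(floor)) floor <- if (population == "nonreversing") 0.2 else 0.4
  force(model)
  function(l) prun(l, model, population = population, floor = floor)
}

#' Mean run length of the reversing population
#'
#' Closed-form mean of the reversing-population run-length density:
#' \eqn{(1/\eta_r)(v/k_d - v k_d/(k_d + k_r)^2)}. It always exceeds
#' `lambda_nr`: motors with longer runs are more likely to have reversed
#' (a selection effect, not a mechanistic difference).
#'
#' @param model a [motor_model()] with `k_r > 0`.
#' @return Mean run length, um.
#' @export
mean_run_reversing <- function(model) {
  stopifnot(inherits(model, "motor_model"))
  check_reversing(model)
  (1 / model$eta_r) * (model$v / model$k_d - model$v * model$k_d / (model$k_d + model$k_r)^2)
}

#' Mean run of reversing motors beyond the detection floor
#'
#' The mean residual run length `E[l - threshold | l > threshold]` of the
#' reversing population: the expected length of the run sections above the
#' minimum detectable distance. Computed in closed form from the survival
#' function \eqn{S(l) = (1/\eta_r)(e^{-k_d l/v} - (k_d/(k_d+k_r)) e^{-(k_d+k_r) l/v})}
#' as \eqn{\int_\tau^\infty S(l)\,dl / S(\tau)}. The conditional mean
#' `E[l | l > threshold]` is the same quantity shifted by the threshold; see
#' [conditional_mean_above()].
#'
#' @param model a [motor_model()] with `k_r > 0`.
#' @param threshold detection floor, um (default 0.4, two minimum segments).
#' @return Mean excess run length, um.
#' @export
mean_excess_above <- function(model, threshold = 0.4) {
  stopifnot(inherits(model, "motor_model"))
  check_reversing(model)
  if (threshold < 0) stop("`threshold` must be >= 0", call. = FALSE)
  ab <- .ab(model)
  a <- ab[["a"]]
  b <- ab[["b"]]
  S <- (exp(-a * threshold) - a / (a + b) * exp(-(a + b) * threshold)) / model$eta_r
  if (S < 1e-300) {
    stop("survival probability underflows at this threshold", call. = FALSE)
  }
  intS <- (exp(-a * threshold) / a - a / (a + b)^2 * exp(-(a + b) * threshold)) / model$eta_r
  intS / S
}

#' Conditional mean run length above a threshold
#'
#' `E[l | l > threshold]` for the reversing population, i.e.
#' `threshold + mean_excess_above(model, threshold)`.
#'
#' @inheritParams mean_excess_above
#' @return Conditional mean run length, um.
#' @export
conditional_mean_above <- function(model, threshold = 0.4) {
  threshold + mean_excess_above(model, threshold)
}

#' Reversal distance
#'
#' The mean distance traveled per reversal event regardless of detachment,
#' `Lambda_r = v / k_r = lambda_nr / eta_r`. Its inverse is the likelihood
#' of a direction reversal per unit length traveled.
#'
#' @param model a [motor_model()].
#' @return Distance in um (`Inf` when `k_r = 0`).
#' @export
reversal_distance <- function(model) {
  stopifnot(inherits(model, "motor_model"))
  model$Lambda_r
}
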