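test_that("track construction validates timestamps", {
  expect_error(motor_track(c(0, 0), c(0, 1), c(0, 0)), "increasing")
  expect_error(motor_track(0, 0, 0), "at least 2")
  tr <- motor_track(0:3, 0:3 * 0.4, rep(0, 4))
  expect_false(tr$discarded)
})

test_that("projection onto a straight spline returns the axial coordinate", {
  straight <- clothoid_spline(c(0, 0), 20)
  x <- c(0.5, 1.3, 2.9, 4.4)
  on_axis <- project_track(motor_track(1:4, x, rep(0, 4)), straight)
  expect_equal(on_axis$projected, x, tolerance = 1e-9)
  # a 0.3 um lateral offset projects to the same coordinates
  off_axis <- project_track(motor_track(1:4, x, rep(0.3, 4)), straight)
  expect_equal(off_axis$projected, x, tolerance = 1e-9)
  expect_false(off_axis$discarded)
})

test_that("projection on a circular spline recovers the analytic arc length", {
  R <- 20
  qc <- clothoid_spline(rep(1 / R, 2), R * pi / 2) # quarter circle from origin
  s_true <- c(2, 7, 15, 24)
  xy <- predict(qc, s_true)
  # displace radially by 0.2 um (outward from the circle center at (0, R))
  cen <- c(0, R)
  out <- t(apply(xy, 1, function(p) cen + (p - cen) * (R + 0.2) / R))
  tr <- project_track(motor_track(1:4, out[, 1], out[, 2], "arc"), qc)
  expect_lt(max(abs(tr$projected - s_true)), 1e-3)
})

test_that("projection flags far or jumping tracks as discarded", {
  straight <- clothoid_spline(c(0, 0), 20)
  far <- project_track(motor_track(1:3, c(1, 2, 3), c(0, 5, 0)), straight)
  expect_true(far$discarded)
  jump <- project_track(motor_track(1:3, c(1, 9, 10), c(0, 0, 0)), straight)
  expect_true(jump$discarded)
  expect_equal(
    decompose_runs(jump)$classification, "discarded"
  )
})

test_that("run decomposition reduces tracks to unidirectional segments", {
  # monotone run
  mono <- decompose_runs(axis_track(seq(0, 1.5, by = 0.3)))
  expect_equal(mono$segments, 1.5)
  expect_equal(mono$run_length, 1.5)
  expect_equal(mono$classification, "nonreversing")
  expect_equal(mono$n_reversals, 0L)

  # one reversal: 0 -> 0.9 -> 0.3
  rev1 <- decompose_runs(axis_track(c(0, 0.45, 0.9, 0.6, 0.3)))
  expect_equal(rev1$segments, c(0.9, -0.6))
  expect_equal(rev1$run_length, 1.5)
  expect_equal(rev1$n_reversals, 1L)
  expect_equal(rev1$classification, "reversing")

  # sub-threshold dip merges: 0 -> 0.9 -> 0.85 -> 1.4
  dip <- decompose_runs(axis_track(c(0, 0.5, 0.9, 0.85, 1.1, 1.4)))
  expect_equal(dip$segments, 1.4)
  expect_equal(dip$classification, "nonreversing")

  # never moves a detectable segment
  still <- decompose_runs(axis_track(c(0, 0.05, 0.1, 0.05)))
  expect_equal(still$classification, "discarded")
  expect_equal(still$run_length, 0)

  expect_error(decompose_runs(motor_track(1:3, 1:3, rep(0, 3))), "projected")
})

test_that("run length survives time reversal and sub-threshold wiggles", {
  p <- c(0, 0.4, 0.9, 0.6, 0.2, 0.5, 1.0)
  fwd <- decompose_runs(axis_track(p))
  bwd <- decompose_runs(axis_track(rev(p)))
  expect_equal(fwd$run_length, bwd$run_length)
  expect_equal(fwd$n_reversals %% 2L, bwd$n_reversals %% 2L)

  set.seed(30)
  wig <- p + c(0, runif(5, -0.04, 0.04), 0)
  expect_equal(decompose_runs(axis_track(wig))$segments, fwd$segments,
    tolerance = 0.1
  )
  expect_equal(decompose_runs(axis_track(wig))$n_reversals, fwd$n_reversals)
})

test_that("pauses accumulate into paused time and drop out of velocities", {
  # walk, pause 4 frames, walk
  p <- c(seq(0, 0.8, by = 0.2), rep(0.81, 4), seq(1.0, 1.8, by = 0.2))
  d <- decompose_runs(axis_track(p), pause_eps = 0.05, pause_window = 3)
  expect_gt(d$paused_time, 2)
  expect_equal(d$paused_time + d$moving_time, length(p) - 1)
  expect_equal(d$classification, "nonreversing")
  st <- population_stats(list(d))
  expect_gt(st$velocity_nonrev[["median"]], d$run_length / (length(p) - 1))
})

test_that("population statistics reproduce the tracked-population summary", {
  # 1048 nonreversing + 80 reversing motors as in the tracked population
  nonrev <- decompose_runs(axis_track(c(0, 0.5, 1.0)))
  rev <- decompose_runs(axis_track(c(0, 0.6, 0.1)))
  decomps <- c(
    replicate(1048, nonrev, simplify = FALSE),
    replicate(80, rev, simplify = FALSE)
  )
  st <- population_stats(decomps)
  expect_equal(st$N, 1128)
  expect_equal(st$N_R, 80)
  expect_equal(st$eta_hat, 80 / 1128)
  expect_equal(round(100 * st$eta_hat, 2), 7.09)

  # identical tracks: l = 1 um over 2 s of walking
  one <- decompose_runs(axis_track(c(0, 0.5, 1.0)))
  stats1 <- population_stats(replicate(10, one, simplify = FALSE))
  expect_equal(stats1$lambda_nr_hat, 1)
  expect_equal(stats1$velocity_nonrev[["median"]], 0.5)
  expect_equal(stats1$lambda_nr_se, 1 / sqrt(10))
  expect_true(is.na(stats1$lambda_r_hat))
})

test_that("simulated populations reproduce the generator's reversing fraction", {
  m <- rates_from_observables(0.07, 0.68, 0.4)
  sim <- simulate_motor_population(m, 4000, noise_sigma = 0.02, seed = 31)
  decomps <- lapply(sim$tracks, decompose_runs)
  st <- population_stats(decomps)
  # the measured population carries known detection biases, so the
  # estimates sit in bands around the generator values rather than on
  # them: at 1 Hz sampling many reversals have no sample in the second
  # segment (mean residual lifetime 1.8 s) or an excursion below the
  # 0.2 um hysteresis, roughly halving eta_hat; surviving nonreversing
  # runs obey E[l | l > floor] = 0.2 + 0.68 = 0.88 um by memorylessness
  # (shifted down by sampling quantization, up by missed reversers).
  expect_gt(st$eta_hat, 0.02)
  expect_lt(st$eta_hat, 0.10)
  expect_gt(st$lambda_nr_hat, 0.6)
  expect_lt(st$lambda_nr_hat, 0.95)
})
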