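test_that("tangent correlation is exact for straight and circular shapes", {
  straight <- clothoid_spline(c(0, 0), 50)
  ct <- tangent_correlation(list(straight), ds = 1)
  expect_equal(ct$value, rep(1, nrow(ct)))

  arc <- clothoid_spline(rep(0.05, 7), 60) # radius 20
  ct <- tangent_correlation(list(arc), ds = 0.5)
  expect_lt(max(abs(ct$value - cos(ct$separation / 20))), 1e-6)
  expect_true(all(abs(ct$value) <= 1 + 1e-12))
  expect_error(tangent_correlation(list()), "empty")
})

test_that("tangent correlation of thermal frames follows the planar WLC decay", {
  P <- 20 # persistence length, um
  EI <- P * bundlekin:::.kB * 298
  th <- simulate_thermal_filament(
    EI = EI, L = 100, n_frames = 100, n_modes = 200,
    n_points = 150, noise_sigma = 0, seed = 5
  )
  ct <- tangent_correlation(th$contours, ds = 1, s_max = 30)
  sel <- which(ct$separation %in% c(10, 20, 30))
  # per-frame scatter gives the standard error of the frame average
  per_frame <- vapply(
    th$contours,
    function(pc) tangent_correlation(list(pc), ds = 1, s_max = 30)$value[sel],
    numeric(length(sel))
  )
  se <- apply(per_frame, 1, sd) / sqrt(length(th$contours))
  want <- exp(-ct$separation[sel] / (2 * P))
  expect_true(all(abs(ct$value[sel] - want) < 3 * se))
})

test_that("curvature correlation matches analytic autocorrelations", {
  # constant curvature: C_KK identically 1
  arc <- clothoid_spline(rep(0.05, 7), 60)
  ck <- curvature_correlation(list(arc), ds = 0.5)
  expect_equal(ck$value, rep(1, nrow(ck)))

  # sinusoidal curvature: autocorrelation is a cosine
  lambda <- 10
  L <- 100
  node_s <- seq(0, L, length.out = 201)
  sin_sp <- clothoid_spline(0.05 * sin(2 * pi * node_s / lambda), L)
  ck <- curvature_correlation(list(sin_sp), ds = 0.25, s_max = 20)
  expect_lt(max(abs(ck$value - cos(2 * pi * ck$separation / lambda))), 0.05)

  # white-noise node curvatures decorrelate within one inter-node spacing
  set.seed(11)
  spacing <- 100 / 20
  wn <- lapply(1:50, function(i) clothoid_spline(rnorm(21), 100))
  ckw <- curvature_correlation(wn, ds = spacing / 4, s_max = 40)
  expect_lt(ckw$value[ckw$separation == spacing], 0.5)

  expect_error(
    curvature_correlation(list(clothoid_spline(c(0, 0), 10))),
    "degenerate"
  )
})

test_that("correlation functions are invariant under rigid motions", {
  set.seed(12)
  K <- rnorm(7, 0, 0.04)
  a <- clothoid_spline(K, 80)
  b <- clothoid_spline(K, 80, base_point = c(13, -4), base_angle = 2.1)
  for (f in list(tangent_correlation, curvature_correlation)) {
    expect_equal(f(list(a), ds = 1)$value, f(list(b), ds = 1)$value)
  }
})

test_that("half-decay length interpolates the first 0.5 crossing", {
  s <- seq(0, 60, by = 0.05)
  expect_equal(half_decay_length(make_corr(s, cos(s / 20))), 20 * pi / 3,
    tolerance = 1e-4
  )
  expect_equal(half_decay_length(make_corr(s, exp(-s / 10))), 10 * log(2),
    tolerance = 1e-4
  )
  expect_true(is.na(half_decay_length(make_corr(s, rep(1, length(s))))))
})

test_that("half-decay length is monotone in the correlation curve", {
  set.seed(13)
  s <- seq(0, 30, by = 0.5)
  for (i in 1:20) {
    lam <- runif(1, 3, 15)
    lo <- exp(-s / lam)
    hi <- pmin(1, lo + runif(length(s), 0, 0.2))
    hi[1] <- 1
    expect_gte(half_decay_length(make_corr(s, hi)), half_decay_length(make_corr(s, lo)))
  }
})

test_that("thermal rigidity estimation recovers the generating EI", {
  th <- simulate_thermal_filament(EI = 4, L = 17, n_frames = 1000, seed = 3)
  est <- estimate_EI_thermal(th$contours)
  expect_lt(abs(est$EI - 4) / 4, 0.15)
  expect_equal(est$n_frames, 1000)
  expect_gt(est$EI, 0)

  # inverse proportionality: doubling all mode variances (halving EI in the
  # generator under the same random stream) halves the estimate
  lo <- simulate_thermal_filament(EI = 2, L = 17, n_frames = 600, seed = 8)
  hi <- simulate_thermal_filament(EI = 4, L = 17, n_frames = 600, seed = 8)
  r <- estimate_EI_thermal(hi$contours)$EI / estimate_EI_thermal(lo$contours)$EI
  expect_lt(abs(r - 2) / 2, 0.1)
})

test_that("thermal rigidity bias shrinks with the number of frames", {
  bias <- vapply(c(200, 1000, 5000), function(nf) {
    th <- simulate_thermal_filament(EI = 7, L = 17, n_frames = nf, seed = 21)
    abs(estimate_EI_thermal(th$contours)$EI - 7) / 7
  }, numeric(1))
  expect_lt(bias[3], 0.10)
  expect_lt(bias[3], bias[1] + 0.05)
})

test_that("rigidity estimation rejects unusable input", {
  th <- simulate_thermal_filament(EI = 4, n_frames = 60, seed = 2)
  expect_error(estimate_EI_thermal(th$contours[1:30]), "at least 50")
  stretched <- th$contours
  stretched[[1]]$points <- stretched[[1]]$points * 1.2
  stretched[[1]]$arclength <- stretched[[1]]$arclength * 1.2
  expect_error(estimate_EI_thermal(stretched), "varies")
})

test_that("across-bundle pooling averages per-bundle correlation curves", {
  a <- make_corr(seq(0, 10, 0.5), exp(-seq(0, 10, 0.5) / 5))
  b <- make_corr(seq(0, 10, 0.5), exp(-seq(0, 10, 0.5) / 10))
  pooled <- pool_correlations(list(a, b))
  expect_equal(pooled$value, (a$value + b$value) / 2)
  expect_error(pool_correlations(list(a, make_corr(seq(0, 10, 0.5), a$value, kind = "curvature"))), "kind")
})
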