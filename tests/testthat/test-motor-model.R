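test_that("rates follow from the two observables without fitting", {
  m <- rates_from_observables(eta = 0.07, lambda_nr = 0.68, v = 0.4)
  expect_equal(m$k_d + m$k_r, 0.4 / 0.68)
  expect_equal(m$k_r, 0.07 * 0.4 / 0.68)
  expect_equal(m$k_d, 0.5470588, tolerance = 1e-6)
  expect_equal(m$k_r, 0.0411765, tolerance = 1e-5)
  expect_equal(m$eta_r, 0.07)
  expect_equal(m$lambda_nr, 0.68)

  # inverse pair: rates -> observables -> rates
  obs <- observables(m)
  m2 <- rates_from_observables(obs["eta"], obs["lambda_nr"], obs["v"])
  expect_equal(m2$k_d, m$k_d)
  expect_equal(m2$k_r, m$k_r)

  # eta -> 0: pure exponential detachment
  m0 <- rates_from_observables(1e-9, 0.68, 0.4)
  expect_lt(m0$k_r, 1e-8)

  expect_error(rates_from_observables(0, 0.68), "eta")
  expect_error(rates_from_observables(1.2, 0.68), "eta")
  expect_error(rates_from_observables(0.07, -1), "lambda_nr")
})

test_that("nonreversing run-length distribution is exponential with mean lambda_nr", {
  m <- rates_from_observables(0.07, 0.68, 0.4)
  expect_equal(drun(0, m, "nonreversing"), 1 / 0.68)
  expect_equal(
    integrate(function(l) drun(l, m, "nonreversing"), 0, Inf,
      rel.tol = 1e-10
    )$value, 1,
    tolerance = 1e-8
  )
  expect_equal(
    integrate(function(l) l * drun(l, m, "nonreversing"), 0, Inf)$value,
    0.68,
    tolerance = 1e-6
  )
  expect_equal(prun(0, m, "nonreversing"), 0)
  expect_equal(prun(0.68, m, "nonreversing"), 1 - exp(-1))
  l <- seq(0, 5, length.out = 100)
  quad <- vapply(l, function(u) {
    integrate(function(z) drun(z, m, "nonreversing"), 0, u)$value
  }, numeric(1))
  expect_lt(max(abs(prun(l, m, "nonreversing") - quad)), 1e-8)
  expect_error(drun(-1, m), ">= 0")
})

test_that("reversing run-length distribution integrates and averages correctly", {
  m <- rates_from_observables(0.07, 0.68, 0.4)
  expect_equal(drun(0, m, "reversing"), 0)
  expect_equal(
    integrate(function(l) drun(l, m, "reversing"), 0, Inf)$value, 1,
    tolerance = 1e-8
  )
  # frozen from quadrature of the closed-form density; prints as 1.4
  expect_equal(mean_run_reversing(m), 1.411183, tolerance = 1e-6)
  expect_equal(
    integrate(function(l) l * drun(l, m, "reversing"), 0, Inf)$value,
    mean_run_reversing(m),
    tolerance = 1e-7
  )
  l <- seq(0, 6, length.out = 100)
  quad <- vapply(l, function(u) {
    integrate(function(z) drun(z, m, "reversing"), 0, u)$value
  }, numeric(1))
  expect_lt(max(abs(prun(l, m, "reversing") - quad)), 1e-8)
  expect_true(all(diff(prun(l, m, "reversing")) >= 0))
  expect_equal(prun(Inf, m, "reversing"), 1)

  m0 <- motor_model(k_d = 1, k_r = 0)
  expect_error(drun(1, m0, "reversing"), "k_r")
  expect_error(mean_run_reversing(m0), "k_r")
})

test_that("k_r -> 0 limit of the reversing mean is two nonreversing stretches", {
  for (eps in c(1e-4, 1e-6)) {
    m <- rates_from_observables(eps, 0.68, 0.4)
    expect_equal(mean_run_reversing(m), 2 * 0.68, tolerance = 1e-3)
  }
  # dimensional scaling in v
  m1 <- rates_from_observables(0.07, 0.68, 0.4)
  m2 <- rates_from_observables(0.07, 0.68 * 3, 1.2) # same rates, 3x speed
  expect_equal(mean_run_reversing(m2), 3 * mean_run_reversing(m1))
})

test_that("mean excess above the detection floor matches quadrature", {
  m <- rates_from_observables(0.07, 0.68, 0.4)
  expect_equal(mean_excess_above(m, 0), mean_run_reversing(m))
  # frozen from quadrature; prints as 1.15
  expect_equal(mean_excess_above(m, 0.4), 1.156046, tolerance = 1e-6)
  expect_equal(conditional_mean_above(m, 0.4), 0.4 + 1.156046, tolerance = 1e-6)
  for (tau in c(0.2, 0.4, 1, 3)) {
    S <- 1 - prun(tau, m, "reversing")
    quad <- integrate(function(l) (l - tau) * drun(l, m, "reversing"), tau, Inf)$value / S
    expect_equal(mean_excess_above(m, tau), quad, tolerance = 1e-8)
  }
  expect_error(mean_excess_above(m, 1e6), "underflow")
})

test_that("reversal distance converts the reversal rate into a length", {
  m <- rates_from_observables(0.07, 0.68, 0.4)
  expect_equal(reversal_distance(m), 0.68 / 0.07)
  expect_equal(round(reversal_distance(m), 1), 9.7)
  expect_equal(reversal_distance(rates_from_observables(0.5, 1)), 2)
  # independent of the speed scale at fixed observables
  expect_equal(
    reversal_distance(rates_from_observables(0.07, 0.68, v = 1.7)),
    reversal_distance(m)
  )
  expect_equal(reversal_distance(motor_model(k_d = 1, k_r = 0)), Inf)
})

test_that("stretched CDFs shift the support to the detection floor", {
  m <- rates_from_observables(0.07, 0.68, 0.4)
  Fr <- stretched_cdf(m, "reversing") # floor 0.4
  expect_equal(Fr(0.4), 0)
  expect_equal(Fr(0.2), 0)
  expect_equal(Fr(Inf), 1)
  expect_equal(Fr(1.4), prun(1.0, m, "reversing"))
  F0 <- stretched_cdf(m, "nonreversing", floor = 0)
  l <- seq(0, 4, by = 0.25)
  expect_equal(F0(l), prun(l, m, "nonreversing"))
})

test_that("population density is the eta-weighted mixture of the two classes", {
  m <- rates_from_observables(0.07, 0.68, 0.4)
  mix <- function(l) {
    (1 - m$eta_r) * drun(l, m, "nonreversing") + m$eta_r * drun(l, m, "reversing")
  }
  expect_equal(integrate(mix, 0, Inf)$value, 1, tolerance = 1e-8)
  # the mixture collapses to the unconditional exponential Exp(k_d / v)
  l <- seq(0, 5, by = 0.1)
  expect_equal(mix(l), (m$k_d / m$v) * exp(-m$k_d * l / m$v), tolerance = 1e-12)

  # two-sample agreement with the simulated population (Kolmogorov distance)
  sim <- simulate_motor_population(m, 1e5, seed = 41)
  l_sim <- sort(sim$truth$run_length)
  Fmix <- 1 - exp(-m$k_d * l_sim / m$v)
  ks <- max(abs(Fmix - (seq_along(l_sim) - 0.5) / length(l_sim)))
  expect_lt(ks, 3 / sqrt(length(l_sim)))
})

test_that("reversing motors have longer mean runs (selection bias)", {
  set.seed(43)
  for (i in 1:20) {
    m <- motor_model(k_d = runif(1, 0.1, 2), k_r = runif(1, 0.01, 1), v = runif(1, 0.1, 1))
    expect_gt(mean_run_reversing(m), m$lambda_nr)
  }
})

test_that("rates are recovered from simulated population statistics", {
  m <- rates_from_observables(0.07, 0.68, 0.4)
  n <- 1e5
  sim <- simulate_motor_population(m, n, seed = 44)
  eta_hat <- mean(sim$truth$reversing)
  lnr_hat <- mean(sim$truth$run_length[!sim$truth$reversing])
  m_hat <- rates_from_observables(eta_hat, lnr_hat, 0.4)
  se_eta <- sqrt(0.07 * 0.93 / n)
  expect_lt(abs(eta_hat - 0.07), 3 * se_eta)
  se_lnr <- 0.68 / sqrt(sum(!sim$truth$reversing))
  expect_lt(abs(lnr_hat - 0.68), 3 * se_lnr)
  # delta-method error propagation keeps the rates within a few percent
  expect_lt(abs(m_hat$k_d - m$k_d) / m$k_d, 0.03)
  expect_lt(abs(m_hat$k_r - m$k_r) / m$k_r, 0.15)
})
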