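test_that("cooling steps follow the geometric and quench laws", {
  expect_equal(geometric_next(100, 0.85), 85)
  expect_equal(geometric_next(geometric_next(1, 0.95), 0.95), 0.9025)
  expect_equal(quench_next(100, 0.85, 0.9), 8.5)
  # tau -> 0 collapses the quench onto the geometric law
  expect_identical(quench_next(50, 0.85, 0), geometric_next(50, 0.85))
  expect_error(geometric_next(10, 0.5), "0.7")
  expect_error(geometric_next(10, 1.0), "0.7")
  expect_error(quench_next(10, 0.85, 1.0), "tau")
})

test_that("quenching cools at least as fast as geometric cooling", {
  set.seed(31)
  T <- runif(1e4, 1e-6, 1e3)
  alpha <- runif(1e4, 0.7, 1 - 1e-9)
  tau <- runif(1e4, 0, 1 - 1e-9)
  for (i in sample.int(1e4, 200)) {
    expect_lte(quench_next(T[i], alpha[i], tau[i]),
               geometric_next(T[i], alpha[i]))
  }
  q <- alpha * (1 - tau) * T
  expect_true(all(q <= alpha * T))
  expect_true(all(q < T))
})

test_that("tau squaring converges in exactly seven updates from 0.90", {
  tau <- 0.90
  k <- 0L
  while (tau >= 0.0009) {
    tau <- update_tau(tau)
    k <- k + 1L
  }
  expect_identical(k, 7L)
  expect_equal(update_tau(0.9), 0.81)
  expect_error(update_tau(1), "tau")
  expect_error(update_tau(0), "tau")
})

test_that("Boltzmann acceptance and its temperature inversions agree", {
  expect_equal(acceptance_probability(0, 5), 1)
  expect_equal(acceptance_probability(3, 3), exp(-1))
  expect_error(acceptance_probability(1, 0), "T")
  expect_equal(initial_temperature(1, exp(-1)), 1)
  expect_equal(initial_temperature(2, 0.9), -2 / log(0.9))
  expect_equal(final_temperature(0.01, exp(-1)), 0.01)
  # inverse pair to high precision, across magnitudes
  set.seed(17)
  for (i in 1:50) {
    dZ <- 10^runif(1, -4, 3)
    P <- runif(1, 0.01, 0.99)
    expect_equal(acceptance_probability(dZ, initial_temperature(dZ, P)), P,
                 tolerance = 1e-12)
    expect_equal(acceptance_probability(dZ, final_temperature(dZ, P)), P,
                 tolerance = 1e-12)
  }
  # monotone: larger T accepts more
  ps <- vapply(c(1, 10, 100, 1e6), function(T) acceptance_probability(1, T),
               numeric(1))
  expect_true(all(diff(ps) > 0))
  expect_lt(final_temperature(0.01, 0.5), initial_temperature(1, 0.5))
})

test_that("schedule parameter invariants are enforced", {
  p <- schedule_params(T0 = 100, Tf = 1e-4)
  expect_s3_class(p, "schedule_params")
  expect_true(p$Tf < p$T_fa && p$T_fa <= p$T_threshold &&
                p$T_threshold < p$T0)
  expect_error(schedule_params(T0 = 1, Tf = 2), "Tf")
  expect_error(schedule_params(T0 = 100, Tf = 1e-4, alpha_quenching = 0.5),
               "0.7")
  expect_error(schedule_params(T0 = 100, Tf = 1e-4, tau0 = 1.2), "tau")
})

test_that("deterioration probing recovers the gap of a two-level landscape", {
  g <- 2.5
  two_level <- function(s) if (s[1] > 0) g else 0
  set.seed(41)
  d <- estimate_deteriorations(two_level, m = 1, n_samples = 500)
  expect_equal(d$dZmax, g)
  expect_equal(d$dZmin, g)
  expect_error(estimate_deteriorations(function(s) 1, m = 3,
                                       n_samples = 100),
               "n_samples")
  set.seed(42)
  dq <- estimate_deteriorations(function(s) sum(s^2), m = 1,
                                n_samples = 1e3)
  expect_true(dq$dZmax >= dq$dZmin && dq$dZmin > 0)
})

test_that("analytic tuning hits the target acceptance probabilities", {
  land <- small_landscape()
  set.seed(51)
  energy <- counted_energy(land$energy)
  p <- tune_schedule(energy, land$m, p_hot = 0.95, p_cold = 0.01)
  expect_gt(evals_of(energy), 0L)
  # T0/Tf invert the Boltzmann relation for the probed deteriorations
  set.seed(51)
  d <- estimate_deteriorations(land$energy, land$m)
  expect_equal(acceptance_probability(d$dZmax, p$T0), 0.95,
               tolerance = 1e-12)
  expect_equal(acceptance_probability(d$dZmin, p$Tf), 0.01,
               tolerance = 1e-12)
})
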