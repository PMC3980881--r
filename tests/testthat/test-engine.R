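# Fixed-deterioration landscape: any move away from the all-zero anchor
# costs exactly dZ, so acceptance statistics can be read off directly.
fixed_deterioration_energy <- function(dZ) {
  function(s) if (all(s == 0)) 0 else dZ
}

test_that("acceptance rate matches the Boltzmann probability", {
  dZ <- 1.7
  energy <- fixed_deterioration_energy(dZ)
  anchor <- solution_state(rep(0, 3), energy)

  rate_at <- function(T, n) {
    set.seed(71)
    acc <- 0L
    for (i in seq_len(n)) {
      st <- metropolis_sweep(anchor, T, 1L, energy)
      acc <- acc + st$n_accept
    }
    acc / n
  }
  # hot limit: everything is accepted
  expect_equal(rate_at(1e12, 2e3), 1)
  # cold limit: nothing is
  expect_equal(rate_at(1e-12, 2e3), 0)
  # calibrated: T chosen so P(accept) = 0.9, binomial 3-sigma band
  n <- 1e4
  r <- rate_at(initial_temperature(dZ, 0.9), n)
  expect_lt(abs(r - 0.9), 3 * sqrt(0.9 * 0.1 / n))
})

test_that("ties in energy are accepted and minima tracked", {
  set.seed(72)
  st <- solution_state(rep(0, 4), function(s) 0)
  st <- metropolis_sweep(st, 1e-9, 200, function(s) 0)
  expect_identical(st$n_accept, 200L)  # dE = 0 always accepted
  land <- small_landscape()
  st2 <- solution_state(random_conformation(land$m), land$energy)
  st3 <- metropolis_sweep(st2, 5, 500, land$energy)
  expect_lte(st3$E_min, st2$E_min)
  expect_lte(st3$E_min, st3$E_i)
})

test_that("chaotic local search is greedy and restores nothing it should not", {
  # empty search returns its input untouched
  set.seed(73)
  ch <- chaos_state("M1")
  sigma <- random_conformation(8)
  out0 <- chaotic_local_search(sigma, 0, ch, function(s) sum(s^2))
  expect_identical(out0$sigma, sigma)

  # 1-D convex well: long greedy chain must strictly improve
  well <- function(s) (s[1] - 10)^2
  set.seed(74)
  out <- chaotic_local_search(100, 200, ch, well)
  expect_lt(out$energy, well(100))
  expect_gt(out$n_improved, 0L)

  # the running best equals the minimum of everything evaluated:
  # greedy acceptance can never lose an improvement
  seen <- new.env(); seen$e <- numeric(0)
  land <- small_landscape()
  recorder <- function(s) {
    v <- land$energy(s)
    seen$e <- c(seen$e, v)
    v
  }
  set.seed(75)
  start <- random_conformation(land$m)
  out2 <- chaotic_local_search(start, 50, ch, recorder)
  expect_equal(out2$energy, min(land$energy(start), seen$e))
})

test_that("the multiquenching phase fires CLS every seven cycles", {
  land <- small_landscape()
  set.seed(81)
  energy <- counted_energy(land$energy)
  params <- schedule_params(T0 = 50, Tf = 1e-9, T_threshold = 1e-9 * 50,
                            T_fa = 1e-8)
  mqp <- run_mqp(energy, land$m, params, chaos_state("M1"), L = 20)
  expect_gte(length(mqp$cls_cycles), 2L)
  expect_true(all(diff(mqp$cls_cycles) == 7))
  expect_identical(mqp$cls_cycles[1], 7L)
  expect_lte(mqp$T, params$T_threshold)
  # quenching cools at least as fast as the geometric law, so it can
  # never need more cycles than the geometric recursion
  expect_lte(nrow(mqp$trace),
             ceiling(log(params$T_threshold / params$T0) /
                       log(params$alpha_quenching)))
  expect_lte(mqp$state$E_min, mqp$trace$E_i[1])
})

test_that("annealing phase cycle counts and equilibrium stopping behave", {
  params <- schedule_params(T0 = 10, Tf = 0.01, T_threshold = 1,
                            T_fa = 0.02)
  # constant landscape: DEP triggers as soon as the window fills
  set.seed(82)
  flat <- function(s) 1
  st <- solution_state(rep(0, 3), flat)
  ap <- run_ap(st, flat, params, L = 5, T_start = params$T_fa,
               dep_window = 12, dep_epsilon = 1e-8)
  expect_identical(ap$dep_cycle, 12L)
  # without DEP the cycle count is the geometric recursion length
  set.seed(83)
  land <- small_landscape()
  st2 <- solution_state(random_conformation(land$m), land$energy)
  ap2 <- run_ap(st2, land$energy, params, L = 10, dep_window = 0)
  expect_identical(nrow(ap2$trace),
                   as.integer(ceiling(log(params$Tf / params$T_threshold) /
                                        log(params$alpha_annealing))))
  expect_true(all(diff(ap2$trace$T) < 0))
  expect_true(all(diff(ap2$trace$E_min) <= 0))
})

test_that("full runs are deterministic given (config, seed)", {
  land <- small_landscape()
  r1 <- run_cmqa(land, seed = 7)
  r2 <- run_cmqa(land, seed = 7)
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$best, r2$best)
  r3 <- run_cmqa(land, seed = 8)
  expect_false(identical(r3$trace$E_i, r1$trace$E_i))
})

test_that("the running minimum never increases in any variant", {
  land <- small_landscape()
  for (run in list(run_cmqa(land, seed = 3),
                   run_mqa_dep(land, seed = 3),
                   run_csa(land, seed = 3))) {
    expect_true(all(diff(run$trace$E_min) <= 0))
    expect_equal(run$best_energy, min(run$trace$E_min))
    expect_equal(run$best_energy, land$energy(run$best))
  }
})

test_that("variant relationships hold: disabled CLS, budgets, baselines", {
  land <- small_landscape()
  cfg0 <- cmqa_config(engine = list(M_chaot = 0L))
  a <- run_cmqa(land, seed = 5, config = cfg0)
  b <- run_mqa_dep(land, seed = 5)
  expect_identical(a$trace$E_i, b$trace$E_i)
  expect_identical(a$best, b$best)
  # CLS evaluations make the chaotic variant strictly more expensive
  full <- run_cmqa(land, seed = 5)
  expect_gt(full$evals, b$evals)
  expect_gte(length(full$cls_cycles), 1L)
  # the full run can only improve on the quench phase minimum
  expect_lte(full$best_energy, full$trace$E_min[full$phase_boundaries$mqp_end])
})

test_that("evaluation budgets cap the work", {
  land <- small_landscape()
  r <- run_cmqa(land, seed = 9, max_evals = 2000)
  expect_lte(r$evals, 2000 + 10 * land$m + land$m + 1)
  rfull <- run_cmqa(land, seed = 9)
  expect_gt(rfull$evals, r$evals)
})
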