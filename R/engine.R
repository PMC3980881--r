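#' Random conformation
#'
#' Draws m dihedral angles independently and uniformly on (-180, 180].
#'
#' @param m Number of dihedral variables.
#' @return Numeric vector of m angles in degrees.
#' @export
random_conformation <- function(m) {
  stopifnot(m >= 1)
  wrap_angle(stats::runif(m, -180, 180))
}

#' Uniform single-coordinate perturbation
#'
#' The Metropolis proposal move: one coordinate, chosen uniformly, is
#' redrawn fresh and uniformly on (-180, 180].
#'
#' @param sigma Numeric vector of dihedral angles.
#' @return The perturbed conformation.
#' @export
uniform_perturb <- function(sigma) {
  j <- sample.int(length(sigma), 1L)
  sigma[j] <- wrap_angle(stats::runif(1, -180, 180))
  sigma
}

#' Annealer solution state
#'
#' Carrier for the current solution S_i, the running best S_min and their
#' energies, plus proposal/acceptance counters. E_min is a running
#' minimum: it never increases under any engine operation.
#'
#' @param sigma Initial conformation (numeric angles in degrees).
#' @param energy Energy function.
#' @return An object of class `solution_state`.
#' @export
solution_state <- function(sigma, energy) {
  stopifnot(is.numeric(sigma), length(sigma) >= 1L, is.function(energy))
  e <- energy(sigma)
  structure(list(S_i = sigma, E_i = e, S_min = sigma, E_min = e,
                 n_accept = 0L, n_propose = 0L),
            class = "solution_state")
}

#' One Metropolis cycle at fixed temperature
#'
#' Performs `L` uniform-perturbation proposals at temperature `T`. A
#' proposal with dE <= 0 is always accepted (exp(0) = 1 beats any uniform
#' draw); a deteriorating one is accepted with the Boltzmann probability
#' exp(-dE / T). The running minimum is updated on every accepted
#' improvement.
#'
#' @param state A `solution_state`.
#' @param T Temperature (> 0).
#' @param L Number of proposals (>= 1).
#' @param energy Energy function.
#' @return The updated `solution_state` (counters accumulate across calls).
#' @export
metropolis_sweep <- function(state, T, L, energy) {
  stopifnot(inherits(state, "solution_state"), T > 0, L >= 1)
  S_i <- state$S_i; E_i <- state$E_i
  S_min <- state$S_min; E_min <- state$E_min
  acc <- 0L
  for (k in seq_len(L)) {
    S_j <- uniform_perturb(S_i)
    E_j <- energy(S_j)
    dE <- E_j - E_i
    if (dE <= 0 || stats::runif(1) < exp(-dE / T)) {
      S_i <- S_j; E_i <- E_j
      acc <- acc + 1L
      if (E_i < E_min) { S_min <- S_i; E_min <- E_i }
    }
  }
  state$S_i <- S_i; state$E_i <- E_i
  state$S_min <- S_min; state$E_min <- E_min
  state$n_accept <- state$n_accept + acc
  state$n_propose <- state$n_propose + as.integer(L)
  state
}

#' Chaotic local search
#'
#' Greedy improvement of the best-so-far conformation using the chaotic
#' perturbation operator: `M_chaot` single-coordinate chaotic steps are
#' applied in sequence, each kept only if it strictly lowers the energy.
#' The surrounding Metropolis trajectory is untouched - the caller's
#' current solution is saved and restored, so the search refines the
#' reported minimum without steering the chain.
#'
#' @param sigma Best-so-far conformation.
#' @param M_chaot Number of chaotic steps (>= 0); by convention equal to
#'   the number of variables.
#' @param chaos A `chaos_state`.
#' @param energy Energy function.
#' @param E Optional precomputed energy of `sigma` (saves one evaluation).
#' @return A list with `sigma`, `energy` (never above the input energy),
#'   the advanced `chaos` state and `n_improved`, the count of accepted
#'   steps.
#' @export
chaotic_local_search <- function(sigma, M_chaot, chaos, energy, E = NULL) {
  stopifnot(is.numeric(sigma), M_chaot >= 0, inherits(chaos, "chaos_state"))
  if (is.null(E)) E <- energy(sigma)
  n_improved <- 0L
  for (k in seq_len(M_chaot)) {
    p <- chaotic_perturb(sigma, chaos)
    chaos <- p$state
    E_j <- energy(p$sigma)
    if (E_j < E) {
      sigma <- p$sigma
      E <- E_j
      n_improved <- n_improved + 1L
    }
  }
  list(sigma = sigma, energy = E, chaos = chaos, n_improved = n_improved)
}

# Internal: shared trace-row builder.
trace_row <- function(cycle, phase, T, state, L, cls) {
  data.frame(cycle = cycle, phase = phase, T = T,
             E_i = state$E_i, E_min = state$E_min,
             acc_rate = state$n_accept / max(1L, state$n_propose),
             cls = cls)
}

#' Multiquenching phase
#'
#' Runs quadratic-quench cooling from `T0` down to `T_threshold`
#' (Metropolis cycle, tau squaring, chaotic local search each time tau
#' converges, tau reset, quench temperature step). Returns the state, the
#' crossover temperature and the per-cycle trace.
#'
#' @param energy Energy function over m angles.
#' @param m Number of dihedral variables.
#' @param params A `schedule_params`.
#' @param chaos A `chaos_state` (advanced across CLS invocations).
#' @param L Proposals per Metropolis cycle (default `10 * m`).
#' @param M_chaot Chaotic steps per CLS firing (default `m`; 0 disables
#'   CLS, giving the plain multiquenching baseline).
#' @param state Optional starting `solution_state` (default: random start).
#' @param max_evals Optional energy-evaluation budget, checked at cycle
#'   boundaries; the counter must be maintained by the caller via
#'   `counted_energy()`.
#' @return A list with `state`, `T` (first temperature at or below the
#'   threshold), `chaos`, `trace` (data frame), and `cls_cycles`.
#' @export
run_mqp <- function(energy, m, params, chaos, L = 10 * m, M_chaot = m,
                    state = NULL, max_evals = Inf) {
  stopifnot(inherits(params, "schedule_params"))
  if (is.null(state)) state <- solution_state(random_conformation(m), energy)
  T <- params$T0
  tau <- params$tau0
  rows <- list(); cls_cycles <- integer(0)
  cycle <- 0L
  while (T > params$T_threshold && evals_of(energy) < max_evals) {
    cycle <- cycle + 1L
    state <- metropolis_sweep(state, T, L, energy)
    tau <- update_tau(tau)
    cls_fired <- FALSE
    if (tau < params$tau_final) {
      tau <- params$tau0
      if (M_chaot > 0) {
        cls <- chaotic_local_search(state$S_min, M_chaot, chaos, energy,
                                    E = state$E_min)
        state$S_min <- cls$sigma
        state$E_min <- cls$energy
        chaos <- cls$chaos
        cls_fired <- TRUE
        cls_cycles <- c(cls_cycles, cycle)
      }
    }
    rows[[cycle]] <- trace_row(cycle, "mqp", T, state, L, cls_fired)
    T <- quench_next(T, params$alpha_quenching, tau)
  }
  list(state = state, T = T, chaos = chaos,
       trace = do.call(rbind, rows), cls_cycles = cls_cycles)
}

#' Annealing phase
#'
#' Classical simulated annealing with geometric cooling from the crossover
#' temperature toward `Tf`. Once the temperature falls to `T_fa` the
#' end-of-cycle energy of the current solution is streamed into an
#' equilibrium window, and the phase stops early when the window's
#' least-squares slope is within `dep_epsilon` of zero.
#'
#' @param state A `solution_state` (as left by [run_mqp()]).
#' @param energy Energy function.
#' @param params A `schedule_params`.
#' @param L Proposals per Metropolis cycle.
#' @param T_start Entry temperature (default `params$T_threshold`).
#' @param dep_window Window length in cycles (default 30); `0` disables
#'   equilibrium detection.
#' @param dep_epsilon Slope threshold (default 1e-3 energy units/cycle).
#' @param cycle0 Offset for cycle numbering in the trace.
#' @param max_evals Optional evaluation budget (see [run_mqp()]).
#' @return A list with `state`, `trace`, and `dep_cycle` (the cycle index
#'   at which equilibrium was declared, or NA).
#' @export
run_ap <- function(state, energy, params, L,
                   T_start = params$T_threshold,
                   dep_window = 30L, dep_epsilon = 1e-3,
                   cycle0 = 0L, max_evals = Inf) {
  stopifnot(inherits(state, "solution_state"),
            inherits(params, "schedule_params"))
  T <- T_start
  win <- if (dep_window >= 3) equilibrium_window(dep_window, dep_epsilon)
  rows <- list(); i <- 0L
  dep_cycle <- NA_integer_
  while (T > params$Tf && evals_of(energy) < max_evals) {
    i <- i + 1L
    state <- metropolis_sweep(state, T, L, energy)
    rows[[i]] <- trace_row(cycle0 + i, "ap", T, state, L, FALSE)
    if (!is.null(win) && T <= params$T_fa) {
      win <- dep_observe(win, state$E_i)
      if (dep_converged(win)) {
        dep_cycle <- cycle0 + i
        break
      }
    }
    T <- geometric_next(T, params$alpha_annealing)
  }
  list(state = state, trace = do.call(rbind, rows), dep_cycle = dep_cycle)
}

#' Wrap an energy function with an evaluation counter
#'
#' All engine drivers count energy evaluations uniformly (Metropolis
#' proposals, chaotic-local-search probes and schedule tuning alike)
#' through this wrapper, which is also how evaluation budgets are
#' enforced in variant comparisons.
#'
#' @param energy Energy function.
#' @return A counting wrapper; read the count with [evals_of()].
#' @export
counted_energy <- function(energy) {
  stopifnot(is.function(energy))
  env <- new.env(parent = emptyenv())
  env$n <- 0L
  f <- function(sigma) {
    env$n <- env$n + 1L
    energy(sigma)
  }
  attr(f, "counter") <- env
  f
}

#' @rdname counted_energy
#' @param counted A function returned by `counted_energy()` (any other
#'   function reports 0).
#' @export
evals_of <- function(counted) {
  env <- attr(counted, "counter")
  if (is.null(env)) 0L else env$n
}

# Internal: resolve an objective argument into list(energy, m, label).
as_objective <- function(objective, m = NULL) {
  if (inherits(objective, "planted_landscape")) {
    return(list(energy = objective$energy, m = objective$m,
                label = sprintf("planted(m=%d)", objective$m)))
  }
  if (inherits(objective, "protein_instance")) {
    return(list(energy = protein_energy(objective), m = objective$m,
                label = paste0("protein(", objective$sequence, ")")))
  }
  if (is.function(objective)) {
    if (is.null(m)) {
      stop("as_objective: supply m when the objective is a bare function",
           call. = FALSE)
    }
    return(list(energy = objective, m = as.integer(m), label = "custom"))
  }
  stop("as_objective: unsupported objective of class ",
       paste(class(objective), collapse = "/"), call. = FALSE)
}

# Internal: finish a run into a cmqa_result.
finish_result <- function(variant, state, trace, obj, config, seed, params,
                          cls_cycles, mqp_end, dep_cycle, evals, t0) {
  structure(list(
    variant = variant,
    best = state$S_min,
    best_energy = state$E_min,
    trace = trace,
    phase_boundaries = list(mqp_end = mqp_end, dep_cycle = dep_cycle),
    cls_cycles = cls_cycles,
    evals = evals,
    seed = seed,
    label = obj$label,
    m = obj$m,
    params = params,
    config = config,
    wall_time = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  ), class = "cmqa_result")
}

#' Run the chaotic multiquenching annealer
#'
#' Full three-phase optimization: multiquenching with chaotic local search
#' from `T0` to `T_threshold`, then classical annealing with the
#' least-squares equilibrium stopping rule. The temperature range is tuned
#' analytically from the landscape unless `params` is supplied. The run is
#' a pure function of (objective, config, seed): replaying with the same
#' arguments reproduces the energy trace bit for bit.
#'
#' @param objective A `planted_landscape`, a `protein_instance`, or a bare
#'   energy function (then supply `m`).
#' @param seed Integer seed for the run's random stream.
#' @param config A `cmqa_config` (defaults: [cmqa_config()]).
#' @param m Number of variables (only for bare-function objectives).
#' @param params Optional pre-built `schedule_params`; skips tuning.
#' @param max_evals Optional energy-evaluation budget.
#' @return A `cmqa_result` with the best conformation and energy, the
#'   per-cycle trace, phase boundaries, CLS firing cycles and the
#'   evaluation count.
#' @examples
#' land <- planted_landscape(m = 5, n_traps = 0, seed = 1)
#' res <- run_cmqa(land, seed = 1)
#' res$best_energy
#' @export
run_cmqa <- function(objective, seed = 1L, config = cmqa_config(), m = NULL,
                     params = NULL, max_evals = Inf) {
  run_variant(objective, seed, config, m, params, max_evals,
              variant = "cmqa")
}

#' Run the multiquenching annealer without chaotic local search
#'
#' Identical to [run_cmqa()] (same phases, same schedule, same
#' equilibrium stopping rule) with the chaotic local search disabled
#' (`M_chaot = 0`); the baseline "MQA plus DEP" of variant comparisons.
#'
#' @inheritParams run_cmqa
#' @return A `cmqa_result`.
#' @export
run_mqa_dep <- function(objective, seed = 1L, config = cmqa_config(),
                        m = NULL, params = NULL, max_evals = Inf) {
  run_variant(objective, seed, config, m, params, max_evals,
              variant = "mqa_dep")
}

#' Run classical simulated annealing
#'
#' Single-phase baseline: geometric cooling straight from `T0` to `Tf`
#' with the same proposal and acceptance rules as the annealing phase, no
#' quenching, no chaotic local search, no equilibrium detection.
#'
#' @inheritParams run_cmqa
#' @param L Proposals per Metropolis cycle; defaults to the configured
#'   multiple of `m`. Variant comparisons override it to match evaluation
#'   budgets across algorithms.
#' @return A `cmqa_result`.
#' @export
run_csa <- function(objective, seed = 1L, config = cmqa_config(), m = NULL,
                    params = NULL, max_evals = Inf, L = NULL) {
  run_variant(objective, seed, config, m, params, max_evals,
              variant = "csa", L_override = L)
}

# Internal: shared driver for the three variants.
run_variant <- function(objective, seed, config, m, params, max_evals,
                        variant, L_override = NULL) {
  stopifnot(inherits(config, "cmqa_config"))
  t0 <- Sys.time()
  obj <- as_objective(objective, m)
  set.seed(as.integer(seed))
  energy <- counted_energy(obj$energy)
  if (is.null(params)) {
    sc <- config$schedule
    if (is.null(sc$tune_samples)) sc$tune_samples <- 100L * obj$m
    params <- tune_schedule(energy, obj$m,
                            p_hot = sc$p_hot, p_cold = sc$p_cold,
                            t_threshold_frac = sc$t_threshold_frac,
                            t_fa_frac = sc$t_fa_frac,
                            tune_samples = sc$tune_samples,
                            alpha_quenching = sc$alpha_quenching,
                            alpha_annealing = sc$alpha_annealing,
                            tau0 = sc$tau0, tau_final = sc$tau_final)
  }
  L <- if (!is.null(L_override)) L_override else config$engine$L_per_var * obj$m
  if (variant == "csa") {
    state <- solution_state(random_conformation(obj$m), energy)
    ap <- run_ap(state, energy, params, L = L, T_start = params$T0,
                 dep_window = 0L, cycle0 = 0L, max_evals = max_evals)
    ap$trace$phase <- "csa"
    return(finish_result(variant, ap$state, ap$trace, obj, config, seed,
                         params, integer(0), NA_integer_, NA_integer_,
                         evals_of(energy), t0))
  }
  M_chaot <- if (variant == "cmqa") {
    if (is.null(config$engine$M_chaot)) obj$m else config$engine$M_chaot
  } else 0L
  ch <- config$chaos
  chaos <- chaos_state(ch$map, x0 = ch$x0, amplitude_deg = ch$amplitude_deg,
                       guard = ch$guard)
  mqp <- run_mqp(energy, obj$m, params, chaos, L = L, M_chaot = M_chaot,
                 max_evals = max_evals)
  mqp_end <- if (is.null(mqp$trace)) 0L else nrow(mqp$trace)
  # the quench step can overshoot well below the crossover; AP is defined
  # to enter at T_threshold
  ap <- run_ap(mqp$state, energy, params, L = L,
               T_start = params$T_threshold,
               dep_window = config$engine$dep_window,
               dep_epsilon = config$engine$dep_epsilon,
               cycle0 = mqp_end, max_evals = max_evals)
  trace <- rbind(mqp$trace, ap$trace)
  finish_result(variant, ap$state, trace, obj, config, seed, params,
                mqp$cls_cycles, mqp_end, ap$dep_cycle,
                evals_of(energy), t0)
}

#' @export
print.cmqa_result <- function(x, ...) {
  cat("<cmqa_result variant=", x$variant, " objective=", x$label, ">\n",
      sep = "")
  cat(sprintf("  best energy: %.6g after %d cycles (%d evaluations)\n",
              x$best_energy, nrow(x$trace), x$evals))
  cat(sprintf("  MQP end cycle: %s  CLS firings: %d  DEP trigger: %s\n",
              as.character(x$phase_boundaries$mqp_end),
              length(x$cls_cycles),
              as.character(x$phase_boundaries$dep_cycle)))
  invisible(x)
}
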