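#' Cooling-schedule parameters
#'
#' Bundles the temperature range and decrement factors of a run. The
#' temperatures are in the same (energy) units as the objective:
#' `T0 > T_threshold >= T_fa > Tf > 0`, with `T_threshold` the
#' multiquenching-to-annealing crossover and `T_fa` the temperature below
#' which the dynamic-equilibrium stopping rule becomes active. Both
#' decrement factors must lie in [0.7, 1), the admissible range of the
#' geometric cooling law.
#'
#' @param T0 Initial temperature.
#' @param Tf Final temperature.
#' @param T_threshold MQP -> AP crossover temperature (default `1e-6 * T0`,
#'   raised to `T_fa` when the deterioration range is too narrow for that
#'   fraction).
#' @param T_fa Equilibrium-detection activation temperature (default `10 * Tf`).
#' @param alpha_quenching Quenching decrement factor in [0.7, 1) (default 0.85).
#' @param alpha_annealing Annealing decrement factor in [0.7, 1) (default 0.95).
#' @param tau0 Initial quadratic-quench parameter in (0, 1) (default 0.90).
#' @param tau_final Convergence cutoff for tau (default 0.0009).
#' @return An object of class `schedule_params`.
#' @seealso [tune_schedule()] for deriving `T0`/`Tf` from a landscape.
#' @export
schedule_params <- function(T0, Tf,
                            T_threshold = max(1e-6 * T0, T_fa),
                            T_fa = 10 * Tf,
                            alpha_quenching = 0.85,
                            alpha_annealing = 0.95,
                            tau0 = 0.90,
                            tau_final = 0.0009) {
  p <- list(T0 = T0, Tf = Tf, T_threshold = T_threshold, T_fa = T_fa,
            alpha_quenching = alpha_quenching,
            alpha_annealing = alpha_annealing,
            tau0 = tau0, tau_final = tau_final)
  for (nm in names(p)) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]])) {
      stop("schedule_params: '", nm, "' must be a finite scalar", call. = FALSE)
    }
  }
  if (!(p$Tf > 0 && p$Tf < p$T_fa && p$T_fa <= p$T_threshold &&
        p$T_threshold < p$T0)) {
    stop("schedule_params: need 0 < Tf < T_fa <= T_threshold < T0 (got Tf=",
         signif(p$Tf, 4), ", T_fa=", signif(p$T_fa, 4), ", T_threshold=",
         signif(p$T_threshold, 4), ", T0=", signif(p$T0, 4), ")",
         call. = FALSE)
  }
  check_alpha(p$alpha_quenching, "alpha_quenching")
  check_alpha(p$alpha_annealing, "alpha_annealing")
  if (!(p$tau_final > 0 && p$tau_final < p$tau0 && p$tau0 < 1)) {
    stop("schedule_params: need 0 < tau_final < tau0 < 1", call. = FALSE)
  }
  structure(p, class = "schedule_params")
}

check_alpha <- function(alpha, name) {
  if (!is.numeric(alpha) || length(alpha) != 1L ||
      alpha < 0.7 || alpha >= 1) {
    stop(name, " must lie in [0.7, 1), got ", alpha, call. = FALSE)
  }
  invisible(alpha)
}

#' @export
print.schedule_params <- function(x, ...) {
  cat("<schedule_params>\n")
  cat(sprintf("  T0 = %.6g  T_threshold = %.6g  T_fa = %.6g  Tf = %.6g\n",
              x$T0, x$T_threshold, x$T_fa, x$Tf))
  cat(sprintf("  alpha_quenching = %.3f  alpha_annealing = %.3f\n",
              x$alpha_quenching, x$alpha_annealing))
  cat(sprintf("  tau0 = %.4g  tau_final = %.4g\n", x$tau0, x$tau_final))
  invisible(x)
}

#' Geometric cooling step
#'
#' The classical exponential schedule T_{k+1} = alpha * T_k, with alpha in
#' [0.7, 1).
#'
#' @param T Current temperature (> 0).
#' @param alpha Decrement factor in [0.7, 1).
#' @return The next temperature, strictly smaller than `T`.
#' @export
geometric_next <- function(T, alpha) {
  stopifnot(is.numeric(T), T > 0)
  check_alpha(alpha, "alpha")
  alpha * T
}

#' Quenching cooling step
#'
#' The quadratic quench T_{k+1} = alpha_q * (1 - tau) * T_k. As tau is
#' squared toward zero over a subphase the step relaxes to the geometric
#' schedule; early in a subphase (tau near tau0) it removes most of the
#' temperature in a single cycle, which is what makes the multiquenching
#' phase fast.
#'
#' @param T Current temperature (> 0).
#' @param alpha_q Quenching decrement factor in [0.7, 1).
#' @param tau Quadratic decrement parameter in [0, 1).
#' @return The next temperature, at most `geometric_next(T, alpha_q)`.
#' @export
quench_next <- function(T, alpha_q, tau) {
  stopifnot(is.numeric(T), T > 0)
  check_alpha(alpha_q, "alpha_q")
  if (!is.numeric(tau) || length(tau) != 1L || tau < 0 || tau >= 1) {
    stop("quench_next: tau must lie in [0, 1)", call. = FALSE)
  }
  alpha_q * (1 - tau) * T
}

#' Quadratic update of the quench parameter
#'
#' tau <- tau^2; repeated application drives tau to zero, ending a
#' multiquenching subphase. From the default tau0 = 0.90 exactly seven
#' updates are needed to fall below the default cutoff 0.0009.
#'
#' @param tau Current value in (0, 1).
#' @return tau squared.
#' @export
update_tau <- function(tau) {
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0 || tau >= 1) {
    stop("update_tau: tau must lie in (0, 1)", call. = FALSE)
  }
  tau * tau
}

#' Boltzmann acceptance probability
#'
#' Probability exp(-dZ / T) of accepting a deteriorating move of size
#' dZ >= 0 at temperature T.
#'
#' @param dZ Energy deterioration (>= 0), vectorized.
#' @param T Temperature (> 0).
#' @return Probabilities in (0, 1].
#' @export
acceptance_probability <- function(dZ, T) {
  if (!is.numeric(T) || length(T) != 1L || T <= 0) {
    stop("acceptance_probability: T must be > 0", call. = FALSE)
  }
  stopifnot(is.numeric(dZ), all(dZ >= 0))
  exp(-dZ / T)
}

#' Initial temperature from the maximal deterioration
#'
#' Inverts the Boltzmann acceptance relation: the initial temperature is
#' the one at which a move deteriorating the objective by `dZmax` is still
#' accepted with probability `P` (close to 1 for a hot start),
#' T0 = -dZmax / ln(P).
#'
#' @param dZmax Maximal observed deterioration (> 0).
#' @param P Target acceptance probability in (0, 1).
#' @return The temperature solving exp(-dZmax / T) = P.
#' @export
initial_temperature <- function(dZmax, P) {
  stopifnot(is.numeric(dZmax), dZmax > 0)
  if (!is.numeric(P) || length(P) != 1L || P <= 0 || P >= 1) {
    stop("initial_temperature: P must lie strictly in (0, 1)", call. = FALSE)
  }
  -dZmax / log(P)
}

#' Final temperature from the minimal deterioration
#'
#' Same inversion as [initial_temperature()] applied to the minimal
#' deterioration `dZmin` and a near-zero target acceptance probability:
#' Tf = -dZmin / ln(P). At `Tf` even the smallest uphill move is accepted
#' only with probability `P`.
#'
#' @param dZmin Minimal observed deterioration (> 0).
#' @param P Target acceptance probability in (0, 1).
#' @return The temperature solving exp(-dZmin / T) = P.
#' @export
final_temperature <- function(dZmin, P) {
  stopifnot(is.numeric(dZmin), dZmin > 0)
  if (!is.numeric(P) || length(P) != 1L || P <= 0 || P >= 1) {
    stop("final_temperature: P must lie strictly in (0, 1)", call. = FALSE)
  }
  -dZmin / log(P)
}

#' Estimate the deterioration range of a landscape
#'
#' Random-walk estimator behind the analytic temperature tuning: from
#' `n_samples` random conformations, apply one uniform single-coordinate
#' perturbation each, record every positive energy deterioration and return
#' its maximum and minimum. Both bound the Boltzmann inversion of
#' [initial_temperature()] / [final_temperature()].
#'
#' @param energy Energy function taking a numeric vector of `m` angles.
#' @param m Number of dihedral variables.
#' @param n_samples Number of probing perturbations (default `100 * m`).
#' @return A list with elements `dZmax` and `dZmin` (both > 0).
#' @export
estimate_deteriorations <- function(energy, m, n_samples = 100 * m) {
  stopifnot(is.function(energy), m >= 1, n_samples >= 2)
  det <- numeric(0)
  for (i in seq_len(n_samples)) {
    s <- random_conformation(m)
    e0 <- energy(s)
    s2 <- uniform_perturb(s)
    d <- energy(s2) - e0
    if (d > 0) det <- c(det, d)
  }
  if (length(det) == 0L) {
    stop("estimate_deteriorations: no deteriorating move found in ",
         n_samples, " samples; the landscape may be constant - ",
         "increase n_samples", call. = FALSE)
  }
  list(dZmax = max(det), dZmin = min(det))
}

#' Analytic schedule tuning for a landscape
#'
#' Derives the full temperature range from the landscape itself: the
#' deterioration range is estimated by [estimate_deteriorations()], then
#' `T0` is set so the maximal deterioration is accepted with probability
#' `p_hot` and `Tf` so the minimal one passes with probability `p_cold`.
#' Crossover and equilibrium-activation temperatures are placed at fixed
#' fractions of `T0` and multiples of `Tf`.
#'
#' @param energy Energy function over `m` angles.
#' @param m Number of dihedral variables.
#' @param p_hot Target hot acceptance probability (default 0.95).
#' @param p_cold Target cold acceptance probability (default 0.01).
#' @param t_threshold_frac `T_threshold` as a fraction of `T0`
#'   (default 1e-6, about two full quench subphases).
#' @param t_fa_frac `T_fa` as a multiple of `Tf` (default 10).
#' @param tune_samples Probing perturbations (default `100 * m`).
#' @param ... Passed to [schedule_params()] (alpha and tau settings).
#' @return A `schedule_params` object.
#' @export
tune_schedule <- function(energy, m, p_hot = 0.95, p_cold = 0.01,
                          t_threshold_frac = 1e-6, t_fa_frac = 10,
                          tune_samples = 100 * m, ...) {
  d <- estimate_deteriorations(energy, m, n_samples = tune_samples)
  T0 <- initial_temperature(d$dZmax, p_hot)
  Tf <- final_temperature(d$dZmin, p_cold)
  T_fa <- t_fa_frac * Tf
  # on landscapes with a narrow deterioration range the nominal crossover
  # fraction can undercut T_fa; keep the ordering Tf < T_fa <= T_threshold
  T_threshold <- max(t_threshold_frac * T0, T_fa)
  schedule_params(T0 = T0, Tf = Tf,
                  T_threshold = T_threshold,
                  T_fa = T_fa, ...)
}
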