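#' Dispatch a run from a configuration snapshot
#'
#' Runs the variant named in the configuration with the configuration's
#' seed. Because every run is a pure function of (objective, config,
#' seed), re-running a persisted snapshot reproduces the original energy
#' trace bit for bit.
#'
#' @param objective Objective (see [run_cmqa()]).
#' @param config A `cmqa_config`.
#' @param m Variable count for bare-function objectives.
#' @param ... Passed to the variant driver (e.g. `max_evals`).
#' @return A `cmqa_result`.
#' @export
run_from_config <- function(objective, config, m = NULL, ...) {
  stopifnot(inherits(config, "cmqa_config"))
  fn <- switch(config$variant, cmqa = run_cmqa, mqa_dep = run_mqa_dep,
               csa = run_csa)
  fn(objective, seed = config$seed, config = config, m = m, ...)
}

#' Paired-seed comparison of the three annealer variants
#'
#' For each seed, runs the full chaotic multiquenching annealer, then the
#' no-chaotic-search baseline (same schedule minus the local-search
#' evaluations) and classical simulated annealing at a matched
#' energy-evaluation budget: the classical run's Metropolis cycle length
#' is scaled so its schedule spends the same number of evaluations the
#' chaotic run consumed, and a hard cap at that budget is enforced.
#'
#' @param objective Objective (see [run_cmqa()]).
#' @param seeds Integer vector of seeds (default 1:10).
#' @param config Base `cmqa_config`.
#' @param m Variable count for bare-function objectives.
#' @return A list with `per_run` (variant, seed, final energy, evaluation
#'   count, minutes) and `summary` (per-variant mean and median energy,
#'   mean minutes).
#' @export
compare_variants <- function(objective, seeds = 1:10,
                             config = cmqa_config(), m = NULL) {
  rows <- list()
  for (s in seeds) {
    r_cmqa <- run_cmqa(objective, seed = s, config = config, m = m)
    budget <- r_cmqa$evals
    r_mqa <- run_mqa_dep(objective, seed = s, config = config, m = m,
                         max_evals = budget)
    p <- r_cmqa$params
    n_cycles <- max(1L, ceiling(log(p$Tf / p$T0) / log(p$alpha_annealing)))
    tune_samples <- config$schedule$tune_samples
    if (is.null(tune_samples)) tune_samples <- 100L * r_cmqa$m
    tune_evals <- 2L * tune_samples + 1L  # probes plus the start state
    L_csa <- max(1L, round((budget - tune_evals) / n_cycles))
    r_csa <- run_csa(objective, seed = s, config = config, m = m,
                     L = L_csa, max_evals = budget)
    for (r in list(r_cmqa, r_mqa, r_csa)) {
      rows[[length(rows) + 1L]] <- data.frame(
        variant = r$variant, seed = s, energy = r$best_energy,
        evals = r$evals, minutes = r$wall_time / 60
      )
    }
  }
  per_run <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(per_run, per_run$variant),
    function(d) data.frame(
      variant = d$variant[1],
      mean_energy = mean(d$energy),
      median_energy = stats::median(d$energy),
      mean_minutes = mean(d$minutes),
      mean_evals = mean(d$evals),
      n_runs = nrow(d)
    )))
  rownames(summary) <- NULL
  summary <- summary[order(match(summary$variant,
                                 c("cmqa", "mqa_dep", "csa"))), ]
  list(per_run = per_run, summary = summary)
}

#' Sweep annealing factor and chaotic map
#'
#' Runs the chaotic multiquenching annealer over a grid of annealing
#' decrement factors and chaotic maps, averaging over seeds, and returns
#' a table shaped like the per-instance report grids: one row per
#' (alpha_annealing, map) cell with mean energy, mean minutes and seed
#' count.
#'
#' @param objective Objective (see [run_cmqa()]).
#' @param alphas Annealing factors (default `c(0.75, 0.80, 0.85, 0.90,
#'   0.95)`).
#' @param maps Chaotic maps (default all four).
#' @param seeds Seeds per cell (default 1:3).
#' @param config Base `cmqa_config`.
#' @param m Variable count for bare-function objectives.
#' @return A data frame with columns alpha_annealing, map, mean_energy,
#'   mean_minutes, n_runs.
#' @export
sweep_grid <- function(objective, alphas = c(0.75, 0.80, 0.85, 0.90, 0.95),
                       maps = c("M1", "M2", "M3", "M4"), seeds = 1:3,
                       config = cmqa_config(), m = NULL) {
  rows <- list()
  for (a in alphas) {
    for (mp in maps) {
      cfg <- cmqa_config(variant = config$variant, seed = config$seed,
                         chaos = utils::modifyList(config$chaos,
                                                   list(map = mp),
                                                   keep.null = TRUE),
                         schedule = utils::modifyList(
                           config$schedule, list(alpha_annealing = a),
                           keep.null = TRUE),
                         engine = config$engine)
      runs <- lapply(seeds, function(s) {
        run_cmqa(objective, seed = s, config = cfg, m = m)
      })
      rows[[length(rows) + 1L]] <- data.frame(
        alpha_annealing = a, map = mp,
        mean_energy = mean(vapply(runs, `[[`, numeric(1), "best_energy")),
        mean_minutes = mean(vapply(runs, `[[`, numeric(1),
                                   "wall_time")) / 60,
        n_runs = length(seeds)
      )
    }
  }
  do.call(rbind, rows)
}
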