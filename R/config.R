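#' Run configuration
#'
#' Builds a fully materialized run configuration. Every field has a
#' default; overrides are supplied as (partial) nested lists and are
#' validated strictly - an unknown key is an error, not a silently
#' ignored typo, and schedule factors outside their admissible ranges are
#' rejected up front.
#'
#' Sections and defaults:
#' \describe{
#'   \item{variant}{"cmqa", "mqa_dep" or "csa".}
#'   \item{seed}{Integer seed (default 1).}
#'   \item{chaos}{`map` ("M1".."M4", default "M1"), `amplitude_deg` (90),
#'     `guard` (1e-6), `x0` (0.3).}
#'   \item{schedule}{`alpha_quenching` (0.85), `alpha_annealing` (0.95),
#'     `tau0` (0.90), `tau_final` (0.0009), `p_hot` (0.95),
#'     `p_cold` (0.01), `t_threshold_frac` (1e-6), `t_fa_frac` (10),
#'     `tune_samples` (NULL, meaning 100 per variable).}
#'   \item{engine}{`L_per_var` (10 proposals per variable per cycle),
#'     `M_chaot` (NULL, meaning one step per variable), `dep_window` (30),
#'     `dep_epsilon` (1e-3).}
#' }
#'
#' @param variant Algorithm variant.
#' @param seed Integer seed.
#' @param chaos,schedule,engine Partial override lists.
#' @return An object of class `cmqa_config` with every field materialized.
#' @seealso [load_config()], [save_config()]
#' @export
cmqa_config <- function(variant = c("cmqa", "mqa_dep", "csa"), seed = 1L,
                        chaos = list(), schedule = list(), engine = list()) {
  variant <- match.arg(variant)
  defaults <- list(
    chaos = list(map = "M1", amplitude_deg = 90, guard = 1e-6, x0 = 0.3),
    schedule = list(alpha_quenching = 0.85, alpha_annealing = 0.95,
                    tau0 = 0.90, tau_final = 0.0009,
                    p_hot = 0.95, p_cold = 0.01,
                    t_threshold_frac = 1e-6, t_fa_frac = 10,
                    tune_samples = NULL),
    engine = list(L_per_var = 10L, M_chaot = NULL,
                  dep_window = 30L, dep_epsilon = 1e-3)
  )
  merge_section <- function(section, override) {
    bad <- setdiff(names(override), names(defaults[[section]]))
    if (length(bad) > 0L) {
      stop("cmqa_config: unknown ", section, " key(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    utils::modifyList(defaults[[section]], override, keep.null = TRUE)
  }
  cfg <- structure(list(
    variant = variant,
    seed = as.integer(seed),
    chaos = merge_section("chaos", chaos),
    schedule = merge_section("schedule", schedule),
    engine = merge_section("engine", engine)
  ), class = "cmqa_config")
  validate_config(cfg)
}

validate_config <- function(cfg) {
  ch <- cfg$chaos; sc <- cfg$schedule; en <- cfg$engine
  if (!ch$map %in% c("M1", "M2", "M3", "M4")) {
    stop("config: chaos.map must be one of M1..M4", call. = FALSE)
  }
  if (ch$amplitude_deg < 0) {
    stop("config: chaos.amplitude_deg must be >= 0", call. = FALSE)
  }
  if (ch$guard <= 0 || ch$guard >= 0.5) {
    stop("config: chaos.guard must lie in (0, 0.5)", call. = FALSE)
  }
  if (ch$x0 <= ch$guard || ch$x0 >= 1 - ch$guard) {
    stop("config: chaos.x0 must lie strictly inside (guard, 1 - guard)",
         call. = FALSE)
  }
  check_alpha(sc$alpha_quenching, "schedule.alpha_quenching")
  check_alpha(sc$alpha_annealing, "schedule.alpha_annealing")
  if (!(sc$tau_final > 0 && sc$tau_final < sc$tau0 && sc$tau0 < 1)) {
    stop("config: need 0 < schedule.tau_final < schedule.tau0 < 1",
         call. = FALSE)
  }
  for (p in c("p_hot", "p_cold")) {
    if (sc[[p]] <= 0 || sc[[p]] >= 1) {
      stop("config: schedule.", p, " must lie strictly in (0, 1)",
           call. = FALSE)
    }
  }
  if (sc$t_threshold_frac <= 0 || sc$t_threshold_frac >= 1) {
    stop("config: schedule.t_threshold_frac must lie in (0, 1)",
         call. = FALSE)
  }
  if (sc$t_fa_frac < 1) {
    stop("config: schedule.t_fa_frac must be >= 1", call. = FALSE)
  }
  if (en$L_per_var < 1) {
    stop("config: engine.L_per_var must be >= 1", call. = FALSE)
  }
  if (en$dep_window != 0 && en$dep_window < 3) {
    stop("config: engine.dep_window must be 0 (off) or >= 3", call. = FALSE)
  }
  if (en$dep_epsilon <= 0) {
    stop("config: engine.dep_epsilon must be > 0", call. = FALSE)
  }
  cfg
}

#' @export
print.cmqa_config <- function(x, ...) {
  cat("<cmqa_config variant=", x$variant, " seed=", x$seed, ">\n", sep = "")
  for (sec in c("chaos", "schedule", "engine")) {
    vals <- vapply(x[[sec]], function(v) {
      if (is.null(v)) "auto" else format(v)
    }, character(1))
    cat("  ", sec, ": ", paste(names(vals), vals, sep = "=",
                               collapse = " "), "\n", sep = "")
  }
  invisible(x)
}

#' Load a run configuration from YAML
#'
#' Reads a (possibly partial, possibly empty) YAML file and materializes
#' all defaults; an empty file yields the pure-default configuration.
#' Unknown keys and invariant violations are errors naming the offending
#' field.
#'
#' @param path Path to a YAML configuration file.
#' @return A `cmqa_config`.
#' @export
load_config <- function(path) {
  stopifnot(file.exists(path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c("variant", "seed", "chaos", "schedule", "engine")
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0L) {
    stop("load_config: unknown top-level key(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  cmqa_config(
    variant = if (is.null(raw$variant)) "cmqa" else raw$variant,
    seed = if (is.null(raw$seed)) 1L else raw$seed,
    chaos = if (is.null(raw$chaos)) list() else raw$chaos,
    schedule = if (is.null(raw$schedule)) list() else raw$schedule,
    engine = if (is.null(raw$engine)) list() else raw$engine
  )
}

#' Persist a run configuration to YAML
#'
#' Writes every field, including defaulted ones, so the saved snapshot is
#' a complete provenance record: loading it back yields an identical
#' configuration.
#'
#' @param config A `cmqa_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "cmqa_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
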