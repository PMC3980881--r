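#' Chaotic driver maps
#'
#' Four sine maps with singularities at 0 (and at 1 for all but the first)
#' are used to drive the chaotic local search. In display order:
#' \describe{
#'   \item{M1}{f(x) = sin(1/x)}
#'   \item{M2}{f(x) = sin((1/x) * (1/(1-x)))}
#'   \item{M3}{f(x) = sin((100/x) * (1/(1-x)))}
#'   \item{M4}{f(x) = sin(1/x) * sin(5/(1-x))}
#' }
#' Near the singular endpoints the argument of the sine diverges, so the
#' maps oscillate with unbounded frequency; sampled on (0, 1) they behave
#' as bounded, highly irregular drivers with values in [-1, 1].
#'
#' @param map_id One of "M1", "M2", "M3", "M4".
#' @return An object of class `chaotic_map`.
#' @seealso [eval_chaotic_map()], [chaos_state()]
#' @export
chaotic_map <- function(map_id = c("M1", "M2", "M3", "M4")) {
  map_id <- match.arg(map_id)
  fn <- switch(map_id,
    M1 = function(x) sin(1 / x),
    M2 = function(x) sin((1 / x) * (1 / (1 - x))),
    M3 = function(x) sin((100 / x) * (1 / (1 - x))),
    M4 = function(x) sin(1 / x) * sin(5 / (1 - x))
  )
  structure(
    list(map_id = map_id, fn = fn,
         # singular points of the map argument; 1 is regular for M1 only
         singular = if (map_id == "M1") 0 else c(0, 1)),
    class = "chaotic_map"
  )
}

#' @export
print.chaotic_map <- function(x, ...) {
  forms <- c(M1 = "sin(1/x)", M2 = "sin((1/x)(1/(1-x)))",
             M3 = "sin((100/x)(1/(1-x)))", M4 = "sin(1/x)*sin(5/(1-x))")
  cat("<chaotic_map ", x$map_id, ": f(x) = ", forms[[x$map_id]], ">\n", sep = "")
  invisible(x)
}

#' Evaluate a chaotic map
#'
#' Evaluates f(x) for one of the four driver maps. Evaluation at (or within
#' `guard` of) a singular point is an error, never a silent clamp: the maps
#' are undefined there and any finite value returned would be arbitrary.
#'
#' @param map A `chaotic_map`.
#' @param x Numeric vector of evaluation points.
#' @param guard Exclusion radius around the singular points (default 1e-6).
#' @return f(x), elementwise, always in [-1, 1].
#' @export
eval_chaotic_map <- function(map, x, guard = 1e-6) {
  stopifnot(inherits(map, "chaotic_map"), is.numeric(x), guard >= 0)
  for (s in map$singular) {
    if (any(abs(x - s) < guard)) {
      stop("eval_chaotic_map: x within guard radius ", guard,
           " of singular point ", s, call. = FALSE)
    }
  }
  map$fn(x)
}

#' Chaotic iteration state
#'
#' Carrier for the deterministic iteration of a chaotic map: the map, the
#' current iterate x in (guard, 1-guard), and the perturbation amplitude in
#' degrees. The maps themselves are static curves; the package iterates
#' them by x' = fold(|f(x)|), re-seeding deterministically from the run's
#' random stream whenever an iterate lands in a guard region or on a fixed
#' point, so the sequence of drivers is bounded, non-degenerate and fully
#' reproducible from (map, x0, seed).
#'
#' @param map A `chaotic_map` or a map id string.
#' @param x0 Initial iterate, strictly inside (guard, 1-guard).
#' @param amplitude_deg Maximal angular perturbation in degrees (default 90).
#' @param guard Exclusion radius around singular points (default 1e-6).
#' @return An object of class `chaos_state`.
#' @export
chaos_state <- function(map = "M1", x0 = 0.3, amplitude_deg = 90,
                        guard = 1e-6) {
  if (is.character(map)) map <- chaotic_map(map)
  stopifnot(inherits(map, "chaotic_map"),
            is.numeric(x0), length(x0) == 1L,
            is.numeric(amplitude_deg), length(amplitude_deg) == 1L,
            amplitude_deg >= 0, guard > 0, guard < 0.5)
  if (x0 <= guard || x0 >= 1 - guard) {
    stop("chaos_state: x0 must lie strictly inside (guard, 1 - guard)",
         call. = FALSE)
  }
  structure(
    list(map = map, x = x0, amplitude_deg = amplitude_deg, guard = guard),
    class = "chaos_state"
  )
}

#' @export
print.chaos_state <- function(x, ...) {
  cat("<chaos_state map=", x$map$map_id, " x=", format(x$x, digits = 6),
      " amplitude=", x$amplitude_deg, "deg guard=", x$guard, ">\n", sep = "")
  invisible(x)
}

#' Advance the chaotic iteration by one step
#'
#' Computes y = f(x) and folds |y| back into (guard, 1-guard) as the next
#' iterate. Degenerate iterates (inside a guard region, or exactly equal to
#' the current x, which would freeze the sequence) are replaced by a draw
#' from the run's random stream, so the caller's RNG state is the single
#' source of randomness and replay is exact.
#'
#' @param state A `chaos_state`.
#' @return A list with elements `state` (advanced state) and `y` (the raw
#'   driver value f(x) in [-1, 1]).
#' @export
advance_chaos <- function(state) {
  stopifnot(inherits(state, "chaos_state"))
  g <- state$guard
  y <- eval_chaotic_map(state$map, state$x, guard = g)
  xn <- abs(y)
  near_singular <- any(abs(xn - state$map$singular) < g) ||
    xn <= g || xn >= 1 - g
  if (near_singular || xn == state$x) {
    xn <- g + (1 - 2 * g) * stats::runif(1)
  }
  state$x <- xn
  list(state = state, y = y)
}

#' Chaotic single-coordinate perturbation
#'
#' Perturbs exactly one coordinate of a conformation: the index is chosen
#' uniformly from the run's random stream and the step is y * amplitude
#' degrees, with y the next chaotic driver value. The result is wrapped
#' back onto (-180, 180].
#'
#' @param sigma Numeric vector of dihedral angles in degrees (length >= 1).
#' @param state A `chaos_state`.
#' @return A list with elements `sigma` (perturbed conformation), `state`
#'   (advanced chaos state) and `index` (the coordinate that moved).
#' @export
chaotic_perturb <- function(sigma, state) {
  stopifnot(is.numeric(sigma))
  if (length(sigma) < 1L) {
    stop("chaotic_perturb: conformation must have at least one variable",
         call. = FALSE)
  }
  j <- sample.int(length(sigma), 1L)
  step <- advance_chaos(state)
  sigma[j] <- wrap_angle(sigma[j] + step$y * state$amplitude_deg)
  list(sigma = sigma, state = step$state, index = j)
}
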