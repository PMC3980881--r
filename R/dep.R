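#' Least-squares slope of an energy window (closed form)
#'
#' Fits E_i = a * x_i + b to the last n per-cycle energies with equally
#' spaced abscissae x_i = 0, ..., n-1 and returns the slope via the closed
#' form
#' \deqn{a = \frac{12 \sum x_i E_i - 6 (n-1) \sum E_i}{n^3 - n},}
#' which is algebraically identical to the general least-squares slope for
#' this x convention but needs a single pass and no matrix solve - the
#' point of using it inside the annealing loop.
#'
#' @param energies Numeric vector of at least 3 per-cycle energies.
#' @return The fitted slope (energy units per cycle).
#' @seealso [dep_intercept()], [dep_converged()]
#' @export
dep_slope <- function(energies) {
  n <- length(energies)
  if (n < 3L || !is.numeric(energies)) {
    stop("dep_slope: need a numeric window of at least 3 energies",
         call. = FALSE)
  }
  x <- seq_len(n) - 1
  (12 * sum(x * energies) - 6 * (n - 1) * sum(energies)) / (n^3 - n)
}

#' Least-squares intercept of an energy window
#'
#' Companion to [dep_slope()]: the intercept b of the fitted line
#' E = a x + b over x_i = 0, ..., n-1, from the general least-squares
#' normal equations.
#'
#' @param energies Numeric vector of at least 3 per-cycle energies.
#' @return The fitted intercept (energy at the window start).
#' @export
dep_intercept <- function(energies) {
  n <- length(energies)
  if (n < 3L || !is.numeric(energies)) {
    stop("dep_intercept: need a numeric window of at least 3 energies",
         call. = FALSE)
  }
  x <- seq_len(n) - 1
  (sum(energies) * sum(x^2) - sum(x) * sum(x * energies)) /
    (n * sum(x^2) - sum(x)^2)
}

#' Equilibrium window for the dynamic stopping rule
#'
#' Fixed-capacity buffer of the most recent per-cycle energies. Once full,
#' the run is declared in dynamic equilibrium when the least-squares slope
#' of the window is closer to zero than `epsilon`: the energy trace has
#' flattened and further cooling is not buying improvement.
#'
#' @param n Window capacity (>= 3, default 30 cycles).
#' @param epsilon Slope threshold in energy units per cycle (default 1e-3).
#' @return An object of class `equilibrium_window`.
#' @export
equilibrium_window <- function(n = 30L, epsilon = 1e-3) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 3,
            is.numeric(epsilon), epsilon > 0)
  structure(list(n = as.integer(n), epsilon = epsilon, energies = numeric(0)),
            class = "equilibrium_window")
}

#' Append one per-cycle energy to an equilibrium window
#'
#' @param window An `equilibrium_window`.
#' @param e End-of-cycle energy.
#' @return The updated window (oldest entry dropped when at capacity).
#' @export
dep_observe <- function(window, e) {
  stopifnot(inherits(window, "equilibrium_window"),
            is.numeric(e), length(e) == 1L)
  window$energies <- c(window$energies, e)
  if (length(window$energies) > window$n) {
    window$energies <- window$energies[-1L]
  }
  window
}

#' Has the energy trace reached dynamic equilibrium?
#'
#' TRUE once the window is full and the magnitude of its least-squares
#' slope is below `epsilon`. An under-filled window never signals
#' equilibrium (and never errors), so the test can be issued every cycle
#' while streaming.
#'
#' @param window An `equilibrium_window`.
#' @return Logical scalar.
#' @export
dep_converged <- function(window) {
  stopifnot(inherits(window, "equilibrium_window"))
  if (length(window$energies) < window$n) return(FALSE)
  abs(dep_slope(window$energies)) < window$epsilon
}
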