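#' Planted-minimum validation landscape
#'
#' Synthetic objective over m dihedral angles with a certified global
#' minimum of exactly 0 at a planted optimum, used to validate the
#' annealing engine. The base surface is a separable cosine well,
#' \deqn{E_0(\sigma) = \sum_i (1 - \cos(\sigma_i - \sigma^*_i)),}
#' and each trap subtracts a compactly supported bump over a pair of
#' coordinates, creating a genuine local minimum away from the optimum.
#'
#' Certification is by construction, not by search: traps act on disjoint
#' coordinate pairs, the trap centers sit 135-180 degrees from the
#' optimum in each of their two coordinates, and each trap depth is
#' pinned strictly between (a) the largest single-coordinate energy drop
#' available from the trap center - so the trap cannot be escaped by one
#' greedy coordinate move, making it a true local minimum - and (b) the
#' minimum of the base energy over the trap's support - so the deducted
#' bump can never take the total below 0. A direct numeric check of the
#' optimum and all trap centers is still run at construction.
#'
#' @param m Number of dihedral variables (>= 1; >= 2 * n_traps).
#' @param n_traps Number of local-minimum traps (default 5).
#' @param sigma_star Planted optimum (default: drawn uniformly).
#' @param trap_width Half-width of the trap support in degrees
#'   (default 45).
#' @param depth_frac Where each trap depth sits between the escape bound
#'   and the positivity bound, in (0, 1) (default 0.5).
#' @param seed Optional seed making the construction self-contained;
#'   when NULL the caller's RNG stream is used.
#' @return An object of class `planted_landscape` with fields `energy`
#'   (the objective function), `m`, `sigma_star`, `minimum` (0), and
#'   `traps` (per-trap coordinates, centers and depths).
#' @examples
#' land <- planted_landscape(m = 19, n_traps = 5, seed = 42)
#' land$energy(land$sigma_star)  # exactly 0
#' @export
planted_landscape <- function(m, n_traps = 5L, sigma_star = NULL,
                              trap_width = 45, depth_frac = 0.5,
                              seed = NULL) {
  stopifnot(m >= 1, n_traps >= 0, trap_width > 0, trap_width <= 45,
            depth_frac > 0, depth_frac < 1)
  if (2L * n_traps > m) {
    stop("planted_landscape: need m >= 2 * n_traps (disjoint trap ",
         "coordinate pairs certify the global minimum)", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (is.null(sigma_star)) sigma_star <- random_conformation(m)
  stopifnot(length(sigma_star) == m)

  coords_pool <- sample.int(m)
  traps <- vector("list", n_traps)
  for (t in seq_len(n_traps)) {
    ij <- coords_pool[c(2L * t - 1L, 2L * t)]
    # offsets far enough out that the in-support base energy dominates
    delta <- sample(c(-1, 1), 2L, replace = TRUE) *
      stats::runif(2L, 135, 180)
    centre <- wrap_angle(sigma_star[ij] + delta)
    base_drop <- 1 - cos(deg2rad(delta))          # per-coordinate escape gain
    box_min <- sum(1 - cos(deg2rad(abs(delta) - trap_width)))
    d_lo <- max(base_drop)                         # below: not a local min
    d_hi <- box_min                                # above: E could go negative
    traps[[t]] <- list(coords = ij, centre = centre,
                       depth = d_lo + depth_frac * (d_hi - d_lo),
                       width = trap_width)
  }

  energy <- function(sigma) {
    d <- deg2rad(wrap_angle(sigma - sigma_star))
    e <- sum(1 - cos(d))
    for (tr in traps) {
      u <- wrap_angle(sigma[tr$coords] - tr$centre) / tr$width
      if (all(abs(u) < 1)) {
        e <- e - tr$depth * prod(cos(pi * u / 2)^2)
      }
    }
    e
  }

  land <- structure(list(m = as.integer(m), sigma_star = sigma_star,
                         traps = traps, minimum = 0, energy = energy,
                         trap_width = trap_width, seed = seed),
                    class = "planted_landscape")
  # spot-check the certificate
  if (abs(energy(sigma_star)) > 1e-12) {
    stop("planted_landscape: construction failed, E(sigma_star) != 0",
         call. = FALSE)
  }
  for (tr in traps) {
    probe <- sigma_star
    probe[tr$coords] <- tr$centre
    if (energy(probe) <= 0) {
      stop("planted_landscape: construction failed, trap centre at or ",
           "below the planted minimum", call. = FALSE)
    }
  }
  land
}

#' @export
print.planted_landscape <- function(x, ...) {
  cat("<planted_landscape m=", x$m, " traps=", length(x$traps),
      " minimum=0>\n", sep = "")
  invisible(x)
}
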