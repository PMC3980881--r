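#' Load reduced-model energy parameters
#'
#' Reads the versioned parameter file (YAML key-value format) holding the
#' per-class Lennard-Jones coefficients, partial charges and dielectric,
#' torsion barriers, and hydrogen-bond 12-10 coefficients of the reduced
#' energy model. The packaged defaults are used when no path is given.
#'
#' @param path Parameter file (default: the file shipped in
#'   `inst/extdata/energy_params.yaml`).
#' @return An object of class `energy_params`.
#' @export
load_energy_params <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "energy_params.yaml", package = "cmqa")
  }
  stopifnot(file.exists(path))
  p <- yaml::read_yaml(path)
  stopifnot(p$dielectric > 0,
            all(vapply(p$lj, function(x) x$rmin > 0 && x$eps > 0,
                       logical(1))))
  structure(p, class = "energy_params")
}

# Internal: nonbonded pair table for a geometry. Excludes the anchor
# atom, 1-2 (bonded) and 1-3 (two-bond) pairs; flags donor-acceptor
# (N, O) pairs at residue separation >= 2 as hydrogen-bonding. The
# topology depends only on the instance, so [protein_energy()] computes
# it once and reuses it across evaluations.
pair_table <- function(geometry) {
  at <- geometry$atoms
  n <- nrow(at)
  keep <- which(at$class != "anchor")
  pairs <- t(utils::combn(keep, 2L))
  adj <- matrix(FALSE, n, n)
  adj[geometry$bonds] <- TRUE
  adj[geometry$bonds[, 2:1]] <- TRUE
  one3 <- (adj %*% adj) > 0
  excl <- adj[pairs] | one3[pairs]
  pairs <- pairs[!excl, , drop = FALSE]
  ci <- at$class[pairs[, 1]]; cj <- at$class[pairs[, 2]]
  sep <- abs(at$residue[pairs[, 1]] - at$residue[pairs[, 2]])
  hb <- ((ci == "N" & cj == "O") | (ci == "O" & cj == "N")) & sep >= 2
  list(pairs = pairs, class_i = ci, class_j = cj, hbond = hb)
}

#' Reduced four-component energy of a built chain
#'
#' Evaluates the surrogate force field on a `chain_geometry`:
#' \itemize{
#'   \item Lennard-Jones: sum over non-excluded pairs of
#'     A_ij / r^12 - B_ij / r^6, with A, B from per-class rmin/eps under
#'     Lorentz-Berthelot combination;
#'   \item electrostatic: sum of k q_i q_j / (D r) over the same pairs;
#'   \item torsion: sum over the enumerated dihedral variables of
#'     (U0/2)(1 + cos(n theta - theta0));
#'   \item hydrogen bond: 12-10 potential A'/r^12 - B'/r^10 over
#'     backbone N...O pairs at residue separation >= 2 (these pairs are
#'     moved out of the Lennard-Jones sum).
#' }
#' Excluded pairs are the bonded (1-2) and geminal (1-3) ones. The
#' 12-power repulsion is soft-core: it saturates at `repulsion_cap`, so
#' clashed conformations score badly but finitely, and pairs closer than
#' the clash floor are charged an additional large finite penalty rather
#' than overflowing.
#'
#' @param geometry A `chain_geometry` from [build_coordinates()].
#' @param params An `energy_params` (default: packaged constants).
#' @param .pairs Optional precomputed pair table (internal reuse).
#' @return A list with `total` and `components`
#'   (`lj`, `electrostatic`, `torsion`, `hbond`); the components sum to
#'   the total exactly.
#' @export
compute_energy <- function(geometry, params = load_energy_params(),
                           .pairs = NULL) {
  stopifnot(inherits(geometry, "chain_geometry"),
            inherits(params, "energy_params"))
  tb <- if (is.null(.pairs)) energy_tables(geometry, params) else .pairs
  xyz <- geometry$xyz
  d <- sqrt(rowSums((xyz[tb$pairs[, 1], , drop = FALSE] -
                       xyz[tb$pairs[, 2], , drop = FALSE])^2))
  clash <- d < params$clash_r_min
  d[clash] <- params$clash_r_min
  penalty <- sum(clash) * params$clash_penalty

  # soft-core: each pair term saturates at repulsion_cap, so the surface
  # stays finite (and the temperature tuning sane) inside clashes
  lj_terms <- pmin(tb$A / d^12 - tb$B / d^6, params$repulsion_cap)
  lj <- sum(lj_terms[!tb$hbond]) + penalty

  elec <- sum(tb$kqq / d)

  dh <- d[tb$hbond]
  hb <- sum(pmin(params$hbond$A / dh^12 - params$hbond$B / dh^10,
                 params$repulsion_cap))

  tor <- sum(tb$tor_U0 / 2 *
               (1 + cos(tb$tor_n * deg2rad(geometry$conformation) -
                          tb$tor_th0)))

  components <- list(lj = lj, electrostatic = elec, torsion = tor,
                     hbond = hb)
  list(total = lj + elec + tor + hb, components = components)
}

# Internal: pair table plus precomputed interaction coefficients (LJ A/B
# under Lorentz-Berthelot combination, Coulomb prefactors, hydrogen-bond
# flags) and per-variable torsion constants. Depends only on topology
# and parameters, so it is computed once per instance.
energy_tables <- function(geometry, params) {
  pt <- pair_table(geometry)
  rmin_i <- vapply(params$lj[pt$class_i], `[[`, numeric(1), "rmin")
  rmin_j <- vapply(params$lj[pt$class_j], `[[`, numeric(1), "rmin")
  eps <- sqrt(vapply(params$lj[pt$class_i], `[[`, numeric(1), "eps") *
                vapply(params$lj[pt$class_j], `[[`, numeric(1), "eps"))
  rmin <- (rmin_i + rmin_j) / 2
  pt$A <- eps * rmin^12
  pt$B <- 2 * eps * rmin^6
  q <- unlist(params$charge)
  pt$kqq <- params$coulomb_k * q[pt$class_i] * q[pt$class_j] /
    params$dielectric

  v <- geometry$instance$variables
  if (nrow(v) > 0L) {
    pt$tor_U0 <- vapply(params$torsion[v$kind], `[[`, numeric(1), "U0")
    pt$tor_n <- vapply(params$torsion[v$kind], `[[`, numeric(1), "n")
    pt$tor_th0 <- deg2rad(vapply(params$torsion[v$kind], `[[`,
                                 numeric(1), "theta0"))
  } else {
    pt$tor_U0 <- pt$tor_n <- pt$tor_th0 <- numeric(0)
  }
  pt
}

#' Energy closure for a peptide instance
#'
#' Binds an instance and parameter set into a plain energy function over
#' conformations (angle vectors), the interface the annealing engine
#' consumes. The nonbonded pair topology is computed once and reused.
#'
#' @param instance A `protein_instance`.
#' @param params An `energy_params`.
#' @return A function `sigma -> total energy`.
#' @export
protein_energy <- function(instance, params = load_energy_params()) {
  stopifnot(inherits(instance, "protein_instance"))
  force(params)
  tb <- energy_tables(build_coordinates(instance, rep(180, instance$m)),
                      params)
  function(sigma) {
    compute_energy(build_coordinates(instance, sigma), params,
                   .pairs = tb)$total
  }
}
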