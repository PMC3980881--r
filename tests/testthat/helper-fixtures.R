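# Shared fixtures: small planted landscapes and hand-made geometries used
# across the unit tests. Everything is generated in code at test time.

small_landscape <- function(m = 6, n_traps = 2, seed = 101) {
  planted_landscape(m = m, n_traps = n_traps, seed = seed)
}

# Manually assembled two-atom "geometry" for closed-form nonbonded checks.
two_atom_geometry <- function(r, class = "CA") {
  structure(list(
    xyz = rbind(c(0, 0, 0), c(r, 0, 0)),
    atoms = data.frame(residue = c(1L, 3L), name = c(class, class),
                       class = c(class, class)),
    bonds = matrix(integer(0), nrow = 0, ncol = 2),
    instance = list(variables = data.frame()),
    conformation = numeric(0)
  ), class = "chain_geometry")
}

# Random rigid transform (proper rotation + translation).
rigid_transform <- function(xyz) {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  R <- matrix(c(
    1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]),
    2 * (q[2] * q[4] + q[1] * q[3]),
    2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2),
    2 * (q[3] * q[4] - q[1] * q[2]),
    2 * (q[2] * q[4] - q[1] * q[3]), 2 * (q[3] * q[4] + q[1] * q[2]),
    1 - 2 * (q[2]^2 + q[3]^2)
  ), nrow = 3, byrow = TRUE)
  sweep(xyz %*% R, 2, stats::rnorm(3, sd = 5), "+")
}
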