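# Fixed internal geometry of the reduced chain representation.
# Bond lengths in Angstrom, bond angles in degrees; standard peptide
# values for the backbone, generic sp3 values for the pseudo side chain.
CHAIN_GEOM <- list(
  b_C_N   = 1.329,  # peptide bond (also anchor->N)
  b_N_CA  = 1.458,
  b_CA_C  = 1.525,
  b_C_O   = 1.231,
  b_CA_CB = 1.530,
  b_X     = 1.520,  # CB->X1 and X->X pseudo bonds
  a_C_N_CA  = 121.7,
  a_N_CA_C  = 111.2,
  a_CA_C_N  = 116.2,
  a_CA_C_O  = 120.8,
  a_C_CA_CB = 110.1,
  a_CA_CB_X = 114.0,
  a_X       = 114.0,
  t_CB_improper = -122.6  # dihedral N-C-CA-CB fixing the CB branch
)

# Place atom d from reference atoms a-b-c given bond |c-d|, angle b-c-d
# (degrees) and dihedral a-b-c-d (degrees). Natural-extension placement.
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- deg2rad(angle); tor <- deg2rad(torsion)
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- pracma_cross(ab, bc)
  n <- n / sqrt(sum(n^2))
  m2 <- pracma_cross(n, bc)
  # z-component negated so the placed dihedral matches the IUPAC sign
  # convention measured by dihedral_angle()
  d_local <- bond * c(-cos(ang), sin(ang) * cos(tor), -sin(ang) * sin(tor))
  c + d_local[1] * bc + d_local[2] * m2 + d_local[3] * n
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Dihedral angle defined by four points
#'
#' Signed torsion angle about the b-c axis, IUPAC sign convention,
#' returned in degrees on (-180, 180].
#'
#' @param a,b,c,d Numeric xyz coordinates (length 3).
#' @return Angle in degrees.
#' @export
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- pracma_cross(b1, b2)
  n2 <- pracma_cross(b2, b3)
  m1 <- pracma_cross(n1, b2 / sqrt(sum(b2^2)))
  wrap_angle(rad2deg(atan2(sum(m1 * n2), sum(n1 * n2))))
}

#' Build Cartesian coordinates from dihedral angles
#'
#' Torsion-driven chain extension with fixed internal geometry: starting
#' from a virtual N-terminal anchor carbon, each residue's N, CA, C, O,
#' CB (non-glycine) and one pseudo-atom per chi variable are placed
#' sequentially by natural extension from the preceding three atoms.
#' Omega torsions are held at 180 degrees when not enumerated as
#' variables. The construction is deterministic and exactly invertible:
#' measuring the torsions of the built chain returns the input angles.
#'
#' @param instance A `protein_instance`.
#' @param conformation Numeric vector of `instance$m` angles in degrees.
#' @return An object of class `chain_geometry`: `xyz` (matrix, one row
#'   per atom), `atoms` (data frame with residue index, atom name and
#'   energy class), `bonds` (two-column index matrix), plus the instance
#'   and conformation that produced it.
#' @export
build_coordinates <- function(instance, conformation) {
  stopifnot(inherits(instance, "protein_instance"))
  if (length(conformation) != instance$m) {
    stop("build_coordinates: conformation has ", length(conformation),
         " angles but the instance has m = ", instance$m, call. = FALSE)
  }
  plan <- chain_plan(instance)
  xyz <- matrix(NA_real_, nrow = nrow(plan$atoms), ncol = 3)
  xyz[1, ] <- plan$seed[1, ]
  xyz[2, ] <- plan$seed[2, ]
  xyz[3, ] <- plan$seed[3, ]
  st <- plan$steps
  atom <- st[, "atom"]; ia <- st[, "ia"]; ib <- st[, "ib"]; ic <- st[, "ic"]
  bond <- st[, "bond"]; var <- st[, "var"]
  angle <- deg2rad(st[, "angle"])
  tor <- st[, "tor0"]
  has_var <- !is.na(var)
  tor[has_var] <- tor[has_var] + conformation[var[has_var]]
  tor <- deg2rad(tor)
  for (r in seq_along(atom)) {
    a <- xyz[ia[r], ]; b <- xyz[ib[r], ]; c <- xyz[ic[r], ]
    bc <- c - b
    bc <- bc / sqrt(sum(bc * bc))
    ab <- b - a
    nn <- c(ab[2] * bc[3] - ab[3] * bc[2],
            ab[3] * bc[1] - ab[1] * bc[3],
            ab[1] * bc[2] - ab[2] * bc[1])
    nn <- nn / sqrt(sum(nn * nn))
    m2 <- c(nn[2] * bc[3] - nn[3] * bc[2],
            nn[3] * bc[1] - nn[1] * bc[3],
            nn[1] * bc[2] - nn[2] * bc[1])
    sa <- sin(angle[r])
    d_local <- bond[r] * c(-cos(angle[r]), sa * cos(tor[r]),
                           -sa * sin(tor[r]))
    xyz[atom[r], ] <- c + d_local[1] * bc + d_local[2] * m2 +
      d_local[3] * nn
  }
  structure(list(
    xyz = xyz,
    atoms = plan$atoms,
    bonds = plan$bonds,
    instance = instance,
    conformation = conformation
  ), class = "chain_geometry")
}

# Internal: the static placement program for an instance - atom table,
# bond list and one natural-extension step per atom after the three seed
# atoms. Each step records its reference atoms, bond length, bond angle
# and torsion source (a conformation variable plus offset, or a fixed
# value). Computed once per instance and cached, since only coordinates
# change between conformations.
chain_plan <- function(instance) {
  cache <- instance$cache
  if (!is.null(cache) && !is.null(cache$plan)) return(cache$plan)
  g <- CHAIN_GEOM
  n <- length(instance$residues)
  v <- instance$variables
  var_of <- function(i, kind, k = NA) {
    hit <- which(v$residue == i & v$kind == kind &
                   (is.na(k) | v$chi_index %in% k))
    if (length(hit) == 1L) hit else NA_integer_
  }

  atoms <- list(); bonds <- list(); steps <- list()
  add_atom <- function(res, name, class, bonded_to = NA) {
    i <- length(atoms) + 1L
    atoms[[i]] <<- list(residue = res, name = name, class = class)
    if (!is.na(bonded_to)) bonds[[length(bonds) + 1L]] <<- c(bonded_to, i)
    i
  }
  add_step <- function(atom, ia, ib, ic, bond, angle, var, tor0) {
    steps[[length(steps) + 1L]] <<- c(atom = atom, ia = ia, ib = ib,
                                      ic = ic, bond = bond, angle = angle,
                                      var = var, tor0 = tor0)
  }

  # N-terminal anchor: a virtual carbonyl carbon that gives residue 1 a
  # measurable phi; it carries no nonbonded interactions.
  i_anchor <- add_atom(0L, "C0", "anchor")
  i_N <- add_atom(1L, "N", "N", i_anchor)
  i_CA <- add_atom(1L, "CA", "CA", i_N)
  seed <- rbind(
    c(0, 0, 0),
    c(g$b_C_N, 0, 0),
    c(g$b_C_N + g$b_N_CA * cos(pi - deg2rad(g$a_C_N_CA)),
      g$b_N_CA * sin(pi - deg2rad(g$a_C_N_CA)), 0)
  )

  prevC <- i_anchor  # atom playing the role of C(i-1) for phi
  for (i in seq_len(n)) {
    res <- instance$residues[i]
    if (i > 1L) {
      i_N_new <- add_atom(i, "N", "N", prevC)
      add_step(i_N_new, i_Nprev, i_CAprev, prevC, g$b_C_N, g$a_CA_C_N,
               var_of(i - 1L, "psi"), 0)
      i_CA_new <- add_atom(i, "CA", "CA", i_N_new)
      add_step(i_CA_new, i_CAprev, prevC, i_N_new, g$b_N_CA, g$a_C_N_CA,
               var_of(i - 1L, "omega"), 0)
      i_N <- i_N_new; i_CA <- i_CA_new
    }
    i_C <- add_atom(i, "C", "C", i_CA)
    add_step(i_C, prevC, i_N, i_CA, g$b_CA_C, g$a_N_CA_C,
             var_of(i, "phi"), 0)
    # carbonyl O is anti to the next N, so psi is realized even at the
    # C-terminus where no next residue exists
    i_O <- add_atom(i, "O", "O", i_C)
    add_step(i_O, i_N, i_CA, i_C, g$b_C_O, g$a_CA_C_O,
             var_of(i, "psi"), 180)
    if (res != "G") {
      i_CB <- add_atom(i, "CB", "CB", i_CA)
      add_step(i_CB, i_N, i_C, i_CA, g$b_CA_CB, g$a_C_CA_CB,
               NA_integer_, g$t_CB_improper)
      n_chi <- if ("chi" %in% instance$angle_set) CHI_COUNTS[[res]] else 0L
      chain <- c(i_N, i_CA, i_CB)
      for (k in seq_len(n_chi)) {
        len <- length(chain)
        i_X <- add_atom(i, paste0("X", k), "X", chain[len])
        add_step(i_X, chain[len - 2L], chain[len - 1L], chain[len],
                 g$b_X, if (k == 1L) g$a_CA_CB_X else g$a_X,
                 var_of(i, "chi", k), 0)
        chain <- c(chain, i_X)
      }
    }
    i_Nprev <- i_N; i_CAprev <- i_CA; prevC <- i_C
  }

  st <- do.call(rbind, steps)
  # fixed fallbacks: torsions without a driving variable default to 180
  # (trans), except those with an explicit offset already encoding it
  fixed <- is.na(st[, "var"]) & st[, "tor0"] %in% c(0, 180)
  st[fixed, "tor0"] <- wrap_angle(st[fixed, "tor0"] + 180)
  plan <- list(
    atoms = data.frame(
      residue = vapply(atoms, `[[`, integer(1), "residue"),
      name = vapply(atoms, `[[`, character(1), "name"),
      class = vapply(atoms, `[[`, character(1), "class")
    ),
    bonds = do.call(rbind, bonds),
    steps = st,
    seed = seed
  )
  if (!is.null(cache)) cache$plan <- plan
  plan
}

#' @export
print.chain_geometry <- function(x, ...) {
  cat("<chain_geometry ", x$instance$sequence, ": ", nrow(x$xyz),
      " atoms, ", nrow(x$bonds), " bonds>\n", sep = "")
  invisible(x)
}

#' Measure the dihedral variables of a built chain
#'
#' Reads every enumerated dihedral back off the Cartesian coordinates
#' using the four defining atoms (phi of residue 1 uses the N-terminal
#' anchor; psi of the last residue is recovered from the carbonyl
#' oxygen). The inverse of [build_coordinates()] on torsion space.
#'
#' @param geometry A `chain_geometry`.
#' @return Numeric vector of `m` angles in degrees, in variable order.
#' @export
measure_torsions <- function(geometry) {
  stopifnot(inherits(geometry, "chain_geometry"))
  inst <- geometry$instance
  at <- geometry$atoms
  xyz <- geometry$xyz
  idx <- function(res, name) {
    which(at$residue == res & at$name == name)[1]
  }
  n <- length(inst$residues)
  v <- inst$variables
  out <- numeric(nrow(v))
  for (r in seq_len(nrow(v))) {
    i <- v$residue[r]
    out[r] <- switch(v$kind[r],
      phi = {
        prev <- if (i == 1L) idx(0L, "C0") else idx(i - 1L, "C")
        dihedral_angle(xyz[prev, ], xyz[idx(i, "N"), ],
                       xyz[idx(i, "CA"), ], xyz[idx(i, "C"), ])
      },
      psi = {
        if (i < n) {
          dihedral_angle(xyz[idx(i, "N"), ], xyz[idx(i, "CA"), ],
                         xyz[idx(i, "C"), ], xyz[idx(i + 1L, "N"), ])
        } else {
          wrap_angle(dihedral_angle(xyz[idx(i, "N"), ], xyz[idx(i, "CA"), ],
                                    xyz[idx(i, "C"), ],
                                    xyz[idx(i, "O"), ]) - 180)
        }
      },
      omega = dihedral_angle(xyz[idx(i, "CA"), ], xyz[idx(i, "C"), ],
                             xyz[idx(i + 1L, "N"), ],
                             xyz[idx(i + 1L, "CA"), ]),
      chi = {
        k <- v$chi_index[r]
        chain_names <- c("N", "CA", "CB", paste0("X", seq_len(k)))
        ids <- vapply(utils::tail(chain_names, 4L),
                      function(nm) idx(i, nm), integer(1))
        dihedral_angle(xyz[ids[1], ], xyz[ids[2], ], xyz[ids[3], ],
                       xyz[ids[4], ])
      }
    )
  }
  out
}
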