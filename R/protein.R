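# Side-chain torsion counts per residue (1-letter code). The convention
# counts the dihedral axes along the longest heavy-atom side chain and
# includes the terminal hydroxyl/thiol/methyl/amine rotor for side chains
# with more than one torsion axis; ring-terminated chains (F, W, H, Y ring)
# contribute their standard two ring-approach torsions, with Y adding the
# hydroxyl rotor. Under this table and backbone phi/psi at every residue
# (omega held rigid), the Met-enkephalin pentapeptide YGGFM has
# 10 + (3+0+0+2+4) = 19 variables.
CHI_COUNTS <- c(
  G = 0L, A = 0L, P = 0L, V = 1L,
  L = 2L, I = 2L, C = 2L, S = 2L, T = 2L,
  F = 2L, W = 2L, H = 2L, D = 2L, N = 2L,
  Y = 3L, E = 3L, Q = 3L,
  M = 4L, K = 5L, R = 5L
)

#' Enumerate the dihedral variables of a peptide
#'
#' Maps an amino-acid sequence to the ordered list of dihedral variables
#' that span its conformational search space. Backbone phi and psi are
#' counted at every residue, including the termini (the builder anchors
#' the N-terminus with a virtual carbonyl carbon and realizes the
#' C-terminal psi through the carbonyl oxygen, so both terminal angles
#' are geometrically meaningful). Omega angles exist between consecutive
#' residues and are held rigid at 180 degrees unless "omega" is
#' requested. Side-chain chi counts follow the package's per-residue
#' table (see the example).
#'
#' @param sequence Amino-acid string in 1-letter code.
#' @param angle_set Which angle kinds are free variables; any subset of
#'   `c("phi", "psi", "omega", "chi")` (default: omega-fixed).
#' @return An object of class `protein_instance` with fields `sequence`,
#'   `variables` (data frame: residue, kind, chi_index) and `m`.
#' @examples
#' enumerate_variables("YGGFM")$m  # 19, the Met-enkephalin dimension
#' @export
enumerate_variables <- function(sequence, angle_set = c("phi", "psi", "chi")) {
  stopifnot(is.character(sequence), length(sequence) == 1L,
            nzchar(sequence))
  angle_set <- match.arg(angle_set, c("phi", "psi", "omega", "chi"),
                         several.ok = TRUE)
  res <- strsplit(toupper(sequence), "")[[1]]
  unknown <- which(!res %in% names(CHI_COUNTS))
  if (length(unknown) > 0L) {
    stop("enumerate_variables: unknown residue code '", res[unknown[1]],
         "' at position ", unknown[1], call. = FALSE)
  }
  n <- length(res)
  rows <- list()
  for (i in seq_len(n)) {
    if ("phi" %in% angle_set) {
      rows[[length(rows) + 1L]] <- data.frame(residue = i, kind = "phi",
                                              chi_index = NA_integer_)
    }
    if ("psi" %in% angle_set) {
      rows[[length(rows) + 1L]] <- data.frame(residue = i, kind = "psi",
                                              chi_index = NA_integer_)
    }
    if ("omega" %in% angle_set && i < n) {
      rows[[length(rows) + 1L]] <- data.frame(residue = i, kind = "omega",
                                              chi_index = NA_integer_)
    }
    if ("chi" %in% angle_set) {
      for (k in seq_len(CHI_COUNTS[[res[i]]])) {
        rows[[length(rows) + 1L]] <- data.frame(residue = i, kind = "chi",
                                                chi_index = k)
      }
    }
  }
  variables <- if (length(rows)) do.call(rbind, rows) else
    data.frame(residue = integer(0), kind = character(0),
               chi_index = integer(0))
  structure(list(sequence = paste(res, collapse = ""), residues = res,
                 variables = variables, m = nrow(variables),
                 angle_set = angle_set,
                 cache = new.env(parent = emptyenv())),
            class = "protein_instance")
}

#' @export
print.protein_instance <- function(x, ...) {
  cat("<protein_instance ", x$sequence, ": n=", length(x$residues),
      " residues, m=", x$m, " variables (",
      paste(x$angle_set, collapse = "/"), ")>\n", sep = "")
  invisible(x)
}
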