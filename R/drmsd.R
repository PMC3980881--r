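#' Distance RMSD between two structures
#'
#' Superposition-free similarity measure: the root-mean-square deviation
#' between the intramolecular pairwise-distance sets of two structures,
#' \deqn{dRMSD = \sqrt{\frac{2}{N(N-1)} \sum_{i<j} (d^A_{ij} - d^B_{ij})^2}.}
#' Because only internal distances enter, the value is invariant under
#' rigid motion and reflection of either structure and symmetric in its
#' arguments. By default the comparison runs over CA atoms.
#'
#' @param a,b Structures: `chain_geometry` objects or plain N x 3
#'   coordinate matrices (N >= 3, equal in both).
#' @param atoms Atom-name selection applied to `chain_geometry` inputs
#'   (default "CA"; NULL selects every non-anchor atom).
#' @return The dRMSD (same length units as the coordinates).
#' @examples
#' tri <- function(d12, d13, d23) {
#'   x2 <- (d12^2 + d13^2 - d23^2) / (2 * d12)
#'   rbind(c(0, 0, 0), c(d12, 0, 0), c(x2, sqrt(d13^2 - x2^2), 0))
#' }
#' drmsd(tri(3, 4, 5), tri(3, 4, 6))  # sqrt(1/3)
#' @export
drmsd <- function(a, b, atoms = "CA") {
  ca <- drmsd_coords(a, atoms)
  cb <- drmsd_coords(b, atoms)
  if (nrow(ca) != nrow(cb)) {
    stop("drmsd: structures have different atom counts (",
         nrow(ca), " vs ", nrow(cb), ")", call. = FALSE)
  }
  if (nrow(ca) < 3L) {
    stop("drmsd: need at least 3 atoms", call. = FALSE)
  }
  da <- stats::dist(ca)
  db <- stats::dist(cb)
  sqrt(mean((da - db)^2))
}

drmsd_coords <- function(x, atoms) {
  if (inherits(x, "chain_geometry")) {
    sel <- if (is.null(atoms)) x$atoms$class != "anchor" else
      x$atoms$name %in% atoms
    return(x$xyz[sel, , drop = FALSE])
  }
  x <- as.matrix(x)
  if (ncol(x) != 3L) {
    stop("drmsd: coordinate matrices must have 3 columns", call. = FALSE)
  }
  x
}
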