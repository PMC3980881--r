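#' Wrap angles into the canonical interval
#'
#' All dihedral angles in the package live on the half-open interval
#' (-180, 180] degrees. Wrapping is the only place the convention is
#' enforced; every operator that modifies an angle routes through it.
#'
#' @param a Numeric vector of angles in degrees.
#' @return Numeric vector of the same length with every element in
#'   (-180, 180].
#' @examples
#' wrap_angle(c(181, -180, 360, 179 + 2))
#' @export
wrap_angle <- function(a) {
  stopifnot(is.numeric(a))
  w <- a %% 360
  w[w > 180] <- w[w > 180] - 360
  w
}

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi
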