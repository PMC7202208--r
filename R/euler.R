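#' Rotation matrix from a Z-X-Z Euler triplet
#'
#' Builds the 3x3 rotation matrix for an intrinsic Z-X-Z Euler triplet
#' `(tdrot, tilt, narot)` in degrees, the convention used throughout the
#' particle tables of this package: first a rotation by `tdrot` about z,
#' then by `tilt` about the new x, then by `narot` about the new z. The
#' matrix acts on column vectors, `R = Rz(tdrot) %*% Rx(tilt) %*% Rz(narot)`.
#'
#' @param tdrot,tilt,narot Euler angles in degrees. `tdrot` may also be a
#'   length-3 vector holding all three angles.
#' @return A 3x3 orthonormal rotation matrix with determinant +1.
#' @examples
#' euler_matrix(0, 0, 0)            # identity
#' euler_matrix(c(90, 45, -90))
#' @export
euler_matrix <- function(tdrot, tilt = NULL, narot = NULL) {
  if (length(tdrot) == 3L && is.null(tilt)) {
    tilt <- tdrot[2L]; narot <- tdrot[3L]; tdrot <- tdrot[1L]
  }
  stopifnot(is.finite(tdrot), is.finite(tilt), is.finite(narot))
  rot_z(tdrot) %*% rot_x(tilt) %*% rot_z(narot)
}

rot_z <- function(a) {
  a <- a * pi / 180
  c <- cos(a); s <- sin(a)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3L, 3L)
}

rot_x <- function(a) {
  a <- a * pi / 180
  c <- cos(a); s <- sin(a)
  matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3L, 3L)
}

#' Geodesic angle between two rotations
#'
#' Angular distance (degrees) between two rotations given as 3x3 matrices or
#' Euler triplets. With `symmetry = "C4"` the distance is taken over the
#' four-fold quotient: the minimum over in-plane rotations of the second pose
#' by multiples of 90 degrees, so that poses equivalent under the particle's
#' C4 symmetry compare as equal.
#'
#' @param a,b Rotation matrices or length-3 Euler triplets (degrees).
#' @param symmetry `"C1"` (default) or `"C4"`.
#' @return Geodesic angle in degrees, in `[0, 180]`.
#' @export
geodesic_angle <- function(a, b, symmetry = c("C1", "C4")) {
  symmetry <- match.arg(symmetry)
  if (!is.matrix(a)) a <- euler_matrix(a)
  if (!is.matrix(b)) b <- euler_matrix(b)
  ang1 <- function(Ra, Rb) {
    ctheta <- (sum(diag(crossprod(Ra, Rb))) - 1) / 2
    acos(min(1, max(-1, ctheta))) * 180 / pi
  }
  if (symmetry == "C1") return(ang1(a, b))
  # C4 about z acts on the reference: pose R is equivalent to R %*% Rz(90 k)
  min(vapply(c(0, 90, 180, 270), function(k) ang1(a, b %*% rot_z(k)),
             numeric(1)))
}

#' Canonicalize the in-plane angle under C4 symmetry
#'
#' Reduces `narot` to the canonical sector `[0, 90)` degrees; with C4 applied
#' to the reference, poses differing by 90-degree in-plane rotations score
#' identically, so the canonical representative is reported.
#'
#' @param narot In-plane angle(s) in degrees.
#' @return Angle(s) in `[0, 90)`.
#' @export
canonical_inplane_c4 <- function(narot) {
  narot %% 90
}

# Deterministic per-stage seed derived from a global seed and a stage name.
# Keeps every stage's randomness on a named substream of one user seed and
# stays below 2^31 - 1.
stage_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 48271 + h * 7919) %% 2147483647)
}
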