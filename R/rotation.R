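#' @name conventions
#' @title Coordinate and sign conventions
#' @description
#' One laboratory frame is used everywhere: axis 1 vertical (up positive),
#' axis 2 mediolateral (left positive), axis 3 anteroposterior (anterior
#' positive), in meters. This matches the smartphone channel semantics
#' (device X vertical, Y mediolateral, Z anteroposterior for the sacral
#' landscape mounting), so both sensor branches share one frame and one sign
#' table.
#'
#' Pelvic angles are stored in degrees with fixed signs for right-leg stance
#' (contralateral = left): positive transverse = forward contralateral
#' rotation (left hemipelvis moves anteriorly), positive frontal =
#' contralateral pelvic drop (left side moves down), positive sagittal =
#' anterior pelvic tilt (top of the pelvis moves forward).
#'
#' Rotations compose intrinsically in the order transverse (about vertical)
#' -> frontal (about anteroposterior) -> sagittal (about mediolateral). Both
#' the simulator's rendering and the marker-based decomposition use this one
#' convention, so ground-truth recovery is exact by construction.
NULL

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Pelvic rotation matrix from the three plane angles
#'
#' Builds the 3x3 rotation matrix (lab frame, axes vertical/mediolateral/
#' anteroposterior) for angles given in degrees under the package sign
#' convention (see [conventions]).
#'
#' @param transverse,frontal,sagittal angles in degrees.
#' @return 3x3 rotation matrix.
#' @export
pelvic_rotation <- function(transverse = 0, frontal = 0, sagittal = 0) {
  r <- rotation_components(deg2rad(transverse), deg2rad(frontal), deg2rad(sagittal))
  matrix(c(r$r11, r$r21, r$r31,
           r$r12, r$r22, r$r32,
           r$r13, r$r23, r$r33), 3L, 3L)
}

# Vectorised entries of R = Rx(a) %*% Rz(b) %*% Ry(-c) for angle vectors in
# radians, where x = vertical, z = anteroposterior, y = mediolateral and the
# sagittal rotation is sign-flipped so +c tilts the pelvis top anteriorly.
rotation_components <- function(a, b, cc) {
  ca <- cos(a); sa <- sin(a)
  cb <- cos(b); sb <- sin(b)
  cg <- cos(cc); sg <- sin(cc)
  list(
    r11 = cb * cg,
    r12 = -sb,
    r13 = -cb * sg,
    r21 = ca * sb * cg - sa * sg,
    r22 = ca * cb,
    r23 = -ca * sb * sg - sa * cg,
    r31 = sa * sb * cg + ca * sg,
    r32 = sa * cb,
    r33 = -sa * sb * sg + ca * cg
  )
}

#' Euler decomposition of a pelvic rotation
#'
#' Inverse of [pelvic_rotation()]: recovers (transverse, frontal, sagittal)
#' in degrees from a rotation matrix. Valid for |frontal| < 90 degrees, far
#' beyond the physiological range of the tasks studied here.
#'
#' @param R 3x3 rotation matrix.
#' @return named numeric vector of the three angles in degrees.
#' @export
pelvic_angles_from_rotation <- function(R) {
  c(transverse = rad2deg(atan2(R[3, 2], R[2, 2])),
    frontal    = rad2deg(asin(max(-1, min(1, -R[1, 2])))),
    sagittal   = rad2deg(atan2(-R[1, 3], R[1, 1])))
}

# Vectorised decomposition from the 9 entry-vectors of per-sample rotation
# matrices (as produced by frame construction); returns a data.frame in deg.
angles_from_components <- function(r) {
  data.frame(
    transverse = rad2deg(atan2(r$r32, r$r22)),
    frontal    = rad2deg(asin(pmax(-1, pmin(1, -r$r12)))),
    sagittal   = rad2deg(atan2(-r$r13, r$r11))
  )
}
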