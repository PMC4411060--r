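cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(v) sqrt(sum(v^2))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero vector", call. = FALSE)
  v / n
}

#' Torsion (dihedral) angle of four points
#'
#' Returns the torsion angle p1-p2-p3-p4 in degrees in `(-180, 180]` under
#' the IUPAC sign convention (looking from p2 towards p3, a clockwise
#' rotation of the far bond is positive; the cis/eclipsed arrangement is 0).
#' This is the angle used for the Fe2-O-Cn-Cm orientation predictor.
#'
#' @param p1,p2,p3,p4 Numeric length-3 coordinate vectors, Angstrom.
#' @return Angle in degrees in `(-180, 180]`.
#' @export
torsion <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (vnorm(n1) < 1e-10 || vnorm(n2) < 1e-10) {
    stop("collinear points: torsion undefined", call. = FALSE)
  }
  m1 <- cross3(n1, unit(b2))
  ang <- atan2(-sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  wrap_angle(ang)
}

#' Wrap an angle in degrees to (-180, 180]
#'
#' @param theta Angle(s) in degrees.
#' @return Wrapped angle(s).
#' @export
wrap_angle <- function(theta) {
  w <- theta - 360 * floor((theta + 180) / 360)
  ifelse(w == -180, 180, w)
}

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues rotation by `angle` degrees about the axis direction `axis`
#' (through the origin); proper rotation, right-handed.
#'
#' @param axis Numeric length-3 axis direction (need not be unit).
#' @param angle Rotation angle, degrees.
#' @return 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle) {
  u <- unit(axis)
  a <- angle * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

#' Place an atom from internal coordinates
#'
#' NeRF-style placement: given three positions `a`, `b`, `c`, returns the
#' point at distance `bond` from `c`, with angle `angle` (degrees) at `c`
#' relative to `b`, and torsion `dihedral` (degrees) for a-b-c-new.
#'
#' @param a,b,c Numeric length-3 coordinates.
#' @param bond Distance from `c`, Angstrom.
#' @param angle Angle b-c-new, degrees.
#' @param dihedral Torsion a-b-c-new, degrees.
#' @return Numeric length-3 coordinates of the new point.
#' @export
place_internal <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- dihedral * pi / 180
  bc <- unit(c - b)
  n <- unit(cross3(b - a, bc))
  m <- cross3(n, bc)
  # sign on the n component chosen so torsion(a, b, c, new) == dihedral
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(dih),
          bond * sin(ang) * sin(dih))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation + translation minimizing the RMSD between
#' paired atoms of two structures; reflections are never returned, so
#' mirror-image selections superpose with nonzero residual. The RMSD is
#' computed over the selection only.
#'
#' @param mobile,reference `arenium_structure` objects.
#' @param selection Two-column integer matrix (or data frame) of paired atom
#'   serials, `cbind(mobile_serial, reference_serial)`; at least 3
#'   non-collinear pairs.
#' @return A list of class `rigid_transform` with elements `rotation` (3x3),
#'   `translation` (length 3), and `rmsd` (Angstrom, over the selection).
#' @export
superpose <- function(mobile, reference, selection) {
  selection <- as.matrix(selection)
  if (nrow(selection) < 3) {
    stop("superposition needs at least 3 paired atoms", call. = FALSE)
  }
  im <- match(selection[, 1], mobile$atoms$serial)
  ir <- match(selection[, 2], reference$atoms$serial)
  if (anyNA(im) || anyNA(ir)) {
    stop("selection refers to serials absent from a structure", call. = FALSE)
  }
  P <- coords_matrix(mobile)[im, , drop = FALSE]
  Q <- coords_matrix(reference)[ir, , drop = FALSE]
  cp <- colMeans(P)
  cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp)
  Qc <- sweep(Q, 2, cq)
  H <- t(Pc) %*% Qc
  sv <- svd(H)
  if (sv$d[2] < 1e-10) {
    stop("degenerate (collinear) superposition selection", call. = FALSE)
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- cq - as.numeric(R %*% cp)
  moved <- Pc %*% t(R) - Qc
  out <- list(rotation = R, translation = tr,
              rmsd = sqrt(mean(rowSums(moved^2))))
  class(out) <- "rigid_transform"
  out
}

#' Apply a rigid transform to a structure
#'
#' @param structure An `arenium_structure`.
#' @param transform A `rigid_transform` from [superpose()].
#' @return The transformed structure.
#' @export
apply_transform <- function(structure, transform) {
  xyz <- coords_matrix(structure) %*% t(transform$rotation)
  xyz <- sweep(xyz, 2, transform$translation, "+")
  set_coords(structure, xyz)
}

#' Validate a rigid transform
#'
#' Checks that the rotation is proper (determinant +1) and orthonormal
#' within `1e-9`.
#'
#' @param transform A `rigid_transform`.
#' @return `TRUE` invisibly, or an error.
#' @export
validate_transform <- function(transform) {
  R <- transform$rotation
  if (abs(det(R) - 1) > 1e-9) stop("rotation is not proper", call. = FALSE)
  if (max(abs(t(R) %*% R - diag(3))) > 1e-9) {
    stop("rotation is not orthonormal", call. = FALSE)
  }
  invisible(TRUE)
}
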