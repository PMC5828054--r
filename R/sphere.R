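#' Spherical coordinate conventions
#'
#' Throughout the package a direction on the unit sphere is parameterized by
#' an azimuth `theta`, measured in the x-y plane from +x toward +y, and an
#' elevation `phi`, measured from the x-y plane toward +z. So
#' `(theta, phi) = (0, 0)` is the +x axis and `(0, pi/2)` is the +z axis.
#' Canonical ranges are `theta` in `[0, 2*pi)` and `phi` in `[-pi/2, pi/2]`;
#' the trigonometric map to Cartesian coordinates is smooth and periodic, so
#' angles outside those ranges still address the correct point on the sphere.
#'
#' @name sphere-coordinates
NULL

#' Normalize spherical angles to their canonical ranges
#'
#' Reflects the elevation back into `[-pi/2, pi/2]` (a step across a pole
#' shifts the azimuth by pi) and reduces the azimuth modulo `2*pi`.
#'
#' @param angles numeric vector `c(theta, phi)` or an n x 2 matrix.
#' @return object of the same shape with canonical angles.
#' @export
wrap_angles <- function(angles) {
  a <- .as_angle_matrix(angles)
  theta <- a[, 1]
  phi <- a[, 2]
  # reduce phi to [-pi, pi), then reflect |phi| > pi/2 across the pole
  phi <- ((phi + pi) %% (2 * pi)) - pi
  hi <- phi > pi / 2
  theta[hi] <- theta[hi] + pi
  phi[hi] <- pi - phi[hi]
  lo <- phi < -pi / 2
  theta[lo] <- theta[lo] + pi
  phi[lo] <- -pi - phi[lo]
  theta <- theta %% (2 * pi)
  out <- cbind(theta = theta, phi = phi)
  if (is.null(dim(angles)) && length(angles) == 2L) out <- out[1L, ] else out
}

.as_angle_matrix <- function(angles) {
  if (is.null(dim(angles))) {
    stopifnot(length(angles) %% 2L == 0L)
    matrix(angles, ncol = 2L, byrow = length(angles) == 2L)
  } else {
    stopifnot(ncol(angles) == 2L)
    as.matrix(angles)
  }
}

.as_direction_matrix <- function(v) {
  if (is.null(dim(v))) {
    stopifnot(length(v) %% 3L == 0L)
    matrix(v, ncol = 3L, byrow = length(v) == 3L)
  } else {
    stopifnot(ncol(v) == 3L)
    as.matrix(v)
  }
}

#' Convert spherical angles to unit vectors
#'
#' @param angles `c(theta, phi)` or an n x 2 matrix of azimuth/elevation in
#'   radians.
#' @return a unit vector `c(x, y, z)` (or n x 3 matrix):
#'   `(cos(phi) cos(theta), cos(phi) sin(theta), sin(phi))`.
#' @export
#' @examples
#' sph_to_unit(c(0, 0))        # +x axis
#' sph_to_unit(c(0, pi / 2))   # +z axis
sph_to_unit <- function(angles) {
  a <- .as_angle_matrix(angles)
  u <- cbind(
    x = cos(a[, 2]) * cos(a[, 1]),
    y = cos(a[, 2]) * sin(a[, 1]),
    z = sin(a[, 2])
  )
  if (is.null(dim(angles)) && length(angles) == 2L) u[1L, ] else u
}

#' Convert unit vectors to spherical angles
#'
#' Inverse of [sph_to_unit()]. At the poles (`|z| = 1`) the azimuth is
#' undefined and returned as 0 by convention.
#'
#' @param v unit vector `c(x, y, z)` or an n x 3 matrix of unit rows.
#' @param tol tolerance on the Euclidean norm check.
#' @return `c(theta, phi)` (or n x 2 matrix) with `theta` in `[0, 2*pi)` and
#'   `phi` in `[-pi/2, pi/2]`.
#' @export
unit_to_sph <- function(v, tol = 1e-6) {
  u <- .as_direction_matrix(v)
  nrm <- sqrt(rowSums(u^2))
  if (any(abs(nrm - 1) > tol)) {
    stop("unit_to_sph: input is not a unit direction (norm deviates from 1 by ",
         format(max(abs(nrm - 1))), ")")
  }
  z <- pmin(1, pmax(-1, u[, 3]))
  phi <- asin(z)
  theta <- atan2(u[, 2], u[, 1]) %% (2 * pi)
  theta[abs(z) >= 1 - 1e-12] <- 0 # pole convention
  out <- cbind(theta = theta, phi = phi)
  if (is.null(dim(v)) && length(v) == 3L) out[1L, ] else out
}

#' Arc angle between two directions, in degrees
#'
#' With `antipodal = TRUE` (the default) the angle is computed on the
#' projective sphere, `acos(|u . v|)` in `[0, 90]` degrees, appropriate for
#' ODF peaks which are sign-indeterminate. With `antipodal = FALSE` the plain
#' great-circle angle `acos(u . v)` in `[0, 180]` degrees is returned.
#'
#' @param u,v unit vectors (length 3) or conformable n x 3 matrices.
#' @param antipodal logical; fold antipodes together?
#' @return angle(s) in degrees.
#' @export
arc_angle <- function(u, v, antipodal = TRUE) {
  a <- .as_direction_matrix(u)
  b <- .as_direction_matrix(v)
  if (nrow(a) == 1L && nrow(b) > 1L) a <- a[rep(1L, nrow(b)), , drop = FALSE]
  if (nrow(b) == 1L && nrow(a) > 1L) b <- b[rep(1L, nrow(a)), , drop = FALSE]
  d <- rowSums(a * b)
  if (antipodal) d <- abs(d)
  ang <- acos(pmin(1, pmax(-1, d))) * 180 / pi
  if (is.null(dim(u)) && is.null(dim(v)) && length(u) == 3L && length(v) == 3L) {
    ang[1L]
  } else {
    ang
  }
}

#' Map directions to the canonical hemisphere
#'
#' ODF peaks come in antipodal pairs; one representative is reported, chosen
#' with `z > 0`, or `z = 0` and `y > 0`, or `(+1, 0, 0)` for the x axis.
#'
#' @param v unit vector or n x 3 matrix.
#' @param tol tolerance for treating a component as zero.
#' @return same shape, with each direction possibly negated.
#' @export
hemisphere <- function(v, tol = 1e-6) {
  u <- .as_direction_matrix(v)
  flip <- u[, 3] < -tol |
    (abs(u[, 3]) <= tol & u[, 2] < -tol) |
    (abs(u[, 3]) <= tol & abs(u[, 2]) <= tol & u[, 1] < 0)
  u[flip, ] <- -u[flip, , drop = FALSE]
  if (is.null(dim(v)) && length(v) == 3L) u[1L, ] else u
}

# shortest signed angular difference, wrapped to [-pi, pi)
.wrap_diff <- function(d) ((d + pi) %% (2 * pi)) - pi

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
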