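## Exact SO(3)/SE(3) primitives.
##
## Internal convention: angles in radians, rotations as 3x3 matrices with
## R^T R = I and det(R) = +1. The stored rotation of a particle maps the
## canonical (reference) frame onto the particle, so the relative pose of a
## neighbor (w2, p2) seen from a query (w1, p1) is (w1^T w2, w1^T (p2 - p1)).
## Axis-angle sign convention: angle in [0, pi]; at angle pi the axis sign is
## fixed by making its first nonzero component positive.

#' Elementary rotations
#'
#' Rotation matrices about the coordinate axes. Angles are given in degrees
#' (the cryo-ET community convention for user-facing interfaces).
#'
#' @param angle rotation angle in degrees.
#' @return a 3x3 rotation matrix.
#' @examples
#' rotZ(90) %*% c(1, 0, 0)  # maps +x to +y
#' @export
rotX <- function(angle) {
  a <- radians(angle); c <- cos(a); s <- sin(a)
  matrix(c(1, 0, 0, 0, c, -s, 0, s, c), 3, 3, byrow = TRUE)
}

#' @rdname rotX
#' @export
rotY <- function(angle) {
  a <- radians(angle); c <- cos(a); s <- sin(a)
  matrix(c(c, 0, s, 0, 1, 0, -s, 0, c), 3, 3, byrow = TRUE)
}

#' @rdname rotX
#' @export
rotZ <- function(angle) {
  a <- radians(angle); c <- cos(a); s <- sin(a)
  matrix(c(c, -s, 0, s, c, 0, 0, 0, 1), 3, 3, byrow = TRUE)
}

#' Rotation about an arbitrary axis
#'
#' @param axis 3-vector (normalized internally).
#' @param angle rotation angle in degrees.
#' @return a 3x3 rotation matrix.
#' @export
rotAxis <- function(axis, angle) {
  expSO3(.unitize(axis, "axis") * radians(angle))
}

#' Validate a rotation matrix
#'
#' Checks orthogonality (\code{R^T R = I}) and \code{det(R) = 1} within
#' tolerance.
#'
#' @param m a 3x3 matrix.
#' @param tol numeric tolerance (default 1e-10).
#' @return \code{TRUE} invisibly; otherwise an error naming the failing
#'   invariant.
#' @export
validateRotation <- function(m, tol = 1e-10) {
  if (!is.matrix(m) || any(dim(m) != c(3, 3)) || !is.numeric(m))
    stop("rotation must be a numeric 3x3 matrix")
  if (max(abs(crossprod(m) - diag(3))) > tol)
    stop("matrix is not orthogonal (R^T R != I within tolerance ", tol, ")")
  if (abs(det(m) - 1) > tol)
    stop("matrix has det != 1 within tolerance ", tol,
         " (improper rotation or scaling)")
  invisible(TRUE)
}

#' @rdname validateRotation
#' @export
isRotation <- function(m, tol = 1e-10) {
  is.matrix(m) && all(dim(m) == c(3, 3)) && is.numeric(m) &&
    max(abs(crossprod(m) - diag(3))) <= tol && abs(det(m) - 1) <= tol
}

#' Rigid motion constructor
#'
#' A rigid motion is a pair (rotation, translation) in SE(3); translations
#' carry the length unit of the particle list they come from.
#'
#' @param rotation 3x3 rotation matrix.
#' @param translation numeric 3-vector.
#' @return an object of class \code{"RigidMotion"} (a validated list).
#' @export
rigidMotion <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  validateRotation(rotation)
  stopifnot(is.numeric(translation), length(translation) == 3L)
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "RigidMotion")
}

#' Compose and invert rigid motions
#'
#' \code{composeMotion(a, b)} returns the motion a * b (first apply b);
#' \code{invertMotion(a)} returns the inverse motion.
#'
#' @param a,b \code{RigidMotion} objects.
#' @return a \code{RigidMotion}.
#' @export
composeMotion <- function(a, b) {
  rigidMotion(a$rotation %*% b$rotation,
              as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' @rdname composeMotion
#' @export
invertMotion <- function(a) {
  rigidMotion(t(a$rotation), as.numeric(-t(a$rotation) %*% a$translation))
}

#' Relative pose of a neighbor in the query's canonical frame
#'
#' Applies the inverse of the query motion to the neighbor:
#' \code{(w1, p1)^-1 (w2, p2) = (w1^T w2, w1^T (p2 - p1))}. The result is
#' invariant under left-composition of both inputs with any common rigid
#' motion, which is the root of the rotational invariance of all descriptors
#' in this package.
#'
#' @param query,neighbor \code{RigidMotion} objects (or lists with
#'   \code{rotation} and \code{translation}).
#' @return a \code{RigidMotion}: the neighbor's pose with the query aligned
#'   to the canonical orientation at the origin.
#' @export
relativePose <- function(query, neighbor) {
  validateRotation(query$rotation)
  validateRotation(neighbor$rotation)
  rigidMotion(
    crossprod(query$rotation, neighbor$rotation),
    as.numeric(crossprod(query$rotation,
                         neighbor$translation - query$translation)))
}

#' Rotation matrix logarithm
#'
#' Returns the axis-angle vector \code{log(r)} (the \dQuote{vee} of the
#' skew-symmetric matrix logarithm) with norm in [0, pi]. Near the identity a
#' first-order skew extraction is used; near angle pi the axis is recovered
#' from the symmetric part \code{(r + I)/2} with the sign fixed by the first
#' nonzero axis component being positive, so that the result is never NaN.
#'
#' @param r a 3x3 rotation matrix.
#' @return numeric 3-vector (radians times unit axis).
#' @export
logSO3 <- function(r) {
  as.numeric(.logRows(.rotToRows(r)))
}

## Vectorized log: rows = M x 9 row-major rotations -> M x 3 zeta.
.logRows <- function(rows) {
  m <- nrow(rows)
  tr <- rows[, 1] + rows[, 5] + rows[, 9]
  ct <- .clamp1((tr - 1) / 2)
  theta <- acos(ct)
  ## skew part (r32 - r23, r13 - r31, r21 - r12)
  sk <- cbind(rows[, 8] - rows[, 6], rows[, 3] - rows[, 7],
              rows[, 4] - rows[, 2])
  out <- matrix(0, m, 3)
  small <- theta < 1e-7
  nearpi <- theta > pi - 5e-4
  mid <- !small & !nearpi
  if (any(mid)) {
    f <- theta[mid] / (2 * sin(theta[mid]))
    out[mid, ] <- sk[mid, , drop = FALSE] * f
  }
  if (any(small)) {
    ## first-order: log(R) ~ skew part / 2
    out[small, ] <- sk[small, , drop = FALSE] / 2
  }
  if (any(nearpi)) {
    idx <- which(nearpi)
    for (k in idx) {
      out[k, ] <- .logNearPi(rows[k, ], theta[k], sk[k, ])
    }
  }
  out
}

## Stable log for theta near pi: the symmetric part of R is
## cos(theta) I + (1 - cos(theta)) a a^T, so the axis is recovered from it
## without contamination by the skew part; the axis sign comes from the
## skew part when informative, otherwise first nonzero component positive.
.logNearPi <- function(row, theta, sk) {
  R <- matrix(row, 3, 3, byrow = TRUE)
  S <- (R + t(R)) / 2
  ct <- (sum(diag(R)) - 1) / 2
  d <- pmax(diag(S) - ct, 0)  # (1 - cos theta) * a_i^2
  a <- sqrt(d)
  i <- which.max(a)
  if (a[i] < 1e-12) return(c(0, 0, 0))  # cannot happen for a rotation
  for (j in setdiff(1:3, i)) {
    ## S[i, j] = (1 - cos theta) a_i a_j determines relative signs
    a[j] <- S[i, j] / a[i]
  }
  a <- a / .vnorm(a)
  if (.vnorm(sk) > 1e-9) {
    if (sum(a * sk) < 0) a <- -a
  } else {
    nz <- which(abs(a) > 1e-12)[1]
    if (a[nz] < 0) a <- -a
  }
  a * theta
}

#' Rotation matrix exponential
#'
#' Rodrigues' formula mapping an axis-angle vector back to SO(3); inverse of
#' \code{\link{logSO3}}.
#'
#' @param zeta numeric 3-vector (radians times axis).
#' @return a 3x3 rotation matrix.
#' @export
expSO3 <- function(zeta) {
  theta <- .vnorm(zeta)
  K <- matrix(c(0, -zeta[3], zeta[2],
                zeta[3], 0, -zeta[1],
                -zeta[2], zeta[1], 0), 3, 3, byrow = TRUE)
  if (theta < 1e-8) return(diag(3) + K + K %*% K / 2)
  diag(3) + sin(theta) / theta * K + (1 - cos(theta)) / theta^2 * (K %*% K)
}

#' Geodesic (angular) distance on SO(3)
#'
#' The rotation angle of \code{r1^T r2}, i.e. \code{||log(r1^T r2)||}, in
#' radians, in [0, pi]. Symmetric and bi-invariant.
#'
#' @param r1,r2 3x3 rotation matrices.
#' @return angle in radians.
#' @export
angularDistance <- function(r1, r2) {
  tr <- sum(diag(crossprod(r1, r2)))
  acos(.clamp1((tr - 1) / 2))
}

#' Twist vector of a particle pair
#'
#' The twist vector encodes the relative pose of a neighbor in the query's
#' canonical frame: the rotational part \code{zeta = log(w1^T w2)} (radians
#' times unit axis) and the positional part \code{trans = w1^T (p2 - p1)}
#' (length units). \code{||trans||} is the Euclidean inter-particle distance
#' and \code{||zeta||} the angular distance of the orientations.
#'
#' @param query,neighbor \code{RigidMotion} objects.
#' @return a list of class \code{"TwistVector"} with elements \code{zeta}
#'   and \code{trans}.
#' @export
twistFromPair <- function(query, neighbor) {
  rel <- relativePose(query, neighbor)
  if (.vnorm(rel$translation) < 1e-12)
    stop("zero-distance pair: a particle cannot be its own neighbor")
  structure(list(zeta = logSO3(rel$rotation), trans = rel$translation),
            class = "TwistVector")
}

#' Swing-twist decomposition
#'
#' Splits a rotation into an in-plane part about a given axis and a cone
#' (swing) part with zero twist about that axis, so that
#' \code{r = cone \%*\% rotAxis(axis, degrees(angle))}.
#'
#' When the rotation maps the axis to its negative (gimbal-degenerate case)
#' the twist angle is reported as 0 by convention and \code{degenerate} is
#' set.
#'
#' @param r a 3x3 rotation matrix.
#' @param axis unit 3-vector.
#' @return list with \code{angle} (radians, in (-pi, pi]), \code{cone} (3x3
#'   rotation) and \code{degenerate} (logical).
#' @export
swingTwist <- function(r, axis) {
  axis <- .unitize(axis, "axis")
  q <- .quatFromRot(r)
  d <- sum(q[2:4] * axis)
  degenerate <- FALSE
  if (abs(q[1]) < 1e-12 && abs(d) < 1e-12) {
    ## rotation by pi about an axis perpendicular to `axis`
    degenerate <- TRUE
    angle <- 0
  } else {
    angle <- 2 * atan2(d, q[1])
  }
  ## wrap to (-pi, pi]
  angle <- angle - 2 * pi * floor((angle + pi) / (2 * pi))
  if (angle <= -pi) angle <- angle + 2 * pi
  cone <- r %*% t(expSO3(axis * angle))
  list(angle = angle, cone = cone, degenerate = degenerate)
}

## unit quaternion (w, x, y, z) with w >= 0 from a rotation matrix
.quatFromRot <- function(r) {
  tr <- r[1, 1] + r[2, 2] + r[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (r[3, 2] - r[2, 3]) / s, (r[1, 3] - r[3, 1]) / s,
           (r[2, 1] - r[1, 2]) / s)
  } else if (r[1, 1] > r[2, 2] && r[1, 1] > r[3, 3]) {
    s <- sqrt(1 + r[1, 1] - r[2, 2] - r[3, 3]) * 2
    q <- c((r[3, 2] - r[2, 3]) / s, 0.25 * s, (r[1, 2] + r[2, 1]) / s,
           (r[1, 3] + r[3, 1]) / s)
  } else if (r[2, 2] > r[3, 3]) {
    s <- sqrt(1 + r[2, 2] - r[1, 1] - r[3, 3]) * 2
    q <- c((r[1, 3] - r[3, 1]) / s, (r[1, 2] + r[2, 1]) / s, 0.25 * s,
           (r[2, 3] + r[3, 2]) / s)
  } else {
    s <- sqrt(1 + r[3, 3] - r[1, 1] - r[2, 2]) * 2
    q <- c((r[2, 1] - r[1, 2]) / s, (r[1, 3] + r[3, 1]) / s,
           (r[2, 3] + r[3, 2]) / s, 0.25 * s)
  }
  if (q[1] < 0) q <- -q
  q / .vnorm(q)
}

## vectorized in-plane (twist about +z) angle of rotations given row-major
## rows; radians in (-pi, pi]. Twist quaternion component about z:
## angle = 2 atan2(q_z, q_w); computed without forming full quaternions:
## q_w^2 = (1 + tr)/4, q_w q_z = (r21 - r12)/4 -> atan2(r21 - r12, 1 + tr)
## (valid when 1 + tr > 0 or skew nonzero; degenerate pi-rotations about an
## in-plane axis get angle from the alternative quaternion branch).
.inplaneAngles <- function(rows) {
  num <- rows[, 4] - rows[, 2]
  den <- 1 + rows[, 1] + rows[, 5] + rows[, 9]
  ang <- 2 * atan2(num, den)
  bad <- den < 1e-9 & abs(num) < 1e-9
  if (any(bad)) {
    for (k in which(bad)) {
      ang[k] <- swingTwist(matrix(rows[k, ], 3, 3, byrow = TRUE),
                           c(0, 0, 1))$angle
    }
  }
  ang <- ang - 2 * pi * floor((ang + pi) / (2 * pi))
  ang[ang <= -pi] <- ang[ang <= -pi] + 2 * pi
  ang
}

#' Project a matrix to the nearest rotation
#'
#' Orthogonal Procrustes projection via SVD: for \code{m = U S V^T} returns
#' \code{U V^T}, with the sign of the last column of U flipped if needed so
#' that the determinant is +1. Idempotent on rotations; used by the noise
#' corruption model to turn perturbed matrices back into valid rotations.
#'
#' @param m a 3x3 matrix of full numerical rank.
#' @return a 3x3 rotation matrix.
#' @export
projectToSO3 <- function(m) {
  stopifnot(is.matrix(m), all(dim(m) == c(3, 3)))
  sv <- svd(m)
  if (sv$d[3] < 1e-12 * max(sv$d[1], 1))
    stop("matrix is numerically rank-deficient; no unique nearest rotation")
  r <- sv$u %*% t(sv$v)
  if (det(r) < 0) {
    u <- sv$u
    u[, 3] <- -u[, 3]
    r <- u %*% t(sv$v)
  }
  r
}

#' Euler angle conversions
#'
#' \code{eulerZYZToMatrix} composes intrinsic z-y'-z'' Euler angles
#' (the Relion \code{rot}, \code{tilt}, \code{psi} convention) into a
#' rotation matrix \code{Rz(rot) Ry(tilt) Rz(psi)}; \code{matrixToEulerZYZ}
#' inverts it. \code{eulerZXZToMatrix} composes the TOM/AV3 motive-list
#' angles \code{phi}, \code{psi}, \code{theta} as
#' \code{Rz(psi) Rx(theta) Rz(phi)}; \code{matrixToEulerZXZ} inverts it.
#' All angles are in degrees.
#'
#' @param rot,tilt,psi,phi,theta Euler angles in degrees (vectorized).
#' @param r a 3x3 rotation matrix.
#' @return a 3x3xN rotation array, or a named numeric vector of angles.
#' @export
eulerZYZToMatrix <- function(rot, tilt, psi) {
  n <- max(length(rot), length(tilt), length(psi))
  rot <- rep_len(radians(rot), n); tilt <- rep_len(radians(tilt), n)
  psi <- rep_len(radians(psi), n)
  c1 <- cos(rot); s1 <- sin(rot); c2 <- cos(tilt); s2 <- sin(tilt)
  c3 <- cos(psi); s3 <- sin(psi)
  out <- array(0, c(3, 3, n))
  out[1, 1, ] <- c1 * c2 * c3 - s1 * s3
  out[1, 2, ] <- -c1 * c2 * s3 - s1 * c3
  out[1, 3, ] <- c1 * s2
  out[2, 1, ] <- s1 * c2 * c3 + c1 * s3
  out[2, 2, ] <- -s1 * c2 * s3 + c1 * c3
  out[2, 3, ] <- s1 * s2
  out[3, 1, ] <- -s2 * c3
  out[3, 2, ] <- s2 * s3
  out[3, 3, ] <- c2
  out
}

#' @rdname eulerZYZToMatrix
#' @export
matrixToEulerZYZ <- function(r) {
  ct <- .clamp1(r[3, 3])
  tilt <- acos(ct)
  if (abs(sin(tilt)) > 1e-9) {
    rot <- atan2(r[2, 3], r[1, 3])
    psi <- atan2(r[3, 2], -r[3, 1])
  } else {
    ## tilt = 0 or pi: only rot +/- psi determined; put it all in rot
    rot <- atan2(r[2, 1], r[1, 1]) * sign(ct + 0.5)
    if (ct < 0) rot <- atan2(-r[2, 1], -r[1, 1])
    psi <- 0
  }
  c(rot = degrees(rot), tilt = degrees(tilt), psi = degrees(psi))
}

#' @rdname eulerZYZToMatrix
#' @export
eulerZXZToMatrix <- function(phi, psi, theta) {
  n <- max(length(phi), length(psi), length(theta))
  phi <- rep_len(radians(phi), n); psi <- rep_len(radians(psi), n)
  theta <- rep_len(radians(theta), n)
  c1 <- cos(psi); s1 <- sin(psi); c2 <- cos(theta); s2 <- sin(theta)
  c3 <- cos(phi); s3 <- sin(phi)
  ## Rz(psi) Rx(theta) Rz(phi)
  out <- array(0, c(3, 3, n))
  out[1, 1, ] <- c1 * c3 - s1 * c2 * s3
  out[1, 2, ] <- -c1 * s3 - s1 * c2 * c3
  out[1, 3, ] <- s1 * s2
  out[2, 1, ] <- s1 * c3 + c1 * c2 * s3
  out[2, 2, ] <- -s1 * s3 + c1 * c2 * c3
  out[2, 3, ] <- -c1 * s2
  out[3, 1, ] <- s2 * s3
  out[3, 2, ] <- s2 * c3
  out[3, 3, ] <- c2
  out
}

#' @rdname eulerZYZToMatrix
#' @export
matrixToEulerZXZ <- function(r) {
  ct <- .clamp1(r[3, 3])
  theta <- acos(ct)
  if (abs(sin(theta)) > 1e-9) {
    psi <- atan2(r[1, 3], -r[2, 3])
    phi <- atan2(r[3, 1], r[3, 2])
  } else {
    phi <- if (ct > 0) atan2(r[2, 1], r[1, 1]) else atan2(-r[2, 1], r[1, 1])
    psi <- 0
  }
  c(phi = degrees(phi), psi = degrees(psi), theta = degrees(theta))
}

#' Random rotations
#'
#' Uniform (Haar) random rotations via normalized quaternions; seeded by the
#' caller's RNG state.
#'
#' @param n number of rotations.
#' @return a 3x3xN array.
#' @export
randomRotations <- function(n) {
  q <- matrix(stats::rnorm(4 * n), n, 4)
  q <- q / .rownorm(q)
  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  out <- array(0, c(3, 3, n))
  out[1, 1, ] <- 1 - 2 * (y^2 + z^2)
  out[1, 2, ] <- 2 * (x * y - z * w)
  out[1, 3, ] <- 2 * (x * z + y * w)
  out[2, 1, ] <- 2 * (x * y + z * w)
  out[2, 2, ] <- 1 - 2 * (x^2 + z^2)
  out[2, 3, ] <- 2 * (y * z - x * w)
  out[3, 1, ] <- 2 * (x * z - y * w)
  out[3, 2, ] <- 2 * (y * z + x * w)
  out[3, 3, ] <- 1 - 2 * (x^2 + y^2)
  out
}
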