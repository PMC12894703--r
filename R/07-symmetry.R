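## Symmetry-ambiguity-free angular score.
##
## A particle with Cn or platonic-solid symmetry has several rotation
## matrices representing the same physical orientation. Instead of
## comparing all representative pairs, orientations act on the vertex set
## of the geometric object fixed by the symmetry group (a regular n-gon on
## the circle for Cn, the solid's vertices on the sphere otherwise); the
## dissimilarity delta_V of two orientations is the spherical Hausdorff
## distance between the two transported vertex sets, and the angular score
## is 1 - delta_V / m_V with m_V the maximal attainable displacement.

#' SymmetryRep class
#'
#' Geometric representative of a symmetry group: the vertex set it fixes,
#' plus (for platonic solids) a reference orientation re-seating the
#' canonical vertex set onto the user's data. For cyclic groups the score
#' is independent of the representative n-gon; the canonical solids are
#' oriented with a vertex at +z.
#'
#' @slot kind "cyclic", "tetrahedron", "cube", "octahedron",
#'   "dodecahedron" or "icosahedron".
#' @slot n fold order (cyclic only; 0 otherwise).
#' @slot vertices k x 2 matrix of unit vectors on the circle (cyclic) or
#'   k x 3 on the sphere (solids).
#' @slot referenceOrientation rotation applied to the canonical vertex set
#'   (solids only).
#' @exportClass SymmetryRep
setClass("SymmetryRep",
         representation(kind = "character", n = "integer",
                        vertices = "matrix",
                        referenceOrientation = "matrix"))

setValidity("SymmetryRep", function(object) {
  msgs <- character(0)
  nrm <- .rownorm(object@vertices)
  if (any(abs(nrm - 1) > 1e-12))
    msgs <- c(msgs, "all vertices must have unit norm")
  if (object@kind == "cyclic") {
    if (object@n < 2L) msgs <- c(msgs, "cyclic symmetry requires n >= 2")
    ang <- atan2(object@vertices[, 2], object@vertices[, 1])
    want <- sort((ang[1] + 2 * pi * (seq_len(object@n) - 1) /
                    object@n) %% (2 * pi))
    if (max(abs(sort(ang %% (2 * pi)) - want)) > 1e-9)
      msgs <- c(msgs, "cyclic vertices must be the n-th roots of unity")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "SymmetryRep", function(object) {
  cat(sprintf("SymmetryRep: %s%s (%d vertices), m_V = %.4f deg\n",
              object@kind, if (object@kind == "cyclic")
                paste0("(", object@n, ")") else "",
              nrow(object@vertices),
              degrees(maxDisplacement(object))))
  invisible(NULL)
})

#' Cyclic symmetry representative
#'
#' Regular n-gon inscribed in the unit circle. The symmetry axis is fixed
#' to the intrinsic z-axis; rotations are reduced to their in-plane part
#' about z before scoring (the cone part is discarded).
#'
#' @param n fold order (>= 2).
#' @param offset_angle rotation of the vertex set in degrees (the score is
#'   provably independent of it; exposed for testing that invariance).
#' @return a \code{\link{SymmetryRep}}.
#' @examples
#' degrees(maxDisplacement(cyclicRep(5)))  # 36 degrees
#' @export
cyclicRep <- function(n, offset_angle = 0) {
  stopifnot(n >= 2L)
  ang <- radians(offset_angle) + 2 * pi * (seq_len(n) - 1) / n
  new("SymmetryRep", kind = "cyclic", n = as.integer(n),
      vertices = cbind(cos(ang), sin(ang)),
      referenceOrientation = diag(3))
}

.solidVertices <- function(kind) {
  phi <- (1 + sqrt(5)) / 2
  v <- switch(kind,
    tetrahedron = rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1),
                        c(-1, -1, 1)),
    cube = as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1))),
    octahedron = rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                       c(0, 0, 1), c(0, 0, -1)),
    icosahedron = {
      m <- rbind(c(0, 1, phi), c(0, 1, -phi), c(0, -1, phi),
                 c(0, -1, -phi))
      rbind(m, m[, c(3, 1, 2)], m[, c(2, 3, 1)])
    },
    dodecahedron = {
      m <- rbind(c(0, 1 / phi, phi), c(0, 1 / phi, -phi),
                 c(0, -1 / phi, phi), c(0, -1 / phi, -phi))
      rbind(as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1))),
            m, m[, c(3, 1, 2)], m[, c(2, 3, 1)])
    },
    stop("unknown platonic solid '", kind, "'"))
  v <- unname(as.matrix(v))
  v / .rownorm(v)
}

## rotation taking unit vector v onto +z
.rotateToZ <- function(v) {
  z <- c(0, 0, 1)
  c_ <- sum(v * z)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) return(rotX(180))
  axis <- .unitize(c(v[2] * z[3] - v[3] * z[2],
                     v[3] * z[1] - v[1] * z[3],
                     v[1] * z[2] - v[2] * z[1]))
  expSO3(axis * acos(.clamp1(c_)))
}

#' Platonic-solid symmetry representative
#'
#' Vertex set of the solid inscribed in the unit sphere, oriented with one
#' vertex at +z; a user-supplied reference orientation re-seats the set to
#' fit the data (for solids, unlike the cyclic case, the score depends on
#' the representative's orientation).
#'
#' @param kind "tetrahedron", "cube", "octahedron", "dodecahedron" or
#'   "icosahedron".
#' @param reference_orientation 3x3 rotation acting on the vertex set.
#' @return a \code{\link{SymmetryRep}}.
#' @export
solidRep <- function(kind = c("tetrahedron", "cube", "octahedron",
                              "dodecahedron", "icosahedron"),
                     reference_orientation = diag(3)) {
  kind <- match.arg(kind)
  validateRotation(reference_orientation)
  v <- .solidVertices(kind)
  v <- v %*% t(.rotateToZ(v[which.max(v[, 3]), ]))
  v <- v %*% t(reference_orientation)
  v <- v / .rownorm(v)  # keep unit norm exact against rounding
  new("SymmetryRep", kind = kind, n = 0L, vertices = v,
      referenceOrientation = reference_orientation)
}

## in-plane angle of a rotation about +z (cone part discarded)
.inplaneOf <- function(r) swingTwist(r, c(0, 0, 1))$angle

## circular distance on S^1
.circDist <- function(a, b) {
  d <- abs(a - b) %% (2 * pi)
  pmin(d, 2 * pi - d)
}

## symmetric Hausdorff between two transported vertex sets
.hausdorffCyclic <- function(rep, a1, a2) {
  m <- max(length(a1), length(a2))
  a1 <- rep_len(a1, m); a2 <- rep_len(a2, m)
  v1 <- outer(a1, atan2(rep@vertices[, 2], rep@vertices[, 1]), "+")
  v2 <- outer(a2, atan2(rep@vertices[, 2], rep@vertices[, 1]), "+")
  ## directed max-min in both directions, vectorized over pairs
  n <- rep@n
  dmin12 <- matrix(Inf, length(a1), n)
  for (j in seq_len(n))
    dmin12 <- pmin(dmin12, .circDist(v1, v2[, j]))
  d12 <- apply(dmin12, 1, max)
  dmin21 <- matrix(Inf, length(a1), n)
  for (j in seq_len(n))
    dmin21 <- pmin(dmin21, .circDist(v2, v1[, j]))
  d21 <- apply(dmin21, 1, max)
  pmax(d12, d21)
}

.hausdorffSolid <- function(v1, v2) {
  g <- acos(.clamp1(v1 %*% t(v2)))
  max(max(apply(g, 1, min)), max(apply(g, 2, min)))
}

#' Orientation dissimilarity under a symmetry group
#'
#' The symmetric Hausdorff distance (great-circle metric) between the
#' vertex sets of the symmetry representative transported by the two
#' rotations. It vanishes exactly when the orientations agree modulo the
#' symmetry group, is invariant under common left rotation, and for cyclic
#' groups is independent of the chosen representative n-gon.
#'
#' @param rep a \code{\link{SymmetryRep}}.
#' @param r1,r2 3x3 rotation matrices.
#' @return dissimilarity in radians, in [0, m_V].
#' @export
deltaV <- function(rep, r1, r2) {
  if (rep@kind == "cyclic") {
    .hausdorffCyclic(rep, .inplaneOf(r1), .inplaneOf(r2))
  } else {
    .hausdorffSolid(rep@vertices %*% t(r1), rep@vertices %*% t(r2))
  }
}

.mvCache <- new.env(parent = emptyenv())

#' Maximal vertex displacement of a symmetry representative
#'
#' The normalization constant m_V at which the angular score reaches 0.
#' For cyclic groups this is exactly pi/n (half the central angle of the
#' n-gon). For platonic solids it is found numerically: by bi-invariance
#' the double maximization over rotation pairs reduces to maximizing
#' delta_V(identity, w); a deterministic Euler grid of more than 10^4
#' rotations is refined by Nelder-Mead in axis-angle coordinates, and the
#' result is cached for the session.
#'
#' @param rep a \code{\link{SymmetryRep}}.
#' @return m_V in radians.
#' @export
maxDisplacement <- function(rep) {
  if (rep@kind == "cyclic") return(pi / rep@n)
  key <- paste(rep@kind,
               paste(signif(rep@referenceOrientation, 12), collapse = ","))
  if (!is.null(.mvCache[[key]])) return(.mvCache[[key]])
  V <- rep@vertices
  f <- function(zeta) .hausdorffSolid(V, V %*% t(expSO3(zeta)))
  ## deterministic grid: 24 x 18 x 24 ZYZ Euler angles (> 10^4 rotations)
  best <- 0; bestz <- c(0, 0, 0)
  a_grid <- 2 * pi * (seq_len(24) - 0.5) / 24
  b_grid <- acos(seq(-1, 1, length.out = 18))
  for (a in a_grid) for (b in b_grid) for (g in a_grid) {
    w <- eulerZYZToMatrix(degrees(a), degrees(b), degrees(g))[, , 1]
    d <- .hausdorffSolid(V, V %*% t(w))
    if (d > best) { best <- d; bestz <- logSO3(w) }
  }
  opt <- stats::optim(bestz, f, control = list(fnscale = -1,
                                               reltol = 1e-12,
                                               maxit = 2000))
  out <- max(best, opt$value)
  .mvCache[[key]] <- out
  out
}

#' Angular score
#'
#' Normalized symmetry-aware orientation similarity:
#' \code{1 - delta_V / m_V}, in [0, 1]. A score of 1 means the two
#' orientations agree modulo the symmetry group; 0 means maximal
#' disagreement (for C5, a vertex displacement of 36 degrees).
#'
#' @param rep a \code{\link{SymmetryRep}}.
#' @param r1,r2 3x3 rotation matrices.
#' @return score in [0, 1].
#' @examples
#' angularScore(cyclicRep(6), rotZ(0), rotZ(60))   # 1: same orientation mod C6
#' angularScore(cyclicRep(6), rotZ(0), rotZ(10))   # 1 - 10/30
#' @export
angularScore <- function(rep, r1, r2) {
  1 - deltaV(rep, r1, r2) / maxDisplacement(rep)
}

#' Angular scores for all records of a descriptor
#'
#' Vectorized scoring of every (query, neighbor) pair. For cyclic
#' representatives the stored in-plane angles of the two particles are
#' used (their cone parts are irrelevant by construction); for solids the
#' relative rotation is rebuilt from the twist vector.
#'
#' @param rep a \code{\link{SymmetryRep}}.
#' @param td a \code{\link{TwistDescriptor}} (or its record table).
#' @return numeric vector of scores, one per record.
#' @export
scoreRecords <- function(rep, td) {
  rec <- if (is(td, "TwistDescriptor")) td@records else td
  if (!nrow(rec)) return(numeric(0))
  if (rep@kind == "cyclic") {
    d <- .hausdorffCyclic(rep, rec$inplane_query, rec$inplane_neighbor)
  } else {
    z <- as.matrix(rec[, c("zeta_x", "zeta_y", "zeta_z")])
    d <- vapply(seq_len(nrow(z)), function(k)
      .hausdorffSolid(rep@vertices,
                      rep@vertices %*% t(expSO3(z[k, ]))), numeric(1))
  }
  1 - d / maxDisplacement(rep)
}

#' Scan candidate cyclic symmetries
#'
#' Computes the distribution of per-pair angular scores under the
#' assumption of Cn symmetry for a range of n, optionally restricted to
#' first-shell pairs. The best candidate is the n with the highest median
#' score (ties broken toward the smallest n) and is compared against every
#' other candidate with the two-sided Mann-Whitney rank-sum test. A scene
#' in which every candidate scores 1 (e.g. all orientations identical) is
#' flagged as degenerate.
#'
#' @param td a \code{\link{TwistDescriptor}}.
#' @param n_range candidate fold orders (subset of 2..12).
#' @param shells optional \code{ShellDecomposition}; when given only
#'   shell-1 pairs are scored.
#' @return list with \code{table} (per-n medians, quartiles, U, p),
#'   \code{best_n}, \code{scores} (list of score vectors), and
#'   \code{degenerate}.
#' @export
symmetryScan <- function(td, n_range = 2:10, shells = NULL) {
  stopifnot(all(n_range >= 2), all(n_range <= 12))
  rec <- td@records
  if (!is.null(shells)) {
    if (length(shells$assignment) != nrow(rec))
      stop("shell decomposition does not match this descriptor")
    rec <- rec[!is.na(shells$assignment) & shells$assignment == 1L, ,
               drop = FALSE]
  }
  if (nrow(rec) < 2L) stop("symmetry scan needs at least 2 pairs")
  scores <- lapply(n_range, function(n) scoreRecords(cyclicRep(n), rec))
  names(scores) <- as.character(n_range)
  med <- vapply(scores, stats::median, numeric(1))
  best_i <- which(med == max(med))[1]  # tie -> smallest n (sorted range)
  q <- vapply(scores, function(s)
    stats::quantile(s, c(.25, .75), names = FALSE), numeric(2))
  U <- p <- rep(NA_real_, length(n_range))
  for (k in seq_along(n_range)) {
    if (k == best_i) next
    rs <- rankSumTest(scores[[best_i]], scores[[k]])
    U[k] <- rs$U; p[k] <- rs$p
  }
  degenerate <- all(vapply(scores, function(s) all(s > 1 - 1e-9),
                           logical(1)))
  if (degenerate)
    warning("all candidate symmetries score 1; orientations are ",
            "degenerate (identical modulo every candidate)")
  list(table = data.frame(n = n_range, n_pairs = nrow(rec), median = med,
                          q25 = q[1, ], q75 = q[2, ], U = U, p = p),
       best_n = n_range[best_i], scores = scores, degenerate = degenerate)
}
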