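## Synthetic quasi-spherical lattice with fivefold defects.

#' Generate a geodesic shell lattice (synthetic capsid analogue)
#'
#' Subdivides each face of an icosahedron at the given frequency and
#' projects the vertices onto a sphere, producing a closed hexagonal
#' lattice containing exactly 12 fivefold vertices (pentamers) among
#' sixfold ones -- the canonical geometry of icosahedral capsids and a
#' stand-in for the pentamer-bearing lattices of retroviral cores. Each
#' particle is oriented with intrinsic +z along the outward surface normal
#' and a deterministic tangent x-axis. Ground-truth class labels
#' ("pentamer"/"hexamer") are set from the construction.
#'
#' @param frequency subdivision frequency (>= 2); the shell has
#'   \code{10 * frequency^2 + 2} vertices.
#' @param radius sphere radius in nm.
#' @return a \code{\link{ParticleList}}.
#' @export
generateGeodesicShell <- function(frequency = 4L, radius = 50) {
  stopifnot(frequency >= 2L, radius > 0)
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / .rownorm(v)
  faces <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11),
                 c(1, 11, 12), c(2, 6, 10), c(6, 12, 5), c(12, 11, 3),
                 c(11, 8, 7), c(8, 2, 9), c(4, 10, 5), c(4, 5, 3),
                 c(4, 3, 7), c(4, 7, 9), c(4, 9, 10), c(5, 10, 6),
                 c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  f <- frequency
  key_env <- new.env(parent = emptyenv())
  pts <- list()
  addPoint <- function(p) {
    p <- p / .vnorm(p)
    key <- paste(round(p, 9), collapse = ",")
    if (is.null(key_env[[key]])) {
      pts[[length(pts) + 1L]] <<- p
      key_env[[key]] <- length(pts)
    }
    key_env[[key]]
  }
  for (fc in seq_len(nrow(faces))) {
    A <- v[faces[fc, 1], ]; B <- v[faces[fc, 2], ]; C <- v[faces[fc, 3], ]
    for (i in 0:f) for (j in 0:(f - i)) {
      k <- f - i - j
      addPoint((i * A + j * B + k * C) / f)
    }
  }
  pos_unit <- do.call(rbind, pts)
  n <- nrow(pos_unit)
  rot <- array(0, c(3, 3, n))
  for (kk in seq_len(n)) {
    z <- pos_unit[kk, ]
    ref <- if (abs(z[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    x <- .unitize(c(ref[2] * z[3] - ref[3] * z[2],
                    ref[3] * z[1] - ref[1] * z[3],
                    ref[1] * z[2] - ref[2] * z[1]))
    y <- c(z[2] * x[3] - z[3] * x[2], z[3] * x[1] - z[1] * x[3],
           z[1] * x[2] - z[2] * x[1])
    rot[, , kk] <- cbind(x, y, z)
  }
  ## pentamers are the 12 original icosahedron vertices
  is_pent <- logical(n)
  for (kk in seq_len(12)) {
    d2 <- rowSums(sweep(pos_unit, 2, v[kk, ])^2)
    is_pent[which.min(d2)] <- TRUE
  }
  particleList(pos_unit * radius, rot,
               class_label = ifelse(is_pent, "pentamer", "hexamer"),
               unit = "nm",
               provenance = list(generator = "geodesic_shell",
                                 frequency = f, radius = radius))
}
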