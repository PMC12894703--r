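## ParticleList: the central container for oriented particles.

#' ParticleList class
#'
#' Container for a set of oriented particles: positions (in the list's
#' length unit), orientations as rotation matrices mapping the canonical
#' reference frame onto each particle, integer identifiers, and optional
#' per-particle score, object affiliation and ground-truth class label.
#'
#' @slot position numeric N x 3 matrix of positions.
#' @slot rotation 3x3xN array of rotation matrices.
#' @slot particleID integer vector, unique non-negative ids.
#' @slot tomoID integer vector, tomogram of each particle.
#' @slot objectID integer vector (NA when unaffiliated).
#' @slot score numeric vector (NA when absent).
#' @slot classLabel character vector (NA when absent); ground-truth tag for
#'   synthetic data.
#' @slot unit length unit, one of "nm", "angstrom", "voxel".
#' @slot pixelSize numeric, Angstrom per voxel; required when unit is
#'   "voxel".
#' @slot provenance list describing the source (format, file, generator
#'   parameters, ground-truth bookkeeping).
#'
#' @exportClass ParticleList
setClass("ParticleList",
  representation(position = "matrix", rotation = "array",
                 particleID = "integer", tomoID = "integer",
                 objectID = "integer", score = "numeric",
                 classLabel = "character", unit = "character",
                 pixelSize = "numeric", provenance = "list"))

setValidity("ParticleList", function(object) {
  n <- nrow(object@position)
  msgs <- character(0)
  if (ncol(object@position) != 3L) msgs <- c(msgs, "position must be N x 3")
  dr <- dim(object@rotation)
  if (length(dr) != 3L || dr[1] != 3L || dr[2] != 3L || dr[3] != n)
    msgs <- c(msgs, "rotation must be a 3x3xN array matching positions")
  for (sl in c("particleID", "tomoID", "objectID", "score", "classLabel"))
    if (length(slot(object, sl)) != n)
      msgs <- c(msgs, sprintf("%s must have length %d", sl, n))
  if (anyDuplicated(object@particleID))
    msgs <- c(msgs, "particle ids must be unique within a list")
  if (any(object@particleID < 0L, na.rm = TRUE))
    msgs <- c(msgs, "particle ids must be >= 0")
  if (!object@unit %in% c("nm", "angstrom", "voxel"))
    msgs <- c(msgs, "unit must be one of nm, angstrom, voxel")
  if (object@unit == "voxel" &&
      (length(object@pixelSize) != 1L || is.na(object@pixelSize) ||
       object@pixelSize <= 0))
    msgs <- c(msgs, "unit 'voxel' requires a positive pixelSize")
  if (n > 1L) {
    key <- paste(object@tomoID, object@position[, 1], object@position[, 2],
                 object@position[, 3])
    if (anyDuplicated(key))
      msgs <- c(msgs, "two particles share an identical (tomo, position)")
  }
  if (n > 0L) {
    ## spot-check orthogonality on a bounded sample to keep validity cheap
    idx <- unique(round(seq(1L, n, length.out = min(n, 25L))))
    for (k in idx) {
      if (!isRotation(object@rotation[, , k], tol = 1e-8))
        msgs <- c(msgs, sprintf("rotation %d is not a valid rotation", k))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a ParticleList
#'
#' @param position numeric N x 3 matrix (or 3-vector for a single particle).
#' @param rotation 3x3xN array, a single 3x3 matrix, or NULL for identity
#'   orientations.
#' @param particle_id,tomo_id,object_id integer vectors (recycled); particle
#'   ids default to 1..N, tomo ids to 1, object ids to NA.
#' @param score,class_label optional per-particle score / label.
#' @param unit "nm" (default), "angstrom" or "voxel".
#' @param pixel_size Angstrom per voxel (required for unit "voxel").
#' @param provenance list of provenance metadata.
#' @return a \code{ParticleList}.
#' @examples
#' pl <- particleList(rbind(c(0, 0, 0), c(5, 0, 0)))
#' nParticles(pl)
#' @export
particleList <- function(position, rotation = NULL, particle_id = NULL,
                         tomo_id = 1L, object_id = NA_integer_,
                         score = NA_real_, class_label = NA_character_,
                         unit = "nm", pixel_size = NA_real_,
                         provenance = list()) {
  if (is.null(dim(position))) position <- matrix(position, ncol = 3)
  position <- as.matrix(position)
  storage.mode(position) <- "double"
  dimnames(position) <- NULL
  n <- nrow(position)
  if (is.null(rotation)) rotation <- array(diag(3), c(3, 3, n))
  if (length(dim(rotation)) == 2L) rotation <- array(rotation, c(3, 3, n))
  if (is.null(particle_id)) particle_id <- seq_len(n)
  new("ParticleList", position = position, rotation = rotation,
      particleID = as.integer(particle_id),
      tomoID = rep_len(as.integer(tomo_id), n),
      objectID = rep_len(as.integer(object_id), n),
      score = rep_len(as.numeric(score), n),
      classLabel = rep_len(as.character(class_label), n),
      unit = unit, pixelSize = as.numeric(pixel_size),
      provenance = provenance)
}

#' @rdname particleList
#' @param x,object a \code{ParticleList}.
#' @export
nParticles <- function(x) nrow(x@position)

#' ParticleList accessors
#'
#' @param x a \code{ParticleList}.
#' @name ParticleList-accessors
NULL

#' @rdname ParticleList-accessors
#' @export
positions <- function(x) x@position

#' @rdname ParticleList-accessors
#' @export
rotations <- function(x) x@rotation

#' @rdname ParticleList-accessors
#' @export
particleIDs <- function(x) x@particleID

#' @rdname ParticleList-accessors
#' @export
tomoIDs <- function(x) x@tomoID

#' @rdname ParticleList-accessors
#' @export
objectIDs <- function(x) x@objectID

#' @rdname ParticleList-accessors
#' @export
scores <- function(x) x@score

#' @rdname ParticleList-accessors
#' @export
classLabels <- function(x) x@classLabel

#' @rdname ParticleList-accessors
#' @export
particleUnit <- function(x) x@unit

#' @rdname ParticleList-accessors
#' @export
pixelSize <- function(x) x@pixelSize

#' @rdname ParticleList-accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname ParticleList-accessors
#' @export
setMethod("provenance", "ParticleList", function(x) x@provenance)

setMethod("length", "ParticleList", function(x) nParticles(x))

setMethod("show", "ParticleList", function(object) {
  n <- nParticles(object)
  cat(sprintf("ParticleList with %d particle%s in %d tomogram%s [unit: %s]\n",
              n, if (n == 1) "" else "s", length(unique(object@tomoID)),
              if (length(unique(object@tomoID)) == 1) "" else "s",
              object@unit))
  if (any(!is.na(object@classLabel))) {
    tab <- table(object@classLabel, useNA = "no")
    cat("  class labels:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  naff <- sum(!is.na(object@objectID))
  if (naff) cat(sprintf("  %d particle%s affiliated to %d object%s\n",
                        naff, if (naff == 1) "" else "s",
                        length(unique(stats::na.omit(object@objectID))),
                        if (length(unique(stats::na.omit(object@objectID)))
                            == 1) "" else "s"))
  invisible(NULL)
})

#' Subset a ParticleList
#'
#' @param x a \code{ParticleList}.
#' @param i logical or integer index.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "ParticleList", function(x, i, j, ..., drop = FALSE) {
  idx <- seq_len(nParticles(x))[i]
  new("ParticleList", position = x@position[idx, , drop = FALSE],
      rotation = x@rotation[, , idx, drop = FALSE],
      particleID = x@particleID[idx], tomoID = x@tomoID[idx],
      objectID = x@objectID[idx], score = x@score[idx],
      classLabel = x@classLabel[idx], unit = x@unit,
      pixelSize = x@pixelSize, provenance = x@provenance)
})

#' Concatenate particle lists
#'
#' Particle ids of later lists are reassigned past the running maximum when
#' they collide; units must agree.
#'
#' @param x first \code{ParticleList}.
#' @param ... further \code{ParticleList}s.
#' @export
concatParticles <- function(x, ...) {
  rest <- list(...)
  for (y in rest) {
    if (y@unit != x@unit) stop("cannot concatenate lists with unit '",
                               x@unit, "' and '", y@unit, "'")
    ids <- y@particleID
    if (any(ids %in% x@particleID))
      ids <- max(x@particleID, -1L) + seq_along(ids)
    x <- new("ParticleList",
             position = rbind(x@position, y@position),
             rotation = array(c(x@rotation, y@rotation),
                              c(3, 3, nParticles(x) + nParticles(y))),
             particleID = c(x@particleID, as.integer(ids)),
             tomoID = c(x@tomoID, y@tomoID),
             objectID = c(x@objectID, y@objectID),
             score = c(x@score, y@score),
             classLabel = c(x@classLabel, y@classLabel),
             unit = x@unit, pixelSize = x@pixelSize,
             provenance = x@provenance)
  }
  x
}

#' Convert the length unit of a particle list
#'
#' nm and Angstrom interconvert exactly (factor 10); voxel conversions use
#' the pixel size (Angstrom per voxel) and are their own inverse.
#'
#' @param pl a \code{ParticleList}.
#' @param to target unit: "nm", "angstrom" or "voxel".
#' @param pixel_size Angstrom per voxel; defaults to the list's stored pixel
#'   size.
#' @return a \code{ParticleList} in the target unit.
#' @export
convertUnits <- function(pl, to = c("nm", "angstrom", "voxel"),
                         pixel_size = pixelSize(pl)) {
  to <- match.arg(to)
  from <- pl@unit
  if (from == to) return(pl)
  if ((from == "voxel" || to == "voxel") &&
      (length(pixel_size) != 1L || is.na(pixel_size) || pixel_size <= 0))
    stop("voxel conversion requires a positive pixel_size (Angstrom/voxel)")
  toA <- switch(from, nm = 10, angstrom = 1, voxel = pixel_size)
  fromA <- switch(to, nm = 10, angstrom = 1, voxel = pixel_size)
  pl@position <- pl@position * (toA / fromA)
  pl@unit <- to
  pl@pixelSize <- as.numeric(pixel_size)
  validObject(pl)
  pl
}

#' Distance-based duplicate cleaning
#'
#' Greedy score-descending sweep: particles are visited by decreasing score
#' (missing scores rank last; ties broken by ascending particle id) and kept
#' iff no already-kept particle in the same tomogram lies within
#' \code{min_distance}. The output is a subset of the input and, given
#' distinct scores, independent of the input row order.
#'
#' @param pl a \code{ParticleList}.
#' @param min_distance minimum allowed inter-particle distance (list units).
#' @return the cleaned \code{ParticleList}.
#' @export
cleanDuplicates <- function(pl, min_distance) {
  stopifnot(min_distance > 0)
  n <- nParticles(pl)
  if (n <= 1L) return(pl)
  s <- pl@score
  ord <- order(ifelse(is.na(s), -Inf, s), -pl@particleID,
               decreasing = TRUE)
  keep <- logical(n)
  pos <- pl@position
  tom <- pl@tomoID
  kept_idx <- integer(0)
  for (i in ord) {
    ok <- TRUE
    if (length(kept_idx)) {
      same <- kept_idx[tom[kept_idx] == tom[i]]
      if (length(same)) {
        d2 <- (pos[same, 1] - pos[i, 1])^2 + (pos[same, 2] - pos[i, 2])^2 +
          (pos[same, 3] - pos[i, 3])^2
        if (any(d2 < min_distance^2)) ok <- FALSE
      }
    }
    if (ok) {
      keep[i] <- TRUE
      kept_idx <- c(kept_idx, i)
    }
  }
  pl[keep]
}

#' Shift particles along an intrinsic axis
#'
#' Moves each particle by \code{distance} along a fixed axis of its own
#' intrinsic frame: \code{p <- p + distance * (w \%*\% axis)}. Rotations are
#' unchanged. Used e.g. to shift ring subunits toward the ring center before
#' affiliation, or ribosome centers to mRNA entry/exit sites.
#'
#' @param pl a \code{ParticleList}.
#' @param axis unit 3-vector in the intrinsic frame.
#' @param distance shift length (list units; may be negative).
#' @return the shifted \code{ParticleList}.
#' @export
shiftAlongIntrinsicAxis <- function(pl, axis, distance) {
  axis <- .unitize(axis, "axis")
  rows <- .rotToRows(pl@rotation)
  dirs <- .rotateRows(rows, matrix(axis, nParticles(pl), 3, byrow = TRUE))
  pl@position <- pl@position + distance * dirs
  ## no re-validation: a shift may legitimately collapse positions (e.g.
  ## ring subunits shifted onto their common center)
  pl
}

#' First-nearest-neighbor statistics
#'
#' Per-tomogram and global distributions of the distance from each particle
#' to its nearest neighbor in the same tomogram; the standard way to choose
#' a twist-descriptor support radius. Tomograms with a single particle are
#' excluded with a warning.
#'
#' @param pl a \code{ParticleList} (needs >= 2 particles in some tomogram).
#' @return a data.frame with one row per tomogram plus a "global" row:
#'   columns tomo, n, min, q25, median, q75, q95, max.
#' @export
nnStats <- function(pl) {
  tomos <- unique(pl@tomoID)
  all_nn <- numeric(0)
  rows <- list()
  for (tm in tomos) {
    idx <- which(pl@tomoID == tm)
    if (length(idx) < 2L) {
      warning("tomogram ", tm, " has a single particle; excluded")
      next
    }
    p <- pl@position[idx, , drop = FALSE]
    d2 <- as.matrix(stats::dist(p))
    diag(d2) <- Inf
    nn <- apply(d2, 1, min)
    all_nn <- c(all_nn, nn)
    q <- stats::quantile(nn, c(0, .25, .5, .75, .95, 1), names = FALSE)
    rows[[length(rows) + 1L]] <-
      data.frame(tomo = as.character(tm), n = length(idx), min = q[1],
                 q25 = q[2], median = q[3], q75 = q[4], q95 = q[5],
                 max = q[6])
  }
  if (!length(all_nn)) stop("no tomogram with >= 2 particles")
  q <- stats::quantile(all_nn, c(0, .25, .5, .75, .95, 1), names = FALSE)
  rows[[length(rows) + 1L]] <-
    data.frame(tomo = "global", n = length(all_nn), min = q[1], q25 = q[2],
               median = q[3], q75 = q[4], q95 = q[5], max = q[6])
  do.call(rbind, rows)
}
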