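## Geometric supports and record filters.
##
## A support is a bounded membership region expressed in the query
## particle's canonical frame (never in extrinsic coordinates), optionally
## re-oriented by a fixed orientation offset. Because twist positions are
## already expressed in that frame, supports and filters act on invariant
## quantities and commute with global rigid motions of the scene.

#' Support classes
#'
#' Membership regions used to reduce a twist descriptor: sphere, cylinder
#' (symmetric about the origin, or one-sided along +axis, with optional
#' axial offset), ellipsoid, cone (one-sided along +axis, optionally
#' mirrored to a double cone along +/-axis), torus, and voxel mask.
#' Construct them with \code{\link{sphereSupport}} and friends.
#'
#' @slot orientationOffset rotation applied (transposed) to twist positions
#'   before the membership test, i.e. the region is rotated by this offset
#'   within the query frame.
#' @name Support-classes
#' @exportClass TwistSupport
setClass("TwistSupport",
         representation("VIRTUAL", orientationOffset = "matrix"),
         prototype(orientationOffset = diag(3)))

#' @rdname Support-classes
#' @exportClass SphereSupport
setClass("SphereSupport", contains = "TwistSupport",
         representation(radius = "numeric"))

#' @rdname Support-classes
#' @exportClass CylinderSupport
setClass("CylinderSupport", contains = "TwistSupport",
         representation(radius = "numeric", height = "numeric",
                        axis = "numeric", oneSided = "logical",
                        axialOffset = "numeric"))

#' @rdname Support-classes
#' @exportClass EllipsoidSupport
setClass("EllipsoidSupport", contains = "TwistSupport",
         representation(semiAxes = "numeric"))

#' @rdname Support-classes
#' @exportClass ConeSupport
setClass("ConeSupport", contains = "TwistSupport",
         representation(halfAngle = "numeric", height = "numeric",
                        axis = "numeric", mirror = "logical"))

#' @rdname Support-classes
#' @exportClass TorusSupport
setClass("TorusSupport", contains = "TwistSupport",
         representation(majorRadius = "numeric", minorRadius = "numeric",
                        axis = "numeric"))

#' @rdname Support-classes
#' @exportClass MaskSupport
setClass("MaskSupport", contains = "TwistSupport",
         representation(mask = "array", voxelSize = "numeric"))

.checkPositive <- function(...) {
  vals <- list(...)
  for (nm in names(vals))
    if (any(!is.finite(vals[[nm]])) || any(vals[[nm]] <= 0))
      stop(nm, " must be positive and finite")
}

#' Support constructors
#'
#' All sizes are in the length unit of the descriptor the support is
#' applied to; axes are unit vectors in the query's canonical frame.
#'
#' @param radius sphere/cylinder radius.
#' @param height cylinder or cone height. The cylinder is symmetric about
#'   the origin (axial range [-height/2, height/2]) unless
#'   \code{one_sided = TRUE}, which selects the range [0, height] along
#'   +axis (the nucleosome-stack convention); an \code{axial_offset}
#'   translates the range.
#' @param axis region axis (default +z).
#' @param one_sided logical, see \code{height}.
#' @param axial_offset numeric shift of the cylinder along its axis.
#' @param semi_axes ellipsoid semi-axis lengths (3-vector).
#' @param half_angle cone half-opening angle in degrees.
#' @param mirror logical: also include the mirrored cone along -axis
#'   (double cone, the DNA entry/exit geometry).
#' @param major_radius,minor_radius torus radii (axis circle radius and
#'   tube radius).
#' @param mask 3D numeric array; membership is a nearest-voxel lookup at
#'   threshold 0.5 with the mask center voxel at the origin.
#' @param voxel_size edge length of a mask voxel in descriptor units.
#' @param orientation_offset 3x3 rotation re-seating the region in the
#'   query frame.
#' @return a \code{TwistSupport} object.
#' @examples
#' s <- cylinderSupport(radius = 4, height = 8, axis = c(0, 1, 0),
#'                      one_sided = TRUE)
#' supportMembership(s, rbind(c(0, 6, 0), c(0, -6, 0)))
#' @export
sphereSupport <- function(radius, orientation_offset = diag(3)) {
  .checkPositive(radius = radius)
  new("SphereSupport", radius = radius,
      orientationOffset = orientation_offset)
}

#' @rdname sphereSupport
#' @export
cylinderSupport <- function(radius, height, axis = c(0, 0, 1),
                            one_sided = FALSE, axial_offset = 0,
                            orientation_offset = diag(3)) {
  .checkPositive(radius = radius, height = height)
  new("CylinderSupport", radius = radius, height = height,
      axis = .unitize(axis, "axis"), oneSided = one_sided,
      axialOffset = axial_offset, orientationOffset = orientation_offset)
}

#' @rdname sphereSupport
#' @export
ellipsoidSupport <- function(semi_axes, orientation_offset = diag(3)) {
  stopifnot(length(semi_axes) == 3L)
  .checkPositive(semi_axes = semi_axes)
  new("EllipsoidSupport", semiAxes = as.numeric(semi_axes),
      orientationOffset = orientation_offset)
}

#' @rdname sphereSupport
#' @export
coneSupport <- function(half_angle, height, axis = c(0, 0, 1),
                        mirror = FALSE, orientation_offset = diag(3)) {
  .checkPositive(half_angle = half_angle, height = height)
  if (half_angle >= 90) stop("cone half_angle must be < 90 degrees")
  new("ConeSupport", halfAngle = half_angle, height = height,
      axis = .unitize(axis, "axis"), mirror = mirror,
      orientationOffset = orientation_offset)
}

#' @rdname sphereSupport
#' @export
torusSupport <- function(major_radius, minor_radius, axis = c(0, 0, 1),
                         orientation_offset = diag(3)) {
  .checkPositive(major_radius = major_radius, minor_radius = minor_radius)
  new("TorusSupport", majorRadius = major_radius,
      minorRadius = minor_radius, axis = .unitize(axis, "axis"),
      orientationOffset = orientation_offset)
}

#' @rdname sphereSupport
#' @export
maskSupport <- function(mask, voxel_size, orientation_offset = diag(3)) {
  if (length(voxel_size) != 1L || is.na(voxel_size) || voxel_size <= 0)
    stop("mask support requires a positive voxel_size")
  if (length(dim(mask)) != 3L) stop("mask must be a 3D array")
  new("MaskSupport", mask = mask, voxelSize = as.numeric(voxel_size),
      orientationOffset = orientation_offset)
}

#' Maximal extent of a support
#'
#' The largest distance from the origin contained in the region; used to
#' verify that a support fits inside the spherical support a descriptor was
#' built on (otherwise information would be missing).
#'
#' @param s a \code{TwistSupport}.
#' @return numeric radius bound.
#' @export
setGeneric("maxExtent", function(s) standardGeneric("maxExtent"))

setMethod("maxExtent", "SphereSupport", function(s) s@radius)
setMethod("maxExtent", "CylinderSupport", function(s) {
  hr <- if (s@oneSided) c(0, s@height) else c(-s@height / 2, s@height / 2)
  hr <- hr + s@axialOffset
  sqrt(s@radius^2 + max(abs(hr))^2)
})
setMethod("maxExtent", "EllipsoidSupport", function(s) max(s@semiAxes))
setMethod("maxExtent", "ConeSupport", function(s)
  s@height / cos(radians(s@halfAngle)))
setMethod("maxExtent", "TorusSupport", function(s)
  s@majorRadius + s@minorRadius)
setMethod("maxExtent", "MaskSupport", function(s)
  .vnorm((dim(s@mask) / 2 + 0.5) * s@voxelSize))

#' Support membership test
#'
#' Decides, for twist positions expressed in the query's canonical frame,
#' whether each point lies inside the support region. All interval bounds
#' are closed (boundary points are kept).
#'
#' @param s a \code{TwistSupport}.
#' @param points numeric N x 3 matrix (or a single 3-vector) of twist
#'   positions.
#' @return logical vector of length N.
#' @export
setGeneric("supportMembership",
           function(s, points) standardGeneric("supportMembership"))

.supPoints <- function(s, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  ## region rotated by offset <=> test offset^T x in the canonical region
  points %*% s@orientationOffset
}

setMethod("supportMembership", "SphereSupport", function(s, points) {
  p <- .supPoints(s, points)
  .rownorm(p) <= s@radius + 1e-12
})

setMethod("supportMembership", "CylinderSupport", function(s, points) {
  p <- .supPoints(s, points)
  ax <- as.numeric(p %*% s@axis) - s@axialOffset
  rad2 <- rowSums(p * p) - (ax + s@axialOffset)^2
  lo <- if (s@oneSided) 0 else -s@height / 2
  hi <- if (s@oneSided) s@height else s@height / 2
  ax >= lo - 1e-12 & ax <= hi + 1e-12 &
    rad2 <= s@radius^2 + 1e-12
})

setMethod("supportMembership", "EllipsoidSupport", function(s, points) {
  p <- .supPoints(s, points)
  rowSums(sweep(p, 2, s@semiAxes, "/")^2) <= 1 + 1e-12
})

setMethod("supportMembership", "ConeSupport", function(s, points) {
  p <- .supPoints(s, points)
  ax <- as.numeric(p %*% s@axis)
  if (s@mirror) ax <- abs(ax)
  r <- .rownorm(p)
  cosang <- ifelse(r > 0, ax / r, 1)
  cosang >= cos(radians(s@halfAngle)) - 1e-12 & ax <= s@height + 1e-12
})

setMethod("supportMembership", "TorusSupport", function(s, points) {
  p <- .supPoints(s, points)
  ax <- as.numeric(p %*% s@axis)
  inplane <- sqrt(pmax(rowSums(p * p) - ax^2, 0))
  (inplane - s@majorRadius)^2 + ax^2 <= s@minorRadius^2 + 1e-12
})

setMethod("supportMembership", "MaskSupport", function(s, points) {
  p <- .supPoints(s, points)
  d <- dim(s@mask)
  center <- ceiling(d / 2)  # center voxel sits at the origin
  idx <- round(sweep(p / s@voxelSize, 2, center, "+"))
  ok <- idx[, 1] >= 1 & idx[, 1] <= d[1] & idx[, 2] >= 1 &
    idx[, 2] <= d[2] & idx[, 3] >= 1 & idx[, 3] <= d[3]
  out <- logical(nrow(p))
  if (any(ok))
    out[ok] <- s@mask[cbind(idx[ok, 1], idx[ok, 2], idx[ok, 3])] >= 0.5
  out
})

#' Reduce a twist descriptor by a support
#'
#' Keeps exactly the records whose twist position lies inside the support.
#' Sequential reduction by two supports equals reduction by their
#' intersection. A support exceeding the descriptor's initial spherical
#' radius is an error (neighbors outside were never collected).
#'
#' @param td a \code{\link{TwistDescriptor}}.
#' @param s a \code{TwistSupport}.
#' @return the reduced \code{TwistDescriptor} (provenance updated).
#' @export
reduceDescriptor <- function(td, s) {
  if (maxExtent(s) > td@radius + 1e-9)
    stop("support extent (", format(maxExtent(s)), ") exceeds the ",
         "descriptor radius (", format(td@radius), "); recompute the ",
         "descriptor with a larger initial support")
  pts <- as.matrix(td@records[, c("trans_x", "trans_y", "trans_z")])
  keep <- if (nrow(pts)) supportMembership(s, pts) else logical(0)
  .subsetDescriptor(td, keep, note = sprintf("support:%s", class(s)))
}

#' Deviation of a relative-rotation axis from a reference axis
#'
#' Angle between the record's rotation axis and a reference axis, folded to
#' [0, 90] degrees (the axis sign is ambiguous). Records with angular
#' distance below 1e-9 have no defined axis and are treated as deviation 0
#' (an identity relative rotation is axis-agnostic).
#'
#' @param record one or more rows of a twist record table (needs the
#'   \code{axis_x/y/z} and \code{angular_distance} columns), or a
#'   \code{TwistDescriptor}.
#' @param reference_axis unit 3-vector in the query canonical frame.
#' @return numeric vector of deviations in degrees.
#' @export
axisDeviation <- function(record, reference_axis) {
  if (is(record, "TwistDescriptor")) record <- record@records
  ref <- .unitize(reference_axis, "reference_axis")
  ax <- as.matrix(record[, c("axis_x", "axis_y", "axis_z")])
  cosang <- abs(ax %*% ref)
  out <- degrees(acos(.clamp1(cosang)))
  out[record$angular_distance < 1e-9] <- 0
  as.numeric(out)
}

#' Record filters
#'
#' A filter keeps records whose field value lies in a closed interval.
#' Angular fields are specified in degrees at this interface
#' (\code{angular_distance}, \code{inplane_query}, \code{inplane_neighbor},
#' \code{axis_deviation}); distances in the descriptor's length unit.
#'
#' @param field one of the scalar record fields
#'   (\code{"euclidean_distance"}, \code{"angular_distance"},
#'   \code{"inplane_query"}, \code{"inplane_neighbor"}, \code{"trans_x"},
#'   \code{"trans_y"}, \code{"trans_z"}) or \code{"axis_deviation"} (which
#'   requires \code{reference_axis}).
#' @param lo,hi closed interval bounds (lo <= hi).
#' @param reference_axis unit 3-vector for \code{axis_deviation}.
#' @return a \code{"TwistFilter"} object.
#' @examples
#' f <- twistFilter("angular_distance", 40, 50)
#' @export
twistFilter <- function(field, lo, hi, reference_axis = NULL) {
  stopifnot(is.character(field), length(field) == 1L)
  if (!(lo <= hi)) stop("filter interval requires lo <= hi")
  if (field == "axis_deviation" && is.null(reference_axis))
    stop("axis_deviation filter requires a reference_axis")
  structure(list(field = field, lo = lo, hi = hi,
                 reference_axis = reference_axis),
            class = "TwistFilter")
}

.ANGULAR_FIELDS <- c("angular_distance", "inplane_query",
                     "inplane_neighbor")

## logical mask of records passing one filter
.filterMask <- function(rec, f) {
  if (f$field == "axis_deviation") {
    val <- axisDeviation(rec, f$reference_axis)
  } else {
    if (!f$field %in% names(rec))
      stop("filter references unknown record field '", f$field, "'")
    val <- rec[[f$field]]
    if (f$field %in% .ANGULAR_FIELDS) val <- degrees(val)
  }
  val >= f$lo - 1e-12 & val <= f$hi + 1e-12
}

#' Apply record filters to a twist descriptor
#'
#' Removes every record failing any filter predicate. In the symmetric
#' (single-list) case a failing pair is removed in both directions so the
#' descriptor stays symmetric; surviving records are unchanged.
#'
#' @param td a \code{\link{TwistDescriptor}}.
#' @param filters list of \code{\link{twistFilter}} objects (an empty list
#'   is the identity).
#' @return the filtered \code{TwistDescriptor}.
#' @export
applyEdgeFilters <- function(td, filters) {
  if (inherits(filters, "TwistFilter")) filters <- list(filters)
  rec <- td@records
  if (!length(filters) || !nrow(rec)) return(td)
  keep <- rep(TRUE, nrow(rec))
  for (f in filters) keep <- keep & .filterMask(rec, f)
  if (td@symmetric) {
    ## drop both directions of any failing unordered pair
    key <- function(a, b) paste(pmin(a, b), pmax(a, b), rec$tomo_id)
    bad <- key(rec$query_id, rec$neighbor_id)[!keep]
    keep <- !(key(rec$query_id, rec$neighbor_id) %in% bad)
  }
  .subsetDescriptor(td, keep, note = "filtered")
}

#' Build supports and filters from a YAML configuration
#'
#' Schema: a top-level \code{support:} mapping with a \code{kind} key
#' (sphere, cylinder, ellipsoid, cone, torus) and the corresponding
#' constructor parameters, and a \code{filters:} sequence of mappings with
#' \code{field}, \code{lo}, \code{hi} and optional \code{reference_axis}.
#'
#' @param config path to a YAML file or an already-parsed list.
#' @return list with elements \code{support} (or NULL) and \code{filters}.
#' @export
supportConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  sup <- NULL
  if (!is.null(config$support)) {
    sc <- config$support
    kind <- match.arg(sc$kind,
                      c("sphere", "cylinder", "ellipsoid", "cone", "torus"))
    get <- function(nm, default = NULL)
      if (!is.null(sc[[nm]])) sc[[nm]] else default
    sup <- switch(kind,
      sphere = sphereSupport(sc$radius),
      cylinder = cylinderSupport(sc$radius, sc$height,
                                 axis = unlist(get("axis", c(0, 0, 1))),
                                 one_sided = isTRUE(sc$one_sided),
                                 axial_offset = get("axial_offset", 0)),
      ellipsoid = ellipsoidSupport(unlist(sc$semi_axes)),
      cone = coneSupport(sc$half_angle, sc$height,
                         axis = unlist(get("axis", c(0, 0, 1))),
                         mirror = isTRUE(sc$mirror)),
      torus = torusSupport(sc$major_radius, sc$minor_radius,
                           axis = unlist(get("axis", c(0, 0, 1)))))
  }
  filters <- lapply(config$filters, function(fc)
    twistFilter(fc$field, fc$lo, fc$hi,
                reference_axis = if (!is.null(fc$reference_axis))
                  unlist(fc$reference_axis)))
  list(support = sup, filters = filters)
}
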