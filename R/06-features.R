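## Per-query features computed from (reduced) twist descriptors.
##
## Every feature returns one row per query particle of the source
## descriptor -- including queries with empty neighborhoods, which take
## documented fill values (occupancy 0, distance statistics NA, footprint
## all-empty) -- so that features of equal length can be concatenated into
## custom descriptors.

#' FeatureMatrix class
#'
#' Fixed-length per-query feature vectors. All columns share the query id
#' vector; matrices computed on the same descriptor can be merged
#' column-wise.
#'
#' @slot queryID integer vector of query particle ids.
#' @slot values data.frame of feature columns (one row per query).
#' @slot provenance list: feature names, parameters, support/filter stack.
#' @exportClass FeatureMatrix
setClass("FeatureMatrix",
         representation(queryID = "integer", values = "data.frame",
                        provenance = "list"))

setValidity("FeatureMatrix", function(object) {
  if (nrow(object@values) != length(object@queryID))
    "values must have one row per query id"
  else if (anyDuplicated(object@queryID))
    "query ids must be unique"
  else TRUE
})

#' @rdname FeatureMatrix-class
#' @param fm,object a \code{FeatureMatrix}.
#' @export
featureValues <- function(fm) fm@values

#' @rdname FeatureMatrix-class
#' @export
queryIDs <- function(fm) {
  if (is(fm, "TwistDescriptor")) fm@queryIDs else fm@queryID
}

setMethod("show", "FeatureMatrix", function(object) {
  cat(sprintf("FeatureMatrix: %d quer%s x %d feature column%s\n",
              length(object@queryID),
              if (length(object@queryID) == 1) "y" else "ies",
              ncol(object@values),
              if (ncol(object@values) == 1) "" else "s"))
  cat("  columns:", paste(names(object@values), collapse = ", "), "\n")
  invisible(NULL)
})

.featureMatrix <- function(ids, values, provenance = list()) {
  new("FeatureMatrix", queryID = as.integer(ids), values = values,
      provenance = provenance)
}

#' Merge feature matrices computed on the same queries
#'
#' @param fm first \code{FeatureMatrix}.
#' @param ... further \code{FeatureMatrix} objects with identical query
#'   ids (an error otherwise).
#' @return the column-concatenated \code{FeatureMatrix}.
#' @export
mergeFeatures <- function(fm, ...) {
  for (other in list(...)) {
    if (!identical(fm@queryID, other@queryID))
      stop("query id mismatch: feature matrices were not computed on the ",
           "same queries")
    fm@values <- cbind(fm@values, other@values)
    fm@provenance <- c(fm@provenance, other@provenance)
  }
  fm
}

## split record row indices by query id, aligned with td@queryIDs
.recordsByQuery <- function(td) {
  rec <- td@records
  idx <- split(seq_len(nrow(rec)),
               factor(rec$query_id, levels = td@queryIDs))
  idx
}

#' Neighborhood occupancy
#'
#' Number of neighbors within the (possibly reduced) support of each query;
#' 0 for empty neighborhoods.
#'
#' @param td a \code{\link{TwistDescriptor}}.
#' @return a \code{\link{FeatureMatrix}} with column \code{occupancy}.
#' @export
featureOccupancy <- function(td) {
  cnt <- lengths(.recordsByQuery(td))
  .featureMatrix(td@queryIDs, data.frame(occupancy = as.integer(cnt)),
                 list(feature = "occupancy"))
}

#' Distance statistics over the support
#'
#' Per-query statistics of the Euclidean distance (descriptor length unit)
#' and the angular distance (degrees) over all neighbors in the support.
#' Empty neighborhoods yield NA.
#'
#' @param td a \code{\link{TwistDescriptor}}.
#' @param statistics subset of \code{"min"}, \code{"median"},
#'   \code{"mean"}, \code{"std"}.
#' @return a \code{\link{FeatureMatrix}} with columns
#'   \code{euclidean_<stat>} and \code{angular_<stat>}.
#' @export
featureDistanceStats <- function(td,
                                 statistics = c("min", "median", "mean",
                                                "std")) {
  known <- c(min = min, median = stats::median, mean = mean,
             std = stats::sd)
  bad <- setdiff(statistics, names(known))
  if (length(bad)) stop("unknown statistic name(s): ",
                        paste(bad, collapse = ", "))
  byq <- .recordsByQuery(td)
  rec <- td@records
  cols <- list()
  for (what in c("euclidean", "angular")) {
    v <- if (what == "euclidean") rec$euclidean_distance
         else degrees(rec$angular_distance)
    for (s in statistics) {
      f <- known[[s]]
      cols[[paste(what, s, sep = "_")]] <- vapply(byq, function(ii) {
        if (!length(ii)) return(NA_real_)
        if (s == "std" && length(ii) == 1L) return(0)
        f(v[ii])
      }, numeric(1))
    }
  }
  .featureMatrix(td@queryIDs, as.data.frame(cols),
                 list(feature = "distance_stats", statistics = statistics))
}

#' Shell decomposition of pair distances
#'
#' Groups the sorted pair distances of a descriptor into concentric shells:
#' maximal runs whose spread stays below \code{tolerance_fraction} times
#' the running group mean. Shells are indexed 1..k by ascending center
#' (shell 1 is a particle's first, nearest shell). If two consecutive
#' groups come closer than half the tolerance window the decomposition is
#' ambiguous and an error advises a smaller tolerance.
#'
#' @param td a \code{\link{TwistDescriptor}}.
#' @param tolerance_fraction relative spread allowed within a shell
#'   (0 < f < 0.5).
#' @return an object of class \code{"ShellDecomposition"}: a list with
#'   \code{edges} (data.frame shell, lo, hi, center, n) and
#'   \code{assignment} (shell index per descriptor record, NA outside all
#'   shells).
#' @export
decomposeShells <- function(td, tolerance_fraction = 0.1) {
  stopifnot(tolerance_fraction > 0, tolerance_fraction < 0.5)
  d <- td@records$euclidean_distance
  if (!length(d)) stop("descriptor has no records to decompose")
  ds <- sort(unique(d))
  groups <- list()
  cur <- ds[1]
  for (x in ds[-1]) {
    if (x - cur[1] <= tolerance_fraction * mean(c(cur, x))) {
      cur <- c(cur, x)
    } else {
      groups[[length(groups) + 1L]] <- cur
      cur <- x
    }
  }
  groups[[length(groups) + 1L]] <- cur
  lo <- vapply(groups, min, numeric(1))
  hi <- vapply(groups, max, numeric(1))
  ctr <- vapply(groups, mean, numeric(1))
  if (length(groups) > 1L) {
    gap <- lo[-1] - hi[-length(hi)]
    if (any(gap < 0.5 * tolerance_fraction * ctr[-length(ctr)]))
      stop("shell groups overlap at tolerance_fraction = ",
           tolerance_fraction, "; use a smaller tolerance")
  }
  edges <- data.frame(shell = seq_along(groups), lo = lo, hi = hi,
                      center = ctr,
                      n = vapply(groups, function(g) sum(d >= g[1] - 1e-12 &
                                                           d <= g[length(g)] +
                                                           1e-12),
                                 numeric(1)))
  assignment <- rep(NA_integer_, length(d))
  for (k in seq_along(groups))
    assignment[d >= lo[k] - 1e-12 & d <= hi[k] + 1e-12] <- k
  structure(list(edges = edges, assignment = assignment,
                 tolerance_fraction = tolerance_fraction),
            class = "ShellDecomposition")
}

#' @export
print.ShellDecomposition <- function(x, ...) {
  cat("ShellDecomposition with", nrow(x$edges), "shells\n")
  print(x$edges, row.names = FALSE)
  invisible(x)
}

#' Angular profile over concentric shells
#'
#' Distribution summary of a per-pair angular quantity within each distance
#' shell: either the raw angular distance (degrees) or the symmetry-aware
#' angular score under a given symmetry representative. Empty shells yield
#' NA rows.
#'
#' @param td a \code{\link{TwistDescriptor}}.
#' @param shells a \code{ShellDecomposition} of the same descriptor.
#' @param score \code{"angular_distance"} or \code{"angular_score"}.
#' @param rep a \code{\link{SymmetryRep}} (required for
#'   \code{"angular_score"}).
#' @return data.frame with one row per shell: n, mean, median, q25, q75.
#' @export
shellAngularProfile <- function(td, shells,
                                score = c("angular_distance",
                                          "angular_score"),
                                rep = NULL) {
  score <- match.arg(score)
  v <- if (score == "angular_distance") degrees(td@records$angular_distance)
  else {
    if (is.null(rep)) stop("angular_score requires a symmetry rep")
    scoreRecords(rep, td)
  }
  if (length(v) != length(shells$assignment))
    stop("shell decomposition does not match this descriptor")
  out <- lapply(shells$edges$shell, function(k) {
    vi <- v[!is.na(shells$assignment) & shells$assignment == k]
    if (!length(vi))
      return(data.frame(shell = k, n = 0L, mean = NA_real_,
                        median = NA_real_, q25 = NA_real_, q75 = NA_real_))
    q <- stats::quantile(vi, c(.25, .75), names = FALSE)
    data.frame(shell = k, n = length(vi), mean = mean(vi),
               median = stats::median(vi), q25 = q[1], q75 = q[2])
  })
  do.call(rbind, out)
}

#' First-shell link statistics
#'
#' For each query, the link is the graph formed by its first-shell
#' neighbors (vertices) and the pairs of neighbors whose mutual distance
#' also falls in the first-shell interval (edges) -- the standard local
#' picture of lattice order. Central angles are the angles subtended at the
#' query by linked neighbor pairs: 60 degrees at an interior vertex of a
#' regular flat hexagonal lattice, 72 degrees at a fivefold (pentamer)
#' vertex.
#'
#' @param td a \code{\link{TwistDescriptor}}.
#' @param shells a \code{ShellDecomposition}; its first shell defines the
#'   neighbor set and the edge distance window.
#' @return a \code{\link{FeatureMatrix}} with columns \code{n_vertices},
#'   \code{n_edges}, \code{euler_characteristic} (V - E), \code{link_type}
#'   (closed_cycle / open_chain / fragments / empty), \code{median_theta}
#'   and \code{std_theta} (central angles, degrees).
#' @export
linkFeatures <- function(td, shells) {
  lo <- shells$edges$lo[1] - 1e-9
  hi <- shells$edges$hi[1] + 1e-9
  rec <- td@records
  in1 <- !is.na(shells$assignment) & shells$assignment == 1L
  byq <- split(which(in1), factor(rec$query_id[in1], levels = td@queryIDs))
  n <- length(td@queryIDs)
  nv <- integer(n); ne <- integer(n)
  med <- rep(NA_real_, n); std <- rep(NA_real_, n)
  type <- character(n)
  for (q in seq_len(n)) {
    ii <- byq[[q]]
    v <- length(ii)
    nv[q] <- v
    if (v == 0L) { type[q] <- "empty"; next }
    pts <- as.matrix(rec[ii, c("trans_x", "trans_y", "trans_z")])
    if (v == 1L) { ne[q] <- 0L; type[q] <- "fragments"; next }
    dm <- as.matrix(stats::dist(pts))
    adj <- dm >= lo & dm <= hi
    diag(adj) <- FALSE
    ep <- which(adj & upper.tri(adj), arr.ind = TRUE)
    ne[q] <- nrow(ep)
    if (nrow(ep)) {
      u <- pts[ep[, 1], , drop = FALSE]
      w <- pts[ep[, 2], , drop = FALSE]
      cosang <- rowSums(u * w) / (.rownorm(u) * .rownorm(w))
      theta <- degrees(acos(.clamp1(cosang)))
      med[q] <- stats::median(theta)
      std[q] <- if (length(theta) > 1L) stats::sd(theta) else 0
    }
    ## connectivity by union-find over the small link graph
    parent <- seq_len(v)
    find <- function(a) { while (parent[a] != a) a <- parent[a]; a }
    if (nrow(ep)) for (e in seq_len(nrow(ep))) {
      ra <- find(ep[e, 1]); rb <- find(ep[e, 2])
      if (ra != rb) parent[rb] <- ra
    }
    ncomp <- length(unique(vapply(seq_len(v), find, integer(1))))
    deg <- rowSums(adj)
    type[q] <- if (ncomp == 1L && ne[q] == v && all(deg == 2)) "closed_cycle"
    else if (ncomp == 1L && ne[q] == v - 1L && all(deg <= 2)) "open_chain"
    else "fragments"
  }
  .featureMatrix(td@queryIDs,
                 data.frame(n_vertices = nv, n_edges = ne,
                            euler_characteristic = nv - ne,
                            link_type = type, median_theta = med,
                            std_theta = std),
                 list(feature = "link", shell1 = c(lo, hi)))
}

## fold rotation axes into the reference hemisphere (z >= 0; on the
## equator x > 0; on the x = 0 meridian y > 0)
.foldAxes <- function(ax) {
  eps <- 1e-12
  flip <- ax[, 3] < -eps |
    (abs(ax[, 3]) <= eps & ax[, 1] < -eps) |
    (abs(ax[, 3]) <= eps & abs(ax[, 1]) <= eps & ax[, 2] < 0)
  ax[flip, ] <- -ax[flip, , drop = FALSE]
  ax
}

## equal-area hemispherical bin index for folded unit axes: bin 1 is a
## polar cap of the same area as every other bin (a cap split into
## azimuth sectors would scatter an axis population sitting exactly on
## the pole across sectors by numerical noise); bands 2..n_rings are
## equal-area z-bands split into n_azimuth sectors. Total bins:
## 1 + (n_rings - 1) * n_azimuth, all of equal area.
.axisBins <- function(ax, n_azimuth, n_rings) {
  nb <- 1L + (n_rings - 1L) * n_azimuth
  depth <- (1 - .clamp1(ax[, 3])) * nb  # 0..nb, uniform under uniform axes
  incap <- depth <= 1
  band <- pmin(pmax(ceiling((depth - 1) / n_azimuth), 1L),
               n_rings - 1L)
  azim <- atan2(ax[, 2], ax[, 1]) %% (2 * pi)
  azbin <- pmin(floor(azim / (2 * pi / n_azimuth)) + 1L, n_azimuth)
  ifelse(incap, 1L, 1L + (band - 1L) * n_azimuth + azbin)
}

#' Histogram of relative-rotation axes
#'
#' Bins the normalized rotational parts of the twist vectors on the unit
#' hemisphere (axes are sign-folded) using an equal-area scheme: a polar
#' cap bin plus \code{n_rings - 1} equal-area bands of \code{n_azimuth}
#' sectors each (every bin covers the same solid angle). The dominant
#' axis is the normalized mean of the axes in the modal bin (ties broken
#' by lowest bin index); the geometric bin center is also reported.
#'
#' @param td a \code{\link{TwistDescriptor}}.
#' @param n_azimuth,n_rings binning resolution (defaults 16 x 8, i.e. 113
#'   equal-area bins).
#' @param min_angular records with angular distance below this (radians)
#'   have no defined axis and are excluded (default 1e-6).
#' @return list with \code{table} (data.frame bin, count),
#'   \code{dominant_axis}, \code{dominant_bin}, \code{bin_center}.
#' @export
rotationAxisHistogram <- function(td, n_azimuth = 16L, n_rings = 8L,
                                  min_angular = 1e-6) {
  rec <- td@records
  ok <- rec$angular_distance > min_angular
  if (!any(ok)) stop("no records with a defined rotation axis")
  ax <- .foldAxes(as.matrix(rec[ok, c("axis_x", "axis_y", "axis_z")]))
  nb <- 1L + (n_rings - 1L) * n_azimuth
  bin <- .axisBins(ax, n_azimuth, n_rings)
  counts <- tabulate(bin, nbins = nb)
  modal <- which.max(counts)  # ties -> lowest bin index
  if (modal == 1L) {
    center <- c(0, 0, 1)
  } else {
    band <- (modal - 2L) %/% n_azimuth + 1L
    az_m <- (modal - 2L) %% n_azimuth + 1L
    zc <- 1 - (1 + (band - 0.5) * n_azimuth) / nb
    azc <- (az_m - 0.5) * 2 * pi / n_azimuth
    center <- c(sqrt(1 - zc^2) * cos(azc), sqrt(1 - zc^2) * sin(azc), zc)
  }
  dom <- colMeans(ax[bin == modal, , drop = FALSE])
  dom <- dom / .vnorm(dom)
  tab <- data.frame(bin = seq_len(nb), count = counts)
  list(table = tab, dominant_axis = as.numeric(dom),
       dominant_bin = modal, bin_center = center,
       scheme = c(n_azimuth = n_azimuth, n_rings = n_rings))
}

## per-record cosine alignment zeta . axis / ||zeta|| (NA for zero zeta)
.alignRecords <- function(td, axis_hat) {
  axis_hat <- .unitize(axis_hat, "axis_hat")
  rec <- td@records
  z <- as.matrix(rec[, c("zeta_x", "zeta_y", "zeta_z")])
  nz <- .rownorm(z)
  out <- as.numeric(z %*% axis_hat) / nz
  out[nz < 1e-12] <- NA_real_
  out
}

#' Alignment of relative-rotation axes with a reference axis
#'
#' Per-record cosine alignment \code{zeta . axis / ||zeta||} in [-1, 1],
#' reduced to one value per query: the value of the nearest neighbor
#' (default) or of the neighbor with the largest absolute alignment.
#'
#' @param td a \code{\link{TwistDescriptor}}.
#' @param axis_hat unit reference axis (e.g. the dominant axis from
#'   \code{\link{rotationAxisHistogram}}).
#' @param reduce \code{"nearest"} or \code{"extremum"}.
#' @return a \code{\link{FeatureMatrix}} with column
#'   \code{axis_alignment} (NA for empty neighborhoods or zero rotation).
#' @export
featureAxisAlignment <- function(td, axis_hat,
                                 reduce = c("nearest", "extremum")) {
  reduce <- match.arg(reduce)
  al <- .alignRecords(td, axis_hat)
  rec <- td@records
  byq <- .recordsByQuery(td)
  val <- vapply(byq, function(ii) {
    if (!length(ii)) return(NA_real_)
    pick <- if (reduce == "nearest")
      ii[which.min(rec$euclidean_distance[ii])]
    else ii[which.max(abs(al[ii]))]
    al[pick]
  }, numeric(1))
  .featureMatrix(td@queryIDs, data.frame(axis_alignment = val),
                 list(feature = "axis_alignment", reduce = reduce))
}

.SHOT_AXES <- rbind(c(0, 1, 0), c(0, -1, 0), c(1, 0, 0),
                    c(-1, 0, 0), c(0, 0, 1), c(0, 0, -1))
.SHOT_NAMES <- c("cone_py", "cone_my", "cone_px", "cone_mx", "cone_pz",
                 "cone_mz")

#' Cone-occupancy (SHOT-style) footprints
#'
#' The spherical support around each query is subdivided into six cones
#' along (+y, -y, +x, -x, +z, -z) in the canonical frame (the order starts
#' with the cone aligned with the intrinsic y-axis). Each neighbor is
#' assigned to the cone of maximal cosine (ties to the lower cone index)
#' provided that cosine exceeds \code{cos(half angle)}; otherwise it is
#' unassigned, so assigned neighbors are partitioned. The footprint id is
#' the binary encoding of the occupancy over the cone order.
#'
#' @param td a \code{\link{TwistDescriptor}}.
#' @param cone_half_angle half-opening angle in degrees (0, 45].
#' @return a \code{\link{FeatureMatrix}} with per-cone neighbor counts and
#'   \code{footprint_id}; the provenance carries the footprint frequency
#'   ranking over all queries.
#' @export
shotFootprint <- function(td, cone_half_angle = 30) {
  stopifnot(cone_half_angle > 0, cone_half_angle <= 45)
  rec <- td@records
  n <- length(td@queryIDs)
  counts <- matrix(0L, n, 6, dimnames = list(NULL, .SHOT_NAMES))
  if (nrow(rec)) {
    pts <- as.matrix(rec[, c("trans_x", "trans_y", "trans_z")])
    u <- pts / .rownorm(pts)
    cosm <- u %*% t(.SHOT_AXES)
    best <- apply(cosm, 1, which.max)  # which.max ties -> lower index
    bestcos <- cosm[cbind(seq_len(nrow(cosm)), best)]
    assigned <- bestcos >= cos(radians(cone_half_angle)) - 1e-12
    qf <- factor(rec$query_id, levels = td@queryIDs)
    for (k in 1:6) {
      t <- table(qf[assigned & best == k])
      counts[, k] <- as.integer(t)
    }
  }
  fid <- as.integer((counts > 0) %*% (2^(0:5)))
  freq <- sort(table(fid[fid > 0]), decreasing = TRUE)
  .featureMatrix(td@queryIDs,
                 data.frame(counts, footprint_id = fid),
                 list(feature = "shot_footprint",
                      cone_half_angle = cone_half_angle,
                      footprint_ranking = freq))
}

#' Build a custom descriptor from a feature list
#'
#' Applies an optional support, then optional filters, then each requested
#' feature to a twist descriptor, and concatenates the resulting columns
#' into one \code{\link{FeatureMatrix}}. Features can be added to or
#' removed from the result with \code{\link{mergeFeatures}} and standard
#' column subsetting.
#'
#' @param td a \code{\link{TwistDescriptor}}.
#' @param features named list: names from the feature catalog
#'   (\code{"occupancy"}, \code{"distance_stats"}, \code{"axis_alignment"},
#'   \code{"shot_footprint"}, \code{"link"}), values lists of arguments
#'   for the corresponding feature function.
#' @param support optional \code{TwistSupport} applied first.
#' @param filters optional list of \code{\link{twistFilter}}s applied after
#'   the support.
#' @return a \code{\link{FeatureMatrix}}.
#' @export
buildCustomDescriptor <- function(td, features, support = NULL,
                                  filters = NULL) {
  if (!length(features)) stop("feature list must be non-empty")
  catalog <- list(occupancy = featureOccupancy,
                  distance_stats = featureDistanceStats,
                  axis_alignment = featureAxisAlignment,
                  shot_footprint = shotFootprint,
                  link = linkFeatures)
  if (!is.null(support)) td <- reduceDescriptor(td, support)
  if (!is.null(filters)) td <- applyEdgeFilters(td, filters)
  mats <- lapply(seq_along(features), function(k) {
    nm <- names(features)[k]
    if (is.null(nm) || !nm %in% names(catalog))
      stop("unknown feature '", nm, "'; catalog: ",
           paste(names(catalog), collapse = ", "))
    do.call(catalog[[nm]], c(list(td), features[[k]]))
  })
  do.call(mergeFeatures, mats)
}
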