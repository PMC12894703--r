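## Analysis pipelines: affiliation/cleaning with evaluation, pentamer
## labeling, stack and dinucleosome classification, footprint/axis pattern
## mining, and the generic PCA / rank-sum contracts they rely on.

#' F1 score
#'
#' \code{F1 = 2 TP / (2 TP + FP + FN)}, the harmonic mean of precision and
#' recall.
#'
#' @param tp,fp,fn non-negative counts (not all zero).
#' @return F1 in [0, 1].
#' @export
f1Score <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  if (tp + fp + fn == 0)
    stop("F1 is undefined when TP, FP and FN are all zero")
  2 * tp / (2 * tp + fp + fn)
}

#' Two-sided Mann-Whitney rank-sum test
#'
#' Standard two-sided Mann-Whitney U. Below the size threshold (both
#' samples <= 50) and without ties the exact null distribution is
#' enumerated; otherwise the normal approximation with tie correction and
#' continuity correction is used (both via \code{stats::wilcox.test}, whose
#' W statistic is the U of the first sample).
#'
#' @param x,y numeric samples (non-empty).
#' @param exact_threshold sample-size threshold for the exact branch.
#' @return list with \code{U} and two-sided \code{p}.
#' @export
rankSumTest <- function(x, y, exact_threshold = 50L) {
  stopifnot(length(x) > 0, length(y) > 0)
  exact <- length(x) <= exact_threshold && length(y) <= exact_threshold &&
    !anyDuplicated(c(x, y))
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Principal component analysis with a variance target
#'
#' Standardizes the feature columns (constant columns are dropped with a
#' warning), runs PCA and retains components until the cumulative
#' explained variance reaches the target; the dominant original feature of
#' each retained component is reported from the loadings.
#'
#' @param x a \code{\link{FeatureMatrix}}, data.frame or numeric matrix
#'   (>= 2 rows and columns).
#' @param variance_target fraction of variance to explain (default 0.95).
#' @return list with \code{n_components}, \code{explained} (per-component
#'   fractions), \code{cumulative}, \code{loadings},
#'   \code{dominant_features}, \code{scores} (retained components).
#' @export
runPCA <- function(x, variance_target = 0.95) {
  if (is(x, "FeatureMatrix")) x <- featureValues(x)
  x <- as.data.frame(x)
  x <- x[vapply(x, is.numeric, logical(1))]
  if (nrow(x) < 2L || ncol(x) < 2L)
    stop("PCA needs at least 2 rows and 2 numeric columns")
  keep <- vapply(x, function(col) stats::sd(col) > 1e-12, logical(1))
  if (any(!keep)) {
    warning("dropping constant column(s): ",
            paste(names(x)[!keep], collapse = ", "))
    x <- x[keep]
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  ncomp <- which(cumsum(expl) >= variance_target)[1]
  dom <- apply(abs(pc$rotation[, seq_len(ncomp), drop = FALSE]), 2,
               function(l) rownames(pc$rotation)[which.max(l)])
  list(n_components = ncomp, explained = expl, cumulative = cumsum(expl),
       loadings = pc$rotation, dominant_features = dom,
       scores = pc$x[, seq_len(ncomp), drop = FALSE])
}

#' Evaluate recovered affiliations against a ground truth
#'
#' Cleaned particles are matched one-to-one to ground-truth particles of
#' the same tomogram by ascending distance within a tolerance (default:
#' half the ground truth's median first-neighbor distance). Each recovered
#' object is assigned to the ground-truth object owning most of its
#' matches; per ground-truth object, TP is the number of its members
#' recovered by its assigned cluster(s), FP the excess particles of those
#' clusters, FN its unmatched members.
#'
#' @param result a \code{\link{ParticleList}} with object ids (the cleaned
#'   and affiliated list).
#' @param ground_truth a \code{ParticleList} with object ids.
#' @param tolerance positional match tolerance (list units).
#' @return list with \code{per_object} (data.frame object, TP, FP, FN,
#'   f1), \code{median_f1} and \code{n_matched}.
#' @export
evaluateAffiliation <- function(result, ground_truth, tolerance = NULL) {
  if (is.null(tolerance)) {
    nst <- nnStats(ground_truth)
    tolerance <- nst$median[nst$tomo == "global"] / 2
  }
  rp <- positions(result); gp <- positions(ground_truth)
  rt <- tomoIDs(result); gt <- tomoIDs(ground_truth)
  ## greedy one-to-one matching by ascending distance
  cand_i <- integer(0); cand_j <- integer(0); cand_d <- numeric(0)
  for (tm in unique(gt)) {
    ri <- which(rt == tm); gi <- which(gt == tm)
    if (!length(ri) || !length(gi)) next
    d2 <- outer(rowSums(rp[ri, , drop = FALSE]^2),
                rowSums(gp[gi, , drop = FALSE]^2), "+") -
      2 * rp[ri, , drop = FALSE] %*% t(gp[gi, , drop = FALSE])
    w <- which(d2 <= tolerance^2, arr.ind = TRUE)
    if (nrow(w)) {
      cand_i <- c(cand_i, ri[w[, 1]]); cand_j <- c(cand_j, gi[w[, 2]])
      cand_d <- c(cand_d, sqrt(pmax(d2[w], 0)))
    }
  }
  ord <- order(cand_d)
  used_r <- logical(nrow(rp)); used_g <- logical(nrow(gp))
  match_g <- rep(NA_integer_, nrow(rp))
  for (k in ord) {
    i <- cand_i[k]; j <- cand_j[k]
    if (!used_r[i] && !used_g[j]) {
      used_r[i] <- TRUE; used_g[j] <- TRUE
      match_g[i] <- j
    }
  }
  g_obj <- objectIDs(ground_truth)
  r_obj <- objectIDs(result)
  ## assign each recovered cluster to the ground-truth object with most
  ## matches
  clus <- unique(stats::na.omit(r_obj))
  clus_owner <- stats::setNames(rep(NA_integer_, length(clus)),
                                clus)
  for (cl in clus) {
    members <- which(r_obj == cl)
    mg <- g_obj[match_g[members]]
    mg <- mg[!is.na(mg)]
    if (length(mg)) clus_owner[as.character(cl)] <-
        as.integer(names(sort(table(mg), decreasing = TRUE))[1])
  }
  objs <- sort(unique(stats::na.omit(g_obj)))
  per <- lapply(objs, function(o) {
    own_clusters <- as.integer(names(clus_owner)[!is.na(clus_owner) &
                                                   clus_owner == o])
    members_r <- which(r_obj %in% own_clusters)
    gt_members <- which(g_obj == o)
    tp <- sum(g_obj[match_g[members_r]] == o, na.rm = TRUE)
    fp <- length(members_r) - tp
    fn <- length(gt_members) - tp
    data.frame(object = o, TP = tp, FP = fp, FN = fn,
               f1 = if (tp + fp + fn > 0) f1Score(tp, fp, fn) else NA_real_)
  })
  per <- do.call(rbind, per)
  list(per_object = per, median_f1 = stats::median(per$f1, na.rm = TRUE),
       n_matched = sum(!is.na(match_g)), tolerance = tolerance)
}

#' Affiliate particles to objects and clean the list
#'
#' The geometric cleaning pipeline: optionally shift particles along an
#' intrinsic axis (e.g. ring subunits toward their ring center), compute
#' the twist descriptor, reduce it by a support, filter edges, and take
#' connected components of at least \code{min_component_size} particles as
#' objects. Particles in no surviving component are dropped. When a
#' ground-truth list is supplied the result is evaluated with
#' \code{\link{evaluateAffiliation}}.
#'
#' @param pl input \code{\link{ParticleList}}.
#' @param radius twist support radius.
#' @param support optional \code{TwistSupport} (must be symmetric about
#'   the origin for the affiliation graph to stay undirected).
#' @param filters optional list of \code{\link{twistFilter}}s.
#' @param min_component_size minimum object size (default 3, e.g. at least
#'   three subunits to accept a ring).
#' @param intrinsic_shift optional list(axis, distance) applied before the
#'   descriptor (positions of the returned list are the originals).
#' @param ground_truth,match_tolerance optional evaluation inputs.
#' @return list with \code{particles} (cleaned list with object ids),
#'   \code{mapping} (object id per input particle id, NA = dropped),
#'   \code{report} (evaluation or NULL).
#' @export
affiliateAndClean <- function(pl, radius, support = NULL,
                              filters = list(), min_component_size = 3L,
                              intrinsic_shift = NULL, ground_truth = NULL,
                              match_tolerance = NULL) {
  work <- pl
  if (!is.null(intrinsic_shift))
    work <- shiftAlongIntrinsicAxis(work, intrinsic_shift$axis,
                                    intrinsic_shift$distance)
  td <- computeTwist(work, radius = radius)
  if (!is.null(support)) td <- reduceDescriptor(td, support)
  if (length(filters)) td <- applyEdgeFilters(td, filters)
  mapping <- proximityClusters(td, min_size = min_component_size)
  keep <- !is.na(mapping[as.character(particleIDs(pl))])
  cleaned <- pl[keep]
  cleaned@objectID <- unname(mapping[as.character(particleIDs(cleaned))])
  report <- NULL
  if (!is.null(ground_truth))
    report <- evaluateAffiliation(cleaned, ground_truth,
                                  tolerance = match_tolerance)
  list(particles = cleaned, mapping = mapping, report = report)
}

#' Label pentamers in a hexagonal lattice
#'
#' Lattice-defect detection: first-shell link statistics (median and
#' standard deviation of the central angles, number of vertices) are
#' standardized, reduced by PCA to the components explaining the variance
#' target, and split into two k-means clusters. The cluster whose median
#' central angle is strictly nearer 72 degrees (the fivefold value) than
#' 60 degrees (the hexagonal value) is labeled pentamer; if neither
#' qualifies, everything is labeled hexamer with a warning.
#'
#' @param pl a lattice-like \code{\link{ParticleList}}.
#' @param radius twist support radius; default 1.6 times the median
#'   first-neighbor distance (covers the first shell only).
#' @param shell_tolerance tolerance fraction for the shell decomposition.
#' @param variance_target PCA variance target (default 0.95).
#' @param seed k-means seed.
#' @return list with \code{labels} (character per particle, named by
#'   particle id), \code{features} (the link \code{FeatureMatrix}),
#'   \code{pca}, \code{cluster_medians}.
#' @export
pentamerLabeling <- function(pl, radius = NULL, shell_tolerance = 0.3,
                             variance_target = 0.95, seed = 1L) {
  if (is.null(radius)) {
    nst <- nnStats(pl)
    radius <- 1.6 * nst$median[nst$tomo == "global"]
  }
  td <- computeTwist(pl, radius = radius)
  shells <- decomposeShells(td, tolerance_fraction = shell_tolerance)
  lf <- linkFeatures(td, shells)
  vals <- featureValues(lf)
  feat <- vals[, c("median_theta", "std_theta", "n_vertices")]
  ok <- stats::complete.cases(feat)
  labels <- stats::setNames(rep("hexamer", nParticles(pl)),
                            queryIDs(lf))
  if (sum(ok) < 4L) {
    warning("too few particles with link features; all labeled hexamer")
    return(list(labels = labels, features = lf, pca = NULL,
                cluster_medians = NULL))
  }
  pca <- runPCA(feat[ok, ], variance_target = variance_target)
  km <- .withSeed(seed, stats::kmeans(pca$scores, centers = 2L,
                                      nstart = 10L))
  med <- vapply(1:2, function(cl)
    stats::median(feat$median_theta[ok][km$cluster == cl]), numeric(1))
  pent_cl <- which.min(abs(med - 72))
  if (abs(med[pent_cl] - 72) < abs(med[pent_cl] - 60)) {
    labels[which(ok)[km$cluster == pent_cl]] <- "pentamer"
  } else {
    warning("no cluster with fivefold central-angle geometry; ",
            "all particles labeled hexamer")
  }
  list(labels = labels, features = lf, pca = pca, cluster_medians = med)
}

#' Classify stacked particles with a one-sided cylindrical support
#'
#' A particle pair is in stacking configuration when one partner lies in
#' the other's one-sided cylinder along the intrinsic +y (stacking) axis
#' and their angular distance falls inside the stack-twist window. Both
#' endpoints of every such pair are labeled stacked (the upper partner of
#' a stack sees its mate at -y, so only the pair as a whole is the
#' stacking evidence). Per ground-truth class, the fraction of particles
#' labeled stacked is reported.
#'
#' @param pl a \code{\link{ParticleList}} (class labels used for the
#'   per-class report when present).
#' @param cylinder_radius,cylinder_height one-sided cylinder along +y (nm).
#' @param angular_window closed angular-distance window in degrees
#'   (default c(5, 25), i.e. the 15-degree stack twist plus/minus 10).
#' @param radius twist support radius; default just covers the cylinder.
#' @return list with \code{stacked} (logical named by particle id),
#'   \code{fractions} (percent per class label), \code{n_pairs}.
#' @export
stackClassifier <- function(pl, cylinder_radius = 4, cylinder_height = 8,
                            angular_window = c(5, 25), radius = NULL) {
  if (is.null(radius))
    radius <- sqrt(cylinder_radius^2 + cylinder_height^2) + 0.1
  td <- computeTwist(pl, radius = radius)
  red <- reduceDescriptor(td, cylinderSupport(cylinder_radius,
                                              cylinder_height,
                                              axis = c(0, 1, 0),
                                              one_sided = TRUE))
  rec <- twistRecords(red)
  ang <- degrees(rec$angular_distance)
  hit <- rec[ang >= angular_window[1] - 1e-12 &
               ang <= angular_window[2] + 1e-12, , drop = FALSE]
  ids <- particleIDs(pl)
  stacked <- stats::setNames(ids %in% c(hit$query_id, hit$neighbor_id),
                             ids)
  cls <- classLabels(pl)
  fractions <- if (any(!is.na(cls))) {
    vapply(split(stacked, cls), function(v) 100 * mean(v), numeric(1))
  } else NULL
  list(stacked = stacked, fractions = fractions, n_pairs = nrow(hit))
}

#' Dinucleosome pattern mining by k-means on twist features
#'
#' Reduces the descriptor to double-cone supports along the intrinsic
#' +/-z axis (the DNA entry/exit direction), finds the dominant
#' relative-rotation axis by hemispherical binning, and clusters the
#' per-record feature triple (Euclidean distance, angular distance,
#' absolute cosine deviation from the dominant axis) with seeded k-means
#' (10 restarts; clusters relabeled by ascending center norm so the
#' partition is reproducible). The per-cluster composition reports, for
#' each ground-truth class, the percentage of that class's particles with
#' at least one query-side record in the cluster.
#'
#' @param pl a \code{\link{ParticleList}}.
#' @param radius twist support radius (default 32 nm).
#' @param cone_half_angle,cone_height double-cone geometry (degrees, nm).
#' @param k number of k-means clusters (default 15).
#' @param seed k-means seed.
#' @return list with \code{records} (query, neighbor, cluster),
#'   \code{composition} (k x class percentage matrix), \code{sizes},
#'   \code{centers} (unstandardized), \code{dominant_axis}.
#' @export
dinucleosomeFinder <- function(pl, radius = 32, cone_half_angle = 35,
                               cone_height = 25.5, k = 15L, seed = 1L) {
  stopifnot(k >= 2L)
  td <- computeTwist(pl, radius = radius)
  red <- reduceDescriptor(td, coneSupport(cone_half_angle, cone_height,
                                          axis = c(0, 0, 1),
                                          mirror = TRUE))
  rec <- twistRecords(red)
  if (nrow(rec) < k)
    stop("fewer records (", nrow(rec), ") than clusters (", k, ")")
  hist <- rotationAxisHistogram(red)
  align <- abs(.alignRecords(red, hist$dominant_axis))
  align[is.na(align)] <- 0
  feat <- cbind(euclidean = rec$euclidean_distance,
                angular = degrees(rec$angular_distance),
                axis_dev = align)
  fs <- scale(feat)
  km <- .withSeed(seed, stats::kmeans(fs, centers = k, nstart = 10L,
                                      iter.max = 100L))
  ## canonical relabeling by ascending cluster-center norm
  ord <- order(sqrt(rowSums(km$centers^2)))
  relabel <- integer(k); relabel[ord] <- seq_len(k)
  cluster <- relabel[km$cluster]
  cls <- classLabels(pl)
  classes <- sort(unique(stats::na.omit(cls)))
  comp <- matrix(0, k, length(classes),
                 dimnames = list(NULL, classes))
  for (cl in seq_len(k)) {
    qin <- unique(rec$query_id[cluster == cl])
    for (cc in classes) {
      idc <- particleIDs(pl)[!is.na(cls) & cls == cc]
      comp[cl, cc] <- 100 * mean(idc %in% qin)
    }
  }
  centers <- sapply(seq_len(k), function(cl)
    colMeans(feat[cluster == cl, , drop = FALSE]))
  list(records = data.frame(query_id = rec$query_id,
                            neighbor_id = rec$neighbor_id,
                            cluster = cluster),
       composition = comp,
       sizes = as.integer(table(factor(cluster, levels = seq_len(k)))),
       centers = t(centers), dominant_axis = hist$dominant_axis)
}

#' Footprint-and-axis pattern mining
#'
#' For the most frequent cone-occupancy footprints of a (possibly
#' cross-list) descriptor: collect the records of the queries showing the
#' footprint, find their modal rotation-axis bin, split the modal-bin
#' records into equal-width angular-distance ranges, and export the medoid
#' pair of each range as its representative.
#'
#' @param queries,neighbors \code{\link{ParticleList}}s (neighbors may be
#'   NULL for the single-list case); shifted entry/exit lists are passed
#'   here after \code{\link{shiftAlongIntrinsicAxis}}.
#' @param radius twist support radius.
#' @param cone_half_angle footprint cone half-angle (degrees).
#' @param n_ranges number of angular-distance sub-bins (default 5).
#' @param top_footprints how many footprints to report (by frequency).
#' @return list of per-footprint reports: \code{footprint_id},
#'   \code{n_queries}, \code{dominant_axis}, \code{ranges} (data.frame
#'   with lo, hi, n, representative pair and its distances).
#' @export
footprintAxisPipeline <- function(queries, neighbors = NULL, radius,
                                  cone_half_angle = 30, n_ranges = 5L,
                                  top_footprints = 3L) {
  td <- computeTwist(queries, neighbors, radius = radius)
  if (!nrow(twistRecords(td))) return(list())
  fp <- shotFootprint(td, cone_half_angle = cone_half_angle)
  ranking <- fp@provenance$footprint_ranking
  ids_by_fp <- split(queryIDs(fp), featureValues(fp)$footprint_id)
  rec <- twistRecords(td)
  out <- list()
  for (fid in names(utils::head(ranking, top_footprints))) {
    qids <- ids_by_fp[[fid]]
    sub <- rec[rec$query_id %in% qids, , drop = FALSE]
    sub <- sub[sub$angular_distance > 1e-6, , drop = FALSE]
    if (!nrow(sub)) next
    subtd <- td
    subtd@records <- sub
    hist <- rotationAxisHistogram(subtd)
    ax <- .foldAxes(as.matrix(sub[, c("axis_x", "axis_y", "axis_z")]))
    inmodal <- .axisBins(ax, hist$scheme[["n_azimuth"]],
                         hist$scheme[["n_rings"]]) == hist$dominant_bin
    modal <- sub[inmodal, , drop = FALSE]
    if (nrow(modal) < n_ranges) {
      warning("footprint ", fid, " has fewer than ", n_ranges,
              " modal-bin records; ranges collapsed")
      n_use <- 1L
    } else n_use <- n_ranges
    a <- degrees(modal$angular_distance)
    br <- seq(min(a), max(a), length.out = n_use + 1L)
    br[length(br)] <- br[length(br)] + 1e-9
    idx <- findInterval(a, br, rightmost.closed = TRUE)
    ranges <- lapply(seq_len(n_use), function(rg) {
      mi <- which(idx == rg)
      if (!length(mi))
        return(data.frame(lo = br[rg], hi = br[rg + 1], n = 0L,
                          rep_query = NA_integer_,
                          rep_neighbor = NA_integer_,
                          rep_distance = NA_real_,
                          rep_angular = NA_real_))
      ## medoid over standardized (distance, angle)
      dd <- scale(cbind(modal$euclidean_distance[mi], a[mi]))
      dd[is.nan(dd)] <- 0
      dist_sum <- rowSums(as.matrix(stats::dist(dd)))
      md <- mi[which.min(dist_sum)]
      data.frame(lo = br[rg], hi = br[rg + 1], n = length(mi),
                 rep_query = modal$query_id[md],
                 rep_neighbor = modal$neighbor_id[md],
                 rep_distance = modal$euclidean_distance[md],
                 rep_angular = a[md])
    })
    out[[length(out) + 1L]] <-
      list(footprint_id = as.integer(fid), n_queries = length(qids),
           n_pairs = nrow(sub), dominant_axis = hist$dominant_axis,
           ranges = do.call(rbind, ranges))
  }
  out
}
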