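## TwistDescriptor: relative poses of all particle pairs within a support.

#' TwistDescriptor class
#'
#' The basic descriptor: one record per ordered (query, neighbor) pair with
#' inter-particle distance in (0, radius] and equal tomogram, holding the
#' pair's twist vector in the query's canonical frame. Because every record
#' is computed from the relative pose, the whole table is invariant under
#' global rigid motions of the scene. The record table doubles as a graph
#' (particles are nodes, records are edges) for proximity clustering.
#'
#' Record columns: \code{query_id}, \code{neighbor_id}, \code{tomo_id},
#' \code{zeta_x/y/z} (radians times axis), \code{trans_x/y/z} (length),
#' \code{euclidean_distance}, \code{angular_distance} (radians),
#' \code{axis_x/y/z} (unit rotation axis; NA below 1e-9 angular distance)
#' and \code{inplane_query}/\code{inplane_neighbor} (twist of each
#' particle's own rotation about its intrinsic z, radians).
#'
#' @slot records data.frame of twist records.
#' @slot radius spherical support radius (length units of the lists).
#' @slot unit length unit of the source lists.
#' @slot symmetric TRUE for the single-list case (record (a,b) present iff
#'   (b,a) present); cross-list descriptors are directed.
#' @slot queryIDs,neighborIDs particle ids of the full source lists
#'   (including particles with empty neighborhoods).
#' @slot querySource,neighborSource provenance lists.
#' @slot version on-disk schema version.
#' @exportClass TwistDescriptor
setClass("TwistDescriptor",
  representation(records = "data.frame", radius = "numeric",
                 unit = "character", symmetric = "logical",
                 queryIDs = "integer", neighborIDs = "integer",
                 querySource = "list", neighborSource = "list",
                 version = "character"))

.TD_VERSION <- "1"

.TD_COLS <- c("query_id", "neighbor_id", "tomo_id",
              "zeta_x", "zeta_y", "zeta_z",
              "trans_x", "trans_y", "trans_z",
              "euclidean_distance", "angular_distance",
              "axis_x", "axis_y", "axis_z",
              "inplane_query", "inplane_neighbor")

setValidity("TwistDescriptor", function(object) {
  msgs <- character(0)
  miss <- setdiff(.TD_COLS, names(object@records))
  if (length(miss))
    msgs <- c(msgs, paste("records missing columns:",
                          paste(miss, collapse = ", ")))
  if (length(object@radius) != 1L || object@radius <= 0)
    msgs <- c(msgs, "radius must be a single positive number")
  if (nrow(object@records)) {
    r <- object@records
    if (any(r$query_id == r$neighbor_id))
      msgs <- c(msgs, "self-pair record (query_id == neighbor_id)")
    if (any(r$euclidean_distance > object@radius + 1e-9))
      msgs <- c(msgs, "record beyond the support radius")
  }
  if (length(msgs)) msgs else TRUE
})

#' @rdname TwistDescriptor-class
#' @param td,object a \code{TwistDescriptor}.
#' @export
twistRecords <- function(td) td@records

#' @rdname TwistDescriptor-class
#' @export
supportRadius <- function(td) td@radius

#' @rdname TwistDescriptor-class
#' @param ... ignored (base generic signature).
#' @export
isSymmetric.TwistDescriptor <- function(object, ...) object@symmetric

setMethod("show", "TwistDescriptor", function(object) {
  cat(sprintf(paste0("TwistDescriptor: %d record%s, radius %g %s, %s\n"),
              nrow(object@records),
              if (nrow(object@records) == 1) "" else "s",
              object@radius, object@unit,
              if (object@symmetric) "symmetric (single list)"
              else "directed (cross-list)"))
  cat(sprintf("  %d quer%s, %d neighbor source particle%s\n",
              length(object@queryIDs),
              if (length(object@queryIDs) == 1) "y" else "ies",
              length(object@neighborIDs),
              if (length(object@neighborIDs) == 1) "" else "s"))
  invisible(NULL)
})

#' Compute the twist descriptor of one or two particle lists
#'
#' For every ordered pair (query, neighbor) with equal tomogram id and
#' Euclidean distance in (0, radius] (closed ball), the relative pose is
#' computed in the query's canonical frame and stored as a twist record.
#' The neighbor search is exact (block-wise scan, identical to brute
#' force). With a single list the descriptor is symmetric; with distinct
#' query and neighbor lists (e.g. ribosome exit sites against entry sites)
#' it is directed.
#'
#' @param queries a \code{\link{ParticleList}}.
#' @param neighbors optional second \code{ParticleList}; defaults to
#'   \code{queries}.
#' @param radius support radius in the lists' length unit.
#' @return a \code{\link{TwistDescriptor}}.
#' @examples
#' pl <- particleList(rbind(c(0, 0, 0), c(5, 0, 0)))
#' td <- computeTwist(pl, radius = 10)
#' twistRecords(td)[, c("query_id", "neighbor_id", "euclidean_distance")]
#' @export
computeTwist <- function(queries, neighbors = NULL, radius) {
  stopifnot(radius > 0)
  symmetric <- is.null(neighbors)
  if (symmetric) neighbors <- queries
  if (queries@unit != neighbors@unit)
    stop("unit mismatch: queries in '", queries@unit, "', neighbors in '",
         neighbors@unit, "'")
  pr <- if (symmetric)
    .fixedRadiusPairs(positions(queries), tomoIDs(queries), radius)
  else
    .fixedRadiusPairs(positions(queries), tomoIDs(queries), radius,
                      positions(neighbors), tomoIDs(neighbors),
                      drop_self = FALSE)
  qrows <- .rotToRows(rotations(queries))
  nrows <- .rotToRows(rotations(neighbors))
  inq <- if (nrow(qrows)) .inplaneAngles(qrows) else numeric(0)
  inn <- if (nrow(nrows)) .inplaneAngles(nrows) else numeric(0)
  i <- pr$i; j <- pr$j
  m <- length(i)
  if (m) {
    rel <- .relRotRows(qrows, i, j)
    dp <- positions(neighbors)[j, , drop = FALSE] -
      positions(queries)[i, , drop = FALSE]
    trans <- .rotateRowsT(qrows[i, , drop = FALSE], dp)
    zeta <- .logRows(rel)
    ang <- .rownorm(zeta)
    axis <- zeta / ifelse(ang > 1e-9, ang, NA_real_)
    rec <- data.frame(query_id = particleIDs(queries)[i],
                      neighbor_id = particleIDs(neighbors)[j],
                      tomo_id = tomoIDs(queries)[i],
                      zeta_x = zeta[, 1], zeta_y = zeta[, 2],
                      zeta_z = zeta[, 3],
                      trans_x = trans[, 1], trans_y = trans[, 2],
                      trans_z = trans[, 3],
                      euclidean_distance = pr$d,
                      angular_distance = ang,
                      axis_x = axis[, 1], axis_y = axis[, 2],
                      axis_z = axis[, 3],
                      inplane_query = inq[i], inplane_neighbor = inn[j])
    rec <- rec[order(rec$query_id, rec$neighbor_id), , drop = FALSE]
    rownames(rec) <- NULL
  } else {
    rec <- as.data.frame(stats::setNames(
      rep(list(numeric(0)), length(.TD_COLS)), .TD_COLS))
    rec$query_id <- integer(0); rec$neighbor_id <- integer(0)
    rec$tomo_id <- integer(0)
  }
  new("TwistDescriptor", records = rec, radius = radius,
      unit = queries@unit, symmetric = symmetric,
      queryIDs = particleIDs(queries),
      neighborIDs = particleIDs(neighbors),
      querySource = provenance(queries),
      neighborSource = provenance(neighbors),
      version = .TD_VERSION)
}

#' Proximity clustering: affiliate particles to objects
#'
#' Interprets the (symmetric) twist descriptor as an undirected graph and
#' returns its connected components as object affiliations. Components
#' smaller than \code{min_size} are given an NA object id (these particles
#' are the ones removed by geometric cleaning). Object ids are assigned
#' deterministically, ascending by the smallest member particle id,
#' starting at 0.
#'
#' @param td a symmetric \code{\link{TwistDescriptor}} (cross-list
#'   descriptors are refused: affiliation is defined on undirected graphs).
#' @param min_size minimum component size to keep (e.g. 3 subunits for a
#'   ring complex).
#' @return named integer vector mapping every query particle id to an
#'   object id (NA for dropped components).
#' @export
proximityClusters <- function(td, min_size = 1L) {
  if (!td@symmetric)
    stop("proximity clustering requires a symmetric (single-list) ",
         "descriptor; cross-list descriptors are directed")
  stopifnot(min_size >= 1L)
  ids <- td@queryIDs
  out <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(td@records$query_id),
               to = as.character(td@records$neighbor_id)),
    directed = FALSE,
    vertices = data.frame(name = as.character(ids)))
  comp <- igraph::components(g)
  memb <- comp$membership
  keep <- which(comp$csize >= min_size)
  if (length(keep)) {
    ## deterministic ids: ascending by smallest member particle id
    mins <- vapply(keep, function(cc)
      min(ids[memb == cc]), numeric(1))
    relabel <- stats::setNames(order(order(mins)) - 1L, keep)
    sel <- memb %in% keep
    out[names(memb)[sel]] <- relabel[as.character(memb[sel])]
  }
  out[as.character(ids)]
}

#' Save / load a twist descriptor
#'
#' Lossless round trip of the record table plus provenance (radius, unit,
#' symmetry flag, source ids) as a typed CSV with a commented header. A
#' version marker is checked on load.
#'
#' @param td a \code{\link{TwistDescriptor}}.
#' @param path file path.
#' @return \code{saveDescriptor}: the path invisibly;
#'   \code{loadDescriptor}: the descriptor.
#' @export
saveDescriptor <- function(td, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# tomotwist descriptor v%s", td@version),
               sprintf("# radius=%.12g", td@radius),
               sprintf("# unit=%s", td@unit),
               sprintf("# symmetric=%d", as.integer(td@symmetric)),
               sprintf("# query_ids=%s",
                       paste(td@queryIDs, collapse = " ")),
               sprintf("# neighbor_ids=%s",
                       paste(td@neighborIDs, collapse = " "))), con)
  utils::write.csv(td@records, con, row.names = FALSE)
  invisible(path)
}

#' @rdname saveDescriptor
#' @export
loadDescriptor <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  vline <- grep("descriptor v", hdr, value = TRUE)
  if (!length(vline))
    stop("not a tomotwist descriptor file (missing version header)")
  v <- sub(".*descriptor v", "", vline[1])
  if (v != .TD_VERSION)
    stop("descriptor version mismatch: file has v", v, ", this package ",
         "reads v", .TD_VERSION)
  getv <- function(key) {
    ln <- grep(paste0("^# ", key, "="), hdr, value = TRUE)
    if (!length(ln)) stop("corrupted descriptor header: missing ", key)
    sub(paste0("^# ", key, "="), "", ln[1])
  }
  rec <- utils::read.csv(text = paste(lines[!grepl("^#", lines)],
                                      collapse = "\n"))
  rec$query_id <- as.integer(rec$query_id)
  rec$neighbor_id <- as.integer(rec$neighbor_id)
  rec$tomo_id <- as.integer(rec$tomo_id)
  new("TwistDescriptor", records = rec,
      radius = as.numeric(getv("radius")), unit = getv("unit"),
      symmetric = getv("symmetric") == "1",
      queryIDs = as.integer(strsplit(getv("query_ids"), " ")[[1]]),
      neighborIDs = as.integer(strsplit(getv("neighbor_ids"), " ")[[1]]),
      querySource = list(file = path), neighborSource = list(file = path),
      version = v)
}

## internal: rebuild a descriptor with a subset of records, preserving
## provenance; `note` is appended to the query source provenance.
.subsetDescriptor <- function(td, keep, note = NULL) {
  rec <- td@records[keep, , drop = FALSE]
  rownames(rec) <- NULL
  td@records <- rec
  if (!is.null(note))
    td@querySource <- c(td@querySource, list(reduction = note))
  td
}
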