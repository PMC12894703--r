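## Readers and writers for particle-list formats.
##
## Orientation adapters (all round-trip tested):
##   relion_star : intrinsic ZYZ angles rot/tilt/psi,
##                 w = Rz(rot) Ry(tilt) Rz(psi)
##   motl_em/csv : TOM/AV3 ZXZ angles phi/psi/theta,
##                 w = Rz(psi) Rx(theta) Rz(phi)
##   dynamo_tbl  : ZXZ angles tdrot/tilt/narot,
##                 w = Rz(narot) Rx(tilt) Rz(tdrot)
##   twist_csv   : rotation matrix stored row-major (r11..r33), no Euler
##                 ambiguity; the package's native interchange dialect.
## Shift/offset columns are folded into positions at read time; writers emit
## zero shifts.

.TWIST_CSV_VERSION <- "1"
.TWIST_CSV_COLS <- c("particle_id", "tomo_id", "x", "y", "z",
                     paste0("r", c(11, 12, 13, 21, 22, 23, 31, 32, 33)),
                     "score", "object_id", "class_label")

.MOTL_CSV_COLS <- c("score", "temp_1", "temp_2", "particle_id", "tomo_id",
                    "object_id", "wedge_id", "x", "y", "z", "shift_x",
                    "shift_y", "shift_z", "temp_3", "temp_4", "temp_5",
                    "phi", "psi", "theta", "class")

#' Read a particle list
#'
#' Readers for common subtomogram-averaging particle-list formats. All
#' orientations are converted to the internal convention (rotation mapping
#' the canonical reference frame onto the particle); shift columns are
#' folded into positions. Row order is preserved. The format is never
#' sniffed: an explicit format argument is required because silent
#' misparses corrupt geometry.
#'
#' @param path input file.
#' @param format one of \code{"relion_star"}, \code{"motl_em"} (binary
#'   TOM/AV3 EM motive list), \code{"motl_csv"}, \code{"dynamo_tbl"},
#'   \code{"twist_csv"} (native dialect, self-describing).
#' @param unit length unit of the coordinates in the file ("voxel" for the
#'   pixel-based formats unless stated otherwise); ignored for
#'   \code{twist_csv}, which stores its unit.
#' @param pixel_size Angstrom per voxel; required when \code{unit} is
#'   "voxel".
#' @return a \code{\link{ParticleList}}.
#' @export
readParticleList <- function(path,
                             format = c("twist_csv", "relion_star",
                                        "motl_em", "motl_csv",
                                        "dynamo_tbl"),
                             unit = "voxel", pixel_size = NA_real_) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
         twist_csv  = .readTwistCsv(path),
         relion_star = .readRelionStar(path, unit, pixel_size),
         motl_em    = .readMotl(.readEmData(path), path, unit, pixel_size),
         motl_csv   = .readMotlCsv(path, unit, pixel_size),
         dynamo_tbl = .readDynamoTbl(path, unit, pixel_size))
}

#' Write a particle list
#'
#' Output is bit-stable for identical input: deterministic field ordering
#' and fixed 6-decimal float precision. Fields a format cannot represent
#' (e.g. class labels in motive lists) are dropped with a warning.
#'
#' @param pl a \code{\link{ParticleList}}.
#' @param path output file.
#' @param format see \code{\link{readParticleList}}.
#' @return the path, invisibly.
#' @export
writeParticleList <- function(pl, path,
                              format = c("twist_csv", "relion_star",
                                         "motl_em", "motl_csv",
                                         "dynamo_tbl")) {
  format <- match.arg(format)
  switch(format,
         twist_csv  = .writeTwistCsv(pl, path),
         relion_star = .writeRelionStar(pl, path),
         motl_em    = .writeMotlEm(pl, path),
         motl_csv   = .writeMotlCsv(pl, path),
         dynamo_tbl = .writeDynamoTbl(pl, path))
  invisible(path)
}

.num6 <- function(x) {
  out <- sprintf("%.6f", x)
  out[is.na(x)] <- "NA"
  out
}

## ---- native twist_csv ------------------------------------------------

.readTwistCsv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  v <- sub(".*particle list v", "", grep("particle list v", hdr, value = TRUE))
  if (!length(v) || v[1] != .TWIST_CSV_VERSION)
    stop("not a twist_csv particle list (or unsupported version; expected v",
         .TWIST_CSV_VERSION, ")")
  meta <- grep("^# unit=", hdr, value = TRUE)
  unit <- sub("^# unit=([a-z]+).*", "\\1", meta[1])
  ps <- suppressWarnings(as.numeric(sub(".*pixel_size=", "", meta[1])))
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        stringsAsFactors = FALSE)
  miss <- setdiff(.TWIST_CSV_COLS, names(df))
  if (length(miss)) stop("twist_csv missing mandatory columns: ",
                         paste(miss, collapse = ", "))
  n <- nrow(df)
  rot <- array(0, c(3, 3, n))
  for (a in 1:3) for (b in 1:3)
    rot[a, b, ] <- df[[paste0("r", a, b)]]
  for (k in seq_len(n)) rot[, , k] <- projectToSO3(rot[, , k])
  particleList(cbind(df$x, df$y, df$z), rot,
               particle_id = df$particle_id, tomo_id = df$tomo_id,
               object_id = df$object_id, score = df$score,
               class_label = ifelse(df$class_label == "" |
                                      is.na(df$class_label),
                                    NA_character_, df$class_label),
               unit = unit, pixel_size = ps,
               provenance = list(format = "twist_csv", file = path))
}

.writeTwistCsv <- function(pl, path) {
  n <- nParticles(pl)
  rows <- .rotToRows(pl@rotation)
  df <- c(list(pl@particleID, pl@tomoID),
          lapply(1:3, function(k) .num6(pl@position[, k])),
          lapply(1:9, function(k) .num6(rows[, k])),
          list(.num6(pl@score),
               ifelse(is.na(pl@objectID), "NA", pl@objectID),
               ifelse(is.na(pl@classLabel), "", pl@classLabel)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# tomotwist particle list v%s", .TWIST_CSV_VERSION),
               sprintf("# unit=%s pixel_size=%s", pl@unit,
                       ifelse(is.na(pl@pixelSize), "NA",
                              .num6(pl@pixelSize)))), con)
  writeLines(paste(.TWIST_CSV_COLS, collapse = ","), con)
  if (n) writeLines(do.call(paste, c(df, sep = ",")), con)
}

## ---- Relion STAR -----------------------------------------------------

.readRelionStar <- function(path, unit, pixel_size) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  ## locate the loop_ whose tags contain coordinates (optics blocks are
  ## skipped); STOPGAP-style STAR variants parse the same way.
  loops <- which(lines == "loop_")
  if (!length(loops)) stop("no loop_ block found in STAR file")
  for (lp in loops) {
    k <- lp + 1L
    tags <- character(0)
    while (k <= length(lines) && startsWith(lines[k], "_")) {
      tags <- c(tags, sub("\\s+#.*$", "", sub("^_", "", lines[k])))
      k <- k + 1L
    }
    if ("rlnCoordinateX" %in% tags) {
      end <- k
      while (end <= length(lines) && !startsWith(lines[end], "data_") &&
             lines[end] != "loop_")
        end <- end + 1L
      body <- if (end > k) lines[k:(end - 1L)] else character(0)
      return(.parseStarBody(body, tags, path, unit, pixel_size))
    }
  }
  stop("no particle loop with rlnCoordinateX found in STAR file")
}

.parseStarBody <- function(body, tags, path, unit, pixel_size) {
  fields <- strsplit(body, "\\s+")
  bad <- lengths(fields) != length(tags)
  if (any(bad)) stop("STAR row(s) with wrong field count: ",
                     paste(utils::head(which(bad), 3), collapse = ", "))
  df <- if (length(fields))
    as.data.frame(do.call(rbind, fields), stringsAsFactors = FALSE)
  else as.data.frame(matrix(character(0), 0, length(tags)),
                     stringsAsFactors = FALSE)
  names(df) <- tags
  need <- c("rlnCoordinateX", "rlnCoordinateY", "rlnCoordinateZ",
            "rlnAngleRot", "rlnAngleTilt", "rlnAnglePsi")
  miss <- setdiff(need, tags)
  if (length(miss)) stop("STAR file missing mandatory columns: ",
                         paste(miss, collapse = ", "))
  num <- function(tag) {
    v <- df[[tag]]
    v[v == "NA"] <- NA_character_
    as.numeric(v)
  }
  pos <- cbind(num("rlnCoordinateX"), num("rlnCoordinateY"),
               num("rlnCoordinateZ"))
  ## sub-voxel shifts in Angstrom are folded into the position (the actual
  ## particle center is coordinate - originAngst / pixelSize in voxels)
  if ("rlnOriginXAngst" %in% tags) {
    if (is.na(pixel_size) || pixel_size <= 0)
      stop("rlnOriginX/Y/ZAngst present: pixel_size (Angstrom/voxel) is ",
           "required to fold shifts into coordinates")
    pos <- pos - cbind(num("rlnOriginXAngst"), num("rlnOriginYAngst"),
                       num("rlnOriginZAngst")) / pixel_size
  }
  rot <- eulerZYZToMatrix(num("rlnAngleRot"), num("rlnAngleTilt"),
                          num("rlnAnglePsi"))
  tomo <- if ("rlnTomoName" %in% tags) {
    ## keep numeric tomogram identifiers when the names carry them;
    ## otherwise number by order of appearance
    if (all(grepl("[0-9]+$", df$rlnTomoName)))
      as.integer(sub(".*?([0-9]+)$", "\\1", df$rlnTomoName))
    else as.integer(factor(df$rlnTomoName,
                           levels = unique(df$rlnTomoName)))
  } else if ("ttTomoID" %in% tags) as.integer(df$ttTomoID) else 1L
  score <- if ("ttScore" %in% tags) num("ttScore")
  else if ("rlnAutopickFigureOfMerit" %in% tags)
    num("rlnAutopickFigureOfMerit") else NA_real_
  pid <- if ("ttParticleID" %in% tags) as.integer(df$ttParticleID) else NULL
  oid <- if ("ttObjectID" %in% tags)
    suppressWarnings(as.integer(df$ttObjectID)) else NA_integer_
  lab <- if ("ttClassLabel" %in% tags)
    ifelse(df$ttClassLabel == "NA", NA_character_, df$ttClassLabel)
  else NA_character_
  particleList(pos, rot, particle_id = pid, tomo_id = tomo,
               object_id = oid, score = score, class_label = lab,
               unit = unit, pixel_size = pixel_size,
               provenance = list(format = "relion_star", file = path))
}

.writeRelionStar <- function(pl, path) {
  n <- nParticles(pl)
  ang <- t(vapply(seq_len(n),
                  function(k) matrixToEulerZYZ(pl@rotation[, , k]),
                  numeric(3)))
  tags <- c("rlnTomoName", "rlnCoordinateX", "rlnCoordinateY",
            "rlnCoordinateZ", "rlnAngleRot", "rlnAngleTilt", "rlnAnglePsi",
            "ttParticleID", "ttScore", "ttObjectID", "ttClassLabel")
  cols <- list(sprintf("tomo_%d", pl@tomoID),
               .num6(pl@position[, 1]), .num6(pl@position[, 2]),
               .num6(pl@position[, 3]),
               .num6(if (n) ang[, 1] else numeric(0)),
               .num6(if (n) ang[, 2] else numeric(0)),
               .num6(if (n) ang[, 3] else numeric(0)),
               as.character(pl@particleID), .num6(pl@score),
               ifelse(is.na(pl@objectID), "NA",
                      as.character(pl@objectID)),
               ifelse(is.na(pl@classLabel), "NA", pl@classLabel))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("", "data_particles", "", "loop_",
               sprintf("_%s #%d", tags, seq_along(tags))), con)
  if (n) writeLines(do.call(paste, cols), con)
}

## ---- TOM/AV3 motive list --------------------------------------------

.motlMatrix <- function(pl) {
  n <- nParticles(pl)
  if (any(!is.na(pl@classLabel)))
    warning("motl format cannot represent class labels; dropped")
  m <- matrix(0, 20, n)
  m[1, ] <- ifelse(is.na(pl@score), 0, pl@score)
  m[4, ] <- pl@particleID
  m[5, ] <- pl@tomoID
  ## object ids are stored 1-based in the feature-number row; 0 keeps its
  ## conventional meaning "unaffiliated"
  m[6, ] <- ifelse(is.na(pl@objectID), 0, pl@objectID + 1L)
  m[8:10, ] <- t(pl@position)
  ang <- vapply(seq_len(n), function(k) matrixToEulerZXZ(pl@rotation[, , k]),
                numeric(3))
  if (n) m[17:19, ] <- ang  # phi, psi, theta in degrees
  m
}

.readMotl <- function(m, path, unit, pixel_size) {
  if (nrow(m) != 20L) stop("motive list must have 20 rows, found ", nrow(m))
  pos <- t(m[8:10, , drop = FALSE] + m[11:13, , drop = FALSE])
  rot <- eulerZXZToMatrix(m[17, ], m[18, ], m[19, ])
  score <- m[1, ]
  oid <- as.integer(m[6, ]) - 1L
  oid[oid < 0L] <- NA_integer_
  particleList(pos, rot, particle_id = as.integer(m[4, ]),
               tomo_id = as.integer(m[5, ]), object_id = oid,
               score = score, unit = unit, pixel_size = pixel_size,
               provenance = list(format = "motl", file = path))
}

.writeMotlEm <- function(pl, path) {
  .writeEmData(.motlMatrix(pl), path)
}

.readMotlCsv <- function(path, unit, pixel_size) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.MOTL_CSV_COLS, names(df))
  if (length(miss)) stop("motl_csv missing mandatory columns: ",
                         paste(miss, collapse = ", "))
  .readMotl(t(as.matrix(df[.MOTL_CSV_COLS])), path, unit, pixel_size)
}

.writeMotlCsv <- function(pl, path) {
  m <- t(.motlMatrix(pl))
  colnames(m) <- .MOTL_CSV_COLS
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(.MOTL_CSV_COLS, collapse = ","), con)
  if (nrow(m))
    writeLines(apply(m, 1, function(r) paste(.num6(r), collapse = ",")), con)
}

## ---- Dynamo table ----------------------------------------------------

.readDynamoTbl <- function(path, unit, pixel_size) {
  if (!length(readLines(path, n = 1L)))
    return(particleList(matrix(0, 0, 3), unit = unit,
                        pixel_size = pixel_size,
                        provenance = list(format = "dynamo_tbl",
                                          file = path)))
  df <- utils::read.table(path, stringsAsFactors = FALSE)
  if (ncol(df) < 26L)
    stop("dynamo table needs >= 26 columns, found ", ncol(df))
  pos <- as.matrix(df[, 24:26]) + as.matrix(df[, 4:6])
  rot <- eulerZXZToMatrix(phi = df[, 7], psi = df[, 9], theta = df[, 8])
  oid <- as.integer(df[, 21]) - 1L  # stored 1-based; 0 = unaffiliated
  oid[oid < 0L] <- NA_integer_
  particleList(pos, rot, particle_id = as.integer(df[, 1]),
               tomo_id = as.integer(df[, 20]), object_id = oid,
               score = df[, 10], unit = unit, pixel_size = pixel_size,
               provenance = list(format = "dynamo_tbl", file = path))
}

.writeDynamoTbl <- function(pl, path) {
  n <- nParticles(pl)
  if (any(!is.na(pl@classLabel)))
    warning("dynamo_tbl format cannot represent class labels; dropped")
  ang <- t(vapply(seq_len(n),
                  function(k) matrixToEulerZXZ(pl@rotation[, , k]),
                  numeric(3)))
  m <- matrix(0, n, 26)
  m[, 1] <- pl@particleID
  m[, 2] <- 1
  if (n) {
    m[, 7] <- ang[, 1]  # tdrot (= phi slot of the ZXZ adapter)
    m[, 8] <- ang[, 3]  # tilt
    m[, 9] <- ang[, 2]  # narot
  }
  m[, 10] <- ifelse(is.na(pl@score), 0, pl@score)
  m[, 20] <- pl@tomoID
  m[, 21] <- ifelse(is.na(pl@objectID), 0, pl@objectID + 1L)
  m[, 24:26] <- pl@position
  con <- file(path, "w")
  on.exit(close(con))
  if (n)
    writeLines(apply(m, 1, function(r) paste(.num6(r), collapse = " ")), con)
  else writeLines(character(0), con)
}

## ---- EM / MRC binary volumes ----------------------------------------

## EM format: 512-byte header (byte 1 machine id, byte 4 data type code;
## int32 dims at bytes 5-16), then the data, x fastest.
.readEmData <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 4)
  dtype <- as.integer(hdr[4])
  dims <- readBin(con, "integer", 3, size = 4, endian = "little")
  readBin(con, "raw", 512 - 16)
  nvox <- prod(dims)
  data <- switch(as.character(dtype),
                 "1" = as.numeric(readBin(con, "integer", nvox, size = 1,
                                          signed = FALSE)),
                 "2" = as.numeric(readBin(con, "integer", nvox, size = 2,
                                          endian = "little")),
                 "4" = as.numeric(readBin(con, "integer", nvox, size = 4,
                                          endian = "little")),
                 "5" = readBin(con, "numeric", nvox, size = 4,
                               endian = "little"),
                 "9" = readBin(con, "numeric", nvox, size = 8,
                               endian = "little"),
                 stop("unsupported EM data type code ", dtype))
  if (length(data) != nvox) stop("truncated EM file: ", path)
  if (dims[3] == 1L) matrix(data, dims[1], dims[2])
  else array(data, dims)
}

.writeEmData <- function(x, path) {
  dims <- dim(x)
  if (length(dims) == 2L) dims <- c(dims, 1L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(6, 0, 0, 5)), con)          # PC machine id, float32
  writeBin(as.integer(dims), con, size = 4, endian = "little")
  writeBin(raw(512 - 16), con)
  writeBin(as.numeric(x), con, size = 4, endian = "little")
  invisible(path)
}

#' Read a binary 3D volume (EM or MRC) as a mask array
#'
#' Minimal readers for the two volume containers used for custom binary
#' mask supports. MRC modes 0 (int8), 1 (int16) and 2 (float32) are
#' supported; the voxel size is taken from the MRC cell dimensions when
#' present.
#'
#' @param path volume file.
#' @param format "em" or "mrc".
#' @return list with \code{data} (3D array) and \code{voxel_size}
#'   (Angstrom, NA when the file does not state one).
#' @export
readVolume <- function(path, format = c("em", "mrc")) {
  format <- match.arg(format)
  if (format == "em")
    return(list(data = .readEmData(path), voxel_size = NA_real_))
  con <- file(path, "rb")
  on.exit(close(con))
  dims <- readBin(con, "integer", 3, size = 4, endian = "little")
  mode <- readBin(con, "integer", 1, size = 4, endian = "little")
  readBin(con, "integer", 3, size = 4, endian = "little")   # nstart
  mxyz <- readBin(con, "integer", 3, size = 4, endian = "little")
  cella <- readBin(con, "numeric", 3, size = 4, endian = "little")
  readBin(con, "raw", 92 - 52)
  nsymbt <- readBin(con, "integer", 1, size = 4, endian = "little")
  readBin(con, "raw", 1024 - 96 + max(nsymbt, 0))
  nvox <- prod(dims)
  data <- switch(as.character(mode),
                 "0" = as.numeric(readBin(con, "integer", nvox, size = 1)),
                 "1" = as.numeric(readBin(con, "integer", nvox, size = 2,
                                          endian = "little")),
                 "2" = readBin(con, "numeric", nvox, size = 4,
                               endian = "little"),
                 stop("unsupported MRC mode ", mode))
  if (length(data) != nvox) stop("truncated MRC file: ", path)
  vs <- if (all(mxyz > 0) && all(cella > 0)) cella[1] / mxyz[1] else NA_real_
  list(data = array(data, dims), voxel_size = vs)
}
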