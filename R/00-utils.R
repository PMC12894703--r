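## Internal helpers shared across the package.

.DEG2RAD <- pi / 180
.RAD2DEG <- 180 / pi

#' Convert degrees to radians
#' @param x numeric vector of angles in degrees.
#' @return numeric vector in radians.
#' @export
radians <- function(x) x * .DEG2RAD

#' Convert radians to degrees
#' @param x numeric vector of angles in radians.
#' @return numeric vector in degrees.
#' @export
degrees <- function(x) x * .RAD2DEG

## clamp to [-1, 1] before acos/asin (x first so dims are preserved)
.clamp1 <- function(x) pmin(pmax(x, -1), 1)

.vnorm <- function(v) sqrt(sum(v * v))

.unitize <- function(v, what = "vector") {
  n <- .vnorm(v)
  if (n < 1e-12) stop(what, " has zero norm")
  v / n
}

## Row-wise norms of an n x 3 matrix
.rownorm <- function(m) sqrt(rowSums(m * m))

## Flatten a 3x3xN rotation array to an N x 9 row-major matrix
## (columns r11, r12, r13, r21, ..., r33).
.rotToRows <- function(rot) {
  if (length(dim(rot)) == 2L) rot <- array(rot, c(3, 3, 1))
  n <- dim(rot)[3]
  out <- matrix(0, n, 9)
  for (a in 1:3) for (b in 1:3) out[, (a - 1L) * 3L + b] <- rot[a, b, ]
  out
}

## Inverse of .rotToRows
.rowsToRot <- function(rows) {
  if (is.null(dim(rows))) rows <- matrix(rows, 1)
  n <- nrow(rows)
  rot <- array(0, c(3, 3, n))
  for (a in 1:3) for (b in 1:3) rot[a, b, ] <- rows[, (a - 1L) * 3L + b]
  rot
}

## Relative rotations R_i^T R_j for index vectors i, j into an N x 9
## row-major rotation table; returns M x 9 row-major matrix.
.relRotRows <- function(rows, i, j) {
  out <- matrix(0, length(i), 9)
  for (a in 1:3) {
    for (b in 1:3) {
      ## rel[a, b] = sum_k R_i[k, a] * R_j[k, b]
      acc <- 0
      for (k in 1:3) {
        acc <- acc + rows[i, (k - 1L) * 3L + a] * rows[j, (k - 1L) * 3L + b]
      }
      out[, (a - 1L) * 3L + b] <- acc
    }
  }
  out
}

## Apply rotations (N x 9 row-major, one per row) to row vectors v (N x 3):
## returns R_i v_i per row.
.rotateRows <- function(rows, v) {
  cbind(rows[, 1] * v[, 1] + rows[, 2] * v[, 2] + rows[, 3] * v[, 3],
        rows[, 4] * v[, 1] + rows[, 5] * v[, 2] + rows[, 6] * v[, 3],
        rows[, 7] * v[, 1] + rows[, 8] * v[, 2] + rows[, 9] * v[, 3])
}

## Same with the transposed rotations: R_i^T v_i per row.
.rotateRowsT <- function(rows, v) {
  cbind(rows[, 1] * v[, 1] + rows[, 4] * v[, 2] + rows[, 7] * v[, 3],
        rows[, 2] * v[, 1] + rows[, 5] * v[, 2] + rows[, 8] * v[, 3],
        rows[, 3] * v[, 1] + rows[, 6] * v[, 2] + rows[, 9] * v[, 3])
}

## Run an expression with a private RNG stream, restoring the caller's state.
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## All ordered same-tomo point pairs with 0 < distance <= radius (closed
## ball). Exact block-wise scan; returns list(i, j, d) with i as query index.
.fixedRadiusPairs <- function(pos, tomo, radius, pos2 = NULL, tomo2 = NULL,
                              drop_self = TRUE, block = 1024L) {
  cross <- !is.null(pos2)
  if (!cross) { pos2 <- pos; tomo2 <- tomo }
  n1 <- nrow(pos); n2 <- nrow(pos2)
  ii <- integer(0); jj <- integer(0); dd <- numeric(0)
  if (n1 == 0L || n2 == 0L) return(list(i = ii, j = jj, d = dd))
  r2 <- radius * radius
  for (start in seq(1L, n1, by = block)) {
    idx <- start:min(start + block - 1L, n1)
    d2 <- outer(rowSums(pos[idx, , drop = FALSE]^2), rowSums(pos2^2), "+") -
      2 * (pos[idx, , drop = FALSE] %*% t(pos2))
    keep <- d2 <= r2 + 1e-12
    ## restrict to equal tomo ids
    keep <- keep & outer(tomo[idx], tomo2, "==")
    if (drop_self && !cross) {
      sel <- cbind(seq_along(idx), idx)
      keep[sel] <- FALSE
    }
    w <- which(keep, arr.ind = TRUE)
    if (nrow(w)) {
      qi <- idx[w[, 1]]
      nj <- w[, 2]
      ## recompute distances by direct subtraction: the blocked quadratic
      ## form suffers cancellation for near-coincident points
      d <- sqrt(rowSums((pos[qi, , drop = FALSE] -
                           pos2[nj, , drop = FALSE])^2))
      pos_ok <- d > 1e-12 & d <= radius + 1e-12
      ii <- c(ii, qi[pos_ok]); jj <- c(jj, nj[pos_ok]); dd <- c(dd, d[pos_ok])
    }
  }
  o <- order(ii, jj)
  list(i = ii[o], j = jj[o], d = dd[o])
}
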