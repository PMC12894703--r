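## Shared fixtures and independent oracles, built in code at test time.

## seeded Haar-random rotations
randRots <- function(n, seed) {
  set.seed(seed)
  randomRotations(n)
}

## apply a global rigid motion (G, t) to a whole particle list
applyGlobalMotion <- function(pl, G, t) {
  pos <- positions(pl) %*% t(G) +
    matrix(t, nParticles(pl), 3, byrow = TRUE)
  rot <- rotations(pl)
  for (k in seq_len(nParticles(pl))) rot[, , k] <- G %*% rot[, , k]
  particleList(pos, rot, particle_id = particleIDs(pl),
               tomo_id = tomoIDs(pl), object_id = objectIDs(pl),
               score = scores(pl), class_label = classLabels(pl),
               unit = particleUnit(pl))
}

## random particle list in a box
randomScene <- function(n, box = 50, seed = 1, tomo_id = 1L) {
  set.seed(seed)
  particleList(matrix(runif(n * 3, 0, box), n, 3), randomRotations(n),
               tomo_id = tomo_id, score = runif(n))
}

## columns of a twist record table that are invariant under global motions
invariantCols <- c("zeta_x", "zeta_y", "zeta_z", "trans_x", "trans_y",
                   "trans_z", "euclidean_distance", "angular_distance",
                   "axis_x", "axis_y", "axis_z")

## independent oracle: connected components by hand-rolled breadth-first
## search over an edge list; returns component label per vertex id
bfsComponents <- function(ids, from, to) {
  adj <- lapply(stats::setNames(vector("list", length(ids)),
                                as.character(ids)), identity)
  for (k in seq_along(from)) {
    adj[[as.character(from[k])]] <- c(adj[[as.character(from[k])]], to[k])
    adj[[as.character(to[k])]] <- c(adj[[as.character(to[k])]], from[k])
  }
  comp <- stats::setNames(rep(NA_integer_, length(ids)),
                          as.character(ids))
  cur <- 0L
  for (v in as.character(ids)) {
    if (!is.na(comp[v])) next
    queue <- v
    comp[v] <- cur
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      for (w in as.character(adj[[u]])) {
        if (is.na(comp[w])) { comp[w] <- cur; queue <- c(queue, w) }
      }
    }
    cur <- cur + 1L
  }
  comp
}

## independent oracle: all ordered pairs within radius by a plain double
## loop over the distance matrix
brutePairs <- function(pos, tomo, radius) {
  n <- nrow(pos)
  out <- NULL
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || tomo[i] != tomo[j]) next
    d <- sqrt(sum((pos[i, ] - pos[j, ])^2))
    if (d > 0 && d <= radius + 1e-12) out <- rbind(out, c(i, j, d))
  }
  out
}

## 4x4 homogeneous matrix of a rigid motion
homog <- function(m) rbind(cbind(m$rotation, m$translation), c(0, 0, 0, 1))

## closed-form oracle for the cyclic delta: fold the in-plane angle
## difference into [0, pi/n]
foldDelta <- function(dalpha, n) {
  m <- abs(dalpha) %% (2 * pi / n)
  pmin(m, 2 * pi / n - m)
}
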