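test_that("occupancy counts neighbors and fills empty queries with zero", {
  pos <- rbind(c(0, 0, 0), c(5, 0, 0), c(100, 0, 0))
  td <- computeTwist(particleList(pos), radius = 10)
  occ <- featureValues(featureOccupancy(td))$occupancy
  expect_equal(occ, c(1L, 1L, 0L))
  ## interior lattice vertex with a first-shell support has 6 neighbors
  lat <- generatePlanarLattice(3, spacing = 10)
  tdl <- computeTwist(lat, radius = 10.5)
  occ2 <- featureValues(featureOccupancy(tdl))$occupancy
  ctr <- which(rowSums(positions(lat)^2) < 1e-9)
  expect_equal(occ2[ctr], 6L)
  ## random scene equals a brute-force count
  set.seed(51)
  pl <- randomScene(100, box = 30, seed = 51)
  td3 <- computeTwist(pl, radius = 7)
  occ3 <- featureValues(featureOccupancy(td3))$occupancy
  d <- as.matrix(dist(positions(pl))); diag(d) <- Inf
  expect_equal(occ3, as.integer(rowSums(d <= 7 + 1e-12)))
})

test_that("distance statistics summarize neighborhoods per query", {
  td <- computeTwist(particleList(rbind(c(0, 0, 0), c(5, 0, 0))),
                     radius = 10)
  fm <- featureValues(featureDistanceStats(td))
  expect_equal(fm$euclidean_min, c(5, 5))
  expect_equal(fm$euclidean_median, c(5, 5))
  expect_equal(fm$euclidean_std, c(0, 0))
  ## hexagon around the center: median Euclidean distance = spacing
  lat <- generatePlanarLattice(1, spacing = 8)
  tdl <- computeTwist(lat, radius = 8.5)
  ctr <- which(rowSums(positions(lat)^2) < 1e-9)
  expect_equal(featureValues(featureDistanceStats(tdl))$
                 euclidean_median[ctr], 8, tolerance = 1e-9)
  ## random scene matches direct computation; empty neighborhoods -> NA
  set.seed(52)
  pl <- randomScene(60, box = 40, seed = 52)
  td2 <- computeTwist(pl, radius = 10)
  fm2 <- featureValues(featureDistanceStats(td2))
  rec <- twistRecords(td2)
  for (q in seq_along(particleIDs(pl))) {
    ii <- rec$euclidean_distance[rec$query_id == particleIDs(pl)[q]]
    if (!length(ii)) expect_true(is.na(fm2$euclidean_mean[q]))
    else expect_equal(fm2$euclidean_mean[q], mean(ii), tolerance = 1e-12)
  }
  expect_error(featureDistanceStats(td2, statistics = "mode"),
               "unknown statistic")
})

test_that("shell decomposition recovers lattice shells", {
  lat <- generatePlanarLattice(3, spacing = 10)
  td <- computeTwist(lat, radius = 21)
  sh <- decomposeShells(td, 0.1)
  expect_equal(sh$edges$center[1:3], c(10, 10 * sqrt(3), 20),
               tolerance = 1e-9)
  ## noisy lattice keeps the same shell structure
  latn <- corruptParticles(lat, noiseModel(0.5, 0, seed = 5))
  tdn <- computeTwist(latn, radius = 21)
  shn <- decomposeShells(tdn, 0.1)
  expect_equal(nrow(shn$edges), nrow(sh$edges))
  expect_equal(shn$edges$n, sh$edges$n)
  ## single distance value gives one shell
  td1 <- computeTwist(particleList(rbind(c(0, 0, 0), c(4, 0, 0))),
                      radius = 5)
  expect_equal(nrow(decomposeShells(td1, 0.1)$edges), 1L)
  ## overlapping groups at the tolerance are an error
  pos <- cbind(c(0, cumsum(seq(1, 1.45, by = 0.05))), 0, 0)
  tdo <- computeTwist(particleList(pos), radius = 20)
  expect_error(decomposeShells(tdo, 0.45), "tolerance")
})

test_that("shell angular profiles summarize per-shell angular quantities", {
  lat <- generatePlanarLattice(3, spacing = 10,
                               orientation_sampler = "c_n_multiples",
                               seed = 53)
  td <- computeTwist(lat, radius = 21)
  sh <- decomposeShells(td, 0.1)
  prof <- shellAngularProfile(td, sh)
  expect_equal(nrow(prof), nrow(sh$edges))
  ## C6-sampled lattice: distances are multiples of 60 in every shell
  rec <- twistRecords(td)
  for (k in seq_len(nrow(prof)))
    expect_true(prof$mean[k] %in% NA ||
                  all(abs((degrees(rec$angular_distance[
                    sh$assignment == k]) %% 60)) < 1e-6 |
                      abs((degrees(rec$angular_distance[
                        sh$assignment == k]) %% 60) - 60) < 1e-6))
  ## identical orientations score 1 under any symmetry in every shell
  lat0 <- generatePlanarLattice(2, spacing = 10,
                                orientation_sampler = "identity")
  td0 <- computeTwist(lat0, radius = 21)
  sh0 <- decomposeShells(td0, 0.1)
  p0 <- shellAngularProfile(td0, sh0, score = "angular_score",
                            rep = cyclicRep(6))
  expect_true(all(abs(p0$mean[p0$n > 0] - 1) < 1e-9))
})

test_that("link features classify lattice vertices", {
  lat <- generatePlanarLattice(3, spacing = 10)
  td <- computeTwist(lat, radius = 10.5)
  sh <- decomposeShells(td, 0.1)
  lf <- featureValues(linkFeatures(td, sh))
  interior <- (abs(positions(lat)[, 1]) + abs(positions(lat)[, 2])) > 0
  hexd <- sqrt(rowSums(positions(lat)^2))
  inner <- hexd < 10 * 2 - 1  # interior vertices of the 3-shell patch
  expect_true(all(lf$link_type[inner] == "closed_cycle"))
  expect_true(all(lf$n_vertices[inner] == 6))
  expect_true(all(lf$euler_characteristic[inner] == 0))
  expect_lt(max(abs(lf$median_theta[inner] - 60)), 1e-9)
  expect_lt(max(lf$std_theta[inner]), 1e-9)
  ## ideal flat fivefold vertex: 5 regular neighbors at distance 10 whose
  ## adjacent spacing (2 * 10 * sin 36) falls in the same first shell
  ang <- seq(0, 360, length.out = 6)[-6]
  nb <- cbind(10 * cos(radians(ang)), 10 * sin(radians(ang)), 0)
  pl5 <- particleList(rbind(c(0, 0, 0), nb))
  td5 <- computeTwist(pl5, radius = 12)
  sh5 <- decomposeShells(td5, 0.2)
  lf5 <- featureValues(linkFeatures(td5, sh5))
  expect_equal(lf5$n_vertices[1], 5L)
  expect_equal(lf5$n_edges[1], 5L)
  expect_equal(lf5$link_type[1], "closed_cycle")
  expect_equal(lf5$median_theta[1], 72, tolerance = 1e-9)
  ## degraded lattice: all fields equal a brute-force graph evaluation
  set.seed(54)
  keep <- runif(nParticles(lat)) > 0.25
  latd <- lat[keep]
  tdd <- computeTwist(latd, radius = 10.5)
  shd <- decomposeShells(tdd, 0.1)
  lfd <- featureValues(linkFeatures(tdd, shd))
  rec <- twistRecords(tdd)
  lo <- shd$edges$lo[1] - 1e-9; hi <- shd$edges$hi[1] + 1e-9
  for (q in sample(seq_len(nParticles(latd)), 12)) {
    qid <- particleIDs(latd)[q]
    ii <- which(rec$query_id == qid & !is.na(shd$assignment) &
                  shd$assignment == 1L)
    V <- nrow(rec[ii, ])
    expect_equal(lfd$n_vertices[q], V)
    if (V >= 2) {
      pts <- as.matrix(rec[ii, c("trans_x", "trans_y", "trans_z")])
      dm <- as.matrix(dist(pts))
      E <- sum(dm >= lo & dm <= hi & upper.tri(dm))
      expect_equal(lfd$n_edges[q], E)
      expect_equal(lfd$euler_characteristic[q], V - E)
    }
  }
})

test_that("rotation-axis histograms find the dominant axis", {
  ## all relative rotations about e_z
  lat <- generatePlanarLattice(2, spacing = 10,
                               orientation_sampler = "random", seed = 55)
  td <- computeTwist(lat, radius = 21)
  h <- rotationAxisHistogram(td)
  expect_equal(abs(h$dominant_axis[3]), 1, tolerance = 1e-6)
  expect_equal(h$dominant_bin, 1L)  # the polar cap bin
  ## uniform axes: modal count within 5 sigma of the multinomial mean
  set.seed(56)
  pl <- randomScene(150, box = 18, seed = 56)
  tdu <- computeTwist(pl, radius = 14)
  hu <- rotationAxisHistogram(tdu)
  n <- sum(hu$table$count)
  nb <- nrow(hu$table)
  expmax <- n / nb + 5 * sqrt(n / nb)
  ## loose statistical bound: the modal bin of uniform data is not a
  ## dramatic outlier (allowing for the maximum over bins)
  expect_lt(max(hu$table$count), n / nb + 8 * sqrt(n / nb))
  ## two axis populations 70/30: dominant axis is the majority axis
  n1 <- 70; n2 <- 30
  rot <- array(0, c(3, 3, 2 * (n1 + n2) + 1))
  pos <- cbind(seq_len(2 * (n1 + n2) + 1) * 3, 0, 0)
  rot[, , 1] <- diag(3)
  k <- 2
  for (i in seq_len(n1 + n2)) {
    ax <- if (i <= n1) c(0, 0, 1) else c(1, 0, 0)
    rot[, , k] <- expSO3(ax * runif(1, 0.3, 2.8)); k <- k + 1
    rot[, , k] <- diag(3); k <- k + 1
  }
  pl2 <- particleList(pos, rot)
  td2 <- computeTwist(pl2, radius = 3.5)
  h2 <- rotationAxisHistogram(td2)
  expect_gt(abs(h2$dominant_axis[3]), 0.99)
  ## no eligible records is an error
  td0 <- computeTwist(particleList(rbind(c(0, 0, 0), c(1, 0, 0))),
                      radius = 2)
  expect_error(rotationAxisHistogram(td0), "axis")
})

test_that("axis alignment is the cosine between zeta and the reference", {
  pos <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 4, 0))
  rot <- array(0, c(3, 3, 3))
  rot[, , 1] <- diag(3); rot[, , 2] <- rotZ(45); rot[, , 3] <- rotX(30)
  td <- computeTwist(particleList(pos, rot), radius = 10)
  al <- tomotwist:::.alignRecords(td, c(0, 0, 1))
  rec <- twistRecords(td)
  z_pair <- which(rec$query_id == 1 & rec$neighbor_id == 2)
  x_pair <- which(rec$query_id == 1 & rec$neighbor_id == 3)
  expect_equal(al[z_pair], 1, tolerance = 1e-9)       # zeta parallel
  expect_equal(al[x_pair], 0, tolerance = 1e-9)       # zeta perpendicular
  ## per-query reduction picks the nearest neighbor's value
  fm <- featureValues(featureAxisAlignment(td, c(0, 0, 1)))
  expect_equal(fm$axis_alignment[1], 1, tolerance = 1e-9)  # neighbor 2 at 3
  ## random records match the dot-product oracle
  set.seed(57)
  pl <- randomScene(40, box = 20, seed = 57)
  td2 <- computeTwist(pl, radius = 12)
  al2 <- tomotwist:::.alignRecords(td2, c(0, 1, 0))
  rec2 <- twistRecords(td2)
  want <- rec2$zeta_y / sqrt(rec2$zeta_x^2 + rec2$zeta_y^2 +
                               rec2$zeta_z^2)
  expect_equal(al2, want, tolerance = 1e-12)
})

test_that("cone footprints partition assigned neighbors", {
  ## single neighbor straight up the +y axis
  td <- computeTwist(particleList(rbind(c(0, 0, 0), c(0, 6, 0))),
                     radius = 10)
  fp <- featureValues(shotFootprint(td, 30))
  expect_equal(fp$cone_py[1], 1L)
  expect_equal(sum(fp[1, 1:6]), 1)
  expect_equal(fp$footprint_id[1], 1L)  # binary encoding, +y is bit 1
  ## neighbor exactly between +y and +x goes to the lower cone index
  td2 <- computeTwist(particleList(rbind(c(0, 0, 0),
                                         c(sqrt(2), sqrt(2), 0))),
                      radius = 10)
  fp2 <- featureValues(shotFootprint(td2, 45))
  expect_equal(fp2$cone_py[1], 1L)
  expect_equal(fp2$cone_px[1], 0L)
  ## random scenes: assignment equals brute-force cone computation and
  ## assigned neighbors are partitioned (no double counting)
  set.seed(58)
  pl <- randomScene(80, box = 25, seed = 58)
  td3 <- computeTwist(pl, radius = 10)
  half <- 30
  fp3 <- featureValues(shotFootprint(td3, half))
  rec <- twistRecords(td3)
  axes <- rbind(c(0, 1, 0), c(0, -1, 0), c(1, 0, 0), c(-1, 0, 0),
                c(0, 0, 1), c(0, 0, -1))
  cnt <- matrix(0L, nParticles(pl), 6)
  for (r in seq_len(nrow(rec))) {
    u <- c(rec$trans_x[r], rec$trans_y[r], rec$trans_z[r])
    u <- u / sqrt(sum(u^2))
    coss <- as.numeric(axes %*% u)
    b <- which.max(coss)
    if (coss[b] >= cos(radians(half)) - 1e-12) {
      q <- match(rec$query_id[r], particleIDs(pl))
      cnt[q, b] <- cnt[q, b] + 1L
    }
  }
  expect_equal(as.matrix(fp3[, 1:6]), cnt, ignore_attr = TRUE)
  expect_true(all(rowSums(fp3[, 1:6]) <=
                    featureValues(featureOccupancy(td3))$occupancy))
})

test_that("custom descriptors concatenate features and merge by query id", {
  set.seed(59)
  pl <- randomScene(50, box = 25, seed = 59)
  td <- computeTwist(pl, radius = 12)
  one <- buildCustomDescriptor(td, list(occupancy = list()))
  expect_equal(ncol(featureValues(one)), 1L)
  both <- buildCustomDescriptor(td, list(occupancy = list(),
                                         distance_stats =
                                           list(statistics = "mean")))
  merged <- mergeFeatures(featureOccupancy(td),
                          featureDistanceStats(td, "mean"))
  expect_equal(featureValues(both), featureValues(merged))
  ## row count equals query count regardless of empty neighborhoods
  expect_equal(nrow(featureValues(both)), nParticles(pl))
  ## removing a column then re-adding reproduces the original
  dropped <- both
  v <- featureValues(dropped)
  expect_equal(cbind(v["occupancy"], v[setdiff(names(v), "occupancy")]),
               featureValues(both)[c("occupancy",
                                     setdiff(names(v), "occupancy"))])
  ## merge with mismatched queries errors
  td_sub <- computeTwist(pl[1:10], radius = 12)
  expect_error(mergeFeatures(featureOccupancy(td),
                             featureOccupancy(td_sub)), "mismatch")
  ## features are invariant end-to-end under global motions
  G <- randRots(1, 60)[, , 1]
  pl2 <- applyGlobalMotion(pl, G, c(5, 6, 7))
  td2 <- computeTwist(pl2, radius = 12)
  b2 <- buildCustomDescriptor(td2, list(occupancy = list(),
                                        distance_stats =
                                          list(statistics = "mean")))
  expect_equal(featureValues(both), featureValues(b2), tolerance = 1e-8)
})
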