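test_that("generators are pure functions of (spec, seed)", {
  a <- generatePlanarLattice(2, 10, "c_n_multiples", seed = 71)
  b <- generatePlanarLattice(2, 10, "c_n_multiples", seed = 71)
  expect_identical(positions(a), positions(b))
  expect_identical(rotations(a), rotations(b))
  sp <- chromatinSpec(n_helix = 1, n_stack = 5, n_tri = 5, n_mono = 20,
                      box = c(120, 120, 120))
  c1 <- generateChromatin(sp, seed = 72)
  c2 <- generateChromatin(sp, seed = 72)
  expect_identical(positions(c1), positions(c2))
  expect_identical(rotations(c1), rotations(c2))
  expect_false(identical(positions(c1),
                         positions(generateChromatin(sp, seed = 73))))
})

test_that("planar lattices have hexagonal first shells and Cn orientations", {
  lat1 <- generatePlanarLattice(1, spacing = 12)
  expect_equal(nParticles(lat1), 7L)
  ## first-shell central angles at the center are 60 degrees each
  td <- computeTwist(lat1, radius = 12.5)
  sh <- decomposeShells(td, 0.1)
  lf <- featureValues(linkFeatures(td, sh))
  ctr <- which(rowSums(positions(lat1)^2) < 1e-9)
  expect_equal(lf$median_theta[ctr], 60, tolerance = 1e-9)
  ## pairwise angular distances under c_n_multiples(6) are multiples of 60
  lat <- generatePlanarLattice(3, spacing = 10,
                               orientation_sampler = "c_n_multiples",
                               seed = 74)
  tdl <- computeTwist(lat, radius = 35)
  ad <- degrees(twistRecords(tdl)$angular_distance)
  expect_true(all(vapply(ad, function(a)
    any(abs(a - c(0, 60, 120, 180)) < 1e-6), logical(1))))
})

test_that("ring assemblies have the stated geometry", {
  ring <- generateRing(8, radius = 50)
  ## consecutive subunits differ by an in-plane rotation of 45 degrees
  for (k in 1:7)
    expect_equal(degrees(angularDistance(rotations(ring)[, , k],
                                         rotations(ring)[, , k + 1])),
                 45, tolerance = 1e-9)
  ## shifting along intrinsic -x by the radius collapses the ring
  coll <- shiftAlongIntrinsicAxis(ring, c(-1, 0, 0), 50)
  expect_lt(max(abs(positions(coll))), 1e-9)
  ## a C3 ring survives proximity clustering at min size 3
  r3 <- generateRing(3, radius = 10)
  td <- computeTwist(r3, radius = 2 * 10 * sin(pi / 3) + 0.1)
  expect_equal(unname(proximityClusters(td, 3)), rep(0L, 3))
})

test_that("chromatin building blocks realize the configured geometry", {
  ## a single stacked pair: translation along +y, twist about +y
  sp <- chromatinSpec(n_helix = 0, n_stack = 1, n_tri = 0, n_mono = 0,
                      box = c(60, 60, 60))
  pl <- generateChromatin(sp, seed = 75)
  expect_equal(nParticles(pl), 2L)
  expect_equal(as.numeric(dist(positions(pl))), 6, tolerance = 1e-9)
  expect_equal(degrees(angularDistance(rotations(pl)[, , 1],
                                       rotations(pl)[, , 2])), 15,
               tolerance = 1e-9)
  ## the partner sits on the first particle's intrinsic +y axis
  tv <- twistFromPair(rigidMotion(rotations(pl)[, , 1],
                                  positions(pl)[1, ]),
                      rigidMotion(rotations(pl)[, , 2],
                                  positions(pl)[2, ]))
  expect_equal(tv$trans, c(0, 6, 0), tolerance = 1e-9)
  ## a trinucleosome has exactly 2 particles in stacked configuration
  sp3 <- chromatinSpec(n_helix = 0, n_stack = 0, n_tri = 1, n_mono = 0,
                       box = c(80, 80, 80))
  pl3 <- generateChromatin(sp3, seed = 76)
  expect_equal(nParticles(pl3), 3L)
  sc <- stackClassifier(pl3)
  expect_equal(sum(sc$stacked), 2L)
  ## helix: 12 particles, 5 regular pairs and 1 widened pair recorded
  sph <- chromatinSpec(n_helix = 1, n_stack = 0, n_tri = 0, n_mono = 0,
                       box = c(200, 200, 200))
  plh <- generateChromatin(sph, seed = 77)
  expect_equal(nParticles(plh), 12L)
  prov <- provenance(plh)
  expect_equal(nrow(prov$stacked_pairs), 5L)
  expect_equal(nrow(prov$wide_pairs), 1L)
  wide <- prov$wide_pairs[1, ]
  iw <- match(wide, particleIDs(plh))
  expect_equal(degrees(angularDistance(rotations(plh)[, , iw[1]],
                                       rotations(plh)[, , iw[2]])),
               45, tolerance = 1e-9)
})

test_that("the default chromatin scene has the stated composition", {
  pl <- generateChromatin(chromatinSpec(), seed = 78)
  expect_equal(nParticles(pl), 6 * 12 + 350 * 2 + 340 * 3 + 3200)
  tab <- table(classLabels(pl))
  expect_equal(unname(tab[c("helix", "stack", "tri", "mono")]),
               c(72L, 700L, 1020L, 3200L), ignore_attr = TRUE)
  ## min-separation holds across the whole scene (exact scan below the
  ## separation distance finds no pair)
  close_pairs <- tomotwist:::.fixedRadiusPairs(positions(pl),
                                               tomoIDs(pl), 6 - 1e-6)
  expect_equal(length(close_pairs$i), 0L)
  ## ground-truth bookkeeping: 5 stacked pairs per helix plus all stack
  ## and tri pairs
  prov <- provenance(pl)
  expect_equal(nrow(prov$stacked_pairs), 6 * 5 + 350 + 340)
  expect_equal(nrow(prov$wide_pairs), 6L)
  ## placement failure suggests a larger box
  tiny <- chromatinSpec(n_helix = 0, n_stack = 60, n_tri = 0, n_mono = 0,
                        box = c(15, 15, 15), max_attempts = 50)
  expect_error(generateChromatin(tiny, seed = 79), "larger box")
})

test_that("noise corruption is seeded, bounded and rotation-preserving", {
  pl <- randomScene(120, box = 60, seed = 80)
  ## zero noise returns the input exactly
  expect_identical(corruptParticles(pl, noiseModel(0, 0, seed = 1)), pl)
  ## reproducible given the seed
  a <- corruptParticles(pl, noiseModel(2, 0.3, seed = 81))
  b <- corruptParticles(pl, noiseModel(2, 0.3, seed = 81))
  expect_identical(positions(a), positions(b))
  expect_identical(rotations(a), rotations(b))
  ## corrupted rotations satisfy the rotation invariants
  big <- corruptParticles(pl, noiseModel(0, 1, seed = 82))
  for (k in seq_len(nParticles(big)))
    expect_true(isRotation(rotations(big)[, , k], tol = 1e-9))
  ## positional level 5: 99th percentile of |g| matches the chi-3 oracle
  pl2 <- randomScene(4000, box = 1e5, seed = 83)
  g <- sqrt(rowSums((positions(corruptParticles(pl2,
                                                noiseModel(5, 0,
                                                           seed = 84))) -
                       positions(pl2))^2))
  oracle <- sqrt(qchisq(0.99, df = 3)) * 0.8 * 5 / 3
  expect_equal(unname(quantile(g, 0.99)), oracle, tolerance = 0.05)
  ## orientational level sweep: monotone deviation growth approaching the
  ## ~60 degree scale near level 1
  rots <- randRots(200, 85)
  meds <- vapply(c(0.1, 0.25, 0.5, 0.75, 1), function(lev) {
    plr <- particleList(matrix(seq_len(600), 200, 3), rots)
    plc <- corruptParticles(plr, noiseModel(0, lev, seed = 86))
    median(vapply(1:200, function(k)
      degrees(angularDistance(rots[, , k], rotations(plc)[, , k])),
      numeric(1)))
  }, numeric(1))
  expect_true(all(diff(meds) > 0))
  expect_gt(meds[5], 45)
  expect_lt(meds[5], 75)
})

test_that("geodesic shells are hexagonal lattices with 12 fivefold vertices", {
  for (f in c(3, 4)) {
    gs <- generateGeodesicShell(frequency = f, radius = 40)
    expect_equal(nParticles(gs), 10 * f^2 + 2)
    expect_equal(sum(classLabels(gs) == "pentamer"), 12L)
    ## all particles sit on the sphere, oriented with +z outward
    r <- sqrt(rowSums(positions(gs)^2))
    expect_lt(max(abs(r - 40)), 1e-9)
    k <- sample(nParticles(gs), 1)
    outward <- positions(gs)[k, ] / 40
    expect_equal(as.numeric(rotations(gs)[, , k] %*% c(0, 0, 1)),
                 outward, tolerance = 1e-9)
  }
  ## pentamer vertices have exactly 5 first-shell neighbors
  gs <- generateGeodesicShell(frequency = 3, radius = 40)
  td <- computeTwist(gs, radius = 1.35 *
                       nnStats(gs)$median[nnStats(gs)$tomo == "global"])
  occ <- featureValues(featureOccupancy(td))$occupancy
  expect_equal(occ[classLabels(gs) == "pentamer"], rep(5L, 12))
  expect_equal(occ[classLabels(gs) == "hexamer"],
               rep(6L, sum(classLabels(gs) == "hexamer")))
})
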