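test_that("every reader/writer pair round-trips fuzzed particle lists", {
  set.seed(21)
  n <- 60
  pl <- particleList(matrix(runif(n * 3, 0, 200), n, 3),
                     randomRotations(n),
                     tomo_id = sample(1:4, n, TRUE),
                     object_id = sample(c(NA, 0:3), n, TRUE),
                     score = runif(n),
                     class_label = sample(c(NA, "a", "b"), n, TRUE),
                     unit = "nm")
  tol_pos <- c(twist_csv = 1e-6, relion_star = 1e-6, motl_csv = 1e-6,
               dynamo_tbl = 1e-6, motl_em = 2e-5)  # motl_em is float32
  for (fmt in names(tol_pos)) {
    f <- withr::local_tempfile()
    suppressWarnings(writeParticleList(pl, f, fmt))
    pl2 <- readParticleList(f, fmt, unit = "nm")
    expect_equal(nParticles(pl2), n)
    expect_lt(max(abs(positions(pl2) - positions(pl))), tol_pos[[fmt]])
    dang <- vapply(seq_len(n), function(k)
      angularDistance(rotations(pl)[, , k], rotations(pl2)[, , k]),
      numeric(1))
    expect_lt(max(dang), if (fmt == "motl_em") 1e-5 else 1e-6)
    expect_identical(tomoIDs(pl2), tomoIDs(pl))
    expect_identical(particleIDs(pl2), particleIDs(pl))
    if (fmt %in% c("twist_csv", "relion_star", "motl_em", "motl_csv",
                   "dynamo_tbl"))
      expect_equal(objectIDs(pl2), objectIDs(pl))
    if (fmt %in% c("twist_csv", "relion_star"))
      expect_identical(classLabels(pl2), classLabels(pl))
    ## writers are bit-stable on identical input
    f2 <- withr::local_tempfile()
    suppressWarnings(writeParticleList(pl, f2, fmt))
    expect_identical(readBin(f, "raw", file.size(f)),
                     readBin(f2, "raw", file.size(f2)))
  }
})

test_that("STAR and motl angle conventions behave as documented", {
  ## all-zero Euler angles give identity rotations
  f <- withr::local_tempfile()
  writeLines(c("data_particles", "", "loop_",
               "_rlnCoordinateX #1", "_rlnCoordinateY #2",
               "_rlnCoordinateZ #3", "_rlnAngleRot #4",
               "_rlnAngleTilt #5", "_rlnAnglePsi #6",
               "1.0 2.0 3.0 0 0 0", "4.0 5.0 6.0 0 0 0"), f)
  pl <- readParticleList(f, "relion_star", unit = "nm")
  expect_equal(nParticles(pl), 2L)
  for (k in 1:2)
    expect_lt(max(abs(rotations(pl)[, , k] - diag(3))), 1e-12)
  ## missing mandatory columns are reported by name
  f2 <- withr::local_tempfile()
  writeLines(c("data_", "", "loop_", "_rlnCoordinateX #1", "1.0"), f2)
  expect_error(readParticleList(f2, "relion_star", unit = "nm"),
               "rlnCoordinateY")
  ## motl phi = 60 with psi = theta = 0 is a 60-degree z-family rotation
  m <- matrix(0, 1, 20)
  colnames(m) <- tomotwist:::.MOTL_CSV_COLS
  m[1, c("particle_id", "tomo_id")] <- 1
  m[1, c("x", "y", "z")] <- c(10, 20, 30)
  m[1, "phi"] <- 60
  f3 <- withr::local_tempfile()
  write.csv(as.data.frame(m), f3, row.names = FALSE)
  pl3 <- readParticleList(f3, "motl_csv", unit = "nm")
  expect_equal(angularDistance(rotations(pl3)[, , 1], rotZ(60)), 0,
               tolerance = 1e-9)
  ## motl shifts are folded into positions
  m2 <- m; m2[1, c("shift_x", "shift_y", "shift_z")] <- c(1, -2, 0.5)
  f4 <- withr::local_tempfile()
  write.csv(as.data.frame(m2), f4, row.names = FALSE)
  expect_equal(positions(readParticleList(f4, "motl_csv",
                                          unit = "nm"))[1, ],
               c(11, 18, 30.5))
})

test_that("empty lists write valid header-only files in all formats", {
  e <- particleList(matrix(0, 0, 3))
  for (fmt in c("twist_csv", "relion_star", "motl_em", "motl_csv",
                "dynamo_tbl")) {
    f <- withr::local_tempfile()
    writeParticleList(e, f, fmt)
    expect_equal(nParticles(readParticleList(f, fmt, unit = "nm")), 0L)
  }
})

test_that("unrepresentable fields are dropped with a warning, never silently", {
  pl <- particleList(rbind(c(0, 0, 0), c(10, 0, 0)),
                     class_label = c("x", "y"))
  f <- withr::local_tempfile()
  expect_warning(writeParticleList(pl, f, "motl_em"), "class label")
  ## STAR carries object ids in a documented column
  pl2 <- particleList(rbind(c(0, 0, 0), c(10, 0, 0)), object_id = c(3, 3))
  f2 <- withr::local_tempfile()
  writeParticleList(pl2, f2, "relion_star")
  expect_true(any(grepl("ttObjectID", readLines(f2))))
  expect_equal(objectIDs(readParticleList(f2, "relion_star",
                                          unit = "nm")),
               c(3L, 3L))
})

test_that("unit conversion is exact and self-inverse", {
  pl <- particleList(rbind(c(1, 2, 3), c(4, 5, 6)), unit = "nm")
  a <- convertUnits(pl, "angstrom")
  expect_equal(positions(a), positions(pl) * 10)
  expect_equal(positions(convertUnits(a, "nm")), positions(pl))
  v <- convertUnits(pl, "voxel", pixel_size = 2.5)  # 2.5 A/voxel
  expect_equal(positions(v), positions(pl) * 10 / 2.5)
  expect_equal(positions(convertUnits(v, "nm")), positions(pl))
  expect_error(convertUnits(pl, "voxel"), "pixel_size")
})

test_that("duplicate cleaning keeps the best-scoring survivor set", {
  ## close pair: higher score survives
  pl <- particleList(rbind(c(0, 0, 0), c(0.1, 0, 0)),
                     score = c(0.9, 0.5))
  out <- cleanDuplicates(pl, min_distance = 1)
  expect_equal(nParticles(out), 1L)
  expect_equal(scores(out), 0.9)
  ## all-distant list is untouched
  pl2 <- particleList(rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0)))
  expect_equal(nParticles(cleanDuplicates(pl2, 1)), 3L)
  ## brute-force oracle on a random 200-particle list
  set.seed(22)
  n <- 200
  pos <- matrix(runif(n * 3, 0, 30), n, 3)
  sc <- runif(n)
  pl3 <- particleList(pos, score = sc, tomo_id = sample(1:2, n, TRUE))
  out3 <- cleanDuplicates(pl3, min_distance = 4)
  ## oracle: plain greedy sweep in score order
  ord <- order(sc, decreasing = TRUE)
  kept <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (j in kept) {
      if (tomoIDs(pl3)[i] == tomoIDs(pl3)[j] &&
          sqrt(sum((pos[i, ] - pos[j, ])^2)) < 4) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, i)
  }
  expect_setequal(particleIDs(out3), particleIDs(pl3)[kept])
  ## row-order independence given distinct scores
  perm <- sample(n)
  pl4 <- particleList(pos[perm, ], score = sc[perm],
                      tomo_id = tomoIDs(pl3)[perm],
                      particle_id = particleIDs(pl3)[perm])
  expect_setequal(particleIDs(cleanDuplicates(pl4, 4)),
                  particleIDs(out3))
})

test_that("intrinsic-axis shifts move positions along rotated axes", {
  pl <- particleList(rbind(c(5, 5, 5)), rotation = diag(3))
  out <- shiftAlongIntrinsicAxis(pl, c(-1, 0, 0), 2)
  expect_equal(positions(out)[1, ], c(3, 5, 5))
  pl2 <- particleList(rbind(c(0, 0, 0)), rotation = rotZ(90))
  out2 <- shiftAlongIntrinsicAxis(pl2, c(-1, 0, 0), 2)
  expect_equal(positions(out2)[1, ], c(0, -2, 0), tolerance = 1e-12)
  ## shifting by d then -d restores the input exactly
  set.seed(23)
  pl3 <- randomScene(30, seed = 23)
  back <- shiftAlongIntrinsicAxis(shiftAlongIntrinsicAxis(pl3,
                                                          c(0, 1, 0), 7),
                                  c(0, 1, 0), -7)
  expect_equal(positions(back), positions(pl3), tolerance = 1e-12)
})

test_that("nearest-neighbor statistics match brute force", {
  lat <- generatePlanarLattice(2, spacing = 8)
  st <- nnStats(lat)
  expect_equal(st$min[st$tomo == "global"], 8, tolerance = 1e-9)
  expect_equal(st$median[st$tomo == "global"], 8, tolerance = 1e-9)
  pl <- particleList(rbind(c(0, 0, 0), c(0, 0, 3)))
  st2 <- nnStats(pl)
  expect_equal(st2$min, c(3, 3))
  set.seed(24)
  pl3 <- randomScene(40, seed = 24)
  st3 <- nnStats(pl3)
  d <- as.matrix(dist(positions(pl3))); diag(d) <- Inf
  expect_equal(st3$median[st3$tomo == "global"],
               median(apply(d, 1, min)), tolerance = 1e-12)
  ## single-particle tomo excluded with a warning
  pl4 <- particleList(rbind(c(0, 0, 0), c(1, 0, 0), c(50, 0, 0)),
                      tomo_id = c(1, 1, 2))
  expect_warning(st4 <- nnStats(pl4), "single particle")
  expect_false("2" %in% st4$tomo)
})

test_that("particle list validity invariants are enforced", {
  expect_error(particleList(rbind(c(0, 0, 0), c(1, 0, 0)),
                            particle_id = c(1, 1)), "unique")
  expect_error(particleList(rbind(c(0, 0, 0), c(0, 0, 0))),
               "identical")
  expect_error(particleList(rbind(c(0, 0, 0)), unit = "voxel"),
               "pixelSize")
  bad <- array(diag(3) * 2, c(3, 3, 1))
  expect_error(particleList(rbind(c(0, 0, 0)), bad), "rotation")
})

test_that("EM and MRC mask volumes are readable", {
  v <- array(as.numeric(runif(4 * 5 * 6) > 0.5), c(4, 5, 6))
  f <- withr::local_tempfile()
  tomotwist:::.writeEmData(v, f)
  out <- readVolume(f, "em")
  expect_equal(out$data, v, tolerance = 1e-7)
})
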