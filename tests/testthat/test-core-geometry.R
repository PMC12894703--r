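test_that("relative pose matches the homogeneous-matrix oracle", {
  ## trivial identity-rotation case
  rp <- relativePose(rigidMotion(diag(3), c(1, 0, 0)),
                     rigidMotion(diag(3), c(2, 0, 0)))
  expect_equal(rp$rotation, diag(3))
  expect_equal(rp$translation, c(1, 0, 0))
  ## analytically forced case with a rotated query
  rp <- relativePose(rigidMotion(rotZ(90), c(0, 0, 0)),
                     rigidMotion(diag(3), c(1, 0, 0)))
  expect_equal(rp$rotation, rotZ(-90), tolerance = 1e-12)
  expect_equal(rp$translation, c(0, -1, 0), tolerance = 1e-12)
  ## random pairs against explicit 4x4 inverse-times-neighbor products
  set.seed(11)
  for (k in 1:20) {
    q <- rigidMotion(randomRotations(1)[, , 1], rnorm(3, sd = 10))
    nb <- rigidMotion(randomRotations(1)[, , 1], rnorm(3, sd = 10))
    rp <- relativePose(q, nb)
    expect_lt(max(abs(homog(rp) - solve(homog(q)) %*% homog(nb))), 1e-10)
    ## invariance under common left-composition
    g <- rigidMotion(randomRotations(1)[, , 1], rnorm(3, sd = 10))
    rp2 <- relativePose(composeMotion(g, q), composeMotion(g, nb))
    expect_lt(max(abs(rp$rotation - rp2$rotation)), 1e-9)
    expect_lt(max(abs(rp$translation - rp2$translation)), 1e-9)
  }
  expect_error(relativePose(list(rotation = diag(3) * 2,
                                 translation = 0:2),
                            rigidMotion()),
               "orthogonal")
})

test_that("inverse-action of a motion on itself gives the identity", {
  set.seed(4)
  for (k in 1:20) {
    m <- rigidMotion(randomRotations(1)[, , 1], rnorm(3, sd = 20))
    idm <- composeMotion(invertMotion(m), m)
    expect_lt(max(abs(idm$rotation - diag(3))), 1e-10)
    expect_lt(max(abs(idm$translation)), 1e-9)
  }
})

test_that("logSO3 returns axis-angle vectors with the documented conventions", {
  expect_equal(logSO3(diag(3)), c(0, 0, 0))
  expect_equal(logSO3(rotZ(60)), c(0, 0, pi / 3), tolerance = 1e-12)
  ## angle-pi case: norm pi along x, first nonzero component positive
  lp <- logSO3(rotX(180))
  expect_equal(sqrt(sum(lp^2)), pi, tolerance = 1e-12)
  expect_equal(lp, c(pi, 0, 0), tolerance = 1e-9)
  ## oracle for a generic pi-rotation: axis = eigenvector of eigenvalue +1
  set.seed(2)
  ax <- c(rnorm(3)); ax <- ax / sqrt(sum(ax^2))
  r <- expSO3(ax * pi)
  ev <- eigen(r)
  v <- Re(ev$vectors[, which.min(abs(Re(ev$values) - 1))])
  v <- v / sqrt(sum(v^2))
  lp <- logSO3(r)
  expect_equal(abs(sum(lp / pi * v)), 1, tolerance = 1e-8)
})

test_that("exp/log round trip on random rotations including near pi", {
  set.seed(5)
  rots <- randomRotations(5000)
  worst <- 0
  for (k in seq_len(dim(rots)[3])) {
    r <- rots[, , k]
    worst <- max(worst, max(abs(expSO3(logSO3(r)) - r)))
  }
  ## dedicated near-pi band [pi - 1e-4, pi]
  for (k in 1:2000) {
    ax <- c(rnorm(3)); ax <- ax / sqrt(sum(ax^2))
    r <- expSO3(ax * (pi - runif(1, 0, 1e-4)))
    worst <- max(worst, max(abs(expSO3(logSO3(r)) - r)))
    expect_false(anyNA(logSO3(r)))
  }
  expect_lt(worst, 1e-8)
})

test_that("angular distance matches the trace formula and is a metric", {
  expect_equal(angularDistance(diag(3), diag(3)), 0)
  expect_equal(angularDistance(diag(3), rotZ(60)), pi / 3,
               tolerance = 1e-12)
  set.seed(6)
  for (k in 1:50) {
    r1 <- randomRotations(1)[, , 1]; r2 <- randomRotations(1)[, , 1]
    tr <- sum(diag(crossprod(r1, r2)))
    expect_equal(angularDistance(r1, r2),
                 acos(pmin(1, pmax(-1, (tr - 1) / 2))), tolerance = 1e-9)
    ## symmetry and bi-invariance
    expect_equal(angularDistance(r1, r2), angularDistance(r2, r1),
                 tolerance = 1e-12)
    g <- randomRotations(1)[, , 1]
    expect_equal(angularDistance(g %*% r1, g %*% r2),
                 angularDistance(r1, r2), tolerance = 1e-9)
    expect_equal(angularDistance(r1 %*% g, r2 %*% g),
                 angularDistance(r1, r2), tolerance = 1e-9)
  }
  ## triangle inequality on sampled triples
  for (k in 1:200) {
    r <- randomRotations(3)
    d12 <- angularDistance(r[, , 1], r[, , 2])
    d23 <- angularDistance(r[, , 2], r[, , 3])
    d13 <- angularDistance(r[, , 1], r[, , 3])
    expect_lte(d13, d12 + d23 + 1e-9)
  }
})

test_that("twist vectors encode relative pose and are rigid-motion invariant", {
  tv <- twistFromPair(rigidMotion(), rigidMotion(rotZ(40), c(1, 2, 3)))
  expect_equal(tv$zeta, c(0, 0, radians(40)), tolerance = 1e-12)
  expect_equal(tv$trans, c(1, 2, 3))
  expect_error(twistFromPair(rigidMotion(rotZ(10), c(1, 1, 1)),
                             rigidMotion(rotZ(50), c(1, 1, 1))),
               "zero-distance")
  set.seed(7)
  for (k in 1:50) {
    q <- rigidMotion(randomRotations(1)[, , 1], rnorm(3, sd = 10))
    nb <- rigidMotion(randomRotations(1)[, , 1], rnorm(3, sd = 10))
    tv <- twistFromPair(q, nb)
    ## norms are the two distances
    expect_equal(sqrt(sum(tv$trans^2)),
                 sqrt(sum((nb$translation - q$translation)^2)),
                 tolerance = 1e-9)
    expect_equal(sqrt(sum(tv$zeta^2)),
                 angularDistance(q$rotation, nb$rotation),
                 tolerance = 1e-9)
    ## global rigid motion leaves the twist unchanged
    g <- rigidMotion(randomRotations(1)[, , 1], rnorm(3, sd = 30))
    tv2 <- twistFromPair(composeMotion(g, q), composeMotion(g, nb))
    expect_lt(max(abs(tv$zeta - tv2$zeta)), 1e-9)
    expect_lt(max(abs(tv$trans - tv2$trans)), 1e-9)
  }
})

test_that("swing-twist decomposition reconstructs the rotation", {
  st <- swingTwist(rotZ(50), c(0, 0, 1))
  expect_equal(degrees(st$angle), 50, tolerance = 1e-10)
  expect_equal(st$cone, diag(3), tolerance = 1e-10)
  st <- swingTwist(rotX(30), c(0, 0, 1))
  expect_equal(st$angle, 0, tolerance = 1e-10)
  expect_equal(st$cone, rotX(30), tolerance = 1e-10)
  set.seed(8)
  for (k in 1:100) {
    r <- randomRotations(1)[, , 1]
    ax <- c(rnorm(3)); ax <- ax / sqrt(sum(ax^2))
    st <- swingTwist(r, ax)
    rec <- st$cone %*% expSO3(ax * st$angle)
    expect_lt(max(abs(rec - r)), 1e-8)
    expect_gt(st$angle, -pi - 1e-12)
    expect_lte(st$angle, pi + 1e-12)
    ## cone part has no twist about the axis
    expect_lt(abs(swingTwist(st$cone, ax)$angle), 1e-8)
  }
  ## gimbal-degenerate: rotation by pi about an axis perpendicular to the
  ## reference axis maps it to its negative
  st <- swingTwist(rotX(180), c(0, 0, 1))
  expect_true(st$degenerate)
  expect_equal(st$angle, 0)
})

test_that("projectToSO3 is the Procrustes projection with det +1", {
  set.seed(9)
  r <- randomRotations(1)[, , 1]
  expect_lt(max(abs(projectToSO3(r) - r)), 1e-12)
  ## small skew perturbation: orthogonality restored, close to the input
  m <- diag(3) + matrix(c(0, 1, -1, -1, 0, 1, 1, -1, 0), 3, 3) * 0.01
  p <- projectToSO3(m)
  expect_lt(max(abs(crossprod(p) - diag(3))), 1e-12)
  expect_equal(det(p), 1, tolerance = 1e-12)
  ## Procrustes oracle: p maximizes trace(t(p) %*% m) among test rotations
  base <- sum(diag(crossprod(p, m)))
  for (k in 1:50) {
    q <- randomRotations(1)[, , 1]
    expect_lte(sum(diag(crossprod(q, m))), base + 1e-12)
  }
  ## reflection input gets its determinant fixed to +1
  refl <- diag(c(1, 1, -1))
  expect_equal(det(projectToSO3(refl + 0.01 * matrix(rnorm(9), 3))), 1,
               tolerance = 1e-10)
  expect_error(projectToSO3(matrix(0, 3, 3)), "rank")
})

test_that("Euler conversions round trip in both conventions", {
  expect_equal(eulerZYZToMatrix(0, 0, 0)[, , 1], diag(3))
  set.seed(10)
  for (k in 1:200) {
    r <- randomRotations(1)[, , 1]
    a <- matrixToEulerZYZ(r)
    expect_lt(max(abs(eulerZYZToMatrix(a[1], a[2], a[3])[, , 1] - r)),
              1e-9)
    b <- matrixToEulerZXZ(r)
    expect_lt(max(abs(eulerZXZToMatrix(b[1], b[2], b[3])[, , 1] - r)),
              1e-9)
  }
  ## gimbal cases
  for (ang in c(0, 180)) {
    r <- rotZ(25) %*% rotY(ang) %*% rotZ(0)
    a <- matrixToEulerZYZ(r)
    expect_lt(max(abs(eulerZYZToMatrix(a[1], a[2], a[3])[, , 1] - r)),
              1e-9)
  }
  ## a motl rotation with theta = psi = 0 is a pure z-rotation
  r <- eulerZXZToMatrix(60, 0, 0)[, , 1]
  expect_equal(angularDistance(r, rotZ(60)), 0, tolerance = 1e-12)
})
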