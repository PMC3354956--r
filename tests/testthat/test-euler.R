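test_that("zero angles compose to the identity and z rotates right-handed", {
  expect_equal(compose_euler(euler_angles(0, 0, 0)), diag(3))
  expect_equal(as.numeric(compose_euler(euler_angles(90, 0, 0)) %*% c(1, 0, 0)),
               c(0, 1, 0), tolerance = 1e-12)
})

test_that("composition equals the explicit product of axis matrices", {
  rot_about <- function(axis, deg) {
    t <- deg * pi / 180
    c <- cos(t); s <- sin(t)
    switch(axis,
           x = matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3),
           y = matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3),
           z = matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3))
  }
  manual <- rot_about("y", 50) %*% rot_about("x", 40) %*% rot_about("z", 30)
  expect_equal(compose_euler(euler_angles(30, 40, 50)), manual,
               tolerance = 1e-12)
})

test_that("compose/factor round trip is exact away from gimbal lock", {
  set.seed(101)
  for (i in 1:1000) {
    a <- euler_angles(runif(1, -179, 179), runif(1, -89.5, 89.5),
                      runif(1, -179, 179))
    b <- hingescan:::factor_euler(compose_euler(a))
    expect_lt(max(abs(as.numeric(a) - as.numeric(b))), 1e-6)
  }
})

test_that("hinge rotation moves only the mobile domain", {
  pair <- dumbbell_fixture()
  start <- pair$apo
  rot <- apply_hinge_rotation(start, pair$domains, euler_angles(10, 25, -30))
  m_res <- domain_residues(pair$domains, "M")
  moved <- rot$protein$resno %in% m_res
  expect_identical(as.matrix(rot$protein[!moved, c("x", "y", "z")]),
                   as.matrix(start$protein[!moved, c("x", "y", "z")]))
  expect_identical(as.matrix(rot$ligand[, c("x", "y", "z")]),
                   as.matrix(start$ligand[, c("x", "y", "z")]))
  # intra-M distances are preserved exactly
  d0 <- dist(as.matrix(start$protein[moved, c("x", "y", "z")]))
  d1 <- dist(as.matrix(rot$protein[moved, c("x", "y", "z")]))
  expect_equal(as.numeric(d1), as.numeric(d0), tolerance = 1e-12)
  # zero rotation is the identity
  same <- apply_hinge_rotation(start, pair$domains, euler_angles(0, 0, 0))
  expect_equal(as.matrix(same$protein[, c("x", "y", "z")]),
               as.matrix(start$protein[, c("x", "y", "z")]),
               tolerance = 1e-12)
})

test_that("a pure x rotation turns the mobile center by that angle", {
  pair <- dumbbell_fixture()
  start <- pair$apo
  m_res <- domain_residues(pair$domains, "M")
  rot <- apply_hinge_rotation(start, pair$domains, euler_angles(0, 40, 0))
  com0 <- center_of_mass(start$protein, m_res)
  com1 <- center_of_mass(rot$protein, m_res)
  expect_equal(sqrt(sum(com1^2)), sqrt(sum(com0^2)), tolerance = 1e-9)
  Rx40 <- compose_euler(euler_angles(0, 40, 0))
  expect_equal(com1, as.numeric(Rx40 %*% com0), tolerance = 1e-9)
})

test_that("Kabsch recovers constructed rigid maps", {
  set.seed(21)
  pts <- matrix(rnorm(30, sd = 5), ncol = 3)
  ident <- kabsch_superpose(pts, pts)
  expect_equal(ident$transform$rotation, diag(3), tolerance = 1e-9)
  expect_equal(ident$rmsd, 0, tolerance = 1e-9)
  R <- compose_euler(euler_angles(25, 0, 0))
  target <- sweep(pts %*% t(R), 2, -c(1, 2, 3))
  fit <- kabsch_superpose(pts, target)
  expect_equal(fit$transform$rotation, R, tolerance = 1e-9)
  expect_equal(fit$transform$translation, c(1, 2, 3), tolerance = 1e-9)
  expect_lt(fit$rmsd, 1e-9)
})

test_that("Kabsch is at least as good as a brute-force rotation grid", {
  set.seed(22)
  mobile <- matrix(rnorm(12, sd = 3), ncol = 3)
  target <- matrix(rnorm(12, sd = 3), ncol = 3)
  fit <- kabsch_superpose(mobile, target)
  # exhaustive coarse grid over rotations (centred configurations)
  cm <- colMeans(mobile); ct <- colMeans(target)
  A <- sweep(mobile, 2, cm); B <- sweep(target, 2, ct)
  best <- Inf
  for (tz in seq(-180, 170, 10)) for (tx in seq(-90, 90, 10))
    for (ty in seq(-180, 170, 10)) {
      R <- compose_euler(euler_angles(tz, tx, ty))
      best <- min(best, sqrt(mean(rowSums((A %*% t(R) - B)^2))))
    }
  expect_lte(fit$rmsd, best + 1e-9)
})

test_that("decomposed angles return exactly what was applied", {
  pair <- dumbbell_fixture()
  start <- pair$apo
  gen <- apply_hinge_rotation(start, pair$domains, euler_angles(30, 20, 10))
  ang <- decompose_angles(gen, start, pair$domains)
  expect_equal(as.numeric(ang), c(30, 20, 10), tolerance = 1e-6)
  zero <- decompose_angles(start, start, pair$domains)
  expect_equal(as.numeric(zero), c(0, 0, 0), tolerance = 1e-8)
})

test_that("decomposition is robust to small coordinate jitter", {
  pair <- dumbbell_fixture()
  start <- pair$apo
  set.seed(31)
  errs <- replicate(10, {
    gen <- apply_hinge_rotation(start, pair$domains,
                                euler_angles(15, 35, -25))
    n <- nrow(gen$protein)
    gen$protein$x <- gen$protein$x + rnorm(n, sd = 0.1)
    gen$protein$y <- gen$protein$y + rnorm(n, sd = 0.1)
    gen$protein$z <- gen$protein$z + rnorm(n, sd = 0.1)
    ang <- decompose_angles(gen, start, pair$domains)
    max(abs(as.numeric(ang) - c(15, 35, -25)))
  })
  expect_lt(median(errs), 1)
  expect_lt(max(errs), 2)
})

test_that("sRMSD is zero on identical structures and sees M displacement", {
  pair <- dumbbell_fixture()
  expect_equal(as.numeric(srmsd(pair$apo, pair$apo, pair$domains)), 0,
               tolerance = 1e-9)
  # uniform (3,4,0) displacement of every M C-alpha gives exactly 5 A
  shifted <- pair$apo
  m_rows <- shifted$protein$resno %in% domain_residues(pair$domains, "M")
  shifted$protein$x[m_rows] <- shifted$protein$x[m_rows] + 3
  shifted$protein$y[m_rows] <- shifted$protein$y[m_rows] + 4
  expect_equal(as.numeric(srmsd(shifted, pair$apo, pair$domains)), 5,
               tolerance = 1e-9)
})

test_that("sRMSD is invariant under rigid motion of either structure", {
  pair <- dumbbell_fixture()
  base <- as.numeric(srmsd(pair$apo, pair$holo, pair$domains))
  expect_gt(base, 5)
  set.seed(41)
  for (i in 1:5) {
    tf <- random_transform()
    moved <- pair$apo
    moved$protein <- apply_transform(moved$protein, tf)
    expect_equal(as.numeric(srmsd(moved, pair$holo, pair$domains)), base,
                 tolerance = 1e-6)
  }
})
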