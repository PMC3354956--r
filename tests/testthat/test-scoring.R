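test_that("radius of gyration matches closed forms and a direct loop", {
  one <- hingescan:::new_atom_tbl(1, "CA", "ALA", 1L, "C", 3, 4, 0)
  expect_equal(radius_of_gyration(one), 0)
  two <- hingescan:::new_atom_tbl(1:2, "CA", "ALA", 1:2, "C",
                                  c(-2.5, 2.5), 0, 0)
  expect_equal(radius_of_gyration(two), 2.5, tolerance = 1e-12)
  set.seed(13)
  xyz <- matrix(rnorm(150, sd = 8), ncol = 3)
  tbl <- hingescan:::new_atom_tbl(1:50, "CA", "ALA", 1:50, "C",
                                  xyz[, 1], xyz[, 2], xyz[, 3])
  com <- colMeans(xyz)
  manual <- sqrt(mean(rowSums(sweep(xyz, 2, com)^2)))
  expect_equal(radius_of_gyration(tbl), manual, tolerance = 1e-12)
})

test_that("radius of gyration is invariant under rigid motion", {
  pair <- dumbbell_fixture()
  base <- radius_of_gyration(pair$apo)
  set.seed(17)
  for (i in 1:5) {
    moved <- apply_transform(pair$apo$protein, random_transform())
    expect_equal(radius_of_gyration(moved), base, tolerance = 1e-9)
  }
})

test_that("the icosahedral orientation set has 60 proper rotations", {
  rots <- hingescan:::icosahedral_rotations()
  expect_length(rots, 60L)
  dets <- vapply(rots, det, numeric(1))
  expect_equal(dets, rep(1, 60), tolerance = 1e-9)
  # all distinct
  flat <- t(vapply(rots, as.numeric, numeric(9)))
  expect_equal(nrow(unique(round(flat, 6))), 60L)
})

test_that("a single atom pair docks at the pair potential's minimum", {
  # one receptor atom at the origin, one-"atom" probe extended to the
  # minimal valid rigid body; the closest probe atom should sit near the
  # contact distance r0 = 2 * r_C = 3.4 A
  prot <- hingescan:::new_atom_tbl(1, "CA", "ALA", 1L, "C", 0, 0, 0)
  lig <- hingescan:::new_atom_tbl(1:3, c("C1", "C2", "C3"), "LIG", 1L, "C",
                                  c(0, 1.4, 0.7), c(0, 0, 1.2), 0,
                                  record = "HETATM")
  cfg <- hs_config(dock = list(pad = 4, top_k = 3))
  out <- dock_score(prot, lig, cfg, seed = 1)
  d <- sqrt(rowSums(as.matrix(out$ligand[, c("x", "y", "z")])^2))
  expect_lt(abs(min(d) - 3.4), 0.35)
  expect_lt(out$G_D, 0)
})

test_that("docking is deterministic and refinement only improves the grid", {
  pair <- dumbbell_fixture()
  cfg <- hs_config()
  a <- dock_score(pair$holo, pair$holo$ligand, cfg, seed = 5)
  b <- dock_score(pair$holo, pair$holo$ligand, cfg, seed = 5)
  expect_identical(a$G_D, b$G_D)
  expect_identical(as.matrix(a$ligand[, c("x", "y", "z")]),
                   as.matrix(b$ligand[, c("x", "y", "z")]))
  # local descent never leaves a start pose worse than it found it
  # (energies under the full potential; jitter is off by default)
  expect_true(all(a$poses$energy <= a$poses$start_energy + 1e-6))
})

test_that("the closed cleft docks the ligand better than the open form", {
  pair <- dumbbell_fixture()
  cfg <- hs_config()
  g_closed <- dock_score(pair$holo, pair$holo$ligand, cfg, 1)$G_D
  g_open <- dock_score(pair$apo, pair$apo$ligand, cfg, 1)$G_D
  expect_lt(g_closed, g_open)
})

test_that("stability penalizes coincident atoms and interpenetration", {
  prot <- tiny_protein()
  clash <- prot
  clash[3, c("x", "y", "z")] <- clash[1, c("x", "y", "z")]
  expect_gt(stability_score(clash), stability_score(prot))
  pair <- dumbbell_fixture()
  crushed <- apply_hinge_rotation(pair$apo, pair$domains,
                                  euler_angles(0, 80, 0))
  expect_gt(stability_score(crushed), stability_score(pair$apo))
})

test_that("stability is invariant under rigid motion", {
  pair <- dumbbell_fixture()
  base <- stability_score(pair$apo)
  set.seed(19)
  moved <- pair$apo
  moved$protein <- apply_transform(moved$protein, random_transform())
  expect_equal(stability_score(moved), base, tolerance = 1e-9)
})

test_that("the fitness is the stated weighted sum and is linear", {
  row <- data.frame(G_D = -10, E_F = 100, R_G = 20)
  expect_equal(evaluate_fitness(row, c(0.35, 0.066, 0.030)), 15.1)
  expect_equal(evaluate_fitness(row, c(1, 0, 0)), -10)
  expect_equal(evaluate_fitness(row, c(0, 0, 0)), 0)
  lam <- c(0.5, 0.25, 0.1)
  scaled <- data.frame(G_D = -20, E_F = 200, R_G = 20 * sqrt(2))
  expect_equal(evaluate_fitness(scaled, lam),
               2 * evaluate_fitness(row, lam), tolerance = 1e-12)
})

test_that("scoring a conformer fills a reproducible score row", {
  pair <- dumbbell_fixture()
  cfg <- hs_config()
  a <- score_conformer(pair$holo, pair$holo$ligand, cfg, seed = 2)
  b <- score_conformer(pair$holo, pair$holo$ligand, cfg, seed = 2)
  expect_identical(a$scores, b$scores)
  expect_true(all(c("G_D", "E_F", "R_G") %in% names(a$scores)))
  expect_gt(a$scores$R_G, 0)
  # the closed form is more compact than the open form
  b_open <- score_conformer(pair$apo, pair$apo$ligand, cfg, seed = 2)
  expect_lt(a$scores$R_G, b_open$scores$R_G)
})
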