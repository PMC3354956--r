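make_chain <- function(n) {
  # straight CA chain with an off-axis wiggle so nothing is collinear
  xyz <- cbind(3.8 * seq_len(n), 1.5 * sin(seq_len(n)), 1.5 * cos(seq_len(n)))
  hingescan:::ca_protein(xyz)
}

test_that("hinge specs parse from strings and lists", {
  h <- hinge_spec("88-89,181-182")
  expect_length(h, 2L)
  expect_equal(h[[1]], 88:89)
  expect_equal(h[[2]], 181:182)
  expect_equal(hinge_spec(list(50:51))[[1]], 50:51)
  expect_error(hinge_spec("10-12,11-13"), class = "hingescan_error_hinge")
  # single-residue strands are allowed
  expect_length(hinge_spec("5,7"), 2L)
  expect_error(hinge_spec(list(1:2, 5:6, 9:10, 13:14)),
               class = "hingescan_error_hinge")
})

test_that("double-stranded hinge assignment matches the alternation rule", {
  prot <- make_chain(300)
  dom <- assign_domains(prot, "88-89,181-182")
  expect_setequal(domain_residues(dom, "L"), c(88, 89, 181, 182))
  expect_setequal(domain_residues(dom, "S"), c(1:87, 183:300))
  expect_setequal(domain_residues(dom, "M"), 90:180)
})

test_that("single-stranded hinge splits the chain in two", {
  prot <- make_chain(100)
  dom <- assign_domains(prot, list(50:51))
  expect_setequal(domain_residues(dom, "S"), 1:49)
  expect_setequal(domain_residues(dom, "M"), 52:100)
})

test_that("domain assignment always partitions the residues", {
  prot <- make_chain(120)
  set.seed(42)
  for (i in 1:20) {
    n_strand <- sample(1:3, 1)
    starts <- sort(sample(5:110, n_strand))
    if (n_strand > 1 && min(diff(starts)) < 8) next
    runs <- lapply(starts, function(s) s + 0:1)
    dom <- assign_domains(prot, hinge_spec(runs))
    expect_setequal(dom$resno, 1:120)
    expect_true(all(table(dom$resno) == 1))
    expect_setequal(domain_residues(dom, "L"), unlist(runs))
    expect_gt(length(domain_residues(dom, "S")), 0)
    expect_gt(length(domain_residues(dom, "M")), 0)
  }
})

test_that("a hinge at the terminus leaving S empty is an error", {
  prot <- make_chain(50)
  expect_error(assign_domains(prot, list(1:2)),
               class = "hingescan_error_hinge")
  expect_error(assign_domains(prot, "10-11,200-201"),
               class = "hingescan_error_hinge")
})

test_that("center of mass matches direct mass-weighted sums", {
  prot <- tiny_protein()
  # single residue: its own coordinates
  expect_equal(center_of_mass(prot, 1), c(0, 0, 0))
  # equal masses at symmetric points average
  expect_equal(center_of_mass(prot, 1:2), c(1.9, 0, 0))
  # brute-force oracle on a random fixture with mixed elements
  set.seed(7)
  xyz <- matrix(rnorm(30, sd = 5), ncol = 3)
  tbl <- hingescan:::new_atom_tbl(
    serial = 1:10, atom = c("CA", rep("X", 9)), resid = "ALA", resno = 1:10,
    element = sample(c("C", "N", "O", "S"), 10, replace = TRUE),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]
  )
  manual <- colSums(xyz * tbl$mass) / sum(tbl$mass)
  expect_equal(center_of_mass(tbl), manual, tolerance = 1e-12)
})

test_that("center of mass is translation-equivariant", {
  pair <- dumbbell_fixture()
  prot <- pair$apo$protein
  set.seed(11)
  for (i in 1:5) {
    t_vec <- rnorm(3, sd = 20)
    moved <- prot
    moved$x <- moved$x + t_vec[1]
    moved$y <- moved$y + t_vec[2]
    moved$z <- moved$z + t_vec[3]
    expect_equal(center_of_mass(moved), center_of_mass(prot) + t_vec,
                 tolerance = 1e-9)
  }
})

test_that("standard orientation places the three centers as required", {
  pair <- dumbbell_fixture()
  # scramble with a random rigid motion, then re-standardize
  set.seed(3)
  tf <- random_transform()
  prot <- apply_transform(pair$apo$protein, tf)
  std <- standard_orientation(prot, pair$domains)
  xs <- center_of_mass(std$protein, domain_residues(pair$domains, "S"))
  xm <- center_of_mass(std$protein, domain_residues(pair$domains, "M"))
  xl <- center_of_mass(std$protein, domain_residues(pair$domains, "L"))
  expect_lt(sqrt(sum(xl^2)), 1e-6)
  expect_lt(abs(xm[1]), 1e-6)
  expect_lt(abs(xm[2]), 1e-6)
  expect_gt(xm[3], 0)
  expect_lt(abs(xs[1]), 1e-6)
  expect_lt(xs[2], 0)
  # rigidity: pairwise CA distances unchanged
  d0 <- dist(as.matrix(prot[prot$atom == "CA", c("x", "y", "z")]))
  d1 <- dist(as.matrix(std$protein[std$protein$atom == "CA",
                                   c("x", "y", "z")]))
  expect_equal(as.numeric(d1), as.numeric(d0), tolerance = 1e-9)
})

test_that("standard orientation is idempotent", {
  pair <- dumbbell_fixture()
  std1 <- standard_orientation(pair$apo$protein, pair$domains)
  std2 <- standard_orientation(std1$protein, pair$domains)
  expect_equal(std2$transform$rotation, diag(3), tolerance = 1e-6)
  expect_equal(std2$transform$translation, c(0, 0, 0), tolerance = 1e-6)
})

test_that("collinear domain centers are a structured error", {
  xyz <- cbind(3.8 * 1:30, 0, 0)  # perfectly straight chain
  prot <- hingescan:::ca_protein(xyz)
  dom <- assign_domains(prot, list(14:16))
  expect_error(standard_orientation(prot, dom),
               class = "hingescan_error_degenerate")
})

test_that("rigid transforms compose, invert, and stay proper rotations", {
  set.seed(5)
  for (i in 1:10) {
    tf <- random_transform()
    expect_equal(det(tf$rotation), 1, tolerance = 1e-9)
    expect_equal(crossprod(tf$rotation), diag(3), tolerance = 1e-9,
                 ignore_attr = TRUE)
    inv <- invert_transform(tf)
    both <- compose_transform(inv, tf)
    expect_equal(both$rotation, diag(3), tolerance = 1e-9)
    expect_equal(both$translation, c(0, 0, 0), tolerance = 1e-9)
    pts <- matrix(rnorm(15), ncol = 3)
    back <- apply_transform(apply_transform(pts, tf), inv)
    expect_equal(back, pts, tolerance = 1e-9)
  }
})
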