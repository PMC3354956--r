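test_that("angles snap to the nearest cell with ties toward zero", {
  grid <- cell_grid()
  expect_equal(cell_of(euler_angles(0, 0, 0), grid),
               c(iy = 0L, ix = 0L, iz = 0L))
  expect_equal(cell_of(euler_angles(0, 0, 7.4), grid)[["iy"]], 0L)
  expect_equal(cell_of(euler_angles(0, 0, -7.4), grid)[["iy"]], 0L)
  expect_equal(cell_of(euler_angles(0, 0, 7.6), grid)[["iy"]], 1L)
  # exact half-spacing boundary rounds toward zero
  expect_equal(cell_of(euler_angles(0, 0, 7.5), grid)[["iy"]], 0L)
  expect_equal(cell_of(euler_angles(0, 0, 22.5), grid)[["iy"]], 1L)
  expect_equal(cell_of(euler_angles(0, 0, -7.5), grid)[["iy"]], 0L)
  # outside the ranges
  expect_null(cell_of(euler_angles(95, 0, 0), grid))
  expect_null(cell_of(euler_angles(0, -30, 0), grid))
  expect_null(cell_of(euler_angles(0, 0, 83), grid))
  # x range is asymmetric: 75 is a valid center, -75 is not
  expect_equal(cell_of(euler_angles(0, 75, 0), grid)[["ix"]], 5L)
})

test_that("line search on a separable quadratic finds the global cell", {
  pair <- dumbbell_fixture()
  # drift-free analytic search: relaxation disabled, separable quadratic
  # fitness with its minimum three cells away from the start on each of
  # two axes, injected through the scorer interface
  target <- c(theta_y = 60, theta_x = -15, theta_z = 45)
  quad <- function(conformer, ligand, config, seed) {
    a <- conformer$angles
    tibble::tibble(
      G_D = ((a[["theta_y"]] - target[["theta_y"]])^2 +
               (a[["theta_x"]] - target[["theta_x"]])^2 +
               (a[["theta_z"]] - target[["theta_z"]])^2) / 100,
      E_F = 0, R_G = 1)
  }
  cfg <- hs_config(scorer = quad, relax = list(max_steps = 0),
                   lambda = c(1, 0, 0))
  start <- pair$apo
  start$angles <- euler_angles(0, 0, 0)
  res <- suppressMessages(line_search(start, pair$domains, cfg))
  expect_true(res$converged)
  best_cell <- cell_of(res$predicted$angles, cell_grid())
  expect_equal(unname(best_cell), c(4L, -1L, 3L))
  # oracle: exhaustive evaluation of the quadratic over all grid cells
  grid <- cell_grid()
  fs <- c()
  for (iy in grid$centers$theta_y) for (ix in grid$centers$theta_x)
    for (iz in grid$centers$theta_z) {
      fs <- c(fs, ((15 * iy - 60)^2 + (15 * ix + 15)^2 +
                     (15 * iz - 45)^2) / 100)
    }
  expect_equal(min(res$scores$f), min(fs), tolerance = 1e-6)
})

test_that("a constant fitness converges in one cycle at the start cell", {
  pair <- dumbbell_fixture()
  cfg <- hs_config(scorer = function(conformer, ligand, config, seed) {
    tibble::tibble(G_D = 1, E_F = 0, R_G = 1)
  }, relax = list(max_steps = 0), lambda = c(1, 0, 0))
  start <- pair$apo
  start$angles <- euler_angles(0, 0, 0)
  res <- suppressMessages(line_search(start, pair$domains, cfg))
  expect_true(res$converged)
  best_cell <- cell_of(res$predicted$angles, cell_grid())
  expect_equal(unname(best_cell), c(0L, 0L, 0L))
})

test_that("the search trajectory keeps its bookkeeping invariants", {
  res <- explore_fixture()
  tr <- res$trajectory
  # running best f is non-increasing
  expect_true(all(diff(tr$best_f) <= 1e-12))
  # every cell is attempted at most twice, infeasible cells never revisited
  key <- paste(tr$iy, tr$ix, tr$iz, sep = ":")
  attempts <- tapply(grepl("attempt|feasible$", tr$outcome), key, sum)
  gen_attempts <- tapply(grepl("relax_failed|drifted|^feasible$", tr$outcome),
                         key, sum)
  expect_true(all(gen_attempts <= 3))  # at most 2 attempts + 1 terminal mark
  inf_rows <- tr[tr$outcome == "infeasible", ]
  for (k in paste(inf_rows$iy, inf_rows$ix, inf_rows$iz, sep = ":")) {
    after <- tr[which(key == k), ]
    mark <- which(after$outcome == "infeasible")
    expect_true(all(seq_len(nrow(after)) <= mark))
  }
  # stored conformers satisfy the cell-membership invariant
  grid <- cell_grid()
  cells <- res$cells[res$cells$status == "feasible", ]
  for (i in seq_len(nrow(cells))) {
    conf <- res$state$conformers[[cells$id[i]]]
    got <- cell_of(conf$angles, grid)
    expect_equal(unname(got), c(cells$iy[i], cells$ix[i], cells$iz[i]))
  }
  # the predicted conformer minimizes f over all feasible cells
  expect_equal(min(res$scores$f),
               res$scores$f[res$scores$id == res$predicted_id])
})

test_that("end-to-end exploration closes the cleft toward the holo form", {
  pair <- dumbbell_fixture()
  res <- explore_fixture()
  expect_true(res$converged)
  # the predicted conformer closes along the cleft-closing axis and at
  # least halves the distance to the holo reference
  closure <- as.numeric(pair$params$closure_angles)
  expect_lt(abs(res$predicted$angles[["theta_x"]] - closure[2]), 7.5)
  s_start <- as.numeric(srmsd(pair$apo, pair$holo, pair$domains))
  s_pred <- as.numeric(srmsd(res$predicted, pair$holo, pair$domains))
  expect_lte(s_pred, 0.5 * s_start)
  # the predicted structure is more compact than the start, as closure
  # demands
  expect_lt(radius_of_gyration(res$predicted),
            radius_of_gyration(pair$apo))
})

test_that("tidy, glance and the plot builders work on a search result", {
  res <- explore_fixture()
  td <- tidy(res)
  expect_true(all(c("iteration", "axis", "outcome", "best_f") %in% names(td)))
  gl <- glance(res)
  expect_equal(gl$n_feasible, sum(res$cells$status == "feasible"))
  p1 <- autoplot(res)
  expect_s3_class(p1, "ggplot")
  p2 <- plot_trajectory(res)
  expect_s3_class(p2, "ggplot")
})
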