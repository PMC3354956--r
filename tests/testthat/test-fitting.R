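test_that("the design matrix squares the gyration radius, in fixed order", {
  tbl <- tibble::tibble(G_D = -5, E_F = 2, R_G = 10)
  x <- design_matrix(tbl)
  expect_equal(as.numeric(x), c(-5, 2, 100))
  expect_equal(colnames(x), c("G_D", "E_F", "R_G2"))
  # column order fixed regardless of input field order
  x2 <- design_matrix(tbl[, c("R_G", "G_D", "E_F")])
  expect_equal(x2, x)
  many <- make_score_table(n_groups = 2, rows_per_group = 10, seed = 3)
  expect_equal(dim(design_matrix(many)), c(20L, 3L))
})

test_that("noiseless responses recover the generating weights exactly", {
  tbl <- make_score_table(n_groups = 3, rows_per_group = 20,
                          true_lambda = c(0.35, 0.066, 0.030),
                          noise_sd = 0, seed = 5)
  fit <- fit_lambda(design_matrix(tbl), tbl$srmsd)
  expect_equal(unname(fit$lambda), c(0.35, 0.066, 0.030), tolerance = 1e-10)
})

test_that("an identity-like system returns the responses as weights", {
  x <- diag(3)
  colnames(x) <- c("G_D", "E_F", "R_G2")
  fit <- fit_lambda(x, c(1, 2, 3))
  expect_equal(unname(fit$lambda), c(1, 2, 3), tolerance = 1e-12)
})

test_that("the solver matches the literal normal equations", {
  set.seed(9)
  for (i in 1:5) {
    x <- cbind(G_D = runif(50, -30, -5), E_F = runif(50, -20, 50),
               R_G2 = runif(50, 100, 600))
    y <- rnorm(50, sd = 4) + x %*% c(0.3, 0.1, 0.01)
    fit <- fit_lambda(x, y)
    manual <- solve(t(x) %*% x) %*% t(x) %*% y
    expect_equal(unname(fit$lambda), as.numeric(manual), tolerance = 1e-8)
    # residuals orthogonal to the columns
    expect_lt(max(abs(t(x) %*% fit$residuals)), 1e-6 * sqrt(sum(y^2)))
  }
})

test_that("duplicated rows leave the minimizer consistent", {
  tbl <- make_score_table(n_groups = 2, rows_per_group = 15, noise_sd = 0,
                          seed = 11)
  fit1 <- fit_lambda(design_matrix(tbl), tbl$srmsd)
  dup <- rbind(tbl, tbl[3, ])
  fit2 <- fit_lambda(design_matrix(dup), dup$srmsd)
  expect_equal(fit2$lambda, fit1$lambda, tolerance = 1e-8)
})

test_that("singular designs raise an error naming the correlated columns", {
  x <- cbind(G_D = 1:10, E_F = 2 * (1:10), R_G2 = runif(10))
  err <- expect_error(fit_lambda(x, rnorm(10)), class = "hingescan_error_fit")
  expect_match(conditionMessage(err), "G_D")
})

test_that("leave-one-group-out fits each fold on the other groups", {
  tbl <- make_score_table(n_groups = 2, rows_per_group = 12, seed = 13)
  tbl <- tbl[c(1:12, 13:20), ]  # unequal folds: 12 and 8
  cv <- loo_cross_validate(tbl)
  expect_equal(nrow(cv), 2L)
  expect_equal(cv$fit[[1]]$n, 8L)   # trained on the other group
  expect_equal(cv$fit[[2]]$n, 12L)
  expect_equal(nrow(cv$predictions[[1]]), 12L)
  # deterministic
  cv2 <- loo_cross_validate(tbl)
  expect_equal(cv$fit[[1]]$lambda, cv2$fit[[1]]$lambda)
})

test_that("identical groups give identical weights across folds", {
  base <- make_score_table(n_groups = 2, rows_per_group = 10, noise_sd = 0,
                           seed = 17)
  half <- base[base$group == "protein1", ]
  copy <- half
  copy$group <- "protein2"
  both <- rbind(half, copy)
  cv <- loo_cross_validate(both)
  expect_equal(cv$fit[[1]]$lambda, cv$fit[[2]]$lambda, tolerance = 1e-12)
})

test_that("simulated five-group tables recover the truth within noise", {
  truth <- c(0.35, 0.066, 0.030)
  tbl <- make_score_table(n_groups = 5, rows_per_group = 40,
                          true_lambda = truth, noise_sd = 0.5, seed = 19)
  cv <- loo_cross_validate(tbl)
  for (i in seq_len(nrow(cv))) {
    lam <- cv$fit[[i]]$lambda
    # OLS sampling error: sigma * sqrt(diag((X'X)^-1)) per fold
    train <- tbl[tbl$group != cv$group[[i]], ]
    x <- design_matrix(train)
    se <- 0.5 * sqrt(diag(solve(t(x) %*% x)))
    expect_true(all(abs(lam - truth) < 4 * se))
  }
  # pooled fit too
  pooled <- fit_lambda(design_matrix(tbl), tbl$srmsd)
  expect_equal(unname(pooled$lambda), truth, tolerance = 0.15)
  # broom-style accessors
  td <- tidy(pooled)
  expect_equal(td$term, c("G_D", "E_F", "R_G2"))
  expect_equal(glance(pooled)$n, 200L)
})

test_that("make_score_table is reproducible by seed", {
  a <- make_score_table(seed = 23)
  b <- make_score_table(seed = 23)
  expect_identical(a, b)
})
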