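# Training the fitness weights. The weights solve the ordinary
# least-squares problem x lambda ~ y where x has one row per scored
# conformer with columns (G_D, E_F, R_G^2) and y holds the sRMSD of each
# conformer to its protein's holo reference. No intercept and no column
# standardization: the weights live on the raw scales of the three terms.

#' Assemble the design matrix from a score table
#'
#' @param table A score table: a data frame with columns `G_D`, `E_F`,
#'   `R_G` (one row per scored conformer). Additional columns (`id`,
#'   `group`, `srmsd`) pass through untouched.
#' @return An n x 3 numeric matrix with columns `G_D`, `E_F`, `R_G2`
#'   (the gyration radius enters squared), rows in input order.
#' @export
design_matrix <- function(table) {
  stopifnot(is.data.frame(table), nrow(table) >= 1L)
  need <- c("G_D", "E_F", "R_G")
  if (!all(need %in% names(table))) {
    abort(paste0("Score table lacks column(s): ",
                 paste(setdiff(need, names(table)), collapse = ", ")),
          class = "hingescan_error_fit")
  }
  x <- cbind(G_D = table$G_D, E_F = table$E_F, R_G2 = table$R_G^2)
  if (!all(is.finite(x))) {
    abort("Non-finite entries in the score table.",
          class = "hingescan_error_fit")
  }
  x
}

#' Fit the fitness weights by least squares
#'
#' Solves `lambda = (x^T x)^{-1} x^T y` for the three weights of the
#' fitness function, using a QR solver (numerically equivalent to the
#' normal equations on well-conditioned inputs). There is no intercept by
#' default, matching the fitness definition; set `intercept = TRUE` to add
#' one for experimentation (the intercept is reported separately and not
#' part of the weights).
#'
#' @param x Design matrix from [design_matrix()] (or a score table, which
#'   is converted), n x 3.
#' @param y Numeric response vector of sRMSD values (Angstroms), length n.
#' @param intercept Add an intercept column (default `FALSE`).
#' @return An object of class `lambda_fit` with elements `lambda` (named
#'   length-3 vector), `intercept`, `fitted`, `residuals`, `kappa`
#'   (condition number of x).
#' @export
fit_lambda <- function(x, y, intercept = FALSE) {
  if (is.data.frame(x)) x <- design_matrix(x)
  y <- as.numeric(y)
  stopifnot(nrow(x) == length(y))
  if (nrow(x) < ncol(x) + intercept) {
    abort("Need at least as many rows as fitted columns.",
          class = "hingescan_error_fit")
  }
  xx <- if (intercept) cbind(`(Intercept)` = 1, x) else x
  k <- kappa(xx, exact = TRUE)
  if (!is.finite(k) || k > 1e10) {
    cc <- suppressWarnings(stats::cor(xx))
    cc[!is.finite(cc)] <- 0
    diag(cc) <- 0
    worst <- which(abs(cc) == max(abs(cc)), arr.ind = TRUE)[1, ]
    abort(paste0(
      "Design matrix is ill-conditioned (condition number ",
      format(k, digits = 3), "); strongest column correlation between ",
      colnames(xx)[worst[1]], " and ", colnames(xx)[worst[2]], "."),
      class = "hingescan_error_fit")
  }
  fit <- stats::lm.fit(xx, y)
  coefs <- fit$coefficients
  lam <- coefs[setdiff(names(coefs), "(Intercept)")]
  structure(list(
    lambda = setNames(as.numeric(lam), c("G_D", "E_F", "R_G2")),
    intercept = if (intercept) unname(coefs["(Intercept)"]) else 0,
    fitted = as.numeric(xx %*% coefs),
    residuals = as.numeric(y - xx %*% coefs),
    kappa = k, n = nrow(xx)
  ), class = "lambda_fit")
}

#' @export
print.lambda_fit <- function(x, ...) {
  cat("<lambda_fit> n =", x$n, "\n")
  cat(sprintf("  f = %.4g * G_D + %.4g * E_F + %.4g * R_G^2",
              x$lambda["G_D"], x$lambda["E_F"], x$lambda["R_G2"]))
  if (x$intercept != 0) cat(sprintf(" + %.4g", x$intercept))
  cat("\n  residual RMS:", signif(sqrt(mean(x$residuals^2)), 4),
      " condition number:", signif(x$kappa, 4), "\n")
  invisible(x)
}

#' @export
tidy.lambda_fit <- function(x, ...) {
  tibble(term = names(x$lambda), estimate = as.numeric(x$lambda))
}

#' @export
glance.lambda_fit <- function(x, ...) {
  tibble(n = x$n, sigma = sqrt(mean(x$residuals^2)), kappa = x$kappa)
}

#' Leave-one-group-out cross-validation of the fitness weights
#'
#' Splits the score table by `group` (one group = one protein's generated
#' ensemble), fits the weights on all rows outside each group in turn, and
#' predicts the held-out group's sRMSD. With k groups this performs k fits;
#' the procedure is deterministic.
#'
#' @param table Score table with columns `group`, `G_D`, `E_F`, `R_G`,
#'   `srmsd` (and optionally `id`).
#' @param intercept Passed to [fit_lambda()].
#' @return A tibble with one row per group: `group`, `fit` (list column of
#'   `lambda_fit`), and `predictions` (list column of tibbles with held-out
#'   `actual` and `predicted` sRMSD).
#' @export
loo_cross_validate <- function(table, intercept = FALSE) {
  stopifnot(is.data.frame(table))
  if (!all(c("group", "srmsd") %in% names(table))) {
    abort("Score table needs 'group' and 'srmsd' columns.",
          class = "hingescan_error_fit")
  }
  groups <- unique(table$group)
  if (length(groups) < 2L) {
    abort("Cross-validation needs at least 2 groups.",
          class = "hingescan_error_fit")
  }
  out <- lapply(groups, function(g) {
    train <- table[table$group != g, , drop = FALSE]
    test <- table[table$group == g, , drop = FALSE]
    fit <- fit_lambda(design_matrix(train), train$srmsd,
                      intercept = intercept)
    pred <- as.numeric(design_matrix(test) %*% fit$lambda) + fit$intercept
    tibble(group = g, fit = list(fit),
           predictions = list(tibble(id = test$id %||% seq_len(nrow(test)),
                                     actual = test$srmsd, predicted = pred)))
  })
  bind_rows(out)
}
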