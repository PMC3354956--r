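#' Plot the explored angular grid
#'
#' Tile map of visited cells in the (theta_y, theta_x) plane, faceted by
#' theta_z, coloured by fitness for feasible cells; infeasible cells are
#' shown hatched grey. The predicted cell is outlined.
#'
#' @param object A `hinge_search` result.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.hinge_search <- function(object, ...) {
  sp <- object$config$grid$spacing
  cells <- object$cells
  cells$theta_y <- cells$iy * sp
  cells$theta_x <- cells$ix * sp
  cells$theta_z <- cells$iz * sp
  feas <- cells[cells$status == "feasible", ]
  feas <- left_join(feas, object$scores[, c("id", "f")], by = "id")
  infeas <- cells[cells$status == "infeasible", ]
  best <- object$predicted$angles
  best_cell <- cell_of(best, as_cell_grid(object$config))
  p <- ggplot2::ggplot() +
    ggplot2::geom_tile(
      data = feas,
      ggplot2::aes(x = .data$theta_y, y = .data$theta_x, fill = .data$f),
      width = sp, height = sp, colour = "grey30", linewidth = 0.1) +
    ggplot2::geom_tile(
      data = infeas,
      ggplot2::aes(x = .data$theta_y, y = .data$theta_x),
      width = sp, height = sp, fill = "grey80", colour = "grey30",
      linewidth = 0.1) +
    ggplot2::facet_wrap(~theta_z, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_viridis_c(name = "fitness f") +
    ggplot2::labs(x = expression(theta[y] * " (deg)"),
                  y = expression(theta[x] * " (deg)"),
                  title = "Explored conformational cells")
  if (!is.null(best_cell)) {
    p <- p + ggplot2::geom_tile(
      data = tibble(theta_y = best_cell[["iy"]] * sp,
                    theta_x = best_cell[["ix"]] * sp,
                    theta_z = best_cell[["iz"]] * sp),
      ggplot2::aes(x = .data$theta_y, y = .data$theta_x),
      width = sp, height = sp, fill = NA, colour = "red", linewidth = 0.6)
  }
  p
}

#' Plot the running best fitness along the search trajectory
#'
#' @param result A `hinge_search` result.
#' @return A ggplot object.
#' @export
plot_trajectory <- function(result) {
  tr <- result$trajectory
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$iteration, y = .data$best_f)) +
    ggplot2::geom_step(colour = "steelblue") +
    ggplot2::labs(x = "cell visit", y = "running best fitness f",
                  title = "Line-search progress")
}

#' Observed vs predicted sRMSD from cross-validation
#'
#' @param cv Output of [loo_cross_validate()].
#' @return A ggplot object.
#' @export
plot_cv <- function(cv) {
  preds <- bind_rows(lapply(seq_len(nrow(cv)), function(i) {
    mutate(cv$predictions[[i]], group = cv$group[[i]])
  }))
  ggplot2::ggplot(preds,
                  ggplot2::aes(x = .data$actual, y = .data$predicted,
                               colour = .data$group)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "observed sRMSD (A)",
                  y = "predicted fitness (held-out group)",
                  title = "Leave-one-protein-out cross-validation")
}
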