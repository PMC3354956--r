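# The search engine. Conformers live on a grid of angular cells spaced
# config$grid$spacing degrees apart (15 by default, so each cell owns
# +/- 7.5 deg per axis). A cell is unvisited, feasible (holds one scored
# conformer), or infeasible (two successive rotate+relax attempts failed to
# land a converged conformer in it). The fitness f is minimized by a line
# search that sweeps one angle at a time over its full range.

#' Angular cell grid
#'
#' @param spacing Cell spacing in degrees (default 15).
#' @param range_y,range_x,range_z Per-axis `(min, max)` ranges in degrees.
#'   The defaults span +/-80 deg in y and z and -20 to 80 deg in x;
#'   positive theta_x closes the cleft in standard orientation.
#' @return An object of class `cell_grid`.
#' @export
cell_grid <- function(spacing = 15, range_y = c(-80, 80),
                      range_x = c(-20, 80), range_z = c(-80, 80)) {
  centers <- function(rng) {
    ks <- seq(ceiling(rng[1] / spacing), floor(rng[2] / spacing))
    as.integer(ks)
  }
  structure(list(
    spacing = spacing,
    ranges = list(theta_y = range_y, theta_x = range_x, theta_z = range_z),
    centers = list(theta_y = centers(range_y), theta_x = centers(range_x),
                   theta_z = centers(range_z))
  ), class = "cell_grid")
}

as_cell_grid <- function(config) {
  g <- config$grid
  cell_grid(g$spacing, g$range_y, g$range_x, g$range_z)
}

# nearest spacing-multiple with the boundary-at-+spacing/2 tie broken
# toward zero
snap_axis <- function(a, spacing) {
  k <- floor(a / spacing)
  rem <- a - k * spacing
  half <- spacing / 2
  idx <- ifelse(abs(rem - half) < 1e-9,
                ifelse(abs(k) < abs(k + 1), k, k + 1),
                ifelse(rem < half, k, k + 1))
  as.integer(idx)
}

#' Locate the cell containing a set of Euler angles
#'
#' @param angles [euler_angles()].
#' @param grid A [cell_grid()].
#' @return Named integer vector `c(iy, ix, iz)` of cell indices (multiply
#'   by `grid$spacing` for the center in degrees), or `NULL` when the
#'   angles fall outside the grid.
#' @export
cell_of <- function(angles, grid) {
  angles <- as_euler(angles)
  sp <- grid$spacing
  idx <- c(iy = snap_axis(angles[["theta_y"]], sp),
           ix = snap_axis(angles[["theta_x"]], sp),
           iz = snap_axis(angles[["theta_z"]], sp))
  ok <- idx[["iy"]] %in% grid$centers$theta_y &&
    idx[["ix"]] %in% grid$centers$theta_x &&
    idx[["iz"]] %in% grid$centers$theta_z
  if (!ok) return(NULL)
  idx
}

cell_key <- function(cell) paste(cell, collapse = ":")

cell_center_angles <- function(cell, grid) {
  sp <- grid$spacing
  euler_angles(theta_z = cell[["iz"]] * sp, theta_x = cell[["ix"]] * sp,
               theta_y = cell[["iy"]] * sp)
}

# rotate the M domain of a standard-orientation conformer by an arbitrary
# rotation matrix about the origin
rotate_m_by_matrix <- function(conf, domains, R) {
  prot <- conf$protein
  idx <- prot$resno %in% domain_residues(domains, "M")
  xyz <- atom_xyz(prot[idx, , drop = FALSE])
  prot[idx, c("x", "y", "z")] <- as.data.frame(xyz %*% t(R))
  new_conformer(prot, conf$ligand, angles = NULL, relaxed = FALSE,
                provenance = conf$provenance)
}

new_search_state <- function(grid, config) {
  st <- new.env(parent = emptyenv())
  st$grid <- grid
  st$config <- config
  st$cells <- list()        # key -> list(status, id)
  st$conformers <- list()   # id -> conformer
  st$attempts <- list()     # key -> attempt count
  st$trajectory <- list()
  st$next_id <- 1L
  st$iteration <- 0L
  st$best_id <- NA_character_
  st$best_f <- Inf
  st
}

cell_status <- function(state, cell) {
  e <- state$cells[[cell_key(cell)]]
  if (is.null(e)) "unvisited" else e$status
}

log_visit <- function(state, axis, cell, outcome, id = NA_character_,
                      f = NA_real_) {
  state$iteration <- state$iteration + 1L
  if (!is.na(f) && f < state$best_f - 1e-12) {
    state$best_f <- f
    state$best_id <- id
  }
  state$trajectory[[length(state$trajectory) + 1L]] <- tibble(
    iteration = state$iteration, axis = axis,
    iy = cell[["iy"]], ix = cell[["ix"]], iz = cell[["iz"]],
    outcome = outcome, id = id, f = f, best_id = state$best_id,
    best_f = state$best_f
  )
  invisible(state)
}

store_feasible <- function(state, cell, conf, f, axis, outcome) {
  id <- sprintf("c%04d", state$next_id)
  state$next_id <- state$next_id + 1L
  conf$provenance <- paste0(conf$provenance, " [", outcome, " ",
                            cell_key(cell), "]")
  state$conformers[[id]] <- conf
  state$cells[[cell_key(cell)]] <- list(status = "feasible", id = id)
  log_visit(state, axis, cell, outcome, id, f)
  id
}

#' Generate (or fail to generate) a conformer in a target cell
#'
#' One unit of the search: rotate the mobile domain of the base conformer
#' by the angle difference to the target cell center, relax, measure the
#' landing angles, and re-dock. Relaxation drift can carry the structure
#' into a different cell; a first miss triggers a second attempt with a
#' proportional drift compensation (aim at `target + (target - landed)`).
#' Two misses (or relaxation failures) mark the target cell infeasible —
#' it sits on the boundary of accessible conformation space and is never
#' attempted again. A converged conformer that lands in a different,
#' unvisited cell is recorded there as a drift capture.
#'
#' @param base Feasible conformer with measured angles, in the start's
#'   S-frame.
#' @param target Cell index triple from [cell_of()].
#' @param state Search state environment (created by [line_search()]).
#' @param start Starting conformer (standard orientation).
#' @param domains Domain tibble.
#' @param axis Axis label for the trajectory log.
#' @return The cell's status after the attempt(s): `"feasible"` or
#'   `"infeasible"`.
#' @keywords internal
generate_in_cell <- function(base, target, state, start, domains,
                             axis = "init") {
  config <- state$config
  grid <- state$grid
  if (is.null(base$angles)) {
    abort("Base conformer has no measured angles.",
          class = "hingescan_error_explore")
  }
  key <- cell_key(target)
  if (cell_status(state, target) != "unvisited") {
    return(state$cells[[key]]$status)
  }
  target_angles <- cell_center_angles(target, grid)
  aim <- as.numeric(target_angles)
  seed <- cell_seed(config$seed, target)
  for (attempt in 1:2) {
    delta <- compose_euler(euler_angles(aim[1], aim[2], aim[3])) %*%
      t(compose_euler(base$angles))
    cand <- rotate_m_by_matrix(base, domains, delta)
    rr <- relax(cand, domains, reference = start, config = config)
    landed <- decompose_angles(rr$conformer, start, domains)
    if (!rr$report$converged) {
      log_visit(state, axis, target,
                paste0("relax_failed_attempt", attempt))
      next
    }
    conf <- rr$conformer
    conf$angles <- landed
    landed_cell <- cell_of(landed, grid)
    conf <- score_conformer(conf, conf$ligand, config, seed + attempt)
    f <- evaluate_fitness(conf$scores, config$lambda)
    if (!is.null(landed_cell) && identical(landed_cell, target)) {
      store_feasible(state, target, conf, f, axis, "feasible")
      return("feasible")
    }
    # drift carried it elsewhere; capture if that cell is unvisited
    if (!is.null(landed_cell) &&
        cell_status(state, landed_cell) == "unvisited") {
      store_feasible(state, landed_cell, conf, f, axis, "drift_capture")
    } else {
      log_visit(state, axis, target, paste0("drifted_attempt", attempt))
    }
    # second attempt aims past the target by the observed drift
    aim <- as.numeric(target_angles) +
      (as.numeric(target_angles) - as.numeric(landed))
  }
  state$cells[[key]] <- list(status = "infeasible", id = NA_character_)
  log_visit(state, axis, target, "infeasible")
  "infeasible"
}

#' Exhaustively explore one angular axis
#'
#' Ensures every cell along `axis` through the current best conformer's
#' cell (the other two indices held fixed) holds a conformer or an
#' infeasible mark, then returns the feasible conformer minimizing the
#' fitness f on that axis. Ties go to the smallest angular distance from
#' the current best, then to the lexicographically smallest cell index.
#'
#' @param best_id Id of the current best conformer in `state`.
#' @param axis `"theta_y"`, `"theta_x"`, or `"theta_z"`.
#' @param state Search state environment.
#' @param start,domains As in [generate_in_cell()].
#' @return Id of the best conformer on the axis.
#' @keywords internal
explore_axis <- function(best_id, axis, state, start, domains) {
  grid <- state$grid
  config <- state$config
  best <- state$conformers[[best_id]]
  base_cell <- cell_of(best$angles, grid)
  # rotations are always applied to the starting structure: with a
  # deterministic relaxer every cell's conformer is then independent of
  # the search path, so the line search is coordinate descent on a fixed
  # cell-indexed fitness (see the methods vignette for the rationale)
  base <- start
  axis_slot <- c(theta_y = "iy", theta_x = "ix", theta_z = "iz")[[axis]]
  for (k in grid$centers[[axis]]) {
    target <- base_cell
    target[[axis_slot]] <- as.integer(k)
    if (cell_status(state, target) == "unvisited") {
      generate_in_cell(base, target, state, start, domains, axis = axis)
    }
  }
  # collect feasible cells on the axis and pick the f-minimizer
  cand <- list()
  for (k in grid$centers[[axis]]) {
    target <- base_cell
    target[[axis_slot]] <- as.integer(k)
    e <- state$cells[[cell_key(target)]]
    if (!is.null(e) && e$status == "feasible") {
      conf <- state$conformers[[e$id]]
      cand[[length(cand) + 1L]] <- list(
        id = e$id, cell = target,
        f = evaluate_fitness(conf$scores, config$lambda),
        dist = abs(k - base_cell[[axis_slot]])
      )
    }
  }
  if (!length(cand)) {
    abort("No feasible cell on the axis (the base cell should be feasible).",
          class = "hingescan_error_explore")
  }
  fs <- map_dbl(cand, "f")
  dists <- map_dbl(cand, "dist")
  keys <- vapply(cand, function(cc) cell_key(cc$cell), "")
  ord <- order(fs, dists, keys)
  cand[[ord[1]]]$id
}

#' Line-search minimization of the fitness over the cell grid
#'
#' Cycles the three rotation axes in `config$axis_order` (default theta_y,
#' theta_x, theta_z), exhaustively exploring each axis through the current
#' best conformer and moving to the axis minimizer. After a full cycle
#' with no change of best cell, one final verification sweep of all three
#' axes is run from the best conformer; convergence is declared when it
#' yields no improvement. `config$max_sweeps` caps runaway searches.
#'
#' @param start Starting conformer in standard orientation, with its
#'   ligand docked.
#' @param domains Domain tibble from [assign_domains()].
#' @param config An [hs_config()].
#' @return An object of class `hinge_search`: list with `predicted`
#'   (best conformer), `trajectory` (tibble), `scores` (score table of all
#'   feasible conformers), `cells` (status tibble), `state`, `converged`.
#' @export
line_search <- function(start, domains, config = hs_config()) {
  config <- as_config(config)
  grid <- as_cell_grid(config)
  state <- new_search_state(grid, config)
  # establish the start's own cell
  start_conf <- start
  if (is.null(start_conf$angles)) {
    start_conf$angles <- decompose_angles(start_conf, start, domains)
  }
  start_cell <- cell_of(start_conf$angles, grid)
  if (is.null(start_cell)) {
    abort("Starting conformer lies outside the angular grid.",
          class = "hingescan_error_explore")
  }
  if (is.null(start_conf$scores)) {
    start_conf <- score_conformer(start_conf, start_conf$ligand, config,
                                  cell_seed(config$seed, start_cell))
  }
  f0 <- evaluate_fitness(start_conf$scores, config$lambda)
  best <- store_feasible(state, start_cell, start_conf, f0, "init", "feasible")
  axes <- config$axis_order
  converged <- FALSE
  for (sweep in seq_len(config$max_sweeps)) {
    before <- best
    for (axis in axes) {
      best <- explore_axis(best, axis, state, start, domains)
    }
    message(sprintf("sweep %d complete: best cell %s, f = %.4f",
                    sweep, cell_key(cell_of(state$conformers[[best]]$angles,
                                            grid)),
                    state$best_f))
    if (identical(best, before)) {
      # verification sweep: all three axes once more from the best
      verify_best <- best
      for (axis in axes) {
        verify_best <- explore_axis(verify_best, axis, state, start, domains)
      }
      if (identical(verify_best, best)) {
        converged <- TRUE
        break
      }
      best <- verify_best
    }
  }
  build_search_result(state, best, start_conf, converged)
}

build_search_result <- function(state, best_id, start_conf, converged) {
  cells_tbl <- bind_rows(lapply(names(state$cells), function(k) {
    idx <- as.integer(strsplit(k, ":", fixed = TRUE)[[1]])
    tibble(iy = idx[1], ix = idx[2], iz = idx[3],
           status = state$cells[[k]]$status,
           id = state$cells[[k]]$id %||% NA_character_)
  }))
  scores_tbl <- bind_rows(lapply(names(state$conformers), function(id) {
    conf <- state$conformers[[id]]
    tibble(id = id,
           theta_y = conf$angles[["theta_y"]],
           theta_x = conf$angles[["theta_x"]],
           theta_z = conf$angles[["theta_z"]],
           G_D = conf$scores$G_D, E_F = conf$scores$E_F,
           R_G = conf$scores$R_G,
           f = evaluate_fitness(conf$scores, state$config$lambda))
  }))
  # the predicted structure is the fitness argmin over every feasible
  # conformer generated, drift captures included
  if (nrow(scores_tbl)) {
    best_id <- scores_tbl$id[which.min(scores_tbl$f)]
  }
  structure(list(
    predicted = state$conformers[[best_id]],
    predicted_id = best_id,
    start = start_conf,
    trajectory = bind_rows(state$trajectory),
    scores = scores_tbl,
    cells = cells_tbl,
    config = state$config,
    converged = converged,
    state = state
  ), class = "hinge_search")
}

#' @export
print.hinge_search <- function(x, ...) {
  n_feas <- sum(x$cells$status == "feasible")
  n_inf <- sum(x$cells$status == "infeasible")
  cat("<hinge_search> ", nrow(x$trajectory), " visits, ", n_feas,
      " feasible / ", n_inf, " infeasible cells",
      if (x$converged) ", converged" else ", NOT converged", "\n", sep = "")
  cat(sprintf("  predicted: %s at angles z=%.1f x=%.1f y=%.1f, f = %.4f\n",
              x$predicted_id, x$predicted$angles[["theta_z"]],
              x$predicted$angles[["theta_x"]],
              x$predicted$angles[["theta_y"]],
              min(x$scores$f)))
  invisible(x)
}

#' @export
tidy.hinge_search <- function(x, ...) x$trajectory

#' @export
glance.hinge_search <- function(x, ...) {
  tibble(
    n_visits = nrow(x$trajectory),
    n_feasible = sum(x$cells$status == "feasible"),
    n_infeasible = sum(x$cells$status == "infeasible"),
    best_f = min(x$scores$f),
    converged = x$converged,
    theta_y = x$predicted$angles[["theta_y"]],
    theta_x = x$predicted$angles[["theta_x"]],
    theta_z = x$predicted$angles[["theta_z"]]
  )
}

#' Run the full hinge-bending exploration
#'
#' End-to-end pipeline: assign domains from the hinge, dock the ligand to
#' the starting structure (before any rotation or relaxation, so the
#' binding cleft is occupied), place everything in standard orientation,
#' relax the start, and minimize the fitness by [line_search()].
#'
#' @param receptor Protein atom tibble or path to an apo PDB file.
#' @param ligand Ligand atom tibble or path to a ligand PDB file.
#' @param hinge A [hinge_spec()] (or string like `"88-89,181-182"`).
#' @param config An [hs_config()].
#' @param out_dir Optional directory; when given, per-conformer PDBs, the
#'   score table (TSV), the trajectory (JSON) and `predicted.pdb` are
#'   written there.
#' @return A `hinge_search` object (see [line_search()]).
#' @export
explore <- function(receptor, ligand, hinge, config = hs_config(),
                    out_dir = NULL) {
  config <- as_config(config)
  protein <- if (is.character(receptor)) read_pdb(receptor) else receptor
  lig <- if (is.character(ligand)) read_ligand(ligand) else ligand
  domains <- assign_domains(protein, hinge)
  # initial docking on the unrotated structure
  dock0 <- dock_score(protein, lig, config, seed = config$seed)
  std <- standard_orientation(protein, domains, dock0$ligand,
                              com_mode = config$com_mode)
  start0 <- new_conformer(std$protein, std$ligand, relaxed = FALSE,
                          provenance = "start")
  rr <- relax(start0, domains, reference = start0, config = config)
  start <- rr$conformer
  if (!rr$report$converged) {
    warn("Relaxation of the starting structure did not converge.")
  }
  # relaxation can shift the linker center of mass slightly; re-establish
  # the standard orientation so hinge rotations stay about the origin
  std2 <- standard_orientation(start$protein, domains, start$ligand,
                               com_mode = config$com_mode)
  start$protein <- std2$protein
  start$ligand <- std2$ligand
  start$angles <- euler_angles(0, 0, 0)
  start$relaxed <- TRUE
  result <- line_search(start, domains, config)
  result$domains <- domains
  if (!is.null(out_dir)) {
    write_search_output(result, out_dir)
  }
  result
}

write_search_output <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(result$scores, file.path(out_dir, "scores.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(result$trajectory, file.path(out_dir, "trajectory.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  for (id in names(result$state$conformers)) {
    conf <- result$state$conformers[[id]]
    write_pdb(conf$protein, file.path(out_dir, paste0(id, ".pdb")),
              ligand = conf$ligand)
  }
  write_pdb(result$predicted$protein, file.path(out_dir, "predicted.pdb"),
            ligand = result$predicted$ligand)
  invisible(out_dir)
}
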