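# The three fitness terms. G_D and E_F stand behind scorer interfaces: any
# function with the same signature (conformer in, score out) can replace
# them, e.g. adapters around physical docking or stability codes. The
# built-in surrogates are simple pairwise potentials with documented
# parameters; their magnitudes are on their own scale.

#' Radius of gyration over C-alpha atoms
#'
#' The distance from the C-alpha mass center at which all C-alpha mass
#' could be concentrated to give the same moment of inertia:
#' `Rg = sqrt(sum_i m_i r_i^2 / M)`, with `r_i` the distance of atom `i`
#' from the center of mass and `M` the total mass. C-alpha atoms all carry
#' the carbon mass, so the weights cancel; they are kept explicit so the
#' definition is mass-weighted.
#'
#' @param protein Protein atom tibble (or a conformer).
#' @return Radius of gyration in Angstroms.
#' @export
radius_of_gyration <- function(protein) {
  if (inherits(protein, "hinge_conformer")) protein <- protein$protein
  ca <- protein[protein$atom == "CA", ]
  if (!nrow(ca)) {
    abort("No C-alpha atoms for radius of gyration.",
          class = "hingescan_error_scoring")
  }
  m <- ca$mass
  xyz <- atom_xyz(ca)
  com <- as.numeric(crossprod(xyz, m) / sum(m))
  r2 <- rowSums(sweep(xyz, 2, com)^2)
  sqrt(sum(m * r2) / sum(m))
}

# the 60 proper rotations of the icosahedral group, via the 120 unit
# quaternions of the binary icosahedral group, deduplicated over q ~ -q
icosahedral_rotations <- function() {
  if (!is.null(.hs_cache$ico_rot)) return(.hs_cache$ico_rot)
  phi <- (1 + sqrt(5)) / 2
  quats <- list()
  # 8 axis units
  for (i in 1:4) for (s in c(1, -1)) {
    q <- numeric(4); q[i] <- s; quats[[length(quats) + 1]] <- q
  }
  # 16 half units
  for (s1 in c(1, -1)) for (s2 in c(1, -1)) for (s3 in c(1, -1))
    for (s4 in c(1, -1)) {
      quats[[length(quats) + 1]] <- c(s1, s2, s3, s4) / 2
    }
  # 96 icosians: even permutations of (0, 1/2, 1/(2 phi), phi/2) with signs
  base <- c(phi / 2, 0.5, 1 / (2 * phi), 0)
  even_perms <- list(
    c(1, 2, 3, 4), c(1, 3, 4, 2), c(1, 4, 2, 3), c(2, 1, 4, 3),
    c(2, 3, 1, 4), c(2, 4, 3, 1), c(3, 1, 2, 4), c(3, 2, 4, 1),
    c(3, 4, 1, 2), c(4, 1, 3, 2), c(4, 2, 1, 3), c(4, 3, 2, 1)
  )
  for (p in even_perms) {
    v <- base[p]
    nz <- which(v != 0)
    for (bits in 0:7) {
      s <- rep(1, 4)
      s[nz] <- ifelse(bitwAnd(bits, 2^(0:2)) > 0, -1, 1)
      quats[[length(quats) + 1]] <- v * s
    }
  }
  qm <- do.call(rbind, quats)
  # canonicalize sign so q and -q collapse
  flip <- apply(qm, 1, function(q) {
    i <- which(abs(q) > 1e-9)[1]
    sign(q[i])
  })
  qm <- qm * flip
  qm <- unique(round(qm, 9))
  stopifnot(nrow(qm) == 60L)
  rots <- lapply(seq_len(nrow(qm)), function(i) quat_to_matrix(qm[i, ]))
  .hs_cache$ico_rot <- rots
  rots
}

.hs_cache <- new.env(parent = emptyenv())

quat_to_matrix <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

#' Surrogate rigid-ligand docking score (G_D)
#'
#' Re-docks a rigid ligand to a receptor conformation and returns the best
#' (lowest) interaction energy found, together with the posed ligand. The
#' search is an exhaustive scan — translations on a grid over the receptor
#' bounding box padded by `config$dock$pad` Angstroms, times a fixed
#' icosahedral set of orientations — followed by local Nelder-Mead descent
#' from the best `top_k` grid poses. The interaction energy is a soft 6-12
#' van der Waals term with per-element radii plus a distance-damped
#' gaussian attraction between polar (N/O) atom pairs. Deterministic given
#' `seed` and `config` (the seed only matters when `jitter_sd > 0`).
#'
#' @param conformer A conformer or bare protein atom tibble (receptor).
#' @param ligand Ligand atom tibble; its current position is ignored (the
#'   ligand is removed and docked afresh).
#' @param config An [hs_config()] (or list of overrides).
#' @param seed Integer seed for the optional pose jitter.
#' @return List with `G_D` (best energy), `ligand` (atom tibble in the best
#'   pose) and `poses` (tibble of refined candidate poses).
#' @export
dock_score <- function(conformer, ligand, config = hs_config(), seed = 1L) {
  config <- as_config(config)
  protein <- if (inherits(conformer, "hinge_conformer")) conformer$protein else conformer
  validate_ligand(ligand)
  dk <- config$dock
  pxyz <- atom_xyz(protein)
  prad <- vdw_radius(protein$element)
  ppol <- is_polar_element(protein$element)
  lxyz <- atom_xyz(ligand)
  lcen <- colMeans(lxyz)
  l0 <- sweep(lxyz, 2, lcen)
  lrad <- vdw_radius(ligand$element)
  lpol <- is_polar_element(ligand$element)
  box_lo <- apply(pxyz, 2, min) - dk$pad
  box_hi <- apply(pxyz, 2, max) + dk$pad
  if (any(box_hi - box_lo < 2 * max(sqrt(rowSums(l0^2))))) {
    abort("Ligand larger than the docking search box.",
          class = "hingescan_error_dock")
  }
  dims <- pmax(2L, as.integer(floor((box_hi - box_lo) / dk$grid_spacing)) + 1L)
  rots <- icosahedral_rotations()[seq_len(dk$n_orientations)]
  rot_stack <- do.call(rbind, rots)
  # the coarse scan runs with softened repulsion (a pose one grid step off
  # a tight site would otherwise score as a clash and be pruned); the
  # local refinement and all reported energies use the full potential
  grid_best <- cpp_dock_scan(pxyz, prad, ppol, l0, lrad, lpol, rot_stack,
                             box_lo, dims, dk$grid_spacing, dk$eps,
                             dk$eps, dk$polar_eps, dk$polar_r0,
                             dk$polar_sigma, dk$soft_frac, dk$cutoff,
                             as.integer(dk$top_k))
  if (!nrow(grid_best)) {
    abort("Docking scan found no candidate poses (receptor shell empty).",
          class = "hingescan_error_dock")
  }
  pose_energy <- function(par, rot) {
    dR <- compose_euler(euler_angles(par[4], par[5], par[6]))
    pts <- sweep(l0 %*% t(dR %*% rot), 2, -par[1:3])
    cpp_pose_energy(pts, lrad, lpol, pxyz, prad, ppol, dk$eps, dk$rep_eps,
                    dk$polar_eps, dk$polar_r0, dk$polar_sigma, dk$soft_frac,
                    dk$cutoff)
  }
  if (dk$jitter_sd > 0) set.seed(as.integer(seed) %% .Machine$integer.max)
  starts <- lapply(seq_len(nrow(grid_best)), function(i) {
    list(rot = rots[[grid_best[i, 2]]], par = c(grid_best[i, 3:5], 0, 0, 0),
         grid_energy = grid_best[i, 1])
  })
  refined <- lapply(starts, function(s) {
    par0 <- s$par
    start_energy <- pose_energy(par0, s$rot)
    if (dk$jitter_sd > 0) {
      par0[1:3] <- par0[1:3] + rnorm(3, sd = dk$jitter_sd)
    }
    fit <- optim(par0, pose_energy, rot = s$rot, method = "Nelder-Mead",
                 control = list(maxit = 300, reltol = 1e-8))
    list(energy = fit$value, par = fit$par, rot = s$rot,
         grid_energy = s$grid_energy, start_energy = start_energy)
  })
  energies <- map_dbl(refined, "energy")
  best <- refined[[which.min(energies)]]
  dR <- compose_euler(euler_angles(best$par[4], best$par[5], best$par[6]))
  posed_xyz <- sweep(l0 %*% t(dR %*% best$rot), 2, -best$par[1:3])
  posed <- set_atom_xyz(ligand, posed_xyz)
  poses <- tibble(
    energy = energies,
    start_energy = map_dbl(refined, "start_energy"),
    grid_energy = map_dbl(refined, "grid_energy"),
    tx = map_dbl(refined, ~ .x$par[1]), ty = map_dbl(refined, ~ .x$par[2]),
    tz = map_dbl(refined, ~ .x$par[3])
  )
  list(G_D = min(energies), ligand = posed, poses = poses)
}

#' Surrogate stability score (E_F)
#'
#' Discriminates energetically feasible conformers from those with
#' interpenetrating or grossly distorted domains: a quadratic-overlap clash
#' penalty over non-bonded protein atom pairs, minus a bounded
#' native-contact reward (C-alpha pairs within the contact shell, counted
#' per residue up to a cap). Invariant under rigid motion of the whole
#' structure. Lower is more stable.
#'
#' @inheritParams dock_score
#' @return Stability score (scalar).
#' @export
stability_score <- function(conformer, config = hs_config()) {
  config <- as_config(config)
  protein <- if (inherits(conformer, "hinge_conformer")) conformer$protein else conformer
  st <- config$stability
  clash <- cpp_clash_energy(atom_xyz(protein), vdw_radius(protein$element),
                            as.integer(protein$resno), st$clash_k,
                            as.integer(st$min_seq_sep))
  ca <- protein[protein$atom == "CA", ]
  contacts <- cpp_contact_count(atom_xyz(ca), st$contact_lo, st$contact_hi,
                                as.integer(st$contact_cap))
  clash - st$contact_w * contacts
}

#' Score a conformer: G_D, E_F, R_G
#'
#' Fills one score row by re-docking the ligand ([dock_score()]), scoring
#' stability ([stability_score()]), and measuring the C-alpha radius of
#' gyration ([radius_of_gyration()]). R_G is recorded unsquared; squaring
#' happens when the design matrix is assembled.
#'
#' @inheritParams dock_score
#' @return The conformer with `scores` set (a one-row tibble with columns
#'   `G_D`, `E_F`, `R_G`) and the re-docked ligand attached.
#' @export
score_conformer <- function(conformer, ligand = conformer$ligand,
                            config = hs_config(), seed = 1L) {
  config <- as_config(config)
  if (is.function(config$scorer)) {
    # scorer interface: any function (conformer, ligand, config, seed) ->
    # one-row tibble with G_D, E_F, R_G can stand in for the built-in
    # surrogates (e.g. adapters around physical docking/stability codes,
    # or analytic scorers in tests)
    conformer$scores <- config$scorer(conformer, ligand, config, seed)
    return(conformer)
  }
  if (is.null(ligand)) {
    abort("score_conformer needs a ligand to dock.",
          class = "hingescan_error_scoring")
  }
  dock <- dock_score(conformer, ligand, config, seed)
  conformer$ligand <- dock$ligand
  conformer$scores <- tibble(
    G_D = dock$G_D,
    E_F = stability_score(conformer, config),
    R_G = radius_of_gyration(conformer)
  )
  conformer
}

#' Evaluate the fitness function
#'
#' `f = lambda_1 * G_D + lambda_2 * E_F + lambda_3 * R_G^2`. Minimizing f
#' over the generated ensemble selects the predicted holo conformer.
#'
#' @param scores A data frame with columns `G_D`, `E_F`, `R_G` (one or more
#'   rows), or a conformer that has been scored.
#' @param lambda Numeric length-3 weight vector for `(G_D, E_F, R_G^2)`.
#' @return Numeric vector of fitness values, one per row.
#' @examples
#' evaluate_fitness(data.frame(G_D = -10, E_F = 100, R_G = 20),
#'                  lambda = c(0.35, 0.066, 0.030))  # 15.1
#' @export
evaluate_fitness <- function(scores, lambda) {
  if (inherits(scores, "hinge_conformer")) scores <- scores$scores
  stopifnot(length(lambda) == 3L, all(is.finite(lambda)))
  as.numeric(lambda[1] * scores$G_D + lambda[2] * scores$E_F +
               lambda[3] * scores$R_G^2)
}
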