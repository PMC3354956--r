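# Desk-scale synthetic fixtures: a two-domain C-alpha "dumbbell" protein
# with an explicit single-stranded hinge, an open/closed pair related by a
# known hinge rotation, and a small rigid ligand shaped to the closed
# cleft. The closed form is constructed so that it genuinely has more
# ligand contacts (lower surrogate docking energy) and a smaller radius of
# gyration than the open form; end-to-end recovery tests rely on these
# constructed properties.

#' Parameters for the synthetic dumbbell
#'
#' @param residues_per_domain Residues in each of S and M (>= 10).
#' @param linker_length Linker residues (>= 2).
#' @param closure_angles [euler_angles()] carrying the known rotation that
#'   maps the open (apo) form to the closed (holo) form; must lie inside
#'   the default angular search ranges. Positive theta_x closes the cleft.
#' @param domain_distance Distance (A) from the hinge to the mobile-domain
#'   center in the open form.
#' @param ligand_atoms Number of ligand atoms (>= 4).
#' @param jitter_sd Gaussian jitter (A) applied to ideal C-alpha positions.
#' @param seed Integer seed making the construction reproducible.
#' @return A list of class `dumbbell_params`.
#' @export
dumbbell_params <- function(residues_per_domain = 24, linker_length = 4,
                            closure_angles = euler_angles(0, 45, 0),
                            domain_distance = 15, ligand_atoms = 8,
                            jitter_sd = 0.02, seed = 1L) {
  stopifnot(residues_per_domain >= 10, linker_length >= 2, ligand_atoms >= 4)
  ca <- as_euler(closure_angles)
  if (ca[["theta_x"]] < -20 || ca[["theta_x"]] > 80 ||
      abs(ca[["theta_y"]]) > 80 || abs(ca[["theta_z"]]) > 80) {
    abort("closure_angles must lie inside the default search ranges.",
          class = "hingescan_error_synthetic")
  }
  structure(list(residues_per_domain = residues_per_domain,
                 linker_length = linker_length, closure_angles = ca,
                 domain_distance = domain_distance,
                 ligand_atoms = ligand_atoms, jitter_sd = jitter_sd,
                 seed = as.integer(seed)),
            class = "dumbbell_params")
}

# ideal alpha-helical C-alpha trace: rise 1.5 A/res, 100 deg/res, r 2.3 A;
# origin is the axis point at the first residue's height
helix_frame <- function(axis) {
  axis <- axis / sqrt(sum(axis^2))
  ref <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- crossprod_vec(axis, ref); e1 <- e1 / sqrt(sum(e1^2))
  e2 <- crossprod_vec(axis, e1)
  list(axis = axis, e1 = e1, e2 = e2)
}

helix_trace <- function(n, origin, axis, phase = 0) {
  fr <- helix_frame(axis)
  i <- seq_len(n) - 1
  ang <- phase + i * 100 * pi / 180
  t(vapply(seq_along(i), function(k) {
    origin + fr$axis * 1.5 * i[k] +
      2.3 * (cos(ang[k]) * fr$e1 + sin(ang[k]) * fr$e2)
  }, numeric(3)))
}

# phase whose radial unit vector points along `dir` (projected off-axis)
phase_toward <- function(axis, dir) {
  fr <- helix_frame(axis)
  d <- dir - sum(dir * fr$axis) * fr$axis
  atan2(sum(d * fr$e2), sum(d * fr$e1))
}

# connect p to q with k intermediate points at ~3.8 A consecutive spacing;
# initial guess on the chord with a sinusoidal bulge, then refined
connect_run <- function(p, q, k, bulge_dir) {
  if (k == 0) return(matrix(numeric(0), 0, 3))
  tfrac <- seq_len(k) / (k + 1)
  chord <- sqrt(sum((q - p)^2))
  bulge_dir <- bulge_dir / sqrt(sum(bulge_dir^2))
  amp <- if (chord < 3.8 * (k + 1)) {
    sqrt(max((3.8 * (k + 1))^2 - chord^2, 0)) / pi
  } else 0
  pts <- t(vapply(tfrac, function(t) {
    p + t * (q - p) + amp * sin(pi * t) * bulge_dir
  }, numeric(3)))
  if (k >= 1) {
    obj <- function(v) {
      m <- rbind(p, matrix(v, ncol = 3), q)
      sum((sqrt(rowSums(diff(m)^2)) - 3.8)^2)
    }
    fit <- optim(as.numeric(pts), obj, method = "BFGS",
                 control = list(maxit = 200, reltol = 1e-12))
    pts <- matrix(fit$par, ncol = 3)
  }
  pts
}

# a compact three-helix bundle: helix 1 up, helix 2 antiparallel, helix 3
# up again, with one turn residue per junction. Connection phases are
# solved so the junction C-alphas face each other, keeping every
# consecutive spacing within reach of a one-residue turn. The chain enters
# at the bottom of helix 1 and exits at the top of helix 3.
helix_bundle <- function(n_res, center, axis, lateral) {
  axis <- axis / sqrt(sum(axis^2))
  lateral <- lateral - sum(lateral * axis) * axis
  lateral <- lateral / sqrt(sum(lateral^2))
  side <- crossprod_vec(axis, lateral)
  n_turn <- 1L
  n_hel <- n_res - 2L * n_turn
  len <- c(ceiling(n_hel / 3), floor(n_hel / 3),
           n_hel - ceiling(n_hel / 3) - floor(n_hel / 3))
  h_height <- max(len) * 1.5
  base <- center - axis * h_height / 2
  offs <- list(-5.0 * lateral, 5.0 * lateral, 4.5 * side)
  # helix 1: end radial points toward helix 2
  ph1_end <- phase_toward(axis, offs[[2]] - offs[[1]])
  ph1 <- ph1_end - (len[1] - 1) * 100 * pi / 180
  h1 <- helix_trace(len[1], base + offs[[1]], axis, phase = ph1)
  # helix 2 (downward): start radial points back toward helix 1
  ph2 <- phase_toward(-axis, offs[[1]] - offs[[2]])
  h2 <- helix_trace(len[2], base + offs[[2]] + axis * (len[2] - 1) * 1.5,
                    -axis, phase = ph2)
  # helix 3: start radial points toward helix 2's actual end point
  p2_end <- h2[nrow(h2), ]
  ph3 <- phase_toward(axis, p2_end - (base + offs[[3]]))
  h3 <- helix_trace(len[3], base + offs[[3]], axis, phase = ph3)
  t1 <- connect_run(h1[nrow(h1), ], h2[1, ], n_turn,
                    bulge_dir = axis + 0.3 * lateral)
  t2 <- connect_run(h2[nrow(h2), ], h3[1, ], n_turn,
                    bulge_dir = -axis + 0.3 * side)
  rbind(h1, t1, h2, t2, h3)
}

ca_protein <- function(xyz, resno_start = 1L, chain = "A") {
  n <- nrow(xyz)
  new_atom_tbl(serial = seq_len(n), atom = "CA", resid = "ALA",
               resno = resno_start + seq_len(n) - 1L, element = "C",
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], chain = chain)
}

# small rigid ligand: an elongated rod (think of a nucleotide lying
# across the cleft) with an oxygen at each end. The lower oxygen docks
# into the floored pocket on the stationary wall; the upper oxygen
# reaches diagonally up and sideways to a single mobile-wall oxygen far
# from every rotation axis, so each contact reports on a different
# component of the closure rotation.
make_cage_ligand <- function(center, u, rod_d, n_atoms = 8) {
  a_end <- center - 1.3 * u
  d <- rod_d / sqrt(sum(rod_d^2))
  rod_len <- 7.0
  b_end <- a_end + rod_len * d
  n_c <- max(n_atoms - 2L, 1L)
  # zigzag the scaffold off the rod axis so the rigid pose (including the
  # spin about the rod) is fully determined; the scaffold spans the rod
  # interior, leaving both oxygen ends clear for their polar partners
  perp <- u - sum(u * d) * d
  perp <- perp / sqrt(sum(perp^2))
  offs <- seq(1.2, rod_len - 1.0, length.out = n_c)
  carbons <- t(vapply(seq_len(n_c), function(k) {
    a_end + offs[k] * d + 0.35 * (-1)^k * perp
  }, numeric(3)))
  xyz <- rbind(carbons, b_end, a_end)
  elements <- c(rep("C", n_c), "O", "O")
  new_atom_tbl(serial = seq_len(nrow(xyz)),
               atom = paste0(elements, seq_len(nrow(xyz))), resid = "LIG",
               resno = 1L, element = elements, x = xyz[, 1], y = xyz[, 2],
               z = xyz[, 3], chain = "L", record = "HETATM")
}

#' Generate a synthetic open/closed dumbbell pair
#'
#' Builds an idealized two-domain C-alpha protein — two three-helix
#' bundles joined by a single-stranded linker — directly in standard
#' orientation, then produces the closed (holo) form by rotating the
#' mobile domain by exactly `closure_angles` about the hinge. A rigid ring
#' ligand is placed in the closed cleft, clash-free, and (since the ligand
#' is stationary with respect to S) sits at the same coordinates in the
#' open form. By construction the closed form has a smaller radius of
#' gyration and more ligand contacts than the open form.
#'
#' @param params A [dumbbell_params()] list.
#' @return List with `apo` (open conformer, in standard orientation, with
#'   the ligand), `holo` (closed conformer), `hinge` (a [hinge_spec()]),
#'   `domains` (from [assign_domains()]), and `params`.
#' @export
make_open_closed_pair <- function(params = dumbbell_params()) {
  stopifnot(inherits(params, "dumbbell_params"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(params$seed)
  n_dom <- params$residues_per_domain
  n_link <- params$linker_length
  d_m <- params$domain_distance
  # S bundle below/behind the hinge, M bundle straight up the +z axis; the
  # S center sits in the -y half plane as the standard orientation demands
  s_xyz <- helix_bundle(n_dom, center = c(0, -11, -11), axis = c(0, 0, 1),
                        lateral = c(1, 0, 0))
  m_xyz <- helix_bundle(n_dom, center = c(0, 0, d_m), axis = c(0, 0, 1),
                        lateral = c(1, 0, 0))
  link_xyz <- connect_run(s_xyz[nrow(s_xyz), ], m_xyz[1, ], n_link,
                          bulge_dir = c(1, 0.2, 0))
  xyz <- rbind(s_xyz, link_xyz, m_xyz)
  xyz <- xyz + matrix(rnorm(length(xyz), sd = params$jitter_sd), ncol = 3)
  spacing <- sqrt(rowSums(diff(xyz)^2))
  if (any(abs(spacing - 3.8) > 0.12)) {
    abort(paste0("Dumbbell construction broke C-alpha spacing (worst ",
                 signif(max(abs(spacing - 3.8)), 3), " A from 3.8)."),
          class = "hingescan_error_synthetic")
  }
  protein <- ca_protein(xyz)
  hinge <- hinge_spec(list(n_dom + seq_len(n_link)))
  domains <- assign_domains(protein, hinge)
  clash <- cpp_clash_energy(xyz, vdw_radius(protein$element),
                            as.integer(protein$resno), 1, 2L)
  if (clash > 0.5) {
    abort(paste0("Dumbbell construction produced steric clashes (penalty ",
                 signif(clash, 3), "); adjust parameters."),
          class = "hingescan_error_synthetic")
  }
  std <- standard_orientation(protein, domains)
  apo0 <- new_conformer(std$protein, NULL, angles = euler_angles(0, 0, 0),
                        relaxed = TRUE, provenance = "synthetic apo")
  holo0 <- apply_hinge_rotation(apo0, domains, params$closure_angles)
  # carve the binding cleft: the S- and M-domain residues that face each
  # other across the closed cleft (away from the hinge) each receive a
  # tethered polar pseudo-side-chain oxygen pointing into the cleft, so
  # the closed form wraps the ligand in a polar cage that the open form
  # cannot assemble — the constructed discriminative property
  m_res <- domain_residues(domains, "M")
  s_res <- domain_residues(domains, "S")
  hm_tbl <- holo0$protein[holo0$protein$resno %in% m_res, ]
  hs_tbl <- holo0$protein[holo0$protein$resno %in% s_res, ]
  hm <- atom_xyz(hm_tbl); hs <- atom_xyz(hs_tbl)
  far <- sqrt(rowSums(hs^2)) > 8          # keep the cage off the hinge
  dmat <- sqrt(pmax(outer(rowSums(hs^2), rowSums(hm^2), "+") -
                      2 * hs %*% t(hm), 0))
  dmat[!far, ] <- Inf
  pair_min <- which(dmat == min(dmat), arr.ind = TRUE)[1, ]
  gap_vec <- hm[pair_min[2], ] - hs[pair_min[1], ]
  gap <- min(dmat)
  cage_center <- hs[pair_min[1], ] + gap_vec / 2
  u <- gap_vec / gap
  ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- crossprod_vec(u, ref); e1 <- e1 / sqrt(sum(e1^2))
  e2 <- crossprod_vec(u, e1)
  # the cage: the rod ligand's lower oxygen sits 1.3 A below the cleft
  # midpoint inside a floored cone of three stationary-wall oxygens at
  # hydrogen-bond distance; its upper oxygen, at the far end of the rod,
  # is met by a single mobile-wall oxygen placed 3 A above it at the
  # exact closure. The upper site lies well off every rotation axis, so
  # yaw, pitch and roll errors all move it out of hydrogen-bond range.
  circle <- function(center, radius, phases_deg, height) {
    t(vapply(phases_deg * pi / 180, function(a) {
      center + height * u + radius * (cos(a) * e1 + sin(a) * e2)
    }, numeric(3)))
  }
  # the rod runs diagonally up and sideways (along the x axis of the
  # standard orientation, projected off the cleft axis), so its far end
  # sits under mobile-domain material far from every rotation axis: yaw,
  # pitch and roll each move the matching mobile-wall oxygen by over an
  # Angstrom per grid cell
  w <- c(1, 0, 0) - u[1] * u
  w <- w / sqrt(sum(w^2))
  # floor-cone phases straddle the rod exit so the rod threads between
  # two tips on its way out of the pocket
  phi_w <- atan2(sum(w * e2), sum(w * e1)) * 180 / pi
  tips_s <- circle(cage_center, 2.3, phi_w + c(60, 180, 300), -3.1)
  rod_d <- 0.55 * u + 0.84 * w
  rod_d <- rod_d / sqrt(sum(rod_d^2))
  rod_b <- cage_center - 1.3 * u + 7.0 * rod_d
  tips_m <- matrix(rod_b + 3.0 * u, nrow = 1)
  # steric carving, all apolar carbons:
  #  - a collar below the ligand plane (anchored to S) shields the pocket
  #    from lateral ligand approaches;
  #  - interdigitating knobs ring the pocket: four anchored to S reach up
  #    past the cleft midplane, four anchored to M reach down, staggered
  #    by 45 degrees. They mesh without contact only at the exact
  #    closure; a twist or tilt of the mobile wall, a sideways capping
  #    approach, or an over-closure drives knob into knob (or knob into
  #    wall) and the conformer becomes infeasible. This is the shape
  #    complementarity real interdomain interfaces supply.
  collar <- circle(cage_center, 5.0, c(30, 90, 150, 210, 270, 330), -2.8)
  knobs_s <- circle(cage_center, 9.0, c(0, 60, 120, 180, 240, 300), 0.5)
  knobs_m <- circle(cage_center, 9.0, c(30, 90, 150, 210, 270, 330), -0.5)
  # anchors must be interior residues of their domain: the pseudo-atom
  # tethers reach the flanking C-alphas, which must rotate with the same
  # domain
  anchor_for <- function(tips, pxyz, tbl, taken = integer(0)) {
    dom_res <- sort(unique(tbl$resno))
    interior <- dom_res[(dom_res - 1L) %in% dom_res &
                          (dom_res + 1L) %in% dom_res]
    vapply(seq_len(nrow(tips)), function(i) {
      d <- sqrt(colSums((t(pxyz) - tips[i, ])^2))
      d[tbl$resno %in% taken | !(tbl$resno %in% interior)] <- Inf
      k <- which.min(d)
      taken <<- c(taken, tbl$resno[k])
      tbl$resno[k]
    }, integer(1))
  }
  # keep only carving atoms that are clash-free against the chain, the
  # ligand, and each other in BOTH end states (the polar cage tips are
  # required and placed clear by construction)
  r_c0 <- compose_euler(params$closure_angles)
  apo_ca <- atom_xyz(apo0$protein)
  holo_ca <- atom_xyz(holo0$protein)
  lig_guess <- rbind(cage_center - 1.3 * u, rod_b,
                     t(vapply(1:6, function(k) {
                       cage_center - 1.3 * u + k * rod_d
                     }, numeric(3))))
  keep_clear <- function(cand, in_m, accepted_holo, accepted_apo,
                         min_d = 3.45) {
    keep <- logical(nrow(cand))
    acc_h <- accepted_holo; acc_a <- accepted_apo
    for (i in seq_len(nrow(cand))) {
      ph <- cand[i, ]
      pa <- if (in_m) as.numeric(t(r_c0) %*% ph) else ph
      ok <- min(sqrt(colSums((t(holo_ca) - ph)^2))) >= min_d &&
        min(sqrt(colSums((t(apo_ca) - pa)^2))) >= min_d &&
        min(sqrt(colSums((t(lig_guess) - ph)^2))) >= min_d &&
        (!nrow(acc_h) || min(sqrt(colSums((t(acc_h) - ph)^2))) >= min_d) &&
        (!nrow(acc_a) || min(sqrt(colSums((t(acc_a) - pa)^2))) >= min_d)
      if (ok) {
        keep[i] <- TRUE
        acc_h <- rbind(acc_h, ph); acc_a <- rbind(acc_a, pa)
      }
    }
    keep
  }
  tip_all_h <- rbind(tips_s, tips_m)
  tip_all_a <- rbind(tips_s, t(t(r_c0) %*% t(tips_m)))
  keep_col <- keep_clear(collar, FALSE, tip_all_h, tip_all_a)
  collar <- collar[keep_col, , drop = FALSE]
  acc_h <- rbind(tip_all_h, collar); acc_a <- rbind(tip_all_a, collar)
  keep_ks <- keep_clear(knobs_s, FALSE, acc_h, acc_a)
  knobs_s <- knobs_s[keep_ks, , drop = FALSE]
  acc_h <- rbind(acc_h, knobs_s); acc_a <- rbind(acc_a, knobs_s)
  keep_km <- keep_clear(knobs_m, TRUE, acc_h, acc_a)
  knobs_m <- knobs_m[keep_km, , drop = FALSE]
  # a sleeve of three stationary-wall carbons grips the rod a third of
  # the way up, locking the rod's direction: without it the pocket acts
  # as a ball joint and the rod could swivel to follow a misplaced
  # mobile-wall oxygen
  perp1 <- u - sum(u * rod_d) * rod_d
  perp1 <- perp1 / sqrt(sum(perp1^2))
  perp2 <- crossprod_vec(rod_d, perp1)
  sleeve_c <- cage_center - 1.3 * u + 2.4 * rod_d
  sleeve <- t(vapply(c(60, 180, 300) * pi / 180, function(a) {
    sleeve_c + 3.55 * (cos(a) * perp1 + sin(a) * perp2)
  }, numeric(3)))
  lin_s <- anchor_for(tips_s, hs, hs_tbl)
  lin_m <- anchor_for(tips_m, hm, hm_tbl)
  collar <- rbind(collar, knobs_s, sleeve)
  col_s <- anchor_for(collar, hs, hs_tbl, taken = lin_s)
  peg_m <- anchor_for(knobs_m, hm, hm_tbl, taken = lin_m)
  r_c <- compose_euler(params$closure_angles)
  add_pseudo <- function(prot, resno_set, tips, in_m, atom, element) {
    out <- prot
    for (i in seq_along(resno_set)) {
      ca_row <- prot[prot$resno == resno_set[i] & prot$atom == "CA", ]
      og_holo <- tips[i, ]
      og_apo <- if (in_m) as.numeric(t(r_c) %*% og_holo) else og_holo
      new_row <- ca_row
      new_row$atom <- atom; new_row$element <- element
      new_row$mass <- element_mass(element)
      new_row$x <- og_apo[1]; new_row$y <- og_apo[2]; new_row$z <- og_apo[3]
      out <- bind_rows(out, new_row)
    }
    out
  }
  apo_prot <- add_pseudo(apo0$protein, lin_s, tips_s, FALSE, "OG", "O")
  apo_prot <- add_pseudo(apo_prot, lin_m, tips_m, TRUE, "OG", "O")
  apo_prot <- add_pseudo(apo_prot, col_s, collar, FALSE, "CB", "C")
  apo_prot <- add_pseudo(apo_prot, peg_m, knobs_m, TRUE, "CB", "C")
  apo_prot <- apo_prot[order(apo_prot$resno, apo_prot$atom != "CA"), ]
  apo_prot$serial <- seq_len(nrow(apo_prot))
  validate_protein(apo_prot)
  apo <- new_conformer(apo_prot, NULL, angles = euler_angles(0, 0, 0),
                       relaxed = TRUE, provenance = "synthetic apo")
  holo <- apply_hinge_rotation(apo, domains, params$closure_angles)
  holo$relaxed <- TRUE
  holo$angles <- params$closure_angles
  holo$provenance <- "synthetic holo"
  ligand <- make_cage_ligand(cage_center, u, rod_d,
                             n_atoms = params$ligand_atoms)
  lig_clash <- cpp_clash_cross(atom_xyz(holo$protein),
                               vdw_radius(holo$protein$element),
                               atom_xyz(ligand), vdw_radius(ligand$element), 1)
  if (lig_clash > 0.5) {
    P <- atom_xyz(holo$protein); L <- atom_xyz(ligand)
    dd <- sqrt(outer(rowSums(P^2), rowSums(L^2), "+") - 2 * P %*% t(L))
    worst <- which(dd == min(dd), arr.ind = TRUE)[1, ]
    abort(paste0("Ligand placement clashes with the closed form (gap ",
                 signif(gap, 3), " A; worst pair ",
                 holo$protein$atom[worst[1]], holo$protein$resno[worst[1]],
                 " - ligand atom ", worst[2], " at ",
                 signif(min(dd), 3), " A); adjust parameters."),
          class = "hingescan_error_synthetic")
  }
  apo$ligand <- ligand
  holo$ligand <- ligand
  list(apo = apo, holo = holo, hinge = hinge, domains = domains,
       params = params)
}

#' Simulate a multi-protein score table with known fitness weights
#'
#' Draws score rows (G_D, E_F, R_G) from documented uniform ranges, then
#' sets `srmsd = G_D*l1 + E_F*l2 + R_G^2*l3 + noise`. Used to exercise the
#' weight fitting and leave-one-group-out machinery against a known truth.
#'
#' @param n_groups Number of protein groups (>= 2).
#' @param rows_per_group Scored conformers per group.
#' @param true_lambda Length-3 generative weight vector for (G_D, E_F,
#'   R_G^2).
#' @param noise_sd Gaussian noise added to the response (Angstroms).
#' @param seed Integer seed.
#' @return A score-table tibble with columns `id`, `group`, `G_D`, `E_F`,
#'   `R_G`, `srmsd`.
#' @export
make_score_table <- function(n_groups = 5, rows_per_group = 40,
                             true_lambda = c(0.35, 0.066, 0.030),
                             noise_sd = 0.5, seed = 1L) {
  stopifnot(n_groups >= 2, length(true_lambda) == 3)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))
  n <- n_groups * rows_per_group
  tbl <- tibble(
    id = sprintf("conf%04d", seq_len(n)),
    group = rep(paste0("protein", seq_len(n_groups)), each = rows_per_group),
    G_D = runif(n, -25, -2),
    E_F = runif(n, -30, 60),
    R_G = runif(n, 12, 25)
  )
  x <- design_matrix(tbl)
  tbl$srmsd <- as.numeric(x %*% true_lambda) + rnorm(n, sd = noise_sd)
  tbl
}
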