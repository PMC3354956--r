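# Surrogate for the MD equilibration step: a hinge rotation leaves broken
# geometry at the L/M boundary (stretched virtual bonds, bent pseudo-angles)
# and often steric clashes between M and the rest of the system. Bounded
# steepest descent on a strain energy repairs exactly those defects without
# allowing substantial domain motion.

backbone_bonds <- function(protein, reference = protein) {
  # consecutive backbone atoms within and between residues; for C-alpha-only
  # chains this reduces to the CA(i)-CA(i+1) virtual bond (ideal 3.8 A)
  ideal <- c("N-CA" = 1.46, "CA-C" = 1.52, "C-N" = 1.33, "CA-CA" = 3.8)
  res <- unique(protein$resno)
  rows_of <- function(resno, atom) which(protein$resno == resno &
                                           protein$atom == atom)
  has_full_bb <- all(c("N", "C") %in% protein$atom)
  bonds <- list()
  for (i in seq_along(res)) {
    r <- res[i]
    if (has_full_bb) {
      n_i <- rows_of(r, "N"); ca_i <- rows_of(r, "CA"); c_i <- rows_of(r, "C")
      if (length(n_i) && length(ca_i))
        bonds[[length(bonds) + 1]] <- c(n_i[1], ca_i[1], ideal["N-CA"])
      if (length(ca_i) && length(c_i))
        bonds[[length(bonds) + 1]] <- c(ca_i[1], c_i[1], ideal["CA-C"])
      if (i < length(res) && res[i + 1] == r + 1L) {
        n_next <- rows_of(res[i + 1], "N")
        if (length(c_i) && length(n_next))
          bonds[[length(bonds) + 1]] <- c(c_i[1], n_next[1], ideal["C-N"])
      }
    } else if (i < length(res) && res[i + 1] == r + 1L) {
      ca_i <- rows_of(r, "CA"); ca_next <- rows_of(res[i + 1], "CA")
      if (length(ca_i) && length(ca_next))
        bonds[[length(bonds) + 1]] <- c(ca_i[1], ca_next[1], ideal["CA-CA"])
    }
  }
  # pseudo-side-chain atoms (the synthetic cleft's lining oxygens and
  # collar carbons) are triangulated against their own and the flanking
  # C-alphas so they move rigidly with their domain; the tether lengths
  # are the current ones, which rigid hinge rotations preserve
  og_rows <- which(!(protein$atom %in% c("N", "CA", "C", "O")))
  for (r in og_rows) {
    rn <- protein$resno[r]
    # the fourth anchor sits a helix turn away, off the local chain axis,
    # so the tether set is non-collinear and the atom cannot swing; rest
    # lengths are measured on the reference structure so the tethers are
    # elastic, never plastic, along a chain of relaxations
    fourth <- if (length(rows_of(rn + 4L, "CA"))) rn + 4L else rn - 4L
    for (anchor_res in c(rn, rn - 1L, rn + 1L, fourth)) {
      ca_r <- rows_of(anchor_res, "CA")
      if (length(ca_r)) {
        r0 <- sqrt(sum((as.numeric(reference[r, c("x", "y", "z")]) -
                          as.numeric(reference[ca_r[1], c("x", "y", "z")]))^2))
        bonds[[length(bonds) + 1]] <- c(ca_r[1], r, r0)
      }
    }
  }
  m <- do.call(rbind, bonds)
  if (is.null(m)) m <- matrix(numeric(0), 0, 3)
  list(idx = matrix(as.integer(m[, 1:2]), ncol = 2), r0 = as.numeric(m[, 3]))
}

ca_angle_triplets <- function(protein, reference) {
  # C-alpha pseudo-angle triplets over consecutive residues; target values
  # are taken from the reference (starting) structure
  ca_rows <- which(protein$atom == "CA")
  res <- protein$resno[ca_rows]
  keep <- which(diff(res, lag = 2) == 2L)
  if (!length(keep)) {
    return(list(idx = matrix(integer(0), 0, 3), t0 = numeric(0)))
  }
  idx <- cbind(ca_rows[keep], ca_rows[keep + 1L], ca_rows[keep + 2L])
  ref <- ca_xyz(reference$protein %||% reference)
  t0 <- vapply(seq_len(nrow(idx)), function(t) {
    rs <- protein$resno[idx[t, ]]
    p <- ref$xyz[match(rs, ref$resno), , drop = FALSE]
    if (anyNA(p)) return(NA_real_)
    u <- p[1, ] - p[2, ]; v <- p[3, ] - p[2, ]
    acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2)))))
  }, numeric(1))
  ok <- is.finite(t0)
  list(idx = idx[ok, , drop = FALSE], t0 = t0[ok])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

strain_terms <- function(conformer, reference, config) {
  protein <- conformer$protein
  ligand <- conformer$ligand
  ref_prot <- if (inherits(reference, "hinge_conformer")) reference$protein else reference
  bb <- if (nrow(ref_prot) == nrow(protein)) backbone_bonds(protein, ref_prot) else backbone_bonds(protein)
  ang <- ca_angle_triplets(protein, reference)
  n_prot <- nrow(protein)
  xyz <- atom_xyz(protein)
  rad <- vdw_radius(protein$element)
  resno <- as.integer(protein$resno)
  if (!is.null(ligand)) {
    xyz <- rbind(xyz, atom_xyz(ligand))
    rad <- c(rad, vdw_radius(ligand$element))
    resno <- c(resno, rep.int(-100000L, nrow(ligand)))
  }
  list(xyz = xyz, n_prot = n_prot, bonds = bb$idx - 1L, bond_r0 = bb$r0,
       angles = ang$idx - 1L, angle_t0 = ang$t0, rad = rad, resno = resno)
}

#' Strain energy of a conformer
#'
#' The objective the relaxer minimizes: harmonic terms on consecutive
#' backbone bond lengths (vs ideal lengths), harmonic C-alpha pseudo-angle
#' terms (vs the starting structure's values), and the quadratic-overlap
#' clash penalty, including protein-ligand clashes.
#'
#' @param conformer A conformer.
#' @param reference The starting conformer supplying the pseudo-angle
#'   targets; defaults to `conformer` itself (zero angle strain).
#' @param config An [hs_config()].
#' @return Strain energy (scalar, same units as the clash penalty).
#' @export
strain_energy <- function(conformer, reference = conformer,
                          config = hs_config()) {
  config <- as_config(config)
  tm <- strain_terms(conformer, reference, config)
  rl <- config$relax; st <- config$stability
  out <- cpp_strain_grad(tm$xyz, tm$n_prot, tm$bonds, tm$bond_r0, rl$bond_k,
                         tm$angles, tm$angle_t0, rl$angle_k, tm$rad,
                         tm$resno, st$clash_k, as.integer(st$min_seq_sep))
  out$energy
}

#' Relax a conformer by bounded steepest descent
#'
#' Adaptive-step steepest descent on [strain_energy()] over all protein
#' atom coordinates; the ligand moves as one rigid body (a translation and
#' small rotation per step) since its internal geometry is owned by the
#' docker. Descent is monotone: a step that would increase the strain is
#' shrunk, never accepted. Convergence is declared when the per-step energy
#' decrease falls below `tol`. The relaxation fails (converged = FALSE)
#' when `max_steps` is exhausted while still improving, when the energy
#' turns non-finite, or when any atom travels farther than
#' `max_displacement` from where it started — the relaxer's job is local
#' repair, not domain motion.
#'
#' @param conformer Conformer to relax.
#' @param domains Domain tibble (used only for provenance; the strain terms
#'   come from the chain itself).
#' @param reference Starting conformer supplying pseudo-angle targets.
#' @param config An [hs_config()]; see its `relax` section.
#' @return List with `conformer` (relaxed, `relaxed = TRUE` when converged)
#'   and `report`: a one-row tibble with `converged`, `steps_used`,
#'   `initial_strain`, `final_strain`, `max_atom_displacement`.
#' @export
relax <- function(conformer, domains = NULL, reference = conformer,
                  config = hs_config()) {
  config <- as_config(config)
  rl <- config$relax; st <- config$stability
  tm <- strain_terms(conformer, reference, config)
  if (!all(is.finite(tm$xyz))) {
    abort("Non-finite coordinates on entry to relax().",
          class = "hingescan_error_relax")
  }
  n_prot <- tm$n_prot
  n_all <- nrow(tm$xyz)
  has_lig <- n_all > n_prot
  xyz0 <- tm$xyz
  xyz <- tm$xyz
  eval_grad <- function(m) {
    cpp_strain_grad(m, n_prot, tm$bonds, tm$bond_r0, rl$bond_k, tm$angles,
                    tm$angle_t0, rl$angle_k, tm$rad, tm$resno, st$clash_k,
                    as.integer(st$min_seq_sep))
  }
  cur <- eval_grad(xyz)
  e0 <- cur$energy
  e <- e0
  step <- rl$step0
  steps_used <- 0L
  converged <- rl$max_steps == 0  # relaxation disabled: pass-through
  failed <- FALSE
  g_prev <- NULL
  xyz_prev <- NULL
  for (it in seq_len(rl$max_steps)) {
    g <- cur$grad
    if (has_lig) {
      # project the ligand gradient onto a rigid translation (rotation is
      # folded into the next re-docking; pure translation keeps descent
      # simple and monotone)
      gl <- g[(n_prot + 1):n_all, , drop = FALSE]
      gmean <- colMeans(gl)
      g[(n_prot + 1):n_all, ] <- matrix(gmean, nrow = n_all - n_prot,
                                        ncol = 3, byrow = TRUE)
    }
    gnorm <- sqrt(sum(g^2))
    if (gnorm < 1e-12) { converged <- TRUE; steps_used <- it - 1L; break }
    # Barzilai-Borwein adaptive step, safeguarded by monotone backtracking
    if (!is.null(g_prev)) {
      dx <- xyz - xyz_prev
      dg <- g - g_prev
      denom <- sum(dg * dg)
      if (denom > 0) {
        bb <- sum(dx * dg) / denom
        if (is.finite(bb) && bb > 0) step <- min(bb, 2)
      }
    }
    accepted <- FALSE
    for (try in 1:30) {
      cand <- xyz - step * g
      res <- eval_grad(cand)
      if (is.finite(res$energy) && res$energy <= e) { accepted <- TRUE; break }
      step <- step / 2
    }
    if (!accepted) { converged <- TRUE; steps_used <- it - 1L; break }
    decrease <- e - res$energy
    xyz_prev <- xyz
    g_prev <- g
    xyz <- cand
    cur <- res
    e <- res$energy
    steps_used <- it
    disp <- sqrt(max(rowSums((xyz - xyz0)^2)))
    if (disp > rl$max_displacement) { failed <- TRUE; break }
    if (!is.finite(e)) { failed <- TRUE; break }
    if (decrease < rl$tol) { converged <- TRUE; break }
  }
  if (failed) converged <- FALSE
  if (!failed && steps_used == rl$max_steps && !converged) converged <- FALSE
  max_disp <- sqrt(max(rowSums((xyz - xyz0)^2)))
  out <- conformer
  out$protein <- set_atom_xyz(out$protein, xyz[seq_len(n_prot), , drop = FALSE])
  if (has_lig) {
    out$ligand <- set_atom_xyz(out$ligand,
                               xyz[(n_prot + 1):n_all, , drop = FALSE])
  }
  out$relaxed <- isTRUE(converged)
  out$provenance <- paste0(conformer$provenance, " +relax(", steps_used, ")")
  report <- tibble(converged = converged, steps_used = steps_used,
                   initial_strain = e0, final_strain = e,
                   max_atom_displacement = max_disp)
  list(conformer = out, report = report)
}
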