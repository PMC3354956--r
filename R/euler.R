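# Euler convention used throughout: active rotations about space-fixed
# (extrinsic) axes through the standard-orientation origin, applied z first,
# then x, then y, so the composed operator is R = Ry(ty) %*% Rx(tx) %*% Rz(tz).
# Angles are degrees at every interface; tx is restricted to [-90, 90] by the
# y-x-z factorization branch so cell assignment is reproducible.

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

rot_x <- function(deg) {
  t <- deg2rad(deg); c <- cos(t); s <- sin(t)
  matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3)
}
rot_y <- function(deg) {
  t <- deg2rad(deg); c <- cos(t); s <- sin(t)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3)
}
rot_z <- function(deg) {
  t <- deg2rad(deg); c <- cos(t); s <- sin(t)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

#' Euler angles of a hinge rotation
#'
#' @param theta_z,theta_x,theta_y Rotation angles in degrees about the
#'   space-fixed z, x, and y axes, applied in that order.
#' @return A named numeric vector of class `euler_angles`.
#' @export
euler_angles <- function(theta_z = 0, theta_x = 0, theta_y = 0) {
  ang <- c(theta_z = as.numeric(theta_z), theta_x = as.numeric(theta_x),
           theta_y = as.numeric(theta_y))
  if (!all(is.finite(ang))) {
    abort("Euler angles must be finite.", class = "hingescan_error_euler")
  }
  # canonical range (-180, 180]
  ang <- ((ang + 180) %% 360) - 180
  ang[ang == -180] <- 180
  class(ang) <- c("euler_angles", "numeric")
  ang
}

#' @export
print.euler_angles <- function(x, ...) {
  cat(sprintf("<euler_angles> z=%.3f x=%.3f y=%.3f (deg)\n",
              x[["theta_z"]], x[["theta_x"]], x[["theta_y"]]))
  invisible(x)
}

#' Compose the hinge rotation matrix from Euler angles
#'
#' Returns the active rotation `Ry(theta_y) Rx(theta_x) Rz(theta_z)`:
#' space-fixed axes, z applied first, then x, then y.
#'
#' @param angles An [euler_angles()] vector (or anything coercible:
#'   a length-3 numeric `c(theta_z, theta_x, theta_y)`).
#' @return A 3x3 proper rotation matrix.
#' @examples
#' compose_euler(euler_angles(90, 0, 0)) %*% c(1, 0, 0)  # -> (0, 1, 0)
#' @export
compose_euler <- function(angles) {
  angles <- as_euler(angles)
  rot_y(angles[["theta_y"]]) %*% rot_x(angles[["theta_x"]]) %*%
    rot_z(angles[["theta_z"]])
}

as_euler <- function(angles) {
  if (inherits(angles, "euler_angles")) return(angles)
  stopifnot(is.numeric(angles), length(angles) == 3L)
  if (!is.null(names(angles)) &&
      all(c("theta_z", "theta_x", "theta_y") %in% names(angles))) {
    return(euler_angles(angles[["theta_z"]], angles[["theta_x"]],
                        angles[["theta_y"]]))
  }
  euler_angles(angles[1], angles[2], angles[3])
}

#' Factor a rotation matrix into hinge Euler angles
#'
#' Inverts [compose_euler()]: given a proper rotation `R`, finds angles such
#' that `Ry(theta_y) Rx(theta_x) Rz(theta_z) = R`, with `theta_x` in
#' [-90, 90]. Near gimbal lock (|cos theta_x| < 1e-8) the z/y split is
#' degenerate and is canonicalized with `theta_z = 0`.
#'
#' @param rotation 3x3 proper rotation matrix.
#' @return An [euler_angles()] vector.
#' @export
factor_euler <- function(rotation) {
  R <- as.matrix(rotation)
  stopifnot(identical(dim(R), c(3L, 3L)))
  sb <- -R[2, 3]
  sb <- max(-1, min(1, sb))
  tx <- asin(sb)
  if (abs(cos(tx)) < 1e-8) {
    # gimbal lock: only (theta_y -/+ theta_z) is determined; put it all in y
    tz <- 0
    ty <- if (sb > 0) atan2(R[1, 2], R[1, 1]) else atan2(-R[1, 2], R[1, 1])
  } else {
    tz <- atan2(R[2, 1], R[2, 2])
    ty <- atan2(R[1, 3], R[3, 3])
  }
  euler_angles(rad2deg(tz), rad2deg(tx), rad2deg(ty))
}

#' Rotate the mobile domain of a standard-orientation conformer
#'
#' Applies `compose_euler(angles)` about the origin to every atom of the
#' M-domain residues; S-domain atoms, linker atoms, and the ligand are left
#' untouched (the ligand stays stationary with respect to S). The input must
#' already be in standard orientation (linker center of mass at the origin).
#'
#' @param conformer A conformer (see [conformer()]) in standard orientation.
#' @param domains Domain tibble from [assign_domains()].
#' @param angles [euler_angles()] to apply.
#' @param tol Maximum allowed distance of the linker center of mass from the
#'   origin before the input is rejected (Angstroms).
#' @return A new conformer, flagged unrelaxed, with `angles` unset (use
#'   [decompose_angles()] after relaxation to measure where it landed).
#' @export
apply_hinge_rotation <- function(conformer, domains, angles, tol = 0.5) {
  stopifnot(inherits(conformer, "hinge_conformer"))
  xl <- center_of_mass(conformer$protein, domain_residues(domains, "L"))
  if (sqrt(sum(xl^2)) > tol) {
    abort(paste0("Conformer is not in standard orientation: |X_L| = ",
                 signif(sqrt(sum(xl^2)), 3), " A."),
          class = "hingescan_error_orientation")
  }
  R <- compose_euler(angles)
  prot <- conformer$protein
  m_res <- domain_residues(domains, "M")
  idx <- prot$resno %in% m_res
  xyz <- atom_xyz(prot[idx, , drop = FALSE])
  prot[idx, c("x", "y", "z")] <- as.data.frame(xyz %*% t(R))
  new_conformer(prot, conformer$ligand, angles = NULL, relaxed = FALSE,
                provenance = paste0(conformer$provenance, " +rot(",
                                    paste(round(as_euler(angles), 2),
                                          collapse = ","), ")"))
}

#' Optimal rigid superposition (Kabsch)
#'
#' Least-squares optimal proper rotation and translation mapping `mobile`
#' onto `target`, with the residual RMSD.
#'
#' @param mobile,target n x 3 coordinate matrices with matched rows (n >= 3,
#'   non-collinear).
#' @return List with `transform` (a [rigid_transform()]) and `rmsd`
#'   (Angstroms).
#' @export
kabsch_superpose <- function(mobile, target) {
  mobile <- matrix(as.numeric(mobile), ncol = 3)
  target <- matrix(as.numeric(target), ncol = 3)
  if (nrow(mobile) != nrow(target)) {
    abort("mobile and target must have the same number of points.",
          class = "hingescan_error_superpose")
  }
  if (nrow(mobile) < 3) {
    abort("Superposition needs at least 3 points.",
          class = "hingescan_error_superpose")
  }
  cm <- colMeans(mobile)
  ct <- colMeans(target)
  A <- sweep(mobile, 2, cm)
  B <- sweep(target, 2, ct)
  if (svd(A)$d[2] < 1e-9 && svd(B)$d[2] < 1e-9) {
    abort("Degenerate (collinear) point sets in superposition.",
          class = "hingescan_error_superpose")
  }
  H <- crossprod(A, B)            # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  t_vec <- ct - as.numeric(R %*% cm)
  moved <- sweep(mobile %*% t(R), 2, -t_vec)
  rmsd <- sqrt(mean(rowSums((moved - target)^2)))
  list(transform = rigid_transform(R, t_vec), rmsd = rmsd)
}

#' Angular position of the mobile domain relative to a starting structure
#'
#' Measures where a generated conformer sits in (theta_y, theta_x, theta_z)
#' space: the generated structure is first aligned onto the starting
#' structure over the S-domain C-alpha atoms, then the best rotation about
#' the standard-orientation origin carrying the starting M-domain C-alpha
#' set onto the aligned generated one is found and factored as
#' `Ry Rx Rz`. Relaxation moves this measurement away from the angles that
#' were applied; that change is the drift.
#'
#' @param generated,start Conformers sharing residue numbering over S and M;
#'   `start` must be in standard orientation.
#' @param domains Domain tibble from [assign_domains()].
#' @return An [euler_angles()] vector.
#' @export
decompose_angles <- function(generated, start, domains) {
  s_res <- domain_residues(domains, "S")
  m_res <- domain_residues(domains, "M")
  gs <- ca_xyz(generated$protein, s_res)
  ss <- ca_xyz(start$protein, s_res)
  shared_s <- intersect(gs$resno, ss$resno)
  fit <- kabsch_superpose(gs$xyz[match(shared_s, gs$resno), , drop = FALSE],
                          ss$xyz[match(shared_s, ss$resno), , drop = FALSE])
  gm <- ca_xyz(generated$protein, m_res)
  sm <- ca_xyz(start$protein, m_res)
  shared_m <- intersect(gm$resno, sm$resno)
  if (length(shared_m) < 3) {
    abort("Fewer than 3 shared M-domain C-alpha atoms.",
          class = "hingescan_error_superpose")
  }
  P <- sm$xyz[match(shared_m, sm$resno), , drop = FALSE]       # start M
  Q <- apply_transform(gm$xyz[match(shared_m, gm$resno), , drop = FALSE],
                       fit$transform)                          # aligned generated M
  # best rotation about the origin (no centroid removal): constrained Kabsch
  H <- crossprod(P, Q)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  factor_euler(R)
}

#' Static RMSD (sRMSD) between two conformers
#'
#' The figure of merit for hinge-bending predictions: the RMSD over the
#' mobile-domain C-alpha atoms after the stationary-domain C-alpha atoms
#' have been optimally superposed. No further fitting is applied to M, so
#' sRMSD measures how far the mobile domain is from its position in the
#' reference.
#'
#' @param conformer,reference Conformers (or bare protein atom tibbles)
#'   sharing residue numbering; the intersection of residue numbers is used.
#' @param domains Domain tibble from [assign_domains()], or any tibble with
#'   `resno`/`domain` columns (for discontinuous S/M definitions).
#' @return sRMSD in Angstroms, with attributes `n_s` and `n_m` giving the
#'   atom counts used.
#' @export
srmsd <- function(conformer, reference, domains) {
  prot_a <- if (inherits(conformer, "hinge_conformer")) conformer$protein else conformer
  prot_b <- if (inherits(reference, "hinge_conformer")) reference$protein else reference
  s_res <- domain_residues(domains, "S")
  m_res <- domain_residues(domains, "M")
  as_ca <- ca_xyz(prot_a, s_res); bs_ca <- ca_xyz(prot_b, s_res)
  shared_s <- intersect(as_ca$resno, bs_ca$resno)
  if (length(shared_s) < 3) {
    abort("Fewer than 3 shared S-domain C-alpha atoms.",
          class = "hingescan_error_superpose")
  }
  fit <- kabsch_superpose(
    as_ca$xyz[match(shared_s, as_ca$resno), , drop = FALSE],
    bs_ca$xyz[match(shared_s, bs_ca$resno), , drop = FALSE])
  am_ca <- ca_xyz(prot_a, m_res); bm_ca <- ca_xyz(prot_b, m_res)
  shared_m <- intersect(am_ca$resno, bm_ca$resno)
  if (!length(shared_m)) {
    abort("No shared M-domain C-alpha atoms.",
          class = "hingescan_error_superpose")
  }
  A <- apply_transform(am_ca$xyz[match(shared_m, am_ca$resno), , drop = FALSE],
                       fit$transform)
  B <- bm_ca$xyz[match(shared_m, bm_ca$resno), , drop = FALSE]
  out <- sqrt(mean(rowSums((A - B)^2)))
  attr(out, "n_s") <- length(shared_s)
  attr(out, "n_m") <- length(shared_m)
  out
}
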