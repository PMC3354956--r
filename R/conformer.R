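#' Conformer: a protein pose plus its docked ligand
#'
#' A conformer bundles a protein atom tibble, a ligand atom tibble, the
#' Euler angles at which its mobile domain sits relative to the starting
#' structure (as measured by [decompose_angles()], `NULL` until measured),
#' an optional score row, and free-text provenance.
#'
#' @param protein Protein atom tibble (see [read_pdb()]).
#' @param ligand Ligand atom tibble (see [read_ligand()]), or `NULL`.
#' @param angles [euler_angles()] or `NULL` if not yet measured.
#' @param relaxed Logical: has this conformer been through [relax()]?
#' @param scores Optional one-row tibble with `G_D`, `E_F`, `R_G`.
#' @param provenance Free text describing how the conformer was made.
#' @return An object of class `hinge_conformer`.
#' @export
conformer <- function(protein, ligand = NULL, angles = NULL, relaxed = FALSE,
                      scores = NULL, provenance = "user") {
  validate_protein(protein)
  if (!is.null(ligand)) validate_ligand(ligand)
  new_conformer(protein, ligand, angles, relaxed, scores, provenance)
}

new_conformer <- function(protein, ligand, angles = NULL, relaxed = FALSE,
                          scores = NULL, provenance = "") {
  structure(list(protein = protein, ligand = ligand,
                 angles = if (!is.null(angles)) as_euler(angles),
                 relaxed = isTRUE(relaxed), scores = scores,
                 provenance = provenance),
            class = "hinge_conformer")
}

#' @export
print.hinge_conformer <- function(x, ...) {
  n_res <- length(unique(x$protein$resno))
  cat("<hinge_conformer> ", n_res, " residues, ", nrow(x$protein), " atoms",
      if (!is.null(x$ligand)) paste0(", ligand ", nrow(x$ligand), " atoms"),
      if (x$relaxed) ", relaxed" else ", unrelaxed", "\n", sep = "")
  if (!is.null(x$angles)) {
    cat(sprintf("  angles: z=%.2f x=%.2f y=%.2f (deg)\n",
                x$angles[["theta_z"]], x$angles[["theta_x"]],
                x$angles[["theta_y"]]))
  }
  if (!is.null(x$scores)) {
    cat(sprintf("  scores: G_D=%.3f E_F=%.3f R_G=%.3f\n",
                x$scores$G_D, x$scores$E_F, x$scores$R_G))
  }
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}
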