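# Atom tables: every structure in hingescan is a tibble with one row per
# atom and columns serial, atom, resid, resno, element, mass, x, y, z,
# chain, record. Proteins carry record == "ATOM", ligands "HETATM".

# monoisotopic-ish standard atomic weights (Da) for the elements seen in
# routine PDB files; lookup is by upper-cased element symbol
.element_masses <- c(
  H = 1.008, D = 2.014, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, SE = 78.971, F = 18.998, CL = 35.45, BR = 79.904, I = 126.904,
  FE = 55.845, ZN = 65.38, MG = 24.305, MN = 54.938, CA = 40.078,
  "NA" = 22.990, K = 39.098, CU = 63.546, NI = 58.693, CO = 58.933
)

element_mass <- function(element) {
  key <- toupper(trimws(element))
  m <- .element_masses[key]
  if (anyNA(m)) {
    bad <- unique(key[is.na(m)])
    abort(paste0("Unknown element symbol(s): ", paste(bad, collapse = ", ")),
          class = "hingescan_error_element")
  }
  unname(m)
}

# element symbol from a PDB atom name when the element column is blank
guess_element <- function(atom_name) {
  nm <- toupper(trimws(atom_name))
  two <- substr(nm, 1, 2)
  ifelse(two %in% names(.element_masses) & !(substr(nm, 1, 1) %in%
           c("C", "N", "O", "H", "S", "P")),
         two, substr(nm, 1, 1))
}

new_atom_tbl <- function(serial, atom, resid, resno, element, x, y, z,
                         chain = "A", record = "ATOM") {
  tibble(
    serial = as.integer(serial), atom = as.character(atom),
    resid = as.character(resid), resno = as.integer(resno),
    element = toupper(as.character(element)),
    mass = element_mass(element),
    x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
    chain = as.character(chain), record = as.character(record)
  )
}

validate_protein <- function(protein) {
  stopifnot(is.data.frame(protein))
  need <- c("serial", "atom", "resno", "element", "mass", "x", "y", "z")
  missing_cols <- setdiff(need, names(protein))
  if (length(missing_cols)) {
    abort(paste0("Atom table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "hingescan_error_protein")
  }
  if (!all(is.finite(as.matrix(protein[, c("x", "y", "z")])))) {
    abort("Atom table contains non-finite coordinates.",
          class = "hingescan_error_protein")
  }
  ca <- protein[protein$atom == "CA", ]
  n_ca <- table(factor(ca$resno, levels = unique(protein$resno)))
  if (any(n_ca != 1L)) {
    bad <- names(n_ca)[n_ca != 1L]
    abort(paste0("Residue(s) without exactly one CA atom: ",
                 paste(head(bad, 5), collapse = ", ")),
          class = "hingescan_error_protein")
  }
  if (is.unsorted(unique(protein$resno), strictly = TRUE)) {
    abort("Residue numbers must be strictly increasing along the chain.",
          class = "hingescan_error_protein")
  }
  invisible(protein)
}

validate_ligand <- function(ligand) {
  stopifnot(is.data.frame(ligand))
  m <- as.matrix(ligand[, c("x", "y", "z")])
  if (nrow(m) < 3) {
    abort("Ligand needs at least 3 atoms for a well-defined rigid pose.",
          class = "hingescan_error_ligand")
  }
  if (!all(is.finite(m))) {
    abort("Ligand contains non-finite coordinates.",
          class = "hingescan_error_ligand")
  }
  s <- svd(scale(m, scale = FALSE))$d
  if (s[2] < 1e-6) {
    abort("Ligand atoms are collinear; rigid pose is degenerate.",
          class = "hingescan_error_ligand")
  }
  invisible(ligand)
}

#' Read a single protein chain from a PDB file
#'
#' Reads ATOM records for one chain of a PDB file into an atom tibble.
#' Everything the search cannot handle is dropped on ingestion: HETATM
#' records (ligands, metals, ions), waters, and all other chains. Alternate
#' locations are resolved to the highest-occupancy conformer (ties broken
#' alphabetically by altloc id). Files with insertion codes are rejected
#' rather than silently renumbered.
#'
#' @param path Path to a PDB file.
#' @param chain Chain identifier, or `"first"` (default) for the first
#'   chain appearing in the file.
#' @return A tibble with one row per atom: `serial`, `atom`, `resid`,
#'   `resno`, `element`, `mass` (Da), `x`, `y`, `z` (Angstroms), `chain`,
#'   `record`.
#' @examples
#' pdb <- tempfile(fileext = ".pdb")
#' writeLines(c(
#'   "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
#'   "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
#'   "END"), pdb)
#' read_pdb(pdb)
#' @export
read_pdb <- function(path, chain = "first") {
  if (!file.exists(path)) {
    abort(paste0("PDB file not found: ", path),
          class = "hingescan_error_io")
  }
  pdb <- suppressWarnings(bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE))
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (!nrow(at)) {
    abort(paste0("No ATOM records in ", path),
          class = "hingescan_error_io")
  }
  if (identical(chain, "first")) chain <- at$chain[1]
  at <- at[at$chain %in% chain, , drop = FALSE]
  if (!nrow(at)) {
    abort(paste0("No ATOM records for chain ", chain, " in ", path),
          class = "hingescan_error_io")
  }
  if (any(nzchar(trimws(at$insert)) & !is.na(at$insert))) {
    abort("Insertion codes are not supported; renumber the chain first.",
          class = "hingescan_error_io")
  }
  # altloc: keep highest occupancy, then alphabetical altloc id
  alt <- ifelse(is.na(at$alt), "", at$alt)
  if (any(nzchar(alt))) {
    occ <- ifelse(is.na(at$o), 1, at$o)
    key <- paste(at$resno, at$elety)
    ord <- order(key, -occ, alt)
    at <- at[ord, , drop = FALSE]
    at <- at[!duplicated(paste(at$resno, at$elety)), , drop = FALSE]
    at <- at[order(at$resno, at$eleno), , drop = FALSE]
  }
  element <- trimws(at$elesy)
  blank <- !nzchar(element) | is.na(element)
  element[blank] <- guess_element(at$elety[blank])
  protein <- new_atom_tbl(
    serial = at$eleno, atom = trimws(at$elety), resid = trimws(at$resid),
    resno = at$resno, element = element,
    x = at$x, y = at$y, z = at$z, chain = at$chain, record = "ATOM"
  )
  validate_protein(protein)
  protein
}

#' Read a small-molecule ligand from a PDB file
#'
#' Accepts either HETATM or ATOM records (whichever the file uses); all
#' records become `record = "HETATM"` rows so the ligand is written back as
#' heteroatoms.
#'
#' @inheritParams read_pdb
#' @return An atom tibble (see [read_pdb()]) with `record = "HETATM"`.
#' @export
read_ligand <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Ligand PDB file not found: ", path),
          class = "hingescan_error_io")
  }
  pdb <- suppressWarnings(bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE))
  at <- pdb$atom
  if (!nrow(at)) {
    abort(paste0("No atom records in ", path), class = "hingescan_error_io")
  }
  element <- trimws(at$elesy)
  blank <- !nzchar(element) | is.na(element)
  element[blank] <- guess_element(at$elety[blank])
  ligand <- new_atom_tbl(
    serial = at$eleno, atom = trimws(at$elety), resid = trimws(at$resid),
    resno = at$resno, element = element,
    x = at$x, y = at$y, z = at$z,
    chain = ifelse(is.na(at$chain), "L", at$chain), record = "HETATM"
  )
  validate_ligand(ligand)
  ligand
}

#' Write protein (and optionally ligand) coordinates to a PDB file
#'
#' Protein atoms are written as ATOM records; ligand atoms, if given, are
#' appended after the protein as HETATM records. Coordinates round-trip
#' through the fixed-width PDB format to about 1e-3 Angstroms; coordinates
#' that do not fit the 8.3 field (|value| >= 10000) raise an error.
#'
#' @param protein Protein atom tibble (see [read_pdb()]).
#' @param path Output file path.
#' @param ligand Optional ligand atom tibble appended after the protein.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(protein, path, ligand = NULL) {
  validate_protein(protein)
  all_xyz <- as.matrix(protein[, c("x", "y", "z")])
  if (!is.null(ligand)) all_xyz <- rbind(all_xyz, as.matrix(ligand[, c("x", "y", "z")]))
  if (max(abs(all_xyz)) >= 1e4) {
    abort("Coordinates exceed the PDB fixed-width field (|x| >= 10000 A).",
          class = "hingescan_error_io")
  }
  fmt <- function(tbl, record, serial0 = 0L) {
    sprintf("%-6s%5d %s%-3s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            record, serial0 + seq_len(nrow(tbl)),
            ifelse(nchar(tbl$atom) >= 4, "", " "),
            ifelse(nchar(tbl$atom) >= 4, tbl$atom, sprintf("%-3s", tbl$atom)),
            substr(ifelse(nzchar(tbl$resid), tbl$resid, "UNK"), 1, 3),
            substr(tbl$chain, 1, 1), tbl$resno,
            tbl$x, tbl$y, tbl$z, 1, 0, substr(tbl$element, 1, 2))
  }
  lines <- fmt(protein, "ATOM")
  if (!is.null(ligand)) {
    validate_ligand(ligand)
    lines <- c(lines, fmt(ligand, "HETATM", serial0 = nrow(protein)))
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

# coordinate matrix helpers
atom_xyz <- function(tbl) as.matrix(tbl[, c("x", "y", "z")])

set_atom_xyz <- function(tbl, m) {
  tbl$x <- m[, 1]; tbl$y <- m[, 2]; tbl$z <- m[, 3]
  tbl
}

ca_xyz <- function(protein, resno = NULL) {
  ca <- protein[protein$atom == "CA", ]
  if (!is.null(resno)) ca <- ca[ca$resno %in% resno, ]
  ca <- ca[order(ca$resno), ]
  list(xyz = atom_xyz(ca), resno = ca$resno)
}
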