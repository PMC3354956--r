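#' Hinge specification
#'
#' A hinge is one to three runs of consecutive residue numbers — the linker
#' (L) residues of each hinge strand. `hinge_spec()` accepts either a
#' character shorthand like `"88-89,181-182"` or a list of integer vectors.
#'
#' @param x Character scalar (`"88-89,181-182"`), or a list of integer
#'   vectors, one per strand, each a run of consecutive residue numbers.
#' @return An object of class `hinge_spec`: a list of integer vectors.
#' @examples
#' hinge_spec("88-89,181-182")
#' hinge_spec(list(50:51))
#' @export
hinge_spec <- function(x) {
  if (inherits(x, "hinge_spec")) return(x)
  if (is.character(x) && length(x) == 1L) {
    parts <- strsplit(x, ",", fixed = TRUE)[[1]]
    runs <- lapply(parts, function(p) {
      p <- trimws(p)
      if (grepl("^-?[0-9]+--?[0-9]+$", p)) {
        ab <- as.integer(strsplit(sub("^(-?[0-9]+)-", "\\1 ", p), " ")[[1]])
        seq.int(ab[1], ab[2])
      } else if (grepl("^-?[0-9]+$", p)) {
        as.integer(p)
      } else {
        abort(paste0("Cannot parse hinge run: '", p, "'"),
              class = "hingescan_error_hinge")
      }
    })
  } else if (is.list(x)) {
    runs <- lapply(x, function(r) as.integer(r))
  } else if (is.numeric(x)) {
    runs <- list(as.integer(x))
  } else {
    abort("hinge_spec takes a string like '88-89,181-182' or a list of runs.",
          class = "hingescan_error_hinge")
  }
  if (length(runs) < 1L || length(runs) > 3L) {
    abort("A hinge has one to three strands.", class = "hingescan_error_hinge")
  }
  for (r in runs) {
    if (!length(r) || any(diff(r) != 1L)) {
      abort("Each hinge strand must be a non-empty run of consecutive residues.",
            class = "hingescan_error_hinge")
    }
  }
  all_res <- unlist(runs)
  if (anyDuplicated(all_res)) {
    abort("Hinge strands must be disjoint.", class = "hingescan_error_hinge")
  }
  structure(runs[order(map_dbl(runs, min))], class = "hinge_spec")
}

#' @export
print.hinge_spec <- function(x, ...) {
  cat("<hinge_spec> ",
      paste(vapply(x, function(r) paste0(min(r), "-", max(r)), ""),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Assign residues to stationary (S), mobile (M), and linker (L) domains
#'
#' Residues from the N-terminus up to the first hinge strand belong to the
#' stationary domain S; residues between the first and second strand to the
#' mobile domain M; after the second strand membership alternates back to S,
#' and so on for a third strand. The hinge residues themselves form L.
#'
#' @param protein Protein atom tibble (see [read_pdb()]).
#' @param hinge A [hinge_spec()] (or anything it accepts).
#' @return A tibble with columns `resno` and `domain` (factor `"S"`, `"M"`,
#'   `"L"`) covering every polymer residue, plus attribute-free access via
#'   [domain_residues()].
#' @examples
#' # see vignette for an end-to-end example on a synthetic dumbbell
#' @export
assign_domains <- function(protein, hinge) {
  hinge <- hinge_spec(hinge)
  resno <- unique(protein$resno[protein$record == "ATOM"])
  hinge_res <- unlist(hinge)
  if (!all(hinge_res %in% resno)) {
    missing_res <- setdiff(hinge_res, resno)
    abort(paste0("Hinge residue(s) absent from protein: ",
                 paste(missing_res, collapse = ", ")),
          class = "hingescan_error_hinge")
  }
  domain <- character(length(resno))
  domain[resno %in% hinge_res] <- "L"
  # alternate S, M, S, M ... in the gaps between (and around) the strands
  bounds <- c(-Inf, map_dbl(hinge, min), Inf)
  labels <- rep(c("S", "M"), length.out = length(hinge) + 1L)
  for (i in seq_along(labels)) {
    lo <- bounds[i]
    hi_strand <- if (i <= length(hinge)) hinge[[i]] else NULL
    in_gap <- !(resno %in% hinge_res) &
      resno > (if (is.infinite(lo)) -Inf else max(hinge[[i - 1L]])) &
      (if (is.null(hi_strand)) TRUE else resno < min(hi_strand))
    if (i == 1L) {
      in_gap <- !(resno %in% hinge_res) & resno < min(hinge[[1L]])
    }
    domain[in_gap] <- labels[i]
  }
  if (!any(domain == "S") || !any(domain == "M")) {
    abort("Hinge placement leaves S or M empty.",
          class = "hingescan_error_hinge")
  }
  tibble(resno = resno, domain = factor(domain, levels = c("S", "M", "L")))
}

#' Residue numbers of one domain
#'
#' @param domains Tibble from [assign_domains()], or an explicit tibble with
#'   `resno` and `domain` columns (useful for discontinuous domains such as
#'   a kinase CORE that a hinge run cannot express).
#' @param which One of `"S"`, `"M"`, `"L"`.
#' @return Integer vector of residue numbers.
#' @export
domain_residues <- function(domains, which) {
  stopifnot(which %in% c("S", "M", "L"))
  domains$resno[domains$domain == which]
}

#' Mass-weighted center of mass of a residue set
#'
#' By default the center of mass is mass-weighted over all atoms of the
#' listed residues, with standard atomic masses by element. Set
#' `mode = "calpha"` for the unweighted centroid of the C-alpha atoms, a
#' convention sometimes preferred for coarse-grained comparisons.
#'
#' @param protein Protein atom tibble.
#' @param residues Integer vector of residue numbers (default: all).
#' @param mode `"mass"` (all atoms, mass-weighted; default) or `"calpha"`.
#' @return Numeric length-3 vector (Angstroms).
#' @export
center_of_mass <- function(protein, residues = NULL, mode = c("mass", "calpha")) {
  mode <- match.arg(mode)
  tbl <- protein
  if (!is.null(residues)) tbl <- tbl[tbl$resno %in% residues, ]
  if (mode == "calpha") tbl <- tbl[tbl$atom == "CA", ]
  if (!nrow(tbl)) {
    abort("Empty residue set for center_of_mass.",
          class = "hingescan_error_domains")
  }
  w <- if (mode == "mass") tbl$mass else rep(1, nrow(tbl))
  as.numeric(crossprod(atom_xyz(tbl), w) / sum(w))
}

#' Place a structure in standard orientation
#'
#' The search convention: the linker center of mass X_L sits at the origin,
#' the mobile-domain center X_M lies on the +z axis, and the stationary
#' center X_S lies in the y < 0 half of the yz plane. All rotations of the
#' M domain are then taken about the origin. The same rigid map is applied
#' to the ligand, so protein-ligand geometry is untouched.
#'
#' @param protein Protein atom tibble.
#' @param domains Domain tibble from [assign_domains()].
#' @param ligand Optional ligand atom tibble, transformed identically.
#' @param com_mode Passed to [center_of_mass()].
#' @return A list with `protein`, `ligand` (or `NULL`) and the
#'   [rigid_transform()] that was applied.
#' @export
standard_orientation <- function(protein, domains, ligand = NULL,
                                 com_mode = "mass") {
  xs <- center_of_mass(protein, domain_residues(domains, "S"), com_mode)
  xm <- center_of_mass(protein, domain_residues(domains, "M"), com_mode)
  xl <- center_of_mass(protein, domain_residues(domains, "L"), com_mode)
  vm <- xm - xl
  vs <- xs - xl
  cr <- crossprod_vec(vm, vs)
  if (sqrt(sum(vm^2)) < 1e-9 || sqrt(sum(cr^2)) / sqrt(sum(vm^2)) < 1e-9) {
    abort("Domain centers of mass are collinear; standard orientation undefined.",
          class = "hingescan_error_degenerate")
  }
  ez <- vm / sqrt(sum(vm^2))
  # x axis normal to the (vm, vs) plane, oriented so that vs ends up at y < 0
  ex <- cr / sqrt(sum(cr^2))
  ey <- crossprod_vec(ez, ex)
  if (sum(vs * ey) > 0) {
    ex <- -ex
    ey <- -ey
  }
  rot <- rbind(ex, ey, ez)
  dimnames(rot) <- NULL
  tf <- rigid_transform(rot, as.numeric(-rot %*% xl))
  out_protein <- apply_transform(protein, tf)
  out_ligand <- if (!is.null(ligand)) apply_transform(ligand, tf) else NULL
  list(protein = out_protein, ligand = out_ligand, transform = tf)
}

crossprod_vec <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
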