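#' Search configuration
#'
#' One place for every tunable of the pipeline. Call with no arguments for
#' the documented defaults; pass named values (possibly nested lists) to
#' override, or `yaml` to load overrides from a YAML file.
#'
#' Sections:
#' \describe{
#'   \item{dock}{Surrogate rigid docker. `grid_spacing` (A, translation grid),
#'     `pad` (A added around the receptor bounding box), `n_orientations`
#'     (fixed icosahedral orientation set, 60), `top_k` poses refined by
#'     local descent, `eps` (6-12 well depth), `polar_eps`/`polar_r0`/
#'     `polar_sigma` (gaussian polar attraction between N/O pairs),
#'     `soft_frac` (fraction of the contact distance below which the 6-12
#'     term is linearized), `cutoff` (A), `jitter_sd` (A, optional seeded
#'     pose jitter before refinement; 0 = fully deterministic).}
#'   \item{stability}{Clash penalty + bounded native-contact reward:
#'     `clash_k` (energy/A^2), `min_seq_sep` (residue separation below which
#'     pairs are bonded, not clashes), `contact_lo`/`contact_hi` (A, contact
#'     shell for C-alpha pairs), `contact_cap` (max counted contacts per
#'     residue), `contact_w` (reward per counted contact).}
#'   \item{relax}{Steepest-descent relaxation: `max_steps`, `tol` (energy
#'     decrease per step at which descent stops), `max_displacement` (A; a
#'     relaxation that moves any atom farther than this is declared failed —
#'     the relaxer repairs local strain, it must not produce domain
#'     motions), `bond_k`, `angle_k` (harmonic constants), `step0` (initial
#'     step size).}
#'   \item{grid}{Angular cell grid: `spacing` (deg) and per-axis ranges
#'     `range_y`, `range_x`, `range_z` (deg). The x range is asymmetric:
#'     positive theta_x closes the cleft in standard orientation.}
#'   \item{lambda}{Fitness weights for (G_D, E_F, R_G^2). Defaults are on
#'     the surrogate scorers' own scales (see vignette); they are not
#'     comparable to weights trained against physical docking/stability
#'     energies.}
#'   \item{com_mode}{`"mass"` or `"calpha"` for centers of mass.}
#'   \item{seed}{Master seed; per-cell seeds are derived from it.}
#'   \item{max_sweeps}{Cap on full line-search axis cycles.}
#' }
#'
#' @param ... Named overrides, e.g. `dock = list(grid_spacing = 2)`.
#' @param yaml Optional path to a YAML file of overrides (applied before
#'   `...`).
#' @return A nested list of class `hs_config`.
#' @export
hs_config <- function(..., yaml = NULL) {
  cfg <- list(
    dock = list(
      grid_spacing = 1, pad = 5, n_orientations = 60, top_k = 10,
      eps = 0.05, rep_eps = 0.05, polar_eps = 2.5, polar_r0 = 2.9,
      polar_sigma = 0.8,
      soft_frac = 0.7, cutoff = 8, jitter_sd = 0
    ),
    stability = list(
      clash_k = 10, min_seq_sep = 2, contact_lo = 4.5, contact_hi = 8,
      contact_cap = 6, contact_w = 0.2
    ),
    relax = list(
      max_steps = 3000, tol = 1e-6, max_displacement = 5,
      bond_k = 100, angle_k = 20, step0 = 1e-3
    ),
    grid = list(
      spacing = 15, range_y = c(-80, 80), range_x = c(-20, 80),
      range_z = c(-80, 80)
    ),
    lambda = c(G_D = 1, E_F = 1, R_G2 = 0.002),
    scorer = NULL,
    com_mode = "mass",
    seed = 1L,
    max_sweeps = 6L,
    axis_order = c("theta_y", "theta_x", "theta_z")
  )
  if (!is.null(yaml)) cfg <- modify_config(cfg, yaml::read_yaml(yaml))
  cfg <- modify_config(cfg, list(...))
  structure(cfg, class = "hs_config")
}

modify_config <- function(cfg, over) {
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(cfg[[nm]])) {
      cfg[[nm]] <- utils::modifyList(cfg[[nm]], over[[nm]])
    } else {
      cfg[[nm]] <- over[[nm]]
    }
  }
  cfg
}

as_config <- function(config) {
  if (is.null(config)) return(hs_config())
  if (inherits(config, "hs_config")) return(config)
  do.call(hs_config, config)
}

# van der Waals radii (A) by element for clash/docking terms
.vdw_radii <- c(
  H = 1.20, D = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
  F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90, FE = 1.50,
  ZN = 1.39, MG = 1.73, MN = 1.50, CA = 1.70, "NA" = 2.27, K = 2.75,
  CU = 1.40, NI = 1.63, CO = 1.50
)

vdw_radius <- function(element) {
  r <- .vdw_radii[toupper(trimws(element))]
  r[is.na(r)] <- 1.7
  unname(r)
}

is_polar_element <- function(element) {
  toupper(trimws(element)) %in% c("N", "O")
}

# derive a reproducible per-cell seed (< 2^31) from the master seed
cell_seed <- function(master, cell) {
  v <- c(as.integer(master), as.integer(round(cell)))
  h <- 0
  for (x in v) h <- (h * 131071 + (x + 360)) %% 2147483629
  as.integer(h)
}
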