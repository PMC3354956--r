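# Shared fixtures, built once per test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

# the default synthetic open/closed dumbbell pair
dumbbell_fixture <- function() {
  if (is.null(.fixture_env$pair)) {
    .fixture_env$pair <- make_open_closed_pair(dumbbell_params())
  }
  .fixture_env$pair
}

# end-to-end exploration of the dumbbell; shared by the recovery and
# search-bookkeeping tests
explore_fixture <- function() {
  if (is.null(.fixture_env$explore)) {
    pair <- dumbbell_fixture()
    .fixture_env$explore <- suppressMessages(
      explore(pair$apo$protein, pair$apo$ligand, pair$hinge, hs_config())
    )
  }
  .fixture_env$explore
}

# minimal hand-written PDB text: one chain, CA-only unless atoms given
write_pdb_text <- function(path, lines) {
  writeLines(c(lines, "END"), path)
  path
}

pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                          occ = 1, b = 0, element = "C", record = "ATOM",
                          altloc = " ") {
  sprintf("%-6s%5d  %-3s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name, altloc, resname, chain, resno, x, y, z,
          occ, b, element)
}

# a tiny 3-residue CA-only protein tibble built through the public reader
tiny_protein <- function() {
  path <- tempfile(fileext = ".pdb")
  write_pdb_text(path, c(
    pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CA", "ALA", "A", 2, 3.8, 0, 0),
    pdb_atom_line(3, "CA", "ALA", "A", 3, 7.6, 0.5, 0)
  ))
  read_pdb(path)
}

# analytic scorer: separable quadratic fitness in the decomposed angles,
# no docking involved (G_D carries the value; E_F and R_G are inert)
quadratic_scorer <- function(conformer, ligand, config, seed) {
  a <- conformer$angles
  tibble::tibble(
    G_D = (a[["theta_y"]]^2 + a[["theta_x"]]^2 + a[["theta_z"]]^2) / 100,
    E_F = 0, R_G = 1
  )
}

# random rigid transform for invariance checks
random_transform <- function() {
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  ang <- runif(1, -pi, pi)
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * K %*% K
  rigid_transform(R, rnorm(3, sd = 10))
}
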