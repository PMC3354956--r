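---
title: "Hinge-bending conformational search: models, surrogates, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hinge-bending conformational search: models, surrogates, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(hingescan)
```

## The problem

Many proteins bind their ligands by domain hinge bending: one structural
domain (the mobile domain, M) rotates relative to another (the stationary
domain, S) about a flexible linker (L), closing a cleft around the ligand.
The unbound (apo) crystal structure is often known while the bound (holo)
form is not, and the closure is too large and too slow for plain molecular
dynamics to find. `hingescan` searches the hinge-bending subspace directly:
it sweeps the mobile domain through Euler rotations on a coarse angular
grid, repairs each rotated structure by a short relaxation, re-docks the
ligand, scores every conformer with a fitness function, and proposes the
fitness minimizer as the predicted holo conformation.

## Coordinate conventions

Every structure is first placed in a *standard orientation*: the linker
center of mass at the origin, the M center of mass on the +z axis, and the
S center of mass in the y < 0 half of the yz plane. Rotations of M are
active rotations about space-fixed axes through the origin, applied z
first, then x, then y, so the composed operator is
`R = Ry(theta_y) %*% Rx(theta_x) %*% Rz(theta_z)`. All interfaces use
degrees. The factorization branch restricts `theta_x` to [-90, 90], which
makes cell assignment reproducible; near gimbal lock (|cos theta_x| below
1e-8) the degenerate z/y split is canonicalized with `theta_z = 0`.

Angular positions of generated conformers are *measured*, not assumed: the
conformer is superposed on the starting structure over the S-domain
C-alpha atoms (Kabsch), the best origin-centered rotation carrying the
starting M-domain C-alpha set onto the aligned generated one is computed
(a constrained Kabsch without centroid removal), and that rotation is
factored into Euler angles. Relaxation shifts this measurement away from
the applied rotation; that shift is the *drift*. When the start itself has
drifted (the relaxed start's linker center moves slightly off the origin),
the standard orientation is re-established before the search so rotations
stay about the origin.

The figure of merit throughout is the static RMSD (sRMSD): the RMSD over
mobile-domain C-alpha atoms after optimal superposition of the
stationary-domain C-alpha atoms only, with no further fitting of M.
Residues missing from either structure are dropped pairwise and the used
counts are reported as attributes.

## The fitness function and its terms

Each relaxed, re-docked conformer receives three scores:

* `G_D` — the surrogate docked energy: best interaction energy of the
  rigid ligand over an exhaustive pose scan (translations on a 1 Å grid
  over the receptor bounding box padded by 5 Å, times 60 icosahedral
  orientations) refined by Nelder-Mead descent from the best ten grid
  poses. The interaction energy is a soft 6-12 van der Waals term with
  per-element radii (well depth `eps = 0.05`) plus a gaussian attraction
  between polar (N/O) atom pairs centered at 2.9 Å with width 0.8 Å and
  depth `polar_eps = 2.5`. Docking is deterministic: the orientation set
  is fixed, and the seed only matters if the optional pose jitter is
  enabled.
* `E_F` — the surrogate stability score: a quadratic-overlap clash penalty
  over non-bonded protein atom pairs (force constant 10 per Å²,
  sequence-separation threshold 2) minus a bounded native-contact reward
  (C-alpha pairs within 4.5–8 Å, counted per residue up to a cap of 6,
  0.2 per counted contact). It exists to exclude interpenetrating or
  grossly distorted conformers, not to rank stable ones finely.
* `R_G` — the C-alpha radius of gyration, which typically decreases on
  cleft closure. It enters the fitness squared.

The fitness is the weighted sum `f = l1*G_D + l2*E_F + l3*R_G^2` and the
predicted structure is the feasible conformer minimizing `f`. The default
weights (1, 1, 0.002) are on the surrogate scorers' own scales: the docked
energy is the primary discriminator, the stability term anchors the search
against un-physical packing, and the compactness term is a mild
tiebreaker. They are *not* comparable to weights trained against physical
docking and stability energies, because the surrogate units are arbitrary;
the weight-fitting machinery (`fit_lambda`, `loo_cross_validate`) exists
precisely so that weights can be re-trained for any scorer set from a
table of scored conformers with known sRMSD responses, by ordinary least
squares `lambda = (x'x)^{-1} x'y` without intercept or column scaling
(an intercept is available behind a flag, off by default, and
ill-conditioning is reported with the offending column correlation rather
than silently repaired).

Both surrogate scorers sit behind a plain functional interface
(`config$scorer`: conformer in, score row out), so adapters calling
physical docking, stability, or MD codes can replace them without touching
the search engine; the tests also use this hook to inject analytic
fitness functions with known minima.

## Relaxation

A hinge rotation breaks geometry at the L/M boundary and can create
steric clashes. The relaxer minimizes a strain energy — harmonic terms on
consecutive backbone bond lengths against ideal values, harmonic C-alpha
pseudo-angle terms against the starting structure's values, and the clash
penalty including protein-ligand overlaps — by monotone gradient descent
with Barzilai-Borwein adaptive step sizes (a step that would increase the
strain is halved, never accepted). The ligand moves as a rigid body
(translation only; its orientation is owned by the re-docking step).
Convergence is declared when the per-step decrease falls below 1e-6
energy units; the default step cap is 3000. A relaxation that moves any
atom more than 5 Å from where it started is declared failed: the
relaxer's job is local repair, and a repair that requires domain-scale
motion means the target geometry is not locally accessible. Tether rest
lengths for pseudo-side-chain atoms are measured on the reference
structure, never the current conformer, so repeated relaxations are
elastic rather than plastic.

## The search engine

Conformers live on a grid of angular cells spaced 15 degrees (so each
cell owns ±7.5 degrees per axis), spanning ±80 degrees in y and z and
-20 to +80 degrees in x; the asymmetric x range reflects the convention
that positive `theta_x` closes the cleft. A cell is unvisited, feasible
(holding one scored conformer), or infeasible. Generation of a cell
rotates the mobile domain to the cell center, relaxes, measures the
landing angles, and re-docks; if drift carries the structure into a
different cell, a second attempt aims past the target by the observed
drift, and two misses (or relaxation failures) mark the cell infeasible —
permanently, as part of the boundary of accessible conformation space. A
converged conformer landing in a different unvisited cell is recorded
there as a drift capture.

One design choice deliberately departs from applying rotations to
intermediate structures: rotations are always applied to the *starting*
structure. With a deterministic surrogate relaxer, generating from the
current best would make each cell's conformer depend on the path by which
the search reached it (different bases relax into different local minima),
so the same cell could score differently in different runs of the same
search. Generating from the start makes every cell's conformer a pure
function of its cell index; the line search then is coordinate descent on
a fixed, reproducible landscape, and any cell can be regenerated in
isolation (per-cell seeds are derived from the master seed by hashing the
cell index). Under a physical MD relaxer the opposite choice is natural,
because intermediate structures carry genuine accumulated relaxation.

The minimization is a line search: the axes are cycled in the order
theta_y, theta_x, theta_z (configurable); each axis is exhaustively
explored through the current best cell (every cell along the axis
generated or marked infeasible) and the fitness minimizer on the axis
becomes the next base. Ties go to the smallest angular distance from the
current best, then to the lexicographically smallest cell index. After a
full cycle without a change of best cell, one verification sweep of all
three axes is run; convergence is declared when it yields no improvement,
and a sweep cap (default 6) bounds runaway searches. The reported
predicted structure is the fitness argmin over every feasible conformer
generated, drift captures included, and the trajectory's running best
fitness is non-increasing by construction.

## The synthetic dumbbell

The generator builds a desk-scale two-domain protein for which the true
answer is known by construction: two three-helix poly-alanine C-alpha
bundles (ideal helical geometry: 1.5 Å rise, 100 degrees per residue,
2.3 Å radius; consecutive C-alpha spacing verified at 3.8 ± 0.12 Å)
joined by a four-residue linker, built directly in standard orientation.
The closed (holo) form is the open form with M rotated by exactly the
closure angles — (0, 45, 0) by default, a closure magnitude typical of
real hinge proteins — so `decompose_angles(holo, apo)` recovers the
closure to machine precision and the starting sRMSD is 11.5 Å.

Smooth helix bundles carry none of the chemical and steric signatures
that make real closures identifiable, so the cleft is carved explicitly
(all carving atoms are pseudo-side-chain atoms tethered elastically to
interior residues of their own domain, with a fourth off-axis anchor so
they cannot swing):

* a floored pocket on the stationary wall — three oxygens in a cone at
  hydrogen-bond distance below the ligand's lower oxygen — plus an
  apolar collar shielding lateral approaches;
* a rod-shaped eight-atom ligand (a zigzag carbon scaffold with an oxygen
  at each end, reminiscent of a nucleotide lying across a cleft) whose
  lower end docks into the pocket and whose upper end reaches diagonally
  up toward the mobile wall;
* a single mobile-wall oxygen placed at hydrogen-bond distance above the
  rod's upper end at the exact closure, far from every rotation axis;
* a sleeve of three stationary-wall carbons gripping the rod mid-span, so
  the pocket is not a free ball joint;
* interdigitated knobs ringing the site from both walls, which mesh
  without contact only near the exact closure — twists, tilts, sideways
  capping, and over-closure drive knob into knob and the conformer
  becomes infeasible.

By construction the closed form has lower docked energy (about -11.4 vs -9.0
surrogate units at the defaults) and smaller radius of gyration (13.4 vs
14.9 Å) than the open form; both structures and the ligand are verified
clash-free at build time, and construction is bitwise reproducible by
seed (the only randomness is a 0.02 Å jitter on ideal positions, which
keeps the geometry from being exactly degenerate).

`make_score_table()` is the second generator: score rows drawn from
documented uniform ranges with sRMSD responses generated by a known weight
vector plus gaussian noise, used to exercise the fitting and
leave-one-protein-out machinery against a recoverable truth.

## What the tests do and do not show

The module tests verify the geometry exactly (Euler compose/factor round
trips to 1e-6 degrees over 1000 draws; Kabsch recovery of constructed
rigid maps to 1e-9 Å; gyration radius against a direct two-pass loop to
1e-12 relative; sRMSD identities and rigid-motion invariance), the fitting
against an independent normal-equations implementation (1e-8 relative on
random well-conditioned 50 x 3 systems; exact recovery without noise), and
the search bookkeeping invariants (monotone running best, at most two
generation attempts per cell, infeasible cells terminal, stored conformers
inside their cells). The line search provably finds the global cell on
separable analytic fitness surfaces, checked against exhaustive
enumeration of all 847 cells.

The end-to-end experiment on the dumbbell is the honest hard case. At the
default construction the search converges, at least halves the sRMSD to
the constructed holo (11.46 to 5.47 Å, a 52% reduction), recovers the
cleft-closing angle `theta_x` within one cell, and makes the predicted
structure more compact than the start. It does not reliably pin the other
two angles to the closure cell: rotations about the axis through the
hinge and the binding site move the mobile domain's bulk while nearly
preserving the binding-site geometry, so the fitness carries a ridge of
near-degenerate minima (spacing a few tenths of a surrogate energy unit)
along that family, and coordinate descent can settle on a ridge member
one to two cells away in yaw and roll. This is a genuine property of
smooth coarse-grained fixtures: the discrimination that pins all three
angles in real systems comes from rugged, chemically heterogeneous
all-atom interfaces, which no amount of carving reproduces at 72 atoms.
The steric interlocks narrow the family substantially (most of its outer
members are infeasible) but do not eliminate it. Passing these tests
therefore demonstrates the machinery — geometry, scoring, relaxation,
bookkeeping, minimization — and closure detection along the hinge axis,
not three-axis pose recovery on real proteins.

## Problem sizes and runtimes

The default dumbbell has 48 chain residues, 24 carving atoms, and an
8-atom ligand; one docking call scans roughly a million poses in about
two seconds, one relaxation converges in a few hundred to a few thousand
descent steps in well under a second, and a full exploration visits
60–100 cells in about two minutes on one core. These sizes were chosen so
the complete test suite and the reproduction script each run comfortably
on a laptop; the machinery itself has no hard-coded size limits, and real
single-domain-pair proteins (200–400 residues) are within reach at a few
seconds per docking call.

## Known limitations

* The surrogates are not physical energies: no solvation, no electrostatics
  beyond the polar gaussian, no side chains. Trained weights are
  scorer-specific.
* The relaxer repairs local strain only; genuine backbone rearrangements
  (partial unfolding at the hinge, shear components) are out of scope.
* Single chains only; insertion codes are rejected; no mmCIF.
* The hinge is user input; hinge detection is a separate problem.
* Three-axis pose recovery on the synthetic fixture is limited by the
  near-isometry family described above.
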