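---
title: "Landscapes, energy networks and transient pockets on synthetic receptors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Landscapes, energy networks and transient pockets on synthetic receptors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(allosteer)
```

`allosteer` implements the three analyses that together describe how a
receptor activates and communicates allosterically — free-energy landscape
reconstruction over two activation collective variables, protein energy
networks with shortest-path maps, and transient-pocket frequency maps —
and validates all of them on synthetic systems whose ground truth is
planted by construction. This vignette explains the models, the defaults
and why they were chosen, and what the synthetic validation does and does
not establish about real molecular systems.

Units throughout: kcal/mol, Angstrom, degrees, Kelvin, elementary charge;
`k_B = 0.0019872041` kcal/(mol K), Coulomb constant `332.0637`
kcal Å/(mol e²).

## 1. The toy CV space

Real activation landscapes live over two collective variables: a torsion of
the TM6 helix (periodic, degrees) and a TM3–TM6 inter-helix center-of-mass
distance (aperiodic, Angstrom). The synthetic stand-in
(`make_potential()`) keeps exactly this geometry: CV1 on `[0, 10]` with
reflective walls, CV2 periodic on `(-180, 180]`. Gaussian wells of standard
deviation `(0.5, 16)` sit in a flat plateau `barrier = 3` kcal/mol above
the shallowest well.

Two modelling points matter:

* **Depths are basin free energies, not bare minima.** A shallower Gaussian
  well is also wider at the bottom, so matching bare well depths would
  contaminate the planted free-energy offsets with entropy differences.
  `make_potential()` therefore calibrates each well amplitude (by
  one-dimensional root finding against a quadrature of the Boltzmann
  weight over the declared basin box) so that the *basin free-energy
  offsets* at 303.15 K equal the requested depths exactly. The default
  `triple_well_2d` template plants offsets of 0, +1.0 and +0.5 kcal/mol.
* **Ground truth is quadrature, not construction.** `basin_free_energies()`
  integrates the Boltzmann weight on a fine trapezoid grid over each basin
  box; every landscape-recovery test compares against that number, never
  against the generator's intent.

Basin boxes are `centers ± 3` standard deviations per CV. These same boxes
are used for basin Boltzmann integrals on reconstructed surfaces, so
estimate and truth always integrate over identical regions.

## 2. Sampling and the well-tempered engine

The sampler is overdamped Langevin dynamics directly in CV space: the CVs
*are* the coordinates, which is the minimal dynamical model consistent with
a Boltzmann distribution over the landscape. The timestep (0.005) and
per-CV diffusion constants `(1, 1296)` — the CV2 value is the CV1 value
scaled by the squared extent ratio `(360/10)²` — were fixed so that the
unbiased sampler reproduces Boltzmann statistics on the confined template
(the test suite checks sampled standard deviations against quadrature) and
the biased updates stay well inside the stability limit of the steepest
well.

Metadynamics follows the classic receptor-activation protocol shape:
initial hill height 0.5 kcal/mol, bias factor γ = 10, ten interacting
walkers depositing into and reading from a single shared bias, and the
deposition log globally time-ordered (within a deposition round walkers
deposit in index order; each walker's well-tempered height uses the exact
bias including all hills deposited earlier in the same round). Hill widths
`(0.2, 6)` are about 40% of the well widths: wide enough to fill the
landscape in minutes of CPU, narrow enough that the resolution limit of
the Gaussian representation does not visibly distort the well bottoms.
Deposition every 100 steps leaves the walkers a few hill widths of
diffusion between deposits, which keeps the bias close to quasi-static.

Two boundary details are easy to get wrong:

* **Periodic CV2** wraps by minimum image inside every Gaussian and in the
  force grid.
* **Reflective CV1 walls** would "leak" the mass of hills deposited near a
  wall outside the domain, biasing the reconstruction low near the edges.
  Hills within five standard deviations of a wall therefore get mirror
  images across it — the bias a reflected walker actually experiences —
  in deposition, dynamics and reconstruction alike. Wall crossings are
  reflected and counted (`run$reflections`).

For speed, the dynamics read bias forces from an incrementally updated
grid (bilinear interpolation, 121 × 121 nodes); hill heights always use
the exact Gaussian sum.

## 3. Estimators: surfaces, differences, errors

`reconstruct_fes()` applies `F = -(γ/(γ-1)) V_bias`, min-anchored. The
instantaneous estimate oscillates as late hills keep arriving, so the
default analysis averages the min-anchored estimate over eight checkpoints
spanning the second half of the run (`average_checkpoints`); the
convergence monitor (`delta_g_timeseries()`) reports both the
instantaneous series and a tail-mean estimator (mean over `(t/2, t]`)
whose flattening indicates convergence.

Basin differences are Boltzmann integrals over the declared boxes rather
than single-minimum lookups — robust to grid noise. Statistical errors use
the standard final-bias ("constant bias") reweighting: per-sample weights
`exp(+V_bias(s)/k_B T)`, histograms over ten contiguous time blocks, and
the per-bin (or per-basin-difference) standard error of `-k_B T ln p`
across blocks.

Two methodological choices deserve a note:

* **Reweighting window.** The constant-bias approximation is exact only
  for samples drawn under the final bias. The reweighting-consistency
  analysis therefore uses the final quarter of the sample stream, where
  the bias is nearly stationary; earlier samples would import a systematic
  drift that no amount of statistics removes.
* **Offset-free profile comparison.** Free energies are defined up to an
  additive constant, and min-anchoring ties that constant to the noisiest
  single bin. When two profile estimates are compared bin by bin
  (`profile_residuals()`), the arbitrary relative offset is removed by an
  inverse-variance weighted fit first. And because the per-bin tolerance
  is two standard errors, the correct expectation is ~95% of bins inside
  the band — demanding every single bin inside a 2σ band would fail for
  any correct implementation once enough bins are compared. The acceptance
  check asserts ≥ 90% coverage with no bin beyond 3σ.

## 4. The planted-pathway receptor

`make_bead_receptor()` folds one bead per residue onto a cubic lattice
(serpentine walk, spacing 5 Å, so sequence neighbours sit at contact
distance, and the Lennard-Jones minimum `2^(1/6) σ` is placed exactly at
the lattice spacing with ε = 1 kcal/mol). The planted pathway is a
balanced monotone staircase of lattice-adjacent residues between the
"extracellular" origin (residue 1) and the farthest residue — by default
8 edges on the 4 × 4 × 3 lattice of the 48-residue receptor. Consecutive
pathway residues carry alternating charges ±0.275 e, giving them roughly
−5 kcal/mol of Coulomb attraction on top of the −1 kcal/mol lattice
contact; after clamp/abs/normalise processing, pathway couplings sit near
1 and ordinary contacts near 1/6 — above the 0.1 node threshold, so the
whole receptor joins the network, but with edge lengths `-log IE` an order
of magnitude longer than the pathway's.

Design details that keep the recovery test honest:

* The staircase is a *shortest* lattice path, so no two non-consecutive
  pathway residues are spatially adjacent — otherwise the alternating
  charges would create attractive shortcut edges that legitimately outrank
  a planted edge. (Longer, detour-extended paths are available via
  `path_edges`, with exactly this caveat documented.)
* Off-path charges are a ±0.01 e seeded jitter, so different seeds give
  genuinely different realisations while the geometry stays fixed.
* The pathway endpoints are local communication centers (the synthetic
  analogue of the extracellular-loop and intracellular hubs): their
  non-path lattice neighbours — excluding any that touch an interior path
  residue and would bypass the terminus — carry a small opposite charge
  (0.11 e), so traffic from the terminal regions funnels through the
  endpoints. Without this, the terminal pathway edges carry only the
  paths that end at a terminus, and topologically they can be outranked
  by "feeder" edges that aggregate off-path traffic into mid-path hubs.
* With `two_chains = TRUE` the residue range splits at the midpoint and
  the staircase necessarily crosses the boundary, planting at least one
  inter-chain communication edge — the construct used to probe
  receptor–G-protein-style inter-chain coupling.

The shortest-path map itself follows the standard recipe: nodes are pairs
with normalised mean interaction energy above 0.1, lengths are natural-log
`-log IE` (the base uniformly rescales lengths and provably cannot change
shortest paths or usage counts; a test asserts this), and a deterministic
Dijkstra runs from every origin. Tie-breaks keep the predecessor with the
lowest residue index; path endpoints are counted in node usage (both
choices are flags). On ≤ 8-node graphs the implementation is checked
exactly against exhaustive path enumeration and against an independent
graph library.

## 5. Cavities and frequency maps

`generate_ensemble()` adds isotropic, atom-uncorrelated Gaussian noise
(default 0.1 Å) and, in a controlled fraction of frames, carves a
spherical cavity by pushing intruding beads radially outward to
`radius + bead radius` — atom count is frame-invariant, and the carved
ball contains no atom. The open/closed schedule is stored with the
ensemble, so the planted frequency is known exactly (`round(n f)` open
frames out of `n`).

The detector is a grid criterion: a voxel is a pocket voxel when a 1.4 Å
probe fits and the voxel is buried. Burial combines a neighbour count
(≥ `burial_min` atoms within `burial_radius`) with **directional
enclosure**: each of the six axis-aligned 45° cones must contain an atom
within the burial radius. The count alone cannot separate a genuine cavity
from bulk voxels hugging a dense surface (both can have hundreds of
neighbours); the enclosure test removes the latter, because bulk voxels
always have at least one open cone. Defaults — spacing 1.0 Å, probe 1.4 Å,
burial radius 8 Å with ≥ 40 neighbours — are tuned on the dense shell
fixture, where the detected volume of a 4 Å carved cavity must match
`(4/3)π(4 − probe)³` within discretisation error; sparse bead receptors
use a relaxed count (radius 10 Å, ≥ 6 atoms) exposed in the config. The
tiny inter-bead voids of the lattice receptor fall below `min_voxels = 5`
and are discarded, so extraction at the conventional Φ = 0.2 iso-value
(26-connectivity components) returns exactly the planted pocket.

Frames are assumed pre-aligned, as pocket mapping requires;
`align_ensemble()` provides Kabsch superposition onto the first frame when
needed.

## 6. The pipeline and its defaults

`run_pipeline()` chains the full workflow from one validated YAML config:
landscape run → surface/convergence/error → state split (half-open
axis-aligned boxes over CV space; the default regions are the potential's
basin boxes; stride-2 subsampling mirrors common practice of analysing
every other structure) → per-state receptor ensembles → per-state
IEM/SPM → per-state frequency maps, pockets and pocket–network overlap.
Each run writes a `manifest.json` (config hash, resolved seed, package and
R versions, outputs); deterministic stages rerun bit-identically from
config + seed. The shipped demo (`inst/extdata/demo_config.yaml`) plants a
state-dependent story — cavity closed in the deepest basin, transient
(Φ = 0.4) in the second, permanent in the third — and finishes in well
under a minute.

Problem sizes used by the validation suite: 160,000 steps per walker
(16,000 hills) for the triple-well recovery, 60,000 steps per walker for
each symmetric-null seed, 40–50 frame ensembles of the 48-residue receptor
for network and pocket recovery over 10 seeds. These sizes give the
estimators comfortable margins over their statistical errors while keeping
a full validation run in the minutes range on one CPU.

## 7. What the synthetic validation shows — and what it does not

The generators emulate the *structure* of the real analyses: a rugged
periodic-by-aperiodic landscape with metastable basins; residue networks
in which strong attractive couplings form a contiguous communication
pathway, including across a chain boundary; ensembles in which cavities
open with a defined frequency at a defined location. Passing tests
establish that the estimators recover planted truth under their own
assumptions — unbiased CV-space diffusion, pairwise additive energetics
with fixed parameters, rigid pre-aligned frames, isotropic uncorrelated
noise.

Real molecular data violate each assumption in ways the toys do not probe:
CV-space dynamics are not overdamped-diffusive (hidden slow degrees of
freedom produce hysteresis no convergence monitor fully detects); interaction
energies fluctuate with conformation- and solvent-dependent screening —
notably, water-mediated couplings such as a bridging-water lock are
invisible to a protein-only energy matrix; pocket shapes are not spheres
and their "open" states are not binary. Recovery rates reported here are
therefore upper bounds on what identical settings achieve on real
trajectories, and the package deliberately exposes every threshold
(network cutoff 0.1, iso-value 0.2, burial parameters, basin boxes) so
sensitivity to them can be mapped on real data.

## 8. Numerical conventions

* Dihedrals use the right-handed atan2 convention, wrapped to
  `(-180, 180]`; COM distances are mass-weighted when masses are given.
* Histograms bin half-open `[lo, hi)` with the last bin closed; empty bins
  are masked `NA`, never imputed — `-ln 0` is undefined and imputation
  biases landscapes.
* Matrix processing: clamp positives to zero, absolute value, divide by
  the global maximum attractive magnitude (per-row normalisation would
  break symmetry). An all-repulsive matrix processes to all zeros and is
  flagged, not errored.
* Dijkstra tie-breaks are deterministic (lowest index); degenerate
  zero-length edges (IE = 1) are handled naturally.
* All generators take explicit integer seeds and restore the caller's RNG
  state; identical seeds give bit-identical outputs.
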