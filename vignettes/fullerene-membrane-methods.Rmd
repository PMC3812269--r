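---
title: "Methods: fullerene aggregation and bilayer perturbation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fullerene aggregation and bilayer perturbation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(fullermem)
```

## The model

C60 fullerene is represented as a rigid cage of 60 identical neutral
Lennard-Jones sites: an ideal equal-edge truncated icosahedron scaled so the
atom-to-centre distance equals the cage radius $R$ = 0.35 nm. Real C60 has
two slightly different bond lengths (6:6 vs 6:5 bonds); because every site
carries the same LJ type ($\sigma$ = 0.34 nm, $\varepsilon$ = 0.36 kJ/mol,
Amber-style neutral carbon), that distinction has no energetic consequence
and the ideal cage is used. The interaction between two cages is the
full-range sum over all $60 \times 60$ atom pairs,

$$E_{AB} = \sum_{i \in A}\sum_{j \in B} 4\varepsilon
  \left[\left(\frac{\sigma}{r_{ij}}\right)^{12} -
        \left(\frac{\sigma}{r_{ij}}\right)^{6}\right].$$

No cutoff is applied in cluster energetics: the 0.9/1.4 nm cutoffs of MD
engines are a simulation-performance device, not part of the interaction
model, and at these system sizes the exact sum is cheap.

### Single-site reduction

Cluster geometry and aggregation kinetics are driven by the
orientation-averaged pair energy
$\bar V(r) = \langle E_{AB}(r, \Omega_A, \Omega_B)\rangle_\Omega$,
tabulated on a 0.9-4.0 nm grid (`build_effective_potential()`) with the same
fixed draw of random mutual orientations reused at every separation (common
random numbers keep $\bar V$ smooth in $r$). The table is interpolated with
a cubic spline; beyond the grid it continues as an attractive $r^{-6}$ tail
matched at the last point, and below it a linear repulsive wall stands in
for the hard core. The reduction is justified because the stacking motifs
are centre-of-mass geometries: at the ~1 nm contact distance the
orientational corrugation of the C60-C60 interaction is small compared with
the ~34 kJ/mol well depth, so rigid-rotor detail does not change the contact
topology. Atomistic energies remain available (`pair_energy_atomistic()`)
and the test suite checks the averaged table against the continuum
(Girifalco-type) two-sphere closed form: agreement is ~0.3 % for
$r \geq 1.0$ nm and degrades only near the zero crossing at ~0.94 nm, where
the relative measure is ill-conditioned (absolute gap ~1.3 kJ/mol at
0.95 nm).

The dimer minimum of $\bar V$ falls at 0.99 nm, reproducing the known
~1.0 nm C60-C60 equilibrium distance in vacuum.

## Cluster global minima (N = 3-6)

`optimize_cluster()` runs basin hopping over centre-of-mass coordinates:
50 random restarts (perturbation scale 0.3 nm) around the running best
minimum, each followed by BFGS descent with analytic gradients from the
spline. Two numerical guards matter in practice:

* the wall slope is clamped (default 400 kJ/mol/nm) so a line search that
  probes the core cannot catapult particles into the flat far field, and
* every start/perturbed configuration is pre-processed so no pair sits
  below the table floor.

Vacuum boundary conditions are used (the reference equilibrium distance is
a vacuum quantity). The resulting minima are the equilateral triangle (3),
tetrahedron (4), regular trigonal bipyramid (5; apex-apex distance
$\sqrt{8/3}\,d_0$) and the octahedron family (6; 12 contacts). For N = 6
the capped-bipyramid ("deformed octahedron") local minimum lies very close
in energy to the regular octahedron, and different restart seeds can return
either; both carry the 12-contact signature and both occur as observed
stacking modes, so the classifier reports the two as separate sub-labels.

## Motif classification

`motif_classify()` works from contact topology: with $d_0$ the minimum
pairwise distance, contacts are pairs closer than $(1 + t)\,d_0$ with
$t = 0.1$ by default (exposed, since no canonical tolerance exists). The
deformed 5-cluster is recognised as a regular tetrahedron plus a fifth
particle bridging one edge (8 contacts with a 6-contact 4-subset); the
deformed 6-cluster as a trigonal bipyramid plus a face-capping particle
(12 contacts, a 9-contact 5-subset, 3 contacts on the extra vertex); the
regular octahedron by its three equal $\sqrt 2\,d_0$ diagonals.

Because $d_0$ is the *minimum* of the noisy contact distances, it is biased
low under coordinate noise, and the $(1+t)d_0$ threshold starts missing
true contacts when the noise reaches ~2 % of $d_0$ (label agreement drops
to ~70-90 % for the 12-contact shapes). The classifier is reliable to ~1 %
COM noise, which is the regime of energy-minimised and block-averaged
geometries it is applied to; the property tests pin the >= 99 % agreement
at that level.

## Synthetic trajectories

`simulate_aggregation()` integrates overdamped (position) Langevin
dynamics,

$$\mathbf{x}_{t+\Delta t} = \mathbf{x}_t
   + \frac{\mathbf{F}}{m\gamma}\,\Delta t
   + \sqrt{\frac{2 k_B T \Delta t}{m\gamma}}\,\boldsymbol{\xi},$$

with the C60 mass $m$ = 720.66 amu fixed and the collision rate $\gamma$
(ps$^{-1}$) as the friction parameter, so the diffusion coefficient is
$D = k_BT/(m\gamma)$. Defaults: $T$ = 298 K, $\gamma$ = 6.9 ps$^{-1}$
(giving $D \approx 5\times10^{-4}$ nm$^2$/ps, the right order for C60 in
water), $\Delta t$ = 0.5 ps, 6 particles in a 6.2 x 6.2 x 9 nm box (the
lateral dimensions of a 128-lipid DOPC patch), initial mutual separations
>= 2 nm. The timestep resolves the stiff contact well of $\bar V$
(curvature ~$10^4$ kJ/mol/nm$^2$); the integrator clamps the tabulated pair
force at the wall value, reflects pairs that step below the table floor
back to it (hard-core reflection), and aborts with a `timestep-too-large`
error if the deterministic drift component of any step exceeds
$\sigma/2$. The drift alone is checked because the Gaussian noise term is
unbounded at any timestep, so a total-displacement criterion would trip
spuriously on rare noise draws.

An overdamped integrator was chosen over full MD deliberately: the analysis
pipeline needs realistic aggregation kinetics and equilibrium placement
with known ground truth, not dynamical fidelity, and thermostat/barostat
machinery is out of scope. Under the defaults, all six particles assemble
into a single cluster within the 100 ns default run in essentially every
seeded run, passing through transient 2-3 particle nuclei of a few ns --
the qualitative phenomenology the emulator is built to reproduce.

### Implicit membrane slab

Partitioning is generated by an external potential along $z$,

$$U(z) = -D_w \exp\!\left(-\frac{(|z-c| - a)^2}{2 w^2}\right)
       + B \exp\!\left(-\frac{(|z-c| - h)^2}{2 w^2}\right),$$

active within $|z - c| < h + 2w$: a Gaussian double well with minima at
$|z - c| = a$ = 1.0 nm (the preferred insertion depth of fullerene clusters
inside a DOPC bilayer) and an optional interface barrier at the slab
surface $|z-c| = h$. Defaults: $h$ = 2.13 nm (half of 4.26 nm), well depth
$D_w$ = 20 kJ/mol -- a literature-scale magnitude for C60 partitioning free
energies into lipid bilayers, chosen a priori since no quantitative barrier
is available for clusters -- width $w$ = 0.3 nm, barrier $B$ = 1 kJ/mol
(small, so both penetration pathways -- assembly completed before entry, or
concurrent with it -- are reachable by tuning $B$). With the defaults the
long-run $|z - c|$ histogram of in-membrane particles peaks at 1.0 nm
within the 0.2 nm bin resolution.

## Synthetic bilayer

`build_synthetic_bilayer()` constructs a ground-truth fixture, not a
physical membrane: pseudo-lipids (1 head bead + 8 tail beads, 0.15 nm
spacing) on a jittered square lattice, two leaflets with head planes
exactly `target_thickness` apart (default 4.26 nm) and lattice area exactly
`target_area_per_lipid` per lipid (default 0.599 nm^2) -- the fluid-phase
DOPC reference values -- plus water-bead slabs. Tail directors are drawn
from a von Mises-Fisher distribution about the inward normal with
concentration $\kappa$ (default 20, which puts the order parameter near the
fluid-bilayer range, $S_{cd} \approx 0.43$). Chains zig-zag +-0.05 nm off
axis: a perfectly straight rod has a degenerate inertia tensor whose short
axes are undefined, which would make the molecular-frame order parameter
ill-posed. Known non-realities: lipids are static (no response to an
inserted cluster), water is a lattice, there are no head-group dipoles and
no undulations. Passing recovery tests on this fixture therefore
demonstrates correctness of the *measurement operators*, not realism of the
membrane; `inject_ball_into_bilayer()` correspondingly carves a simple
lateral cavity without modelling lipid wrapping.

## Membrane measurement operators

* **Midplane and half thickness** (`membrane_center()`): leaflets split at
  the median head-bead $z$; centre = midpoint of leaflet mean head heights.
  Head beads, not whole-lipid centres, keep the estimate robust to tail
  disorder.
* **Insertion depth** (`insertion_depth()`): signed $z_{COM} - c$ per ball
  per frame, reported against the fullerene-free half thickness as the
  leaflet-border reference line.
* **Density profile** (`density_profile()`): per-component counts in
  $z$-bins referenced to the per-frame instantaneous midplane (removing
  bilayer drift), divided by bin volume and frame count. Bins always cover
  the data range, so each component's profile integrates exactly back to
  its atom count -- an invariant the tests assert for every bin width. No
  leaflet symmetrisation is applied (real profiles are asymmetric).
* **Order parameter** (`order_parameter()`): per lipid, the molecular long
  axis is the minimal-moment principal axis of the unit-mass inertia
  tensor, signed toward the lipid's own leaflet outward normal; maximal
  moment = molecular x, and y completes the right-handed frame. With
  $\theta_a$ the angle between molecular axis $a$ and the bilayer normal,
  $S_{aa} = \langle(3\cos^2\theta_a - 1)/2\rangle$ over lipids and
  $S_{cd} = -\tfrac23 S_{xx} - \tfrac13 S_{yy}$. Aligned axes give
  $S_{cd} = 1/2$, isotropic axes 0; the tensor is traceless by
  construction. Averaging is per frame over lipids, then over frames.
  Degenerate (collinear) molecules are resolved by the lowest-index
  eigenvector with a warning.
* **Grid thickness / area per lipid** (`grid_thickness_apl()`): GridMAT
  style. Per xy-cell, thickness is the $z$ gap between the nearest
  (periodic xy) top- and bottom-leaflet head; each cell is owned by the
  lipid of its nearest same-leaflet head, so per-lipid areas tile the box
  exactly per leaflet. Nearest-head ties are broken deterministically by
  lowest atom index. Area per lipid is reported per leaflet (top and
  bottom), since conventions differ on whether the quantity is a leaflet or
  bilayer average.

## Pipeline and reproducibility

`validate_config()` parses a strict YAML schema (unknown keys rejected by
name) with the standard defaults: 0.6 nm clustering cutoff, 1 ns blocks,
298 K. `run_pipeline()` chains generate -> cluster analysis -> membrane
analysis and writes a JSON report embedding the seed and an MD5 hash of the
canonicalised config; identical config + seed reproduce the report byte for
byte. Every stochastic component (orientation draws, placements, thermal
noise, bilayer tilt) consumes an explicit seed.

## Problem sizes

The shipped analyses use 6 particles over 100-200 ns of overdamped
dynamics, 100-150 orientation samples per separation for the averaged
potential, 50 basin-hopping restarts for N <= 6, 128-800 lipid synthetic
bilayers, and $10^4$-$10^5$ molecules for the statistical limits of the
order parameter -- sizes at which every stage completes in seconds to a few
minutes on one core while leaving the statistical checks well-powered.

## Known limitations

* The effective potential discards orientational corrugation; it cannot
  resolve orientation-dependent docking effects.
* The Langevin emulator has no hydrodynamic interactions and no explicit
  lipids; membrane entry kinetics are governed by the imposed barrier
  height, which is a free parameter, not a calibrated quantity.
* The synthetic bilayer is static: perturbation *of* the membrane by an
  inserted cluster (thinning, wrapping, pore formation) is outside the
  generator's vocabulary -- the analysis operators would measure such
  effects on real trajectories, but the fixture cannot produce them.
* Motif classification targets energy-minimised or lightly noisy
  geometries; at coordinate noise above ~2 % of the contact distance the
  minimum-referenced contact threshold under-counts contacts.
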