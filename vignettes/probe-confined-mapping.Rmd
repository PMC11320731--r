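---
title: "Probe-confined dynamic mapping: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probe-confined dynamic mapping: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(probemap)
```

probemap is a desk-scale implementation of probe-confined dynamic
mapping: small fragment-like molecules are confined near one face of a
receptor by a cylindrical flat-bottom wall, sampled with Langevin
dynamics, and the trajectory is mined for binding-site hotspots. This
vignette documents the models, every tunable that matters, the
numerical choices, and what the synthetic validation system does and
does not establish about real receptors.

## The confinement wall

The sampling region is a cylinder with its open face over the pocket
mouth and its axis pointing away from the receptor. Writing `a` for the
signed axial coordinate of a probe centre (measured from the open
face), `r` for its perpendicular distance from the axis, `R` and `L`
for the cylinder radius and length, the wall energy is the flat-bottom
half-harmonic

    E(a, r) = k/2 * [ max(0, r - R)^2 + max(0, a - L)^2 ]

with the axial term dropped when the far end is declared open. No
penalty is applied through the open face (`a < 0`): that face abuts the
receptor surface, which blocks escape physically, and probes must be
able to reach it. `E` is zero throughout the interior and C1 at the
walls — both the energy and its gradient vanish at the boundary — so
the integrator sees no force discontinuities.

The default stiffness `k = 10 kcal mol^-1 A^-2` is a typical
flat-bottom restraint value: stiff enough that thermal excursions past
the wall are a fraction of an angstrom (`sqrt(2 kT / k)` is about
0.35 A at 310 K), soft enough not to constrain the time step. When the
region is anchored with `region_from_residues()`, the open face sits at
the heavy-atom centroid of the anchor residues (by default the three
generic positions 2.43, 7.56 and 8.48 that define the intracellular
pocket centre), the axis runs outward from the receptor centre of
geometry, the radius is half the maximum anchor spread plus 6 A and the
length is 15 A. These dimensions are declared package defaults, not
values inherited from any particular production protocol, and all are
configurable.

## Nonbonded model and sampler

Interactions are pairwise Coulomb plus Lennard-Jones:
`k_c q_i q_j / (eps_r r)` with `k_c = 332.0637 kcal A mol^-1 e^-2`, and
`eps_ij [(Rmin_ij/r)^12 - 2 (Rmin_ij/r)^6]` with geometric-mean well
depths and additive `Rmin/2`. The cutoff defaults to 12 A; with
switching on (the sampler default) both terms are taken smoothly to
zero from 10 A so forces stay continuous. There is no periodic box, no
explicit water or membrane, and no mean-field electrostatics beyond the
scalar dielectric: solvent appears only through the dielectric constant
and the Langevin friction. Probe and receptor parameters (partial
charges, LJ, masses) are supplied per atom in plain-text definition
files; the two packaged probe templates carry generic
cheminformatics-derived placeholder charges and are meant to be
overridden when better parameters exist.

Probes are rigid bodies — translation plus quaternion rotation about
the principal axes of inertia — and the receptor is held fixed. Both
are deliberate fidelity losses relative to restrained-backbone
all-atom MD: they remove the force-field and conformational-sampling
burden while preserving the geometry-plus-energetics signal the mapping
statistics consume, and they are the main reason results on real
receptors should be read qualitatively (which residues, not how many
kcal/mol).

The integrator is a BAOAB Langevin splitting at 310 K with friction
1 ps^-1 and a 2 fs (0.002 ps) default time step; rotations use the
exact free-rotor quaternion update within each half-step and an
Ornstein-Uhlenbeck kick on body-frame angular velocities. Single-bead
probes (zero inertia) skip the rotational part. All randomness — probe
placement, initial Maxwell-Boltzmann velocities, thermostat noise —
flows from one seed through R's generator, so a `(config, seed)` pair
replays bit-identically; every run records its energies and kinetic
temperature in a per-frame diagnostics table. The sampler aborts with
the offending step index if the potential energy exceeds a configurable
divergence threshold (default 1e6 kcal/mol).

## Trajectory statistics

* **Pocket occupancy** — the percentage of frames with at least one
  probe heavy atom within 4 A of any heavy atom of any pocket-centre
  residue. The centre is the union of the three anchor residues;
  requiring proximity to all three simultaneously would undercount a
  pocket the size of a fragment. Any-heavy-atom (rather than probe
  centre-of-mass) proximity is used for the same reason.
* **Density grid** — per frame, a voxel (1 A cell side by default) is
  occupied when its centre lies within the van der Waals radius of a
  selected atom (C 1.7, N 1.55, O 1.52, S 1.8, H 1.2, P 1.8 A); the
  grid value is the occupied-frame fraction, so values live in [0, 1].
  Thresholding keeps voxels with value >= the isovalue (default 0.5)
  *and* value > 0, so an isovalue of zero still excludes
  never-occupied space. Grids export as OpenDX fields (z index
  fastest) and PDB pseudo-atoms.
* **Hotspot table** — residues with any heavy atom within 5 A of any
  probe atom in a frame receive that frame's full residue-probe
  electrostatic and vdW energy. Means and SDs are taken over
  contributing frames (frames with the residue inside the shell);
  averaging zeros over the whole run would dilute exactly the strong,
  intermittent contacts the analysis exists to find. The contributing
  frame count is reported, and `average = "all"` switches to
  whole-run averaging, under which the per-residue means sum exactly
  to the whole receptor-probe energy when the shell is infinite.
  Ranking is ascending by mean energy (most favourable first), ties
  broken by residue id.
* **Hydrogen bonds** — donor-acceptor distance <= 3.5 A and D-H...A
  angle >= 90 degrees. A 90-degree "angle cutoff" is ambiguous between
  minimum-angle and deviation-from-linearity conventions; probemap
  implements the minimum D-H...A angle at the hydrogen (180 = linear).
  Donors must be given with their hydrogens explicitly, as the package
  stores no bond topology.
* **Contacts, RMSD, RMSF** — contact frequency is the fraction of
  frames with minimum heavy-atom distance <= 4 A (the ionic-lock
  statistic). Superposition is Kabsch on heavy atoms with the
  reflection branch rejected (det = +1); RMSF aligns to the mean
  structure (align to first frame, average, re-align) and reports
  per-residue means over heavy atoms.

## Pocket geometry

SASA is Shrake-Rupley with a 1.4 A water probe and 960 golden-spiral
test points per atom (doubling the points moves totals by well under
1%). The hydrophobic/hydrophilic split is by element — C and S
hydrophobic, everything else hydrophilic — a deliberately simple rule
chosen because the split is reported but no partition convention is
universal; it is stored per atom so any other rule can be applied to
the tidy per-atom output. Pocket volume is a grid estimate inside the
confinement region: a voxel counts when a water-sized probe centred
there clears every atom (centre >= vdW + 1.4 A) yet stays within probe
reach of the surface (no further than two probe radii beyond the
nearest atom's vdW surface), which excludes open solvent beyond the
pocket mouth. This stands in for alpha-sphere cavity detection and is
validated against constructed cavities of known volume, not against
any external pocket program.

## Concentration-response statistics

The 4PL model is `y = basal + (emax - basal) / (1 + 10^((logEC50 - x) h))`
in log10 molar units, the common concentration-response convention.
The basal response is fixed to zero by default, matching the
delta-over-vehicle construction of BRET-style readouts. Fitting is
unweighted least squares via Levenberg-Marquardt with a deterministic
multistart grid — logEC50 over the observed concentration range, Hill
slopes {0.5, 1, 2}, Emax at the extreme observed responses; best final
SS wins, ties to the first start — and standard errors from the
Jacobian at the optimum. Flat data yield a near-zero Emax and an
`ill_conditioned` flag rather than a silent failure. Normalisation to
percent-of-vehicle-maximum uses the reference condition's maximum
per-concentration mean response (a fitted-Emax variant is provided).
Nested-model comparison is the extra sum-of-squares F test between
independent per-condition fits and a global fit sharing one parameter;
both Emax- and potency-sharing are exposed because which parameter is
constrained is an analysis choice, not a package decision.

## The synthetic study system

`make_toy_receptor()` builds a hollow shell of single-atom residues
(80 atoms on a 12 A sphere, 0.15 A coordinate jitter) with a ~22 degree
cap removed as the pocket mouth and six residues ringing the mouth
annotated with the pocket's generic labels (anchors 2.43/7.56/8.48,
hotspots 8.49/7.53/6.36), mirroring the intracellular-pocket topology
so that package defaults run unchanged on fixtures. The residue
labelled 8.49 — the primary anchoring position — is the planted
attractor: it gains extra LJ well depth (default 2 kcal/mol) and a
-0.4 e charge, making it the unambiguous ground-truth hotspot.
`planted_hotspot_trajectory()` either runs the real sampler on this
receptor or synthesises frames directly with a probe placed inside the
occupancy shell in an exact fraction of frames; the direct mode exists
so analysis tests never inherit sampler stochasticity.

What the toy system emulates: the geometry of a semi-enclosed pocket
with annotated anchors, a localised energetic hotspot, confined probe
diffusion, and exact ground truth for occupancy and ranking. What it
does not: chemical realism (one atom per residue, placeholder
parameters), receptor flexibility, solvent structure, or the
competitive binding of multiple hotspots of similar strength. Passing
the recovery tests therefore demonstrates that the statistics find a
planted signal through the full sampling pipeline — not that the
pipeline reproduces production-scale mapping of a real GPCR, whose
headline numbers require cluster-scale all-atom simulations outside
this package's scope.

## Validation problem sizes

The test suite and the acceptance script size their computations as
follows, chosen to give each statistic comfortable convergence margins
at desk scale: harmonic-trap and equipartition checks use a single
40 amu bead for 2-5 x 10^5 steps (variance against kT/k pooled over
axes, both within 5%); confinement checks 10 beads above a repulsive
slab for 5 x 10^4 steps against a 1 A buffer; hotspot recovery runs 10
seeds of 8 probes x 2 x 10^4 steps (40 ps) on toy receptors with a
3 kcal/mol attractor, requiring the planted residue to rank first in
at least 9; EC50 recovery uses 100 noisy datasets (sigma = 0.02, 3 x 8
design) within +/-0.2 log units, and the F test's type-I error is
calibrated on 400-1000 null datasets against a 3-7% band at alpha
= 0.05. Brute-force oracles (double-loop energies, per-voxel
rasterisation, all-pairs distance scans) are re-implemented
independently inside the tests.

## Known limitations

Receptor atoms never move, so induced fit, side-chain rearrangement
and RMSF of the receptor itself are out of reach of the sampler (the
RMSF/RMSD statistics still apply to any externally supplied
trajectory). Probe parameters are placeholders unless the user provides
better ones. Electrostatics are unscreened beyond the scalar
dielectric, which overweights charge-charge contacts in open solvent.
The pocket-volume estimator needs a sensible confinement region and is
not a cavity detector. None of the numerical defaults have been tuned
to reproduce any published per-residue energy table, and the package
intentionally reports energies in relative, ranking-oriented terms.
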