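---
title: "Models and methods behind cgfork"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cgfork}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`cgfork` simulates protein-DNA assemblies at one bead per amino acid and
three beads per nucleotide, and analyses the resulting trajectories with the
quantities used to characterise histone recycling at a replication fork.
This vignette documents the model, its parameters and their defaults, the
numerical choices, and what the synthetic test systems do and do not
establish.

## The energy model

**Representation.** Protein residues are single beads at the C-alpha
position. Nucleotides contribute base, sugar and phosphate beads; by
convention the 5'-terminal nucleotide of each strand carries no phosphate,
so a duplex of n base pairs has 2(3n - 1) beads. Folded protein regions and
duplex DNA carry native-anchored local terms (harmonic bonds and angles,
periodic dihedrals, all referenced to the build geometry); disordered
regions carry 3.8 A harmonic bonds plus a weak generic angle term
(k = 1 kcal/mol/rad^2 around 125 deg) and no dihedral, which keeps coils
flexible. Single-stranded DNA likewise keeps only bonds and weak angles.

**Native contacts.** The attractive non-local term is the structure-based
pair potential

$$V = \sigma \sum_{ij} \epsilon_{ij}\left[5\left(\frac{r_{ij0}}{r_{ij}}\right)^{12} - 6\left(\frac{r_{ij0}}{r_{ij}}\right)^{10}\right],$$

minimised exactly at the native distance $r_{ij0}$ with depth
$\sigma\,\epsilon_{ij}$. Contact lists are derived from reference
coordinates with the common structure-based-model criterion: any mapped
heavy-atom pair within 6.5 A, sequence separation of at least 4 within a
chain. The per-contact strength defaults to a uniform
$\epsilon_{ij} = 0.3$ kcal/mol; per-contact decompositions from all-atom
energetics are deliberately out of scope, and both the strength rule and
the criterion are arguments of `derive_native_contacts()`. The global
scale $\sigma$ belongs to each labelled contact set separately, so a single
cross-molecular interaction (for instance the donor-tail/histone set) can
be calibrated without touching intra-molecular sets. Base pairing in
duplexes is maintained by a native-anchored cross-strand contact set built
with the duplex, which stands in for an explicit hydrogen-bonding potential;
sequence-dependent DNA thermodynamics (melting, hybridisation kinetics) are
not modelled.

**Electrostatics.** Screened Coulomb interactions from Debye-Hueckel theory,
with the Debye length computed from ionic strength, dielectric constant and
temperature (defaults 300 mM, 78.0, 300 K give 5.55 A). Protein beads carry
formal charges (+1 e for Lys/Arg, -1 e for Asp/Glu, 0 otherwise); surface-
charge optimisation is not implemented, but per-bead overrides accept
externally computed charges. Phosphates are dual-valued: -0.6 e toward DNA
partners (counter-ion condensation) and -1.0 e toward protein partners
(counter-ion release on binding); the pair kernel resolves the context from
the partner's molecule class. The default truncation is an energy shift at
50 A, about nine Debye lengths at 300 mM, so the discarded tail is orders
of magnitude below thermal noise; `cutoff = Inf` disables truncation, which
is what closed-form comparisons use.

**Excluded volume.** A purely repulsive
$\epsilon_{ev}[(d_{ij}/r)^{12} - 1]$ for $r < d_{ij} = r_i + r_j$, zero
beyond (the shift makes the energy continuous). Defaults:
$\epsilon_{ev} = 0.6$ kcal/mol, radii 2.5 A (residue), 2.0/2.5/2.0 A
(base/sugar/phosphate). The DNA radii were sized to the fiber geometry the
duplex builder produces - stacked base sites sit 4.2 A apart, so base radii
above 2.1 A would put the native structure inside its own repulsive wall.
1-2 and 1-3 bonded neighbours are excluded from all nonbonded terms, and
native-contact pairs are excluded from excluded volume (their minimum is
the Go well).

**Units.** Lengths in A, energies in kcal/mol, masses in amu; in this system
the intrinsic time unit is $\sqrt{\text{amu}\,\text{A}^2\,\text{mol}/\text{kcal}} = 48.9$ fs
and no conversion constants enter the equations of motion
($k_B = 0.0019872$ kcal/mol/K). Every bead carries one standard bead mass
of 137 amu, the average residue mass. Equilibrium sampling is independent
of the mass assignment; the value only sets the stable-timestep scale, and
137 amu makes the conventional 0.3-unit (~14.7 fs) timestep comfortably
stable for all default stiffnesses.

## Dynamics

`run_langevin()` integrates with the BAOAB splitting of Langevin dynamics
(defaults: timestep 0.3 units, friction 0.843 inverse units, 300 K), chosen
for its accurate configurational sampling at this friction and step size.
Velocities are Maxwell-distributed at start unless supplied. The kinetic
temperature measured from on-step velocities carries the usual
$O(\omega^2\Delta t^2)$ discretisation bias; with the toy-system
stiffnesses (bond 20, angle 10, dihedral 1; $\omega\Delta t \approx 0.16$)
it is well below one percent, which is why the equipartition check can use
a 2% band. Runs that reach non-finite or absurd potential energies abort
and return the trajectory up to the last stable frame, flagged in the
metadata. `minimize_energy()` (capped steepest descent) removes residual
steric strain from constructed initial structures before production runs.

`run_remd()` runs one replica per temperature rung with neighbour-pair
Metropolis exchanges, acceptance $\min(1, e^{(\beta_i-\beta_j)(E_i-E_j)})$,
alternating even/odd pairings. The exchange interval defaults to 1000 steps
(an unprescribed scheduling choice). Configurations swap with velocity
rescaling by $\sqrt{T_{new}/T_{old}}$; the log records every attempt and a
round-by-round replica map, so per-temperature and per-replica continuous
trajectories are both recoverable. One counter-based generator seed per
replica segment is derived from the run seed and logged.
`free_energy_differences()` estimates dimensionless free-energy differences
between adjacent rungs by exponential averaging with block-averaged errors;
the three-dimensional harmonic oscillator ($\Delta f = \tfrac32 \ln(T_{lo}/T_{hi})$)
is the analytic validation case.

## Binding free energies and sigma calibration

The Q-score is the fraction of native cross contacts formed, a pair
counting when within 1.2x its native distance. The bound state is Q > 0
(even partial native-contact formation counts as bound); a minimum-distance
criterion (default cutoff 10 A) is provided as the robustness alternative,
and on the dimer benchmark the two definitions agree within a few tenths of
a kcal/mol.

From a trajectory confined to a sphere, the standard-state binding free
energy is

$$\Delta G^\circ = -k_BT\left[\ln\frac{P_b}{P_u} + \ln\frac{V_{free}}{V^\circ}\right],$$

with $V^\circ = 1661$ A^3 and $V_{free}$ the confinement volume accessible
to the unbound ligand (the sphere minus the receptor's bounding-sphere
core; both the estimate's components are reported separately, so the
uncorrected convention is recoverable by subtracting the volume term).
Errors come from block averaging over 10 contiguous blocks, and the
estimate carries the sampled transition count with a warning flag below 5
transitions - the single most informative convergence diagnostic for this
estimator. Analysis uses the rung nearest the requested temperature; a
multi-temperature reweighting estimator was considered and deferred, since
single-rung analysis is unbiased and the REMD ladder's role here is mixing,
not reweighting.

`calibrate_sigma()` runs a user-supplied estimation protocol over a sigma
grid and selects the sigma whose free energy lands closest to the target,
returning the full sigma/dG/SE table. The package validates the whole loop
on the dimer benchmark: with single-bead chains the estimator's expected
value has an exact one-dimensional radial quadrature, and re-calibrating
against a point read off a measured dG(sigma) curve recovers the
generating sigma.

## Fork trajectory analytics

All "contacting" analyses use a bead-bead cutoff, default 10 A (a
convention, not a derived value), and every geometric analysis is invariant
under rigid motion of the snapshot. The hub-ring frame has its origin at
the ring's centre of mass; Z is the unit normal of the ring's best-fit
plane (smallest singular vector of the centred ring coordinates), oriented
toward the designated N-tier side; X is the projection of the Mcm2
centre-of-mass direction orthogonal to Z; Y completes the right-handed
frame. Elevation and azimuth of a tracked point are
$\varphi = \operatorname{atan2}(v\cdot Z, v\cdot X)$ and
$\theta = \operatorname{atan2}(v\cdot Y, v\cdot X)$; angle statistics use
circular means and standard deviations because the distributions straddle
the 180-degree cut.

Spatial densities histogram the frame-local tracked point on a regular
grid (default spacing 5 A), normalised by point count times voxel volume so
the grid integral is one. Iso-surfaces (default level 1e-4 per A^3) are
extracted as the polygon mesh bounding the super-level set - the
quadrilateral faces between voxels inside and outside the set. This
voxel-boundary mesh matches the histogram's own resolution; a smoothed
marching-cubes surface would suggest sub-voxel precision the histogram does
not have. Region overlaps are intersection volumes of super-level sets
divided by a chosen reference set's volume; the intersection is symmetric
by construction.

The recycling classifier declares deposition when the cargo's contact count
with a single duplex group stays at or above `n_dep` for at least `t_dep`
consecutive frames while donor-tail contacts stay at or below `n_tail`;
the destination may be the leading, lagging or parental duplex. The
pathway is carrier-mediated iff the cargo-carrier contact count reaches
`n_car` within `window` frames before deposition. Defaults
(n_dep = 30, t_dep = 50 frames, n_tail = 5, n_car = 10, window = 200) scale
with the tens-of-residues contact plateaus a deposited tetramer shows; all
are arguments. The tetrasome dyad is the median distance-from-junction
among destination nucleotides with any site bead within the cutoff of the
cargo - the median is robust to ragged footprint edges, and no alternative
dyad estimator changed any label in the scripted suite. Destination
distances count nucleotides from the fork junction through the
single-stranded gap (the junction nucleotide is zero of each daughter-arm
coordinate); the 3-D junction distance is from the cargo's centre of mass
to the junction base-pair midpoint.

## The synthetic systems, and what passing tests show

`build_toy_replisome()` emulates the statistical structure the analyses
assume: a six-chain ring (solenoid chains on a 35 A circle) defining a
plane, axis and an Mcm2-like sector; an 80-residue disordered tail
(every 4th residue +1 e, every 9th -1 e) anchored to that sector and
carrying a compact, basic four-helix cargo; a 50-residue carrier with a
16-residue all-acidic loop; a fork with 12/24/24 bp duplexes and 6/8 nt
gaps; and optional rigid binders that occlude and lengthen (by 10 nt each)
the lagging gap. Placement is deterministic given the seed, with rejection
sampling that keeps the tail and cargo clear of the carrier and DNA so
that contact-based analyses start from a well-defined "held" state.
Scripted label trajectories move the cargo along piecewise-linear paths
with per-frame Gaussian jitter; every defining event of the classifier is
satisfied or violated with at least a 20% margin relative to the
thresholds, which is what makes 100% label recovery a meaningful
correctness criterion rather than a tuned one.

The toy is not a structural model of the replisome. Passing tests
demonstrate that the energy terms, samplers, estimators and analytics are
correct on systems whose ground truth is known by construction or in
closed form; they do not establish quantitative correspondence with any
real fork's recycling statistics, which emerge only from production-scale
runs of structure-derived systems (supported as configuration through the
PDB pathway, not exercised in the test suite).

## Numerical choices and problem sizes

* Electrostatic truncation: energy shift at 50 A, pair skip at zero charge.
* Degenerate inputs are hard errors with named culprits: missing C-alpha
  atoms, insertion codes, collinear ring selections, zero-distance pairs,
  unbridgeable disordered spans, empty cargo footprints, unsampled bound or
  unbound states.
* Ties in the classifier (two duplex groups qualifying at the same frame)
  resolve to the higher contact count; in practice the margins make ties
  unreachable.
* Test and verification sizes were chosen to give each stochastic check
  statistical headroom at desk scale: equipartition on the 360-bead ring
  over 6e4 steps; replica exchange over 1200 rounds of 200 steps;
  dimer free energies from 8e6-step runs in a 15 A sphere (thousands of
  binding transitions, standard errors well under 0.1 kcal/mol); 42
  scripted trajectories of 320 frames for the classifier at three cutoffs.

## Known limitations

No sequence-dependent DNA mechanics, protonation logic or all-atom
reconstruction; electrostatics are pairwise-screened only (no long-range
solver), appropriate at physiological ionic strength but not at low salt;
binding estimates assume the confinement sphere is the only volume
restriction on the unbound state; the excluded-volume and bonded
stiffness values are conventions of this engine, configurable but not
fitted to data.
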