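---
title: "Methods: implicit-solvent energetics and design for TCR-pMHC interfaces"
author: "tcrforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: implicit-solvent energetics and design for TCR-pMHC interfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcrforge)
```

# Scope

tcrforge evaluates the binding energetics of a T cell receptor (TCR) bound
to a peptide-MHC (pMHC) complex with an implicit-solvent MM-GBSA model, and
builds three analyses on top of it:

* per-residue **binding free energy decomposition** (BFED) and
  **computational alanine scanning** (CAS), with a local-summation
  ΔΔG rule for scoring designed point mutations;
* a **rigid-body orientation scan** that predicts the TCR docking angle
  over the pMHC from long-range polar interactions alone;
* **free-energy estimators**: thermodynamic integration (TI) over a λ
  grid with endpoint extrapolation, and Jarzynski work averaging (direct
  exponential and second-order cumulant), with potential-of-mean-force
  (PMF) reconstruction from steered-work profiles and a 1-D overdamped
  toy simulator that generates such profiles.

Everything operates on plain PDB input (single model or multi-MODEL
ensembles standing in for trajectory frames) plus a bundled residue
parameter table. Deterministic synthetic fixtures make every module
testable without any external download.

# The energy model

## Terms and conventions

The binding free energy is assembled as the gas-phase interaction
(electrostatic + van der Waals), plus the desolvation free energy
(Generalized Born electrostatics + a surface-area nonpolar term):

$$\Delta G_\mathrm{bind} = \Delta H_\mathrm{elec} + \Delta G_\mathrm{vdW}
  + \Delta G_\mathrm{elec,solv} + \Delta G_\mathrm{np,solv}
  \,(+\,\Delta H_\mathrm{intra} - T\Delta S)$$

All energies are kcal/mol, lengths Å, charges elementary. The package
uses the *single-trajectory* scheme throughout: complex and isolated
partners are evaluated on the same coordinates (frames), so the
conformational reorganisation term is identically zero, and the Δelec and
ΔvdW terms reduce exactly to the inter-partner pair sums. Vibrational /
rotational / translational entropies are not computed; `binding_energy()`
accepts an externally supplied `entropy` value (as $-T\Delta S$, kcal/mol)
that is simply added to the total. Ranking residues and designs without
the entropy term is the intended default use.

Each term is the arithmetic mean over frames; a single structure is a
valid one-frame ensemble.

## Electrostatics and solvation

* Coulomb: $k_C q_i q_j / (\varepsilon_\mathrm{in} r_{ij})$ with
  $k_C = 332.0637$ kcal·Å/(mol·e²); no distance cutoff (all sums are
  exact at the problem sizes this package targets).
* Lennard-Jones 12-6 with $r_{min,ij} = r_{min/2,i} + r_{min/2,j}$ and
  $\varepsilon_{ij} = \sqrt{\varepsilon_i \varepsilon_j}$.
* GB: the pairwise form with the standard smooth interpolation
  $f_{GB} = \sqrt{r^2 + a_i a_j e^{-r^2/4a_ia_j}}$, self terms included.
  Effective radii come from the Hawkins–Cramer–Truhlar pairwise
  descreening approximation (offset 0.09 Å, element-wise scale factors),
  recomputed *within each subset*: removing one partner changes the
  descreening of the other, which is precisely the desolvation physics the
  binding difference needs. Degenerate inverse radii are capped at a large
  effective radius rather than allowed to go negative.
* Defaults: $\varepsilon_\mathrm{in} = 1$, $\varepsilon_\mathrm{out} = 78.5$;
  all exposed through `dielectric_model()`. A Poisson–Boltzmann solver is
  deliberately out of scope; GB is the model this toolkit validates.
* Nonpolar solvation: $\gamma \cdot \mathrm{SASA} + b$ with the
  conventional $\gamma = 0.00542$ kcal/mol/Å², $b = 0.92$ kcal/mol, probe
  1.4 Å (`nonpolar_params()`). The intercept $b$ is treated as a
  per-solute-molecule constant: it contributes to the *absolute* solvation
  of a system (`effective_energy()`) but cancels in binding differences.
  Differencing it instead would leave a spurious constant $-b$ in every
  ΔG, visible immediately in the no-interaction limit (partners at
  infinite separation must give ΔG → 0).

## SASA

Solvent-accessible surface areas use a Shrake–Rupley quadrature with a
deterministic Fibonacci point set (512 points per atom by default), heavy
atoms only (hydrogens carry zero area in the united-atom convention).
The point set is oriented in a *body-fixed frame* (gyration eigenvectors
with third-moment sign canonicalisation), which makes the numerical SASA
exactly invariant under rigid rotations of the input for generic
structures — a fixed lab-frame point set would drift by a few tenths of
an Å² under rotation. Near-symmetric structures whose third moments
vanish fall back to the lab frame.

# Parameterisation

The bundled table (`default_parameter_table()`) is a self-contained
united-atom protein set: heavy atoms plus explicit polar hydrogens, with
partial charges, LJ parameters and intrinsic Born radii for the 20
standard amino acids. Charges sum exactly to the formal charge of every
template. The table is an input, not a constant: any TSV with the same
columns passes `read_parameter_table()` validation and can be swapped in.

`assign_parameters()` accepts structures without hydrogens (the common
case for crystallographic PDB files) and constructs the polar hydrogens
by ideal geometry from per-template internal coordinates; hydrogens
present in the input but absent from the united-atom table (nonpolar
hydrogens of all-atom files) are dropped with a warning. Unknown residues
either abort or are excluded from scoring (`unknown_policy`). The
operation is idempotent.

Alternate locations resolve to the highest-occupancy conformer (ties to
'A'); residue identity is (chain, author residue number, insertion code)
and is never renumbered.

# Decomposition, scanning, and design scoring

## BFED

The pairwise decomposition attributes every inter-partner pair term
(Coulomb, LJ, GB cross terms) half to each pair member's residue; GB self
terms and intra-partner differences, and per-atom SASA changes, go to the
owning residue. Implementation-wise each symmetric ordered-pair energy
matrix is reduced by row sums, which performs the half/half split and
makes the conservation identity — residue contributions summing exactly
to the binding total — hold to rounding error on every fixture and frame
count. Negative contribution = the residue favours binding.

## CAS

`alanine_scan()` truncates each scanned residue to alanine
(`build_alanine_mutant()`: side chain cut at Cβ, backbone untouched, all
frames mutated consistently) and recomputes the binding energy:
ΔΔG = ΔG(mutant) − ΔG(wild type), so positive = the side chain favoured
binding. GLY/PRO/ALA are skipped with a warning. The wild type and mutant
share frames — no re-simulation is attempted, which is also the main
accuracy limitation for residues whose removal would trigger
conformational rearrangement.

`compare_cas_bfed()` correlates the two per-residue measures; because a
favourable residue is *negative* in BFED and *positive* in CAS, the BFED
column is negated by default before the Pearson correlation
(`bfed_sign = -1`).

## Designed mutations

`build_point_mutant()` grows the new side chain by ideal internal
geometry, keeping the backbone and any shared side-chain stem at
wild-type coordinates (shared χ angles are measured from the wild type),
and choosing among a small canonical rotamer library (≤ 9 χ combinations
per type) the rotamer with least hard-sphere overlap; a mutation whose
every rotamer clashes (pair distance < 0.6 × the vdW-radius sum) is
rejected with the clash list. This is a deterministic minimal scheme —
a stand-in for side-chain packing, not a reconstruction of any published
protocol, and a documented limitation.

`ddg_mutation()` scores a design by the local-summation rule: the sum of
per-residue contribution changes over the mutated residue and every
residue (either partner) with a heavy atom within `contact_cutoff`
(default 4.5 Å, config-exposed) of the site in either structure. The
local sum suppresses noise from distant residues; with the cutoff at
infinity it reduces exactly to the full-sum difference, which is its
audit. Negative ΔΔG = improved binding — stated in every output header.
`kd_fold_change()` converts measured dissociation constants to the
experimental-side quantities (fold improvement, $RT\ln$ fold).

# The orientation scan

`rigid_scan()` implements the rigid displacement protocol: the receptor
is translated 6–12 Å away from the ligand along the receptor's principal
axis, then rotated about that axis through its (displaced) center of mass
over a full revolution in 5° steps, the ligand staying fixed. At every
grid point the effective energy is evaluated; in the default polar mode
that is the inter-partner Coulomb term plus the whole-system GB
solvation — no vdW, no surface term — because the long-range polar field
is what carries the orientation signal. Poses with any inter-partner
heavy-atom pair closer than 0.5 × the vdW-radius sum are flagged and
excluded from the minimum search. Angle 0 is the input pose, so for a
bound crystal structure the located minimum directly measures the angular
shift from the native orientation (`angular_shift()` gives the minimal
circular difference).

Design choices the protocol leaves open, decided here:

* **Axis**: the gyration-tensor eigenvector best aligned with the
  receptor→ligand center-of-mass vector, sign-oriented toward the ligand.
  A near-spherical receptor (eigenvalue spread < 1%) is an error that
  asks for an explicit axis; the `axis` argument also serves flat,
  disk-like inputs — including this package's own toy fixtures — whose
  principal axis is geometrically ambiguous.
* **Rotation center**: the receptor center of mass after translation.
* **Tie-breaks**: the grid minimum prefers the smallest angle, then the
  smallest distance; the reported margin is the gap to the lowest point
  more than one angle step away.

`subgroup_contributions()` decomposes the inter-partner polar profile
over receptor groups defined by region tags (CDR1/2, CDR3, framework by
default). Group profiles sum to the total profile at every angle. Each
group's `share` of the orientation signal is its profile variance as a
fraction of the summed group variances — a number in [0, 1] summing to 1
over groups. The raw ratio against the total profile's variance is also
returned (`var_ratio`), but it is ill-conditioned as a dominance
statistic: covariance terms make it fluctuate around (and beyond) 1 for a
dominant group even when every other group is negligible.

# Free-energy estimators

## Thermodynamic integration

`ti_integrate()` applies the trapezoidal rule over the supplied λ grid
(the classic 11-point grid 0.02, 0.1, …, 0.9, 0.98 is available as the
`"paper11"` preset of `make_lambda_series()`), with the unsampled end
segments handled by one of three extrapolation models fitted to the
nearest grid points: a line (2 points), a parabola (3 points), or the
singular form $a + c\,\lambda^{-3/4}$ (2 points; mirrored in $1-\lambda$
at the top). The pow34 local model *also* covers the outermost grid
interval, which it interpolates by construction. That choice is what
makes the scheme accurate for integrands diverging like $\lambda^{-3/4}$
at an endpoint (the known behaviour of the Hamiltonian derivative when
atoms vanish without soft-core potentials): a plain trapezoid on the
first interval of such an integrand is the dominant error source and no
tail-only fit can repair it — on the 11-point grid the tail-only variant
misses the analytic reference $\int_0^1 \lambda^{-3/4} d\lambda = 4$ by
8%, while the local-model variant is within 0.7% and remains exact for
constant and linear integrands under every scheme. The reported
uncertainty is the propagated per-point standard error (trapezoid
weights) plus half the spread across the three schemes.

## Jarzynski estimators

For work values $W$ (kJ/mol; the TI path uses kcal/mol and the two never
mix — containers carry unit tags):

* `ji_direct()`: $-\beta^{-1}\ln\langle e^{-\beta W}\rangle$, evaluated
  with a log-sum-exp contract so $|\beta W|$ up to $10^4$ cannot
  overflow. Jensen's inequality guarantees the estimate never exceeds the
  sample mean.
* `ji_cumulant()`: $\bar W - \tfrac{\beta}{2}s^2$ with the unbiased
  (n−1) sample variance — exact for Gaussian work.

`pmf_from_work()` applies either estimator at every point of the shared
reaction-coordinate grid and anchors $G(\xi_0)=0$. The work is attributed
at the guide position (the stiff-spring approximation); the full
time-dependent histogram-reweighting treatment used with soft guiding
potentials is an extension point, not silently approximated.

`steered_toy_simulate()` is a 1-D overdamped Langevin system pulled by a
harmonic guide moving at constant speed, with the external work
accumulated as $dW = -k_g (x - z)\,v\,dt$ (pulling against resistance
gives $W > 0$). It exists to generate work ensembles with controlled
ground truth: a flat potential has an identically zero PMF; a harmonic
well pulled quasi-statically reproduces $\tfrac12 k(\xi-\xi_0)^2$; fast
pulling dissipates. A stability guard rejects
$k_g\,dt/\gamma_f \ge 0.5$.

## The finite-sample bias phenomenology

The shifted-gamma work generator
(`make_work_ensemble("shifted-gamma")`) emulates strongly dissipative
protein–protein unbinding at 300 K: defaults shape 30, scale 6 kJ/mol,
shift 5 kJ/mol give work of order $10^2$ kJ/mol, dissipation far
exceeding $k_BT$, a distribution near-Gaussian in its central part but
with a shorter-than-Gaussian lower tail — the regime in which, at ~150
trajectories, direct exponential averaging *overestimates* the exact
free energy (the dominant low-work region is never sampled) while the
cumulant expansion *underestimates* it (the Gaussian assumption imputes
a longer lower tail than the distribution has). The family is chosen
because its exact Jarzynski free energy is available in closed form,
$\Delta G = s + (k/\beta)\ln(1+\beta\theta)$, so both bias directions are
measured against an analytic truth rather than a simulation.

# Synthetic fixtures

`make_toy_complex()` builds a miniature TCR-pMHC-like complex encoding,
by construction, the statistical and geometric structure the analyses
assume — and nothing more. Its components:

* a ligand "MHC" chain carrying a ring of eight ±1-charged residues
  (LYS/ASP, radius 14 Å) in a seed-derived aperiodic pattern with at
  least three of each sign, and a complementary ring on the receptor's
  CDR1/2-tagged loops. The complementary rings close an electrostatic
  lock at a known rotation angle; site charge centers are kept on their
  site azimuths (side-chain spins minimise the charge's tangential
  spread) and both CA rings are coplanar, so the angular energy profile
  is even about the lock by symmetry. The bridge tips face each other at
  5.5 Å: the ring is long-range orientation machinery, outside the
  contact interface.
* a four-leucine "peptide" engaged by four receptor CDR3-tagged nonpolar
  patches of graded strength (MET, MET, ILE, LEU at calibrated vdW
  gaps) plus a no-contact serine. These patches are the interface's
  genuine hotspots: van der Waals contacts are not screened by the
  solvent model, whereas a solvent-exposed salt bridge is nearly
  free-energy-neutral under GB (its Coulomb gain and desolvation penalty
  cancel) — which is also why alanine scans of charge-dominated toy
  interfaces are dominated by Born-radius relaxation terms that a
  wild-type-only decomposition cannot contain. A packing-dominated
  contact interface with graded magnitudes is the regime in which CAS
  and BFED agree, as they do on real interfaces.
* a framework counterweight residue placed so the receptor's lateral
  center of mass sits exactly on the ring axis (the scan rotates about
  the receptor COM; an offset would skew the angular landscape).

Every fixture is byte-reproducible from its seed, ships a JSON truth
sidecar (native angle, construction axis, charge pattern, hotspot ids)
next to the PDB and a region-map YAML, and is screened for hard clashes
(with bonded and same-partner ring neighbours exempt; placement is
regenerated with fresh jitter up to a bounded number of attempts).

What the fixtures do **not** emulate: real protein topology (residues
are disconnected), conformational response to mutation, shape
complementarity, or a prolate receptor body — the toy receptor is a flat
loop disk whose inertia axis is deliberately ambiguous, so scans of toys
should pass the recorded construction axis. Passing tests on fixtures
therefore validates the machinery and its invariants, not predictive
accuracy on real TCR complexes.

# Hydrogen-bond and contact maps

`detect_hbonds()` uses a purely geometric criterion — donor-acceptor
distance ≤ 3.5 Å and donor-H···acceptor angle ≥ 120°, both config-exposed
via `hbond_criteria()` — with donors/acceptors from bundled per-template
tables; polar hydrogens must be present (they are built at
parameterisation). `detect_np_contacts()` reports carbon/sulfur pairs
across the interface within 4.5 Å. `occurrence_map()` bins a labelled
ensemble by a separation coordinate ξ and reports, per bin, the fraction
of frames in which each interacting pair exists; ξ labels are caller
metadata, so the module works for any ensemble source. Loosening the
distance cutoff can only add detections (monotonicity), and a single-bin
map equals the plain frame average.

# Problem sizes and numerical choices

The bundled test-suite and the acceptance script run at desk scale by
design: toy complexes of ~250 atoms, 20 fixture seeds for conservation
and orientation recovery, six fixtures (48 residues) for the CAS/BFED
correlation, $10^5$ Gaussian work samples, and 150-trajectory dissipative
ensembles (the trajectory count a steered-dissociation study would use).
Exact $O(N^2)$ nonbonded sums, 512-point SASA quadrature and full 72 × 4
orientation grids are comfortable at these sizes.

Other numerical decisions: grid-minimum tie-breaks prefer smaller angles
then smaller distances; HCT inverse radii are capped; coincident atoms
(r < 10⁻⁶ Å) abort pair sums; the λ grid must lie strictly inside (0, 1);
work profiles must start at zero; the toy integrator refuses unstable
time steps.

# Known limitations

* No Poisson–Boltzmann reference, no explicit solvent, no entropy
  calculation (external hook only), no kinetics.
* Single-trajectory mutants: no conformational relaxation upon mutation;
  outliers are expected exactly where a real side chain would repack.
* The rotamer library is minimal and the built geometry idealised;
  mutants at buried sites should be treated as hypotheses, not
  structures.
* Numerical SASA rotation-invariance relies on a generic (asymmetric)
  structure; highly symmetric synthetic inputs fall back to the lab
  frame.
* The GB flavour is HCT-style pairwise descreening; other flavours can be
  added behind `dielectric_model()`/`born_radii()` but are not included.
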