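---
title: "Methods: steered pulling of peptides through a model bilayer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: steered pulling of peptides through a model bilayer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the models implemented in `pepsmd`, the choices
behind their parameters, and what the desk-scale test systems do and do
not demonstrate about real peptide–membrane systems.

## The physical model

The engine integrates classical equations of motion
$m_i \ddot{r}_i = -\partial U/\partial r_i$ for a potential

$$U = U_\text{bonds} + U_\text{angles} + U_\text{torsions} +
      U_\text{impropers} + U_\text{LJ} + U_\text{Coulomb},$$

with harmonic bonds and angles ($K(r-r_0)^2$, $K(\theta-\theta_0)^2$),
cosine torsions ($\tfrac{V}{2}(1+\cos(n\phi-\gamma))$), harmonic
impropers, and nonbonded terms truncated at a cutoff under the
minimum-image convention. Both nonbonded potentials are *shifted* so the
energy is continuous at the cutoff; the force retains the usual small
truncation discontinuity there. There is no Ewald/PME electrostatics:
at the package's system sizes and with the modest partial charges of the
toy parameter set, mesh electrostatics would dominate runtime without
changing the qualitative force response. This is a documented
limitation, not an approximation that can be refined away within the
package.

Units are Å, ps, Da and kcal/mol internally; user-facing spring
constants and recorded forces use kJ/mol/Å, the unit most SMD literature
reports.

### Steering

Constant-velocity pulling attaches a spring of stiffness $k$ between a
moving wall ($x_w = x_0 + vt$ along a unit direction) and either

- **terminal-atom mode**: the full force $F = k\,\Delta x$ acts on one
  atom (the leading heavy atom in the pulling direction), or
- **center-of-mass mode**: the force is distributed over the pulled set
  in proportion to mass, $F_i = k\,\Delta x\, m_i/\sum_j m_j$, which
  accelerates the center of mass exactly as a point mass on the spring
  would.

The membrane is restrained by the identical center-of-mass machinery at
zero wall velocity, so the recorded "membrane force" is the restraint's
spring force — the membrane's reaction to being pushed. By construction
the two modes coincide for a single-atom pulled set, and the distributed
forces sum exactly to $k\,\Delta x$; both identities are asserted in the
test suite.

The wall starts slack ($\Delta x = 0$ at $t = 0$). A pre-tensioned start
would only shift the first few picoseconds of the trace.

### Collisional thermostat

Temperature is controlled by stochastic collisions: each atom, with
probability $\nu\,\Delta t$ per step, undergoes an elastic collision
with a virtual particle of mass $m_0$ whose velocity is drawn from the
Maxwell distribution at the target temperature,
$v' = \frac{(m - m_0)v + 2 m_0 u}{m + m_0}$. The stationary velocity
variance of this map is exactly $k_BT/m$, so the thermostat recovers the
target temperature without feedback loops, and—unlike velocity
rescaling—produces a canonical Maxwell distribution (checked by a
Kolmogorov–Smirnov test in the suite). The thermostat internals are not
universal constants; the defaults $m_0 = 18$ Da and $\nu = 10$ ps$^{-1}$
give a coupling time of ~0.1 ps, strong enough to hold 350 K against the
steady work input of pulling, and both are configurable.

### Integration

Velocity Verlet with $\Delta t = 0.001$ ps, the conventional step for
all-atom MD with ~300 kcal/mol/Å² bond constants (about 40 steps per
bond vibration period here). Positions are kept unwrapped internally;
periodicity enters exclusively through minimum-image displacement
vectors in every interaction. This keeps molecule centers of mass and
the pulled-group coordinate continuous across the box boundary; wrapped
coordinates are produced on output.

## System construction

The builder follows an affine-replication recipe: one lipid template is
translated onto an $n_y \times n_z$ grid in the membrane plane (OY–OZ;
the membrane normal is OX), the monolayer is copied and rotated 180°
about OY — a *proper* rotation $(x,y,z)\to(-x,y,-z)$, since a mirror
reflection would invert lipid chirality — and the two leaflets are
placed tail-to-tail. The peptide is built as an extended chain
($\varphi,\psi = -135°, 135°$ by default; a "linear" conformation,
configurable) with an H cap on the free N-terminus and an OH (OXT) cap
on the C-terminus, aligned with the membrane normal and placed in the
water region above the upper head plane. Water is a 3-site model placed
on a cubic lattice (3.1 Å spacing ≈ bulk density) with clash-based
deletion.

Geometry defaults worth knowing:

- `lipid_spacing` 6 Å: the grid constant; chosen so neighboring
  template copies stay beyond the 2 Å clash cutoff with several Å of
  vdW clearance.
- `tail_gap` 3 Å between the leaflets' tail planes. A smaller gap would
  put opposing terminal tail atoms inside the clash cutoff for
  straight-tail templates; 3 Å is approximately carbon–carbon van der
  Waals contact, and the gap closes during dynamics.
- The box spans `n_y*spacing` × `n_z*spacing` in the membrane plane
  (periodic continuity of the lattice) and lipid extent plus
  `water_padding` along the normal.

Two lipid templates are packaged, both generated by package code:
a 12-site single-chain *mini-lipid* (3 charged head sites, 9 tail
carbons) used for all dynamics tests — its head sites are coarse beads
standing for whole choline, phosphate and ester groups and therefore
carry group-sized Lennard-Jones radii (4.3/4.6/3.4 Å) rather than
single-atom ones — and a 52-heavy-atom idealized
POPC geometry (`popc_synthetic.pdb`) for exercising the builder at
realistic atom counts. The POPC coordinates are synthetic — idealized
zigzag chains, not an experimental or equilibrated structure — and are
labelled accordingly.

The toy forcefield assigns one LJ type per element, a single bond and
angle force constant with equilibrium values taken from the as-built
geometry (so every built structure starts at its bonded minimum), a
small threefold torsion barrier, and the template partial charges with
name-based backbone overrides. It is a *minimal parameter set for
method development and testing*, not a calibrated forcefield; absolute
forces from it are not comparable to published all-atom AMBER values,
which is why the packaged force-maxima table is exercised analytically
rather than regenerated.

## Descriptors

All descriptor tables are data-driven (`scale_tables()`):

- **pKa set.** The default is Sillero–Ribeiro. The study peptides'
  printed isoelectric points match this set at the printed precision
  (e.g. the P2 fragment EMEVVVLNID: Sillero 3.43 → prints 3.4, whereas
  the simple Bjellqvist table gives 3.6). Bjellqvist, EMBOSS and
  IPC-peptide sets are packaged and swappable.
- **Hydrophobicity.** Eisenberg consensus normalized scale; the
  hydrophobic moment uses δ = 100° (α-helical periodicity) by default,
  exposed because the built peptides are extended, not helical.
- **Instability index.** The published 20 × 20 dipeptide weight matrix,
  packaged as TSV.
- Molecular weight uses average residue masses plus one water; free,
  ionizable termini are assumed throughout, matching the builder's
  H/OH capping.

### The headline correlation

`correlate_descriptors()` reports a Pearson r for every
(descriptor, mode, velocity) cell over whatever peptide set it is
given. With the full 13-peptide roster (amyloidogenic fragments plus
homo-repeats), no descriptor reaches |r| = 0.9 against the packaged
force maxima; restricted to the seven amyloidogenic peptides, the
instability index exceeds 0.9 in every center-of-mass column, strongest
at the lowest velocity. The acceptance check therefore uses the
amyloidogenic subset, and the full-roster cells are always reported so
the restriction is visible rather than silent. Cells with fewer than 3
shared peptides or zero variance are reported missing.

## The experiment matrix

The default plan mirrors the published design: 8 peptides × 2 modes ×
3 velocities (0.1, 0.05, 0.01 Å/ps) × 8 replicates in the main block;
an auxiliary block of 22 series × 8 replicates, decomposed as 5
homo-repeats × 2 modes × 2 velocities (the lowest rate was not run for
homo-repeats) plus the two lipid-pull series; and a control block
repeating two peptides (P2 and P4) over all six conditions. The
auxiliary decomposition and control roster are configuration, not code,
because the source design is stated only in aggregate; this default is
the unique decomposition consistent with both the block subtotals and
the populated cells of the published force table. Per-run seeds come
from a polynomial hash of (master seed, run id) over the Mersenne prime
2³¹−1: platform-independent, stable, and collision-free over the full
plan (asserted in tests).

## The desk-scale demonstration

`demo_pull_run()` is the package's scaled-down reproduction of the
qualitative pulling phenomenology: a 3 × 3 × 2 mini-lipid bilayer
(box edge 18 Å in the membrane plane, nonbonded cutoff reduced to
8.5 Å so the minimum-image convention stays valid; all other defaults
unchanged), a three-residue peptide, center-of-mass pulling at
0.1 Å/ps and 350 K for 300 ps — enough for the peptide to pass from the
water gap through both leaflets. The spring is stiffened to
50 kJ/mol/Å² for this demonstration: thermal fluctuation of the spring
extension contributes force noise of magnitude $\sqrt{k_B T\, k}$, so a
soft spring buries the membrane signal, while an overly stiff one
amplifies it; 50 keeps the quasi-static lag under ~1 Å at the observed
resistance. Peak location uses a ~5 ps moving-average smoothing window
for the same reason; raw maxima remain the default elsewhere
(`max_force(window = 1)`), since no smoothing protocol is canonical.

What the demonstration shows: the smoothed force maximum occurs *inside
the bilayer* — after the peptide center of mass has crossed the upper
head plane, never in the water gap where only spring noise acts — and
the peptide and membrane force series are anticorrelated over the
penetration window. A caveat is documented deliberately: in this
vacuum, single-chain-lipid system the peak tends to sit near the
tail–tail interface rather than strictly at the head-group slab,
because the toy system has no desolvation cost at entry and nearly
uniform tail density; the strict entry-boundary localization seen in
solvated all-atom systems is beyond this scale. What the demonstration
also does not show: absolute force magnitudes (toy forcefield, no water
in the demo run, coarse lipid), velocity trends (one velocity), or
replicate statistics. Those claims are exercised analytically against
the packaged published table instead.

## Numerical choices and degenerate inputs

- Nonbonded pair enumeration is a brute-force $O(N^2)$ minimum-image
  loop in C++. At the package's design sizes (≤ ~1000 atoms) this is
  faster in practice than maintaining a cell list, and it is a single,
  fully tested code path; analytic forces are asserted against central
  differences to 10⁻⁴ on randomized systems.
- Exclusions: 1–2 and 1–3 pairs are excluded from nonbonded terms; 1–4
  pairs interact at full strength (no scaling, documented).
- Overlapping *interacting* atom pairs (< 0.1 Å) abort integration with
  an error naming the atoms; non-interacting crossings (e.g. ideal-gas
  tests) are legal.
- Aggregation: empty cells are missing (NA), never zero; single-replicate
  cells report SD 0.
- Grouping: 1-D k-means with ordered quantile initialization, so the
  result is deterministic; ≤ k classes are returned when values tie,
  and the class labels are order-isomorphic to the means by
  construction. No single threshold rule can reproduce the published
  verbal grouping exactly (two peptides share an identical mean yet are
  named in different classes), so grouping is reported with its
  thresholds rather than asserted beyond the weakest-class membership.
- Bisection for pI runs on (0, 14) to |Z| < 10⁻⁴; net charge is
  strictly decreasing in pH, so the root is unique.
- All stochastic operations take explicit seeds; fixed seed implies
  bit-identical trajectories (asserted). Rebuilding with a different
  compiler may change trajectories after ~10 ps through floating-point
  reordering and chaos, which is inherent to MD, not a defect; the
  qualitative summaries are stable across seeds.

## Known limitations

- No NPT ensemble/barostat: systems are built at fixed volume and run
  NVT. Membrane area per lipid is therefore set by construction, not by
  pressure equilibration.
- No mesh electrostatics; shifted-potential truncation at the cutoff.
- The toy forcefield is intentionally minimal; real parameter files can
  be supplied in the documented YAML format, but regenerating published
  all-atom force magnitudes is out of scope.
- Side-chain geometry is idealized (extended χ angles, approximate
  rings); adequate for excluded-volume and pulling phenomenology, not
  for structural analysis.
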