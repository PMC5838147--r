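---
title: "Methods: ensemble polar surface area and peptide pharmacokinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble polar surface area and peptide pharmacokinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sapsa)
```

## The descriptor

Passive membrane permeability of cyclic peptides correlates poorly with
the conventional topological polar surface area (PSA), because PSA sums
tabulated fragment contributions and ignores the 3D structure entirely.
The descriptor implemented here — the solvent-accessible polar surface
area, SAPSA — repairs both shortcomings:

* the surface is the *accessible* (probe-center) surface: the area
  traced by the center of a water-sized probe sphere (radius 1.4 Å)
  rolling over the van der Waals spheres, i.e. areas measured on
  spheres of radius $r_i + 1.4$ Å.  It is **not** the contact surface
  on the atoms themselves;
* the polar atom set is all nitrogen, all oxygen, and every hydrogen
  bonded to one of them.  Apolar atoms still occlude the polar
  spheres — this is precisely the shielding mechanism (intramolecular
  hydrogen bonding, steric masking by side chains) that makes a
  conformer less polar than its topology suggests;
* the per-conformer value is averaged over a conformational ensemble,
  so a molecule whose polar groups are buried most of the time scores
  low even if individual conformers expose them.

For a conformer with coordinates $x_i$ and expanded radii
$R_i = r_i + r_\mathrm{probe}$, the accessible area of atom $i$ is
$4\pi R_i^2$ times the fraction of its sphere farther than $R_j$ from
every other atom $j$; SAPSA is the sum over polar atoms.  Empirically,
for cyclic hexapeptide scaffolds of this class, ensemble-mean SAPSA
below 80 Å² indicates high passive permeability and above 150 Å² low
permeability; `classify_permeability()` places both boundary values in
the intermediate class (a documented tie-break, since the thresholds
are stated as strict inequalities on either side).

## Surface integration: numerical choices

* **Shrake–Rupley with deterministic points.**  Each expanded sphere is
  sampled with `n_sphere_points` (default 960) golden-spiral points —
  deterministic, quasi-uniform, centroid within $10^{-4}$ of the
  origin — so results are bit-reproducible.  Doubling the point count
  moves totals by well under 0.5 % on the bundled fixtures; the test
  suite holds the engine within 1 % of an independent Monte-Carlo
  surface integration with random directions.
* **Tie-break.**  A test point exactly at distance $R_j$ from an
  occluder counts as exposed.  The case has measure zero; fixing it
  keeps the engine deterministic across platforms.
* **Canonical pose.**  Before integration, coordinates are moved to a
  canonical pose: centroid at the origin and axes along principal axes,
  with signs fixed by a rotation-invariant functional (the largest
  anchor projection).  This makes areas *exactly* invariant under
  rigid-body motion of the input, which a fixed space-frame point set
  cannot achieve on its own.  The pose is anchored to the **polar**
  atoms whenever at least three of them span a stable frame: the polar
  subgeometry is untouched by apolar side-chain edits, so the original
  and the truncated trajectory are integrated with literally the same
  discretization and per-frame differences reflect occlusion only.
  With fewer (or degenerate) polar atoms the anchor falls back to all
  atoms.
* **Radii.**  Bondi van der Waals radii (C 1.70, N 1.55, O 1.52,
  H 1.20, S 1.80 Å) ship in `inst/extdata/bondi.yaml` and are fully
  overridable; no radius is defaulted silently at compute time.
  Element symbols in user YAML must be quoted (`"N"`, `"Y"` are YAML
  booleans when bare).
* **Hydrogens are required.**  The polar-H rule needs explicit
  hydrogens; structures without them are rejected with a message rather
  than silently protonated — protonation is out of scope.
* **Bonds.**  Precedence is CONECT records, then a user bond file
  (0-based pairs), then distance inference
  ($d \le 0.6\,(r_i + r_j)$ on the vdW table, tolerance 0 Å): the
  truncation machinery needs reliable bonds, so explicit sources win.
  Every hydrogen must end with exactly one bond or the structure is
  rejected with the offending atoms named.

## Ensemble statistics

`ensemble_sapsa()` reports the mean and the *population* standard
deviation (divisor $n$) of the per-frame SAPSA, plus means/SDs over
consecutive non-overlapping blocks.  The block size is expressed in
frames and defaults to 1000: a 20 ns trajectory stored as 20,000
frames then yields 1 ns block averages, the conventional way to
visualise slow conformational drift.  Because the spread convention
behind published "±" values is often unstated, both the frame-level SD
and the block-level series are reported; for equal-sized blocks the
block means average back to the global mean exactly.

Dominant conformers come from leader clustering on heavy-atom,
best-fit (Kabsch) RMSD in frame order with a 1.0 Å default cutoff —
deliberately the simplest deterministic clustering that yields a
dominant cluster and a representative (the member with minimal mean
RMSD to its cluster).  Frame order dependence is inherent to leader
clustering and accepted for reproducibility.

## The truncation decomposition

To separate *direct shielding* by a side-chain group from its
*indirect, conformational* effect on the scaffold,
`truncate_side_chain()` edits a trajectory in place: the hydrogens of a
terminal heavy atom are deleted, the atom becomes the replacement
element (default H), and it is repositioned along the old bond vector
at 1.09 Å (a standard C–H length; the geometry rule is a package
choice).  Applied to an ethyl (2-aminobutyryl) side chain this yields
the alanine analogue *on the donor's own scaffold geometry*.  With
ensembles $A$ (larger chain), $B$ (smaller analogue, independently
sampled) and $A_t$ (A truncated):

* direct shielding $= \overline{A_t} - \overline{A}$,
* conformational $= \overline{B} - \overline{A_t}$,

and the two sum to $\overline{B} - \overline{A}$ by construction (the
identity is asserted numerically, not assumed).  Removing occluders
can only expose polar atoms, and the replacement hydrogen's occlusion
sphere is geometrically contained in the replaced carbon's, so
per-frame SAPSA never decreases under the edit — a property the test
suite checks frame by frame.

## What the synthetic generators emulate — and what they do not

The conformer sampler (`sample_ensemble()`) is a seeded torsional
Metropolis chain: one random torsion proposal per recorded frame, a
soft-sphere clash penalty
$E = s\sum \max(0,\,0.8(r_i+r_j)-d_{ij})^2$ over non-bonded pairs
(1–2/1–3 excluded, their distances are torsion-invariant) minus a
reward per polar-H···N/O contact under 2.5 Å, and Metropolis
acceptance at 300 K.  Its contract is to produce topologically valid,
seeded, conformationally diverse ensembles for pipeline testing.  It
is **not** molecular dynamics: the energy model is intentionally
minimal and non-physical, there is no solvent model, no ring-closure
move (ring torsions are rejected), and no thermodynamic observable
should be read off it.  The MD settings a production study would use
(implicit water, dielectric 80, Langevin friction 1/ps, 20 ns /
20,000 frames) are carried only as provenance metadata.

`make_two_state_fixture()` is the controlled stand-in for a peptide
whose polar backbone alternates between shielded and exposed states: a
hand-built mini-molecule in which a mobile apolar carbon either parks
far from everything or hovers over the amide-like polar group.  The
blocker height is solved by a 1-D root-find so the polar-area gap
between states equals `delta_area` (default 30 Å², mid-range of what a
single occluder can hide); states are i.i.d. draws, so the ensemble
mean has the closed form $p\,A_{exp} + (1-p)\,A_{sh}$ with both state
areas computed exactly by the engine.  The Abu-like methyl deliberately
has no sight line to any polar atom, which pins the direct-shielding
component at zero and makes the conformational component the whole
side-chain effect.  Passing tests on these fixtures demonstrates the
*machinery* (integration, editing, statistics) — not force-field
realism: real ensembles have correlated frames, many more states and
force-field-dependent populations, so absolute SAPSA values from real
trajectories are not reproduced here, only the defined arithmetic on
whatever ensemble is supplied.

## Non-compartmental pharmacokinetics

`nca()` computes the standard model-free parameters.  Choices that are
genuinely open in practice and fixed here:

* **AUC** defaults to linear-up/log-down trapezoids (exact on
  mono-exponential decline); a pure linear method is selectable.
* **Terminal slope** is the best adjusted-$r^2$ log-linear fit over
  candidate terminal windows of at least 3 quantifiable points after
  Tmax; flat or rising windows are flagged unreliable rather than
  silently used.
* **Bolus C0.**  When an i.v. bolus profile starts after $t=0$, C0 is
  back-extrapolated log-linearly through the first two declining points
  and the $[0, t_1]$ segment enters AUC/AUMC; without it, clearance on
  a 0.08–24 h sampling design is biased high by the missed early area.
  Cmax/Tmax always come from observed points only.
* **BLQ rule** (LLOQ-censored values): leading BLQ are set to 0,
  embedded and trailing BLQ are dropped with a note; `drop_all` and
  `zero_all` are selectable.  All-BLQ profiles are an error.
* **Units.**  ng/mL ↔ nM conversion requires an explicit molecular
  weight; it is never guessed.  CL is reported in mL/min/kg, Vss in
  L/kg ($V_{ss} = CL \cdot MRT$), oral bioavailability as
  $100 \cdot AUC_{dn}(oral) / AUC_{dn}(iv)$ from dose-normalized AUCs.

The hepatic first-pass effect from paired portal/jugular sampling is
$100\,(1 - AUC_{jug}/AUC_{port})$, computed on the common sampling
window without extrapolation by default (the quantity is a same-window
exposure ratio; extrapolating two differently-censored tails would
manufacture precision).  A jugular AUC above portal is reported as
negative extraction, never clipped.  The implied hepatic clearance is
compared against a reference hepatic blood flow of 90 mL/min/kg
(mouse-scale default, configurable).

## The PK simulator

`simulate_iv()`/`simulate_oral_paired()` are closed-form
one-compartment solutions used as the NCA test harness: elimination
$k = CL/V$, first-order absorption $k_a$ (with the $k_a = k$ flip-flop
limit handled in closed form), bioavailability $F = f_{abs}(1-E_H)$,
and a portal concentration that adds the absorption flux over portal
flow, $C_{port} = C_{sys} + k_a f_{abs}\,D\,e^{-k_a t}/Q_{pv}$ — the
standard well-stirred-consistent additive-flux approximation,
documented as a test harness rather than a physiological claim.  Two
analytic identities anchor the tests:
$AUC_{jug}^\infty = f_{abs}(1-E_H)D/CL$ and
$AUC_{port} - AUC_{jug} = f_{abs} D / Q_{pv}$.  The AUC-ratio
first-pass estimator equals $E_H$ only when clearance is entirely
hepatic ($CL = E_H Q_{pv}$); the defaults are coupled that way (dose
3 mg/kg, $Q_{pv}$ 90 mL/min/kg, $E_H$ 0.77 giving CL 69.3 mL/min/kg,
V 2.8 L/kg, oral sampling 0.25–24 h, LLOQ 0.4 ng/mL — a realistic
rodent portal-vein study design).  With extrahepatic clearance the
estimator carries a positive absorption-flux bias, which one test
documents explicitly at $E_H = 0$.  Multiplicative log-normal noise
(`noise_cv`) and LLOQ censoring complete the emulation; the simulator
does not model multi-compartment distribution, enterohepatic
recirculation, transporters or gut-wall metabolism.

## Problem sizes used by the test suite

Fixture ensembles use 10-atom molecules with 20–2000 frames (2000 for
the mixture-recovery check, where the closed form gives the sampling
SD); the Monte-Carlo oracle uses $10^6$ random directions per atom for
the deep single-cluster comparison and $2\times10^5$ for the 20-cluster
sweep (standard error well under the 1 % comparison band); PK recovery
uses a 169-point dense schedule and the 8-point study schedule.  These
sizes were chosen so every statistical assertion sits several standard
errors away from its bound.

## Known limitations

* No analytic (LCPO/power-diagram) surface, volumes, or curvatures;
  accuracy is set by the point count.
* Leader clustering is frame-order dependent by design; it is a
  reconstruction of "dominant conformer" extraction, not a published
  clustering method.
* The sampler cannot move ring torsions, so macrocycle backbone
  conformations must come from the user (or the two-state fixture).
* NCA assumes a single profile per subject/site/route; no
  population-level statistics beyond what the caller aggregates.
* mmCIF and binary trajectory formats (DCD/XTC) are not read; only
  multi-model PDB.
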