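---
title: "Modeling ligand permeation through a pentameric channel: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling ligand permeation through a pentameric channel: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(permeakit)
```

## The scientific problem

Aminoglycoside antibiotics such as dihydrostreptomycin are large (~10 Å) and
carry a net +3 charge, which makes unassisted membrane crossing implausible.
One proposed uptake route is the mechanosensitive channel of large
conductance (MscL), a pentameric bacterial channel whose open pore is wide
enough to pass such a molecule. Probing this computationally requires a
specific toolbox: a way to drive the ligand through the pore on tractable
timescales (an external electric field applied only to the ligand), a
permeation coordinate and event detector, and structural statistics that
quantify what the channel does while the ligand passes (helix rotations,
pore-radius profiles, lipid contacts, implicit-membrane solvation
energies).

permeakit implements that toolbox end to end at coarse-grained desk scale:
a synthetic channel system with controllable ground truth, a Langevin
engine with the field term, and the full set of trajectory and structure
statistics. The package does **not** attempt to reproduce any all-atom
simulation's numbers; it reproduces the *machinery*, validated against
closed forms and brute-force oracles, and the qualitative field-dependence
of permeation.

## The synthetic system

`build_pentamer()` constructs an idealized five-fold symmetric channel:
136 residues per monomer, two pseudo-atoms per residue (backbone CA and
side-chain CB, 2.0 Å radii), ideal α-helical segments (1.5 Å rise and 100°
twist per residue, 2.3 Å wrap) for the four named domains — the N-terminal
S1 helix, the pore-lining TM1 and lipid-facing TM2 transmembrane helices,
and the cytoplasmic C-terminal bundle — with coil residues routed along
length-matched arcs between helix anchors. The membrane normal is +Z, the
periplasm is at +Z and the ligand exits toward −Z; this orientation is a
package convention (it makes the sign of the permeation coordinate and the
"clockwise seen from the periplasm" handedness attribute concrete), not a
claim about any reference structure.

Two residues are functionally labeled: residue 106 is the cytoplasmic
lysine (LYS) whose five copies form the reference ring of the permeation
coordinate, and residue 103 is the lipid-facing asparagine (ASN) used by
the contact-number statistics. Residue numbering follows the
concatenated-subunit convention — residue *n* of monomer *m* is numbered
*n* + 136·*m*, so the lysine ring appears as K106/K242/K378/K514/K650 and
the asparagine counterparts as N239/N375/N511/N647. The selection language
resolves `resnum` against per-monomer numbers and `resid` against the
concatenated numbers.

The pore constriction is a controlled ground truth: the TM1 side chain
nearest the configured constriction z (default −5 Å) is placed as an exact
ring whose clearance from the axis equals `pore_constriction_radius`
(default 2.5 Å, an open pore that passes the 2.0 Å ligand beads; 1.0 Å is
the closed control that blocks them). The builder verifies that no other
atom narrows the pore below the requested value and errors otherwise.

The ligand surrogate is a rigid cluster of three collinear +1 beads whose
cloud diameter is 10 Å and whose total mass is 583.5 amu — the charge,
size and mass of dihydrostreptomycin, without internal torsions. The bath
holds 95 K⁺ and 95 Cl⁻ placed by rejection sampling (3 Å minimum
separation, outside the 18 Å membrane slab and every vdW sphere), and 230
surrogate lipids, each a PC/PA/OL three-residue molecule with the PA and
OL residues flagged hydrophobic and the PC head carrying a leaflet marker
atom at the slab face. No counter-ions are added for the ligand, so the
default system carries a net +3 charge, which the build log reports.

Two bath choices deserve comment because they deviate from a literal
solvated system. First, ions are excluded from a 20 Å cylinder around the
channel axis: without explicit water, a bare ion parked in the permeation
pathway exerts an unscreened Coulomb force on the ligand that solvated
systems do not, and in early builds a single such ion reversed the
ligand's drift. Second, the lipid surrogates are static scatterers for the
contact statistics, not a fluid bilayer. What passing tests show about
real data is therefore limited: the machinery is exact (oracle-tested),
but the synthetic conditions do not emulate hydrodynamics, lipid
deformation, or ionic screening.

## The force field and its conventions

The energy model is deliberately minimal: Coulomb
(332.0636·q₁q₂/r kcal/mol, no cutoff — the systems are small and particle-
mesh methods are out of scope), a WCA repulsion that vanishes exactly at
the pair contact distance r₁+r₂ (ε = 0.2 kcal/mol), harmonic positional
restraints, and the external-field term

  f_i = c_i · EEF,

applied per component to a masked atom subset only, with the field in V/Å
converted to kcal/(mol·Å) per e by 23.0609. Unit conversions live in one
constants table (`pk_constants()`).

The restraint convention is E = k·d² — no factor ½ — because the force
constants this model inherits (the 20/15/10/5/2/1 kcal/mol/Å² relaxation
ladder) are only meaningful under the convention of the engine family that
uses them. The equipartition variance under this convention is k_BT/(2k),
and the test suite checks the integrator against exactly that.

Like any molecular force field, the coarse model needs non-bonded
exclusions: atoms within one small molecule (ligand cluster, lipid
surrogate), within one residue, or within four residues along a protein
chain do not interact. Four is the 1-4 analog appropriate for a model with
1.5–2.5 Å backbone spacing; without it, near-neighbor pseudo-atoms sit
permanently on the repulsive wall.

## Dynamics

The integrator is the BAOAB splitting of Langevin dynamics with a 0.01 ps
default timestep (the 1–2 fs steps of all-atom work are an atomistic
setting; the coarse model's stiffest interaction tolerates far larger
steps), friction 5 ps⁻¹ and snapshots every 4 ps by default. Scaffold
atoms are static unless selected mobile; the ligand moves as a
translation-only rigid cluster (net force on the centroid, fixed internal
offsets), which keeps bead pairwise distances fixed to machine precision.
Rotational diffusion of the surrogate is deliberately absent — the
collinear bead geometry means pore passage is orientation-independent
along the axis. All thermostat noise is drawn from R's seeded RNG, so
trajectories are bitwise reproducible per seed on one platform.

Two closed forms pin the engine down quantitatively: a bead under constant
force F reaches terminal drift velocity F/(mγ) at T = 0 (tested to 1%),
and a harmonic well at 300 K equipartitions to variance k_BT/(2k) per
coordinate (tested to 5%).

`run_permeation_protocol()` runs the field sweep: one trajectory per
(field, seed) with the field along −Z applied to the ligand only, and a
first-passage summary. On the default channel, 0.2 V/Å drives passage in
every replicate within ~20 ps, 0.1 V/Å in most but more slowly, and
0.05 V/Å only sometimes within the 200 ps window — the qualitative
monotone field response, with the strong field reliably permissive and
weaker fields progressively not, that this kind of accelerated-permeation
protocol is designed to show. The timescales themselves are not
comparable to atomistic simulation (the toy has no water friction beyond
the Langevin bath).

## Trajectory statistics

**ΔZ.** The permeation coordinate is the Z difference between the
unweighted geometric centers ("geometrical", not mass-weighted — a
deliberate reading) of the ligand and of the five lysine-ring residues
(their CA pseudo-atoms by default; the atom-level choice is configurable
because reference conventions differ). ΔZ ≥ 0 on or above the ring plane.

**Crossings.** Passage detection uses hysteresis: a downward event is
recorded when the series, having most recently been at or above z_upper
(+10 Å default), first reaches z_lower (−5 Å default); these defaults are
explicit configuration, chosen well inside the excursion range of driven
trajectories, because no principled threshold exists. Hysteresis makes
the count robust to noise around a single threshold; a two-state automaton
over symbolized values serves as the independent oracle in the tests.

**Stages.** Permeation events are conventionally narrated in stages
(initial, transition, exit, ...). `segment_stages()` makes that
reproducible: frames are labeled by explicit ΔZ bands, runs shorter than a
minimum dwell are merged into their longer neighbor (shortest first), and
stage boundaries are placed midway between adjacent frames of different
stages so the stages partition the analyzed window exactly. Band edges are
always explicit configuration — the underlying notion ("according to the
residence time and the energies") is qualitative, so the package never
infers them.

**Ion displacement** is the per-ion endpoint Z difference by default
(window-mean minus initial is available as an option) with negative values
meaning motion toward the −Z exit side; the endpoint/time-average
ambiguity in how such shifts are usually reported is resolved by offering
both and logging which was used.

**Contact numbers** count, per frame and per monomer copy of the target
residue, the hydrophobic lipid residues (PA/OL) whose geometric center
lies within the threshold — 6.5 Å by default, *inclusive*, matching the
"equal to or smaller" convention — of the target residue's center.

## Structure geometry

Superposition is a weighted Kabsch fit with the reflection corrected, so
the rotation is always proper. The two-selection RMSD protocol fits each
frame on one selection (all α-carbons, typically) and measures the RMSD
over another without re-fitting — the standard way to ask how much a
domain moved beyond the global motion. Helix rotations are quantified by
fitting each helix directly onto its reference counterpart (no global
pre-alignment by default; a flag enables it, because rotation analyses
and RMSD analyses traditionally make opposite choices here) and converting
the fitted rotation to an axis-angle pair with the angle in [0°, 180°],
the axis sign fixed by its largest component, and handedness reported
explicitly as whether the *motion's* rotation axis (the inverse of the
fitted mobile-to-reference rotation, read off the raw antisymmetric part
before sign normalization) points toward −Z — clockwise as seen from the
periplasmic +Z side.

The pore profiler is HOLE-like but deliberately simpler: at each z the
sphere center is constrained to the slice plane and to within a few Å of
the axis, optimized from a deterministic seed grid by Nelder–Mead. Full
HOLE lets the center wander in 3D; for near-axial pores the planar
constraint loses little and makes the profile deterministic. Bottlenecks
are strict local minima of the sampled profile, leftmost sample on
plateaus. Analytic fixtures pin the implementation: a ring of radius 5
with 1.5 Å atoms must give 3.5 Å, an hourglass one bottleneck, a double
constriction exactly two (the "W" profile shape characteristic of a
partially open channel with two pinch points).

Membrane thickness is the difference of mean marker-atom Z between
leaflets — the simple estimator that motivates fixing an 18 Å implicit
slab when the measured average is ~18 Å.

## Implicit-membrane Poisson energy

The polar solvation energy solves the linearized Poisson equation (zero
ionic strength by default — no salt is assumed in this step) on a regular
grid with a 7-point stencil and harmonic-mean edge dielectrics:
ε = 1 inside any solute sphere (the conventional interior value; only the
two external dielectrics, 80 for water and 4 for the membrane, are
physically prescribed), ε = 4 in an 18 Å slab, ε = 80 elsewhere. The slab
tracks the membrane, not the solute: a per-conformation Z offset (the
"mctrdz" convention) equal to the membrane-marker center minus the solute
center shifts the slab each frame. Boundary conditions are the analytic
Coulomb potential in a uniform reference dielectric; charges spread
trilinearly; the solver is Jacobi-preconditioned conjugate gradients to a
1e-8 relative residual, with an error carrying the residual history on
non-convergence.

The energy is the two-solve reaction-field difference
½·Σqᵢ(φ_env − φ_ref), with φ_ref from a uniform-ε_in solve on the same
grid, so the grid self-energy of the spread charges cancels — the
standard finite-difference practice when the self-energy handling is
otherwise unspecified. Grid defaults are 0.5 Å spacing with a 10 Å
buffer. The Born ion is the quantitative anchor: at 0.25 Å spacing the
reaction energy is within a few percent of −166.0318·q²(1−1/ε)/R and the
error at least halves from 0.5 to 0.25 Å. The total MM-PB energy is
E_MM + E_PB with no nonpolar surface-area term, mirroring protocols that
omit it for membrane systems where surface-tension parameters are
unreliable.

## The pipeline and reproducibility

`run_pipeline()` chains build → simulate → analyze and writes the full
artifact set (system + charges, XYZ trajectory, ΔZ series, permeation
report, per-frame MM-PB energies, pore profile, per-helix rotations) plus
a manifest recording the configuration hash, seed and package version.
All CSV and XYZ writers format numbers deterministically, so identical
configuration and seed give byte-identical artifacts; the test suite
asserts this. A failed stage still writes the manifest, marked FAILED.

Demo problem sizes are chosen for interactive turnaround: a 60 ps driven
trajectory with the ligand and cations mobile (≈2,250 atoms), six MM-PB
frames at 1 Å spacing on the protein+ligand subsystem, and a 2 Å pore
sampling. These are the package's demonstration settings, not scientific
recommendations; every size is a config field.

## Known limitations

* The scaffold is rigid (or restrained), so the demo cannot show induced
  helix rotations; the rotation operators are validated on constructed
  motions instead.
* No explicit water: permeation kinetics are Langevin-bath kinetics, and
  ionic screening is absent (hence the axial ion-exclusion cylinder).
* The pore profiler's planar, near-axis search diverges from full HOLE
  for strongly tilted or off-axis channels.
* The Poisson solver's Dirichlet boundary uses a single uniform reference
  dielectric; with a thick slab filling the whole grid this contributes a
  few percent of error (visible in the slab-interior Born check).
* Absolute MM-PB values depend on the toy charges and radii and are not
  comparable to all-atom force-field energies; only differences and
  trends within one model are meaningful.
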