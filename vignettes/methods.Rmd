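---
title: "Methods: exposure, screening and interface metrics in crydimer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exposure, screening and interface metrics in crydimer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crydimer)
```

crydimer implements the computational workflow used to propose and
characterise disulfide-linked protein homodimers: find surface cysteines,
screen rigid-body dimer poses by sulfur–sulfur distance, characterise the
resulting interfaces over conformational ensembles, and confront the models
with cross-linking mass-spectrometry restraints and Ellman-assay cysteine
counts. This vignette records the models, the tunable parameters, and the
design decisions behind each stage, in enough detail that every number the
package produces can be traced to a formula.

## Coordinate model

A structure is a tibble with one row per atom (`chain`, `residue_seq`,
`name`, `element`, `x/y/z` in Å, plus bookkeeping columns); an ensemble is
the same tibble with multiple `model` values and positionally identical
topology across models. PDB input and output handle
`ATOM`/`HETATM`/`MODEL`/`ENDMDL`/`TER`, coordinates quantised to the
format's three decimals. Alternate locations are resolved at read time
(default: highest occupancy, ties to first occurrence); insertion codes are
rejected outright because they make `(chain, residue_seq)` keys ambiguous.
Hydrogens are kept on read — disulfide formation and hydrogen-bond
detection need them — and can be stripped with a flag. Coordinates are
treated as orthogonal Å with no periodic imaging: ensembles are assumed to
be whole-molecule and pre-imaged, which is the form in which trajectory
snapshots are normally exported for analysis.

## Solvent-accessible surface area

SASA uses the Shrake–Rupley construction: each atom is inflated by the
probe radius (1.4 Å, water), a quasi-uniform lattice of points is placed on
the inflated sphere, and the exposed fraction is the fraction of points not
inside any neighbour's inflated sphere. Two choices matter:

* **Deterministic lattice.** Points come from a golden-spiral (Fibonacci)
  lattice, not random sampling, so results are exactly reproducible without
  seeds. The lattice is fixed in the laboratory frame, so SASA is invariant
  under rigid motion only to within the lattice discretisation (≈0.5% in
  practice; the tests assert this bound).
* **Heavy atoms only** by default, with an element-keyed Bondi-type radius
  set (C 1.70, N 1.55, O 1.52, S 1.80 Å, …). Including hydrogens is a flag;
  the radius table is caller-replaceable.

Accuracy is controlled by `n_sphere_points` (default 960; values below 32
are refused). Against closed forms, an isolated carbon sphere
(4π(1.7+1.4)² ≈ 120.76 Å²) and a symmetric two-sphere overlap (exposed area
4πR² − 2πR(R − d/2) per sphere) agree within 1% at 960 points and within
0.2% at 10 000.

## Relative exposure and cysteine classification

Absolute SASA is not comparable across residue types, so per-residue
exposure is normalised by the residue's maximum attainable SASA (MSA):
`exposure = 100 × SASA / MSA`, with MSA taken from the same residue X in a
Gly–X–Gly tripeptide. The package generates idealized extended tripeptides
for all twenty standard residues and computes the reference table itself
(`default_msa_table()`); when a conformer ensemble is supplied, MSA is the
maximum over conformers by default ("maximum SASA"), with a mean mode for
sensitivity analysis.

Two conventions are deliberately left open, since either reading is
defensible:

* **Scope.** The default numerator and denominator are *sidechain-only*
  areas, matching how cysteine accessibility is usually quoted; a
  whole-residue scope is a flag. Glycine's "sidechain" is its Cα, the usual
  convention so that its reference area is non-zero.
* **Frame averaging.** For ensembles the default computes exposure per
  frame and then averages ("time-averaged" snapshots); averaging SASA first
  and dividing once is available behind a flag (for a fixed MSA the two
  orders coincide).

Exposure above 100% — a conformation more exposed than the tripeptide
reference — is possible, reported, flagged, and never clamped.

Cysteines are classified with two thresholds: exposed above 20%, buried
below 7%, both strict, values exactly at a threshold falling in the
intermediate band. These bands mirror the empirical split between
disulfide-competent surface cysteines and core cysteines.

## Dimer-pose screening

For a two-chain pose the package enumerates every inter-chain cysteine pair
and measures Sγ–Sγ distances (Cβ–Cβ for models without sidechain detail).
The verdict is three-banded on the minimum distance: *candidate* at ≤ 6 Å
(close enough that a disulfide can form with modest rearrangement),
*rejected* above 10 Å (not worth refining), *marginal* in between. The two
cutoffs correspond to the selection criterion used when identifying
candidate poses and the exclusion bound applied before simulation; keeping
the band explicit (rather than collapsing to a single cutoff) preserves the
practically important middle class, which restrained refinement can
sometimes rescue — refinement itself is out of scope here and marginal
poses are simply flagged.

In-silico disulfide formation follows the standard construction: the thiol
hydrogens (HG) of both cysteines are deleted and the S–S connection is
recorded (emitted as an SSBOND header on write). No coordinate relaxation
is attempted — the recorded bond may be "abnormally long", and shrinking it
to ~2.05 Å is a simulation engine's job.

C2 symmetry is tested exactly: swap the chains, superpose the swapped dimer
onto the original (Kabsch), and compare the residual RMSD to a tolerance (a
1 × 10⁻⁶ Å numerical floor keeps exactly constructed poses symmetric even
at tolerance zero).

## Interface metric panel

Over an ensemble of dimer frames the panel reports, per frame and as
mean ± SD:

* **E_tot** — inter-chain non-bonded energy, the sum of Lennard-Jones 12-6
  (`ε[(r_min/r)¹² − 2(r_min/r)⁶]`, Lorentz–Berthelot-style combination)
  and Coulomb (`332.0636 q₁q₂ / εᵣ r` kcal/mol) over *inter-chain pairs
  only*, both multiplied by a C¹ polynomial switching function that is 1
  below 10 Å and 0 beyond 12 Å. Because only non-bonded inter-chain terms
  are ever computed, a covalent S–S term is excluded by construction.
  Parameters come from a caller-supplied table; the bundled default
  (element-keyed LJ, formal charges on Asp/Glu carboxylate oxygens, Lys NZ
  and Arg NH) exists so the machinery is testable without distributing a
  force field — absolute agreement with any published force-field energies
  is explicitly not claimed, and on unrelaxed synthetic poses E_tot can be
  positive (steric contacts are not minimised).
* **R_g** — mass-weighted radius of gyration of the complex.
* **RMSD** — backbone RMSD against a chosen reference frame, after optimal
  Kabsch superposition (SVD route with reflection correction; the rotation
  is always proper). An independent quaternion eigenvalue oracle in the
  tests agrees to 10⁻⁶ Å.
* **RMSF** — per-atom fluctuation about the ensemble-average position,
  after iteratively superposing all frames onto their mean structure (two
  passes: superpose to the frame-1-anchored mean, re-average, re-superpose;
  further passes change nothing at the coordinate-noise level). The default
  selection is every carbon; Cα-only is available. For isotropic Gaussian
  jitter of standard deviation σ per coordinate the expected RMSF is σ√3,
  which the tests recover within 5% at 2000 frames (the superposition
  itself removes six rigid-body degrees of freedom, biasing RMSF low by
  roughly `sqrt(1 − 6/(3N))`; with the ≥ 60-atom selections used here that
  bias is under 2%).
* **A_IS** — buried interface area, `SASA(A) + SASA(B) − SASA(AB)`;
  non-negative, exactly zero once the chains are beyond probe contact, and
  symmetric in the chain labels.
* **Hydrogen bonds** — inter-chain donor/acceptor (N, O) pairs within
  3.5 Å whose donor–H–acceptor angle is at least 140°. These two criteria
  are *choices*, recorded in the panel metadata: typical geometric
  definitions vary by ±0.2 Å and ±20°, and the source workflow does not
  pin its own values. A heavy-atom-only fallback handles hydrogen-free
  models.
* **Salt bridges** — an Asp/Glu carboxylate group and a Lys/Arg (optionally
  His) cationic group on opposite chains count as bridged in a frame when
  their minimum heavy-atom distance is ≤ 4.0 Å; a bridge is *counted* only
  when present in strictly more than 10% of frames. The strict inequality
  follows the "more than 10% of frames" convention — a bridge at exactly
  10% occupancy is excluded, and the tests pin this boundary.

Whether ensemble-level bond counts should be means or maxima is genuinely
ambiguous in most published tables; the panel reports frame means (plus the
occupancy-filtered bridge count) and keeps per-frame values available.

## Cross-link distance restraints

Amine-reactive cross-linkers (DSSO, DSBU) connect lysines whose Cα atoms
lie within ≈2.7 nm, so each identified link becomes a 27 Å Cα–Cα ceiling
(one shared default for both linkers, since one reach figure covers both;
per-linker overrides exist because spacer arms differ). Disulfide records
are measured Sγ–Sγ with a 6 Å default ceiling for *formable* bonds (the
screening criterion) or 2.5 Å for *formed* ones, selectable per table.

On a homodimer all four chain assignments are evaluated (A–A, B–B, A–B,
B–A). A record is *satisfied* when exactly one of {intra, inter} can meet
the ceiling, *ambiguous* when both can — the homodimer indistinguishability
problem — and *violated* when neither does. Self-pairs (the same residue
number on both sides) have no intra-chain distance at all: in a dimer they
are testable only as intermolecular, and on a lone monomer they are
reported *untestable*. Fraction-provenance classification is independent of
geometry: links seen only in the dimer fraction are assigned
intermolecular, links also present in the monomer fraction lean
intramolecular, and unknown provenance stays ambiguous. Residue numbering
is taken verbatim from the model; any construct offset (e.g. an N-terminal
purification-tag remnant) is the caller's responsibility.

## Ellman (DTNB) arithmetic

The calibration series (free cysteine at 0–30 µM against 412 nm absorbance)
is fitted by ordinary least squares *with* an intercept — Beer–Lambert
implies a zero intercept, but blank drift is routine, so the intercept is
estimated and discarded and only the slope `a` is used. Accessible
cysteines per molecule are then `N_Cys = E/(a·c)` for sample absorbance `E`
and protein concentration `c`; the quantity is real-valued by design (a
population average over partially reactive thiols).

## The synthetic-fixture generator

All tests and the end-to-end pipeline run on generated structures, chosen
so that ground truth is analytic:

* **Monomers** are ideal α-helices (rise 1.5 Å, 100°/residue, Cα radius
  2.3 Å) with template sidechains, backbone amide hydrogens, and cysteine
  Cβ/Sγ/HG. Sidechains are laid out as zigzag chains with correct atom
  counts and elements — surface areas, not rotamer realism, are what the
  downstream stages consume. "Buried" cysteines receive an explicit shell
  of dummy shield atoms (HETATM residue `SHL`, pruned where it would
  collide with the protein) so their SASA is near zero by construction.
* **Dimer poses** place a second copy by a 180° rotation about an axis
  parallel to the helix axis, positioned (by root-finding on the measured
  minimum) so the minimum inter-chain Sγ–Sγ distance equals the target
  within 0.01 Å; in C2 mode the pose is exactly two-fold symmetric, and in
  the asymmetric mode a 1 Å axial shift turns the rotation into a screw
  motion, breaking the symmetry without introducing clashes. Targets that
  would push heavy atoms below a 1 Å hard-sphere limit are refused.
* **Trajectories** are i.i.d. isotropic Gaussian jitter per atom (default
  σ = 0.3 Å, an equilibrated-backbone fluctuation scale), fully determined
  by the seed, with the caller's RNG state left untouched. Contact
  occupancy schedules are honoured *exactly*: the scheduled Lys sidechain
  is placed at the contact distance in `round(occupancy × n_frames)`
  frames chosen by a deterministic stride (never Bernoulli draws, so
  occupancy tests cannot flake), at a far distance otherwise, and the
  participating sidechains are exempted from jitter.
* **What this does not emulate:** force-field physics, correlated motions,
  solvent, realistic packing, or sequence realism. Passing tests therefore
  demonstrate that the *estimators and filters* are correct on inputs with
  known truth — not that any particular protein dimerises. A real
  structure (e.g. a cryptochrome homology model) can be fed through the
  identical functions via `read_pdb()`.

## Problem sizes and numerical choices

Default problem sizes keep the whole suite desk-scale: 960 lattice points
for routine SASA (10 000 only in convergence checks), helices of 10–30
residues, ensembles of 4–100 frames for schedule tests and 2000 frames for
the RMSF recovery study, and a 5-frame, 480-point pipeline configuration.
Root-finding for pose construction uses `uniroot` at 10⁻⁴ Å tolerance
against a 0.01 Å contract. Degenerate inputs fail loudly and early:
fewer than 3 points for superposition, a single frame for RMSF, zero total
mass for R_g, all-equal concentrations for the calibration fit, unmapped
elements for SASA, residues missing their distance atoms for screening and
restraint evaluation.

## Known limitations

* The bundled non-bonded parameter table is minimal and intentionally not
  a force field; E_tot values are comparative, not absolute.
* SASA rigid-motion invariance is exact only up to the fixed lattice
  (≤ 0.5%); there are no analytic derivatives.
* No docking, no coordinate refinement, no PBC imaging, no mmCIF or binary
  trajectory formats.
* Insertion codes and multi-character chain identifiers are rejected
  rather than handled.
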