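---
title: "DiGb scaffolds: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{DiGb scaffolds: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(digb)
```

## The system

A Di-Gembody (DiGb) is a covalent nanobody dimer used as a cryo-EM imaging
scaffold. Each subunit is a Gembody (Gb): a nanobody carrying the core
framework substitutions S7N; L12C; Q14K; T125M (IMGT numbering), which
predispose a nanobody-to-nanobody interface and place a reactive cysteine
at position 12. Oxidative coupling of the two C12 side chains yields a
disulfide-linked dimer that displays two target proteins (the same target
for homodimers, two different ones for heterodimers) across a constrained
interface. Three computational questions around these constructs are
covered here: which residues to substitute on an arbitrary nanobody, whether
a given target:nanobody complex fits on the scaffold without steric
clashes, and how rigid the dimer interface actually is.

## IMGT numbering by reference alignment

Nanobody CDR loops vary in length, so author residue numbers are not
comparable across nanobodies. All positions in this package are IMGT
positions, obtained by globally aligning the query (BLOSUM62, affine gaps,
open 10 / extend 1) against an embedded IMGT-numbered VHH reference and
transferring numbers through the aligned columns. The reference
(`gb_reference()`) is a constructed consensus, one residue per occupied
IMGT slot, with the canonical framework identities at every position this
package cares about (C23/W41/C104 anchors; S7, L12, Q14, Q44, P46, G47,
K84, Q120, Q123, T125 at the interface). It is a synthetic consensus, not
a database germline.

Two consequences of this design are worth stating. First, framework
positions — the only positions the Gb substitutions and the geometry
analyses use — transfer unambiguously, because framework regions are
highly conserved (the mapping is insensitive to the alignment scoring; the
defaults are configurable regardless). Second, numbering *inside* CDRs is
approximate: residues between the framework anchors of a CDR are
renumbered over the IMGT span (27–38, 56–65, 105–117) with the symmetric
middle-gap convention, and loops longer than the span receive 111/112-style
insertion codes. A dedicated numbering service may place CDR-internal
insertion codes slightly differently; framework positions agree either
way. Queries whose framework identity falls below 0.5 are rejected as not
nanobodies. Query indices are 1-based, following R convention.

The named substitution sets shipped in `gb_variants()` are transcribed
from the published Gb constructs (core; Gb5-006 with its solubility
substitutions; GbD12; GbS2A4; GbH12; GbRBD1/3/6; GbC4; Gb113 and the other
minimal-set constructs). `design_gb_substitutions()` instantiates a set
against a query: positions already carrying the replacement are omitted
(making design idempotent), and a listed wild type that disagrees with the
observed residue is flagged but still replaced, since the replacement
defines the designed interface. `check_interface_conservation()` never
errors — deviations at interface positions (for example lysines at 120,
observed to shift the dimer interface to a different stable state) are
advisories, because such nanobodies can still dimerize.

## Scaffold placement and clash scoring

Applicability screening asks: if two copies of a target:nanobody complex
are placed onto the two Gb chains of a DiGb scaffold, do the targets
collide? Placement is least-squares rigid superposition (Kabsch, SVD with
reflection correction) over paired C&alpha; atoms at shared framework IMGT
positions. CDRs are excluded from the correspondence because their
conformations differ between a target-bound nanobody and the scaffold Gb,
while nanobody frameworks superpose to about 1 Å across the family;
positions missing a C&alpha; on either side simply drop out, and fewer
than 20 shared positions is an error. Weights are uniform and there is no
outlier rejection by default: the placement is already determined to small
fractions of an Ångström by ~80 framework positions, and a deterministic
rule is easier to reason about than an unspecified iterative one.

A target heavy atom is *clashed* when it lies within 4.0 Å (inclusive at
the boundary — determinism requires picking a convention) of any heavy
atom of the other placed copy, nanobody atoms included; only target atoms
are counted as probes. Waters, non-polymer heteroatoms and hydrogens are
excluded. The clash score divides by the total number of target heavy
atoms across both copies — the interpretation of "maximal clash" as every
target atom clashing — so it lives in [0, 1], and the 5% applicability
threshold is `score < 0.05`. Both the normaliser and the threshold are
explicit arguments, since other normalisations are conceivable. The
neighbour search bins the environment into cutoff-sized cells and is
exactly equivalent to all-pairs counting (this equivalence is asserted
against a brute-force oracle in the tests). Library surveys record
per-entry failures (unannotatable chains, failed placements) as skipped
entries rather than aborting.

## Interface geometry

Each Gb's orientation is summarised by the axis vector **D** from its
heavy-atom centre of mass to the C&alpha; of residue 12 — the disulfide
site, so **D** points at the dimer interface. Over a series of *n* docked
models (one coordinate file per frame; 60 frames is typical for a 3D
variability series), every frame is first superposed on the static Gb of
the reference frame, then for the mobile Gb

- the average vector is the plain arithmetic mean of the unnormalised
  per-frame vectors, **D**<sub>a</sub> = Σ**D**<sub>i</sub>/n (no
  pre-normalisation — this is exactly the stated definition);
- the per-frame wobble angle is β<sub>i</sub> =
  arccos(**D**<sub>a</sub>·**D**<sub>i</sub> /
  (|**D**<sub>a</sub>||**D**<sub>i</sub>|)), with the cosine clamped to
  [−1, 1] before `acos`;
- the intra-DiGb angle is the angle between the static and mobile
  **D**<sub>a</sub>.

Angles are reported in degrees (tables round to 0.1°). Two conventions are
fixed and documented rather than guessed: the centre of mass uses atomic
masses over heavy atoms by default, with a uniform mode provided because
the choice is not uniquely determined by the definition (on globular
synthetic bodies the difference shifts angles by well under a degree); and
the tip-minus-origin orientation of **D** is used everywhere, so an angle
and its supplement are never conflated. Both a series entry point
(`wobble_series()`) and a single-model entry point (`digb_geometry()`)
exist, because a consensus model and the average over a variability series
are both legitimate sources of a per-variant angle.

Contact analysis (`interface_contacts()`) lists residue pairs across the
interface with minimum heavy-atom distance within 4.0 Å. Hydrogen bonds
are flagged on a distance-only criterion — an N/O–N/O pair within 3.5 Å —
because deposited cryo-EM models typically lack hydrogens; when hydrogens
are absent no angular criterion can be applied, and this is stated rather
than silently approximated.

## Coordinate I/O

PDB files are parsed through bio3d; mmCIF `atom_site` loops are read by a
minimal reader in this package (bio3d's CIF reader is marked beta and
offers no control over model selection, and no installed package writes
mmCIF). Author chain ids and residue numbers are used. Alternate locations
resolve deterministically to the highest-occupancy conformer, first listed
on a tie. Only model 1 of a multi-model file is used, with a notice — a
motion series is supplied as a list of files, not as one multi-model file.
Hydrogens are kept on read but excluded from every mass and distance
default; occupancies outside [0, 1] are rejected. PDB output round-trips
coordinates at the format's 3-decimal precision (and one-character chain
ids); mmCIF output round-trips at 6 decimals.

## Synthetic structures with planted truth

Because the real survey inputs (hundreds of deposited complexes) and the
variability series behind the interface analysis are external data, every
analysis stage is validated against deterministic generators whose output
predicts the measurement exactly:

- `make_toy_gb(seed, n_res)` builds a rigid, chirality-bearing backbone
  (N/CA/C/O per residue, 30–140 residues, default 90) along an irregular
  helical curve with seeded jitter, labelled with IMGT framework positions
  (the ten interface-critical ones always included). These are not
  physically realistic immunoglobulin folds, and are not meant to be: all
  in-scope computations are geometric, and need only labelled rigid bodies
  of non-degenerate shape. What passing tests on them shows is that the
  *measurement machinery* is exact; they say nothing about, for example,
  how real CDR flexibility degrades a placement.
- `assemble_digb(gb, intra_angle, c12_separation)` creates the second
  chain by a screw motion about an axis perpendicular to the axis vector
  through C&alpha;(12): the rotation changes the inter-axis angle by
  exactly the requested amount and the axial slide sets the C12–C12 span
  (default 6 Å, within the 4–8 Å disulfide-like range) exactly. Closure is
  verified to 0.1° / 0.01 Å at generation time.
- `make_wobble_series(digb, amplitude, n_frames, seed)` tilts the mobile
  Gb about its hinge in azimuth-opposed pairs, so the mean axis equals the
  untilted one exactly and the planted per-frame tilts *are* the wobble
  angles the analysis should recover, with maximum tilt equal to the
  amplitude; each frame additionally receives a random global rigid motion
  that the analysis must undo.
- `make_clash_scene(n, k, cutoff, seed)` plants exactly `k` clashing probe
  atoms (the rest strictly farther than cutoff + 1 Å), verified all-pairs
  before returning. `make_survey_entry(scaffold, fraction, ...)` plants an
  exact clash *fraction* through full placement: because the scaffold's
  generating transform is a screw motion, target atoms laid out on and
  around its axis have images at exactly computable distances, and each
  planted pair contributes one clashing target atom per placed copy.

All generators draw randomness from an explicit seed through a private RNG
stream (the caller's RNG state is untouched), making every output
bit-reproducible.

## Problem sizes and numerical tolerances

The test-suite and acceptance-script workloads use 60-frame series,
90-residue toy bodies, 10-entry survey libraries with 100-atom targets,
random clash scenes up to 500 atoms per set, and 10<sup>4</sup>-rotation
sampling oracles — sizes chosen so the whole validation runs in well under
a minute while exercising every code path at realistic scale. Exact-count
checks (clash oracle, survey fractions, substitution lists) use equality;
geometric closures use 1e-6° for formula identities, 0.1° for assembly
closure, 0.5° for amplitude recovery over 60 frames, and 1e-9 Å for
isometry and equivariance properties. Degenerate inputs fail loudly:
collinear point sets for superposition, zero-length axis vectors,
empty-after-filter atom selections for mass or clash computations.

## Known limitations

- CDR-internal insertion-code placement is approximate (framework
  positions are exact); germline assignment, humanisation and HMM-based
  numbering are out of scope.
- The clash criterion is a fixed distance sphere, not a van-der-Waals or
  energy model — deliberately, as the applicability score is defined that
  way.
- The survey runs on user-supplied libraries; no attempt is made to
  harvest or curate the published nanobody complexes, whose selection
  criteria are not part of this package.
- Density maps are never handled; the motion analysis consumes models
  already docked into variability maps by external tools.
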