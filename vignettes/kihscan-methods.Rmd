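---
title: "Detecting coiled coils by knobs-into-holes packing: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting coiled coils by knobs-into-holes packing: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kihscan)
```

## The model

Coiled coils are assemblies of two or more α-helices wrapped around a
common supercoiled axis. Their interfaces are stereotyped: a *knob*
side chain of one helix inserts into a *hole* bounded by four side
chains of a partner helix, and the underlying sequence shows a
7-residue (heptad) periodicity labelled a–g, with knobs concentrated at
a and d in canonical dimers. `kihscan` operationalises this definition
geometrically and works from coordinates alone — no sequence profile,
no oligomer-state prior, and no cap on the number of helices, which is
what allows cyclic α-helical barrels (whose interface graph is a ring)
to be found by the same rule as dimers.

The pipeline is a chain of small, testable stages:
structure ingest → helix assignment → side-chain centers → inter-helix
contacts → knobs/holes → complementary interfaces → connected-component
assembly → orientation, crossing angles, registers → reports.
Every stage returns a tidy table, and the whole pipeline is
deterministic: identical input and configuration give byte-identical
rendered output.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| packing cutoff | 7.0 (dial 6.0–8.0, `force` to override) | Å | maximum side-chain-center distance for a contact contributing to a hole |
| helix extension | 0 | residues | grows each assigned helix end before the KIH search |
| minimum helix length | 7 | residues | one heptad; shorter runs cannot carry a meaningful repeat |
| minimum knobs per interface | 3 | count | with ≥ 1 complementary pair, suppresses single spurious contacts |
| knob-type boundaries | 45° / 90° | degrees | packing-angle thresholds separating insertion types 3/2/1; type 4 additionally requires the knob CA within the cutoff of all four hole centers |

The cutoff dial is inclusive (a pair at exactly 7.0 Å is a contact):
an inclusive boundary makes the dial's semantics exact and
reproducible. The knob-type thresholds are one package-level
operationalisation of a four-level insertion classification; they are
isolated in a single function and exposed as arguments so they can be
calibrated against other implementations when shared reference
structures are available.

## Structure ingest

PDB and mmCIF files are parsed (via bio3d) into one tidy heavy-atom
table. Policy decisions, applied identically to both formats:

* only the first model's coordinates are kept (multi-model handling is
  deliberately out of scope);
* alternate locations resolve to the highest occupancy, ties to
  altloc `A` — deterministic and in line with common practice;
* hydrogens are stripped on ingest, so protonated inputs give exactly
  the same side-chain centers;
* waters and het-groups without a CA atom are dropped (they cannot
  form KIH packing), while CA-bearing heteroresidues are retained;
* `MODRES` / `pdbx_struct_mod_residue` records — or a built-in table of
  common modifications such as MSE→MET — set a residue's standard
  parent. The parent is used **only** for reporting (one-letter
  sequences, register tables); all geometry uses the atoms actually
  present, which is what keeps nonnatural residues first-class knobs
  and holes. Unmatched heteroresidues are retained with parent `UNK`.

## Helix assignment

Classic fixed-column DSSP output is parsed when supplied (the mmCIF
DSSP dialect is rejected with guidance). Otherwise an internal assigner
reproduces the Kabsch–Sander α-helix convention: the amide H is
reconstructed 1 Å from N along the preceding C=O direction, the
hydrogen-bond energy is
`E = 27.888·(1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN)` kcal/mol with a bond
at `E < −0.5`, and a residue is helical when it lies in a run supported
by two consecutive i→i+4 turns. Only the α-helix part of the DSSP
vocabulary is implemented — sheets, bridges and turns are not needed
here. 3~10~ (`G`) and π (`I`) codes do not seed segments by default
(the target is α-helical coiled coils) but can be included by flag.

Helix extension grows segments one residue per round, in helix order,
only over residues that exist on the same chain with contiguous
numbering and that no other segment has claimed. Extension never merges
segments and never crosses chain breaks, so helix identity is stable
under parameter sweeps and the residue set at extension *k* is always a
subset of that at *k*+1. The round-based claim rule makes the shared
gap between two approaching segments split deterministically.

## Knobs, holes, interfaces

The side-chain center is the **unweighted** centroid of heavy atoms
from CB outward; glycine falls back to CA. Mass-weighting would move
centers by under 0.2 Å for standard residues while requiring an element
table that breaks on nonnatural residues — the unweighted choice is
simpler and residue-agnostic. The hole is defined as the four contacted
residues nearest to the knob center (distance ties broken by ascending
residue number, for full determinism), not a stereochemical template:
this keeps the detector sequence-agnostic.

A helix pair is accepted as a coiled-coil interface when at least one
knob pair is complementary (each knob occupies the other's hole) and at
least three knobs cross the interface in total. Assemblies are then
**connected components** of the interface graph — deliberately not
cliques: a barrel helix touches only its two neighbours, so components
are the only rule that recovers assemblies of unbounded order. A
component containing a graph cycle is reported as `cyclic`, the barrel
signature; trees are `open`.

## Geometry and registers

Helix axes are fitted by principal component through a running mean of
the CA trace (window 7, about two turns). The smoothing is what makes
the reported rmsd meaningful: raw CAs lie on a cylinder of radius
~2.3 Å around the axis by construction, so an unsmoothed residual would
measure the helix radius rather than the fit quality; the smoothed
trace of an ideal straight helix collapses onto its axis (rmsd well
under 0.25 Å) and follows the superhelical arc of a supercoiled one.
Directions are signed N→C, and interhelix angles are the arccosine of
the dot product, reported **unsigned** in [0°, 180°] with one decimal
(handedness of the crossing is not resolved); pairs up to 90° are
`parallel`, beyond `antiparallel`, with the 90° tie going to parallel.

Registers are anchored on knob spacings only: consecutive knob
residues 3 apart give `a…d`, 4 apart `d…a`; each anchor proposes a
phase for the whole segment, the majority wins (ties to the smaller
phase), minority anchors are counted in `conflicts`, and letters
propagate by heptad arithmetic so `letter(i+7) = letter(i)`. With fewer
than two knobs, or only non-heptad spacings, the register is left
unassigned rather than guessed. Each helix gets a single a–g register
plus a conflict count; helices whose knobs sit at barrel e/g-type
positions will show conflicts, which are reported, not suppressed.

## The synthetic-structure generator

`crick_backbone()` builds idealised coiled coils from the standard
two-level (Crick) parameterisation: a minor helix of radius R1 wound on
a left-handed superhelix of radius R0 and pitch P. Backbone atoms N, C,
O and a single CB pseudo-side-chain atom are placed around the CA trace
using the cylindrical geometry of an ideal straight α-helix (built
internally by natural-extension chain growth at φ = −57.8°, ψ = −47°),
expressed in the local radial/binormal/tangent frame of the
superhelical path.

Defaults are canonical dimer values from the coiled-coil literature:
R0 = 4.9 Å, R1 = 2.26 Å, P = 148 Å, rise 1.495 Å/residue, 28 residues
per helix. The minor-helix periodicity is specified in the
supercoil-following frame and defaults to 3.5 residues/turn — the exact
heptad value, equivalent to ≈ 3.6 residues/turn in the laboratory frame
for these parameters; this is what makes core positions recur exactly
every seven residues, so the generator can state which residues are
`a`/`d` by construction (`intended_register` attribute). The default
interface phase points the CB atoms (what knob detection actually sees)
of the a/d seam at the superhelix axis. Antiparallel helices are
generated by a proper axial flip plus a minor-phase correction that
re-aligns the flipped helix's core seam with its partner at the bundle
mid-plane (a packs against the d′ seam, as in real antiparallel coiled
coils). Cn barrels place n copies at superhelical phases 2πi/n with the
neighbour separation held at the dimer value (R0 = 4.9/sin(π/n) Å) and
the pitch scaled to preserve the supercoil pitch angle, giving exactly
Cn-symmetric structures.

What the generator emulates: ideal supercoil geometry, heptad
periodicity, orientations, barrel symmetry, coordinate noise (optional
Gaussian jitter, capped below 0.3 Å so assignments stay stable). What
it does not: real side-chain shapes and rotamers, sequence diversity,
helix fraying, stutters/stammers in the repeat, solvation, crystal
contacts. Tests passing on these fixtures therefore demonstrate the
correctness of the detector's geometry and graph logic under the KIH
definition — they do not measure recall on experimental structures,
where side-chain heterogeneity and imperfect helices add variance that
the cutoff dial is there to absorb.

## Numerical choices and degenerate inputs

* Inclusive cutoff; all distance ties broken by ascending residue
  number; assemblies ordered by (smallest chain, first residue); so
  reruns and chain relabelings are exactly reproducible.
* Glycine knobs have an undefined packing angle: reported as missing,
  typed 1, never dropped.
* Helices too short for an axis fit (< 7 CAs) get `NA` axes and their
  pair orientations are reported unassigned.
* Structures with no helices, or helices but no coiled coils, produce
  valid reports (and exit code 0 from the command line), not errors.
* Residues missing backbone atoms are labelled non-helical with a
  warning; residues with neither CA nor side-chain atoms are skipped
  with a warning. Warnings never abort a run.

## Problem sizes in the test suite

The suites run on generated fixtures only: dimers of 21–35 residues per
helix, bundles of 2–4 helices, barrels of 3–9 helices (28
residues/helix), 20 jitter replicates for stability checks, 50 jittered
replicates plus all clean fixtures for brute-force oracle equivalence,
and a 7-point interface-phase grid for register round-trips. These
sizes exercise every code path — larger inputs change nothing
structurally, since the detector is quadratic in helix residues and the
assembly step works on the (tiny) helix graph.

## Known limitations

* First model only; biological-assembly expansion is the user's job
  (supply expanded coordinates).
* Classic DSSP format only; the mmCIF DSSP dialect is rejected.
* Crossing angles are unsigned; supercoil handedness is not reported.
* No Crick-parameter fitting to detected coiled coils, no
  oligomer-state prediction from sequence, no β-layer packing.
* The knob-type thresholds are a package-level convention pending
  calibration against other implementations on shared structures.
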