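---
title: "Analysing protein interfaces with rRNA structural motifs"
author: "ribomotif"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing protein interfaces with rRNA structural motifs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribomotif)
```

## The problem

Ribosomal proteins (r-proteins) bind ribosomal RNA not uniformly but with a
marked preference for structured RNA elements: tetraloops, kink-turns and
other single-stranded motifs appear at protein-RNA interfaces more often
than on the RNA surface at large. `ribomotif` implements the computational
side of that analysis for protein-RNA complexes such as the large and small
ribosomal subunits (e.g. PDB entries 1S72, 2AWB, 1FJF): extracting contact
surfaces, quantifying their composition, superposing motif-anchored
interfaces into a common frame, summarising them as 2-D interaction maps,
and searching protein surfaces for a recurrent binding-site geometry -- the
*tripod* -- around single extruded nucleotides.

## Contact surfaces

Interface extraction is a transparent distance rule set rather than a
reimplementation of any particular contact-analysis program: a contact is
any RNA/protein heavy-atom pair within `contact_dist` (default 4.5 Å); a
pair is classed as a hydrogen bond when both atoms are nitrogen or oxygen
and lie within `hbond_dist` (default 3.5 Å), otherwise as van der Waals.
The RNA-side atoms of the pairs form the RNA contact surface (R-CS), the
protein-side atoms the protein contact surface (P-CS); one surface is
reported per protein chain against the merged RNA chains. Hydrogens and
solvent are excluded throughout -- published interface statistics are
heavy-atom statistics -- and alternate locations are resolved to the
highest-occupancy copy at load time.

Distance rules are deliberate: they are testable (the grid-based neighbour
search is checked against an all-pairs enumeration), monotone in their
cutoffs, and sufficient for every downstream statistic. The consequence is
that composition tables computed on archival entries reproduce published
values qualitatively, not digit for digit, since the original extraction
tool's parameterization is not documented.

## Composition statistics

Atom-type, residue and structural-element compositions are plain percent
tables. The RNA-side atom names partition into phosphate
(`P`, `OP1`, `OP2`), ribose (the nine sugar atoms `O5'` ... `C1'`) and base
(every other heavy atom); `prb_summary()` collapses an atom-type table onto
that P-R-B split. On the published pooled R-CS column this split comes out
as 18.85 / 60.02 / 21.13 -- roughly 80% of interface atoms are backbone,
with ribose preferred over phosphate by better than 3:1. (The printed
summary rows of the source table carry swapped ribose/base labels; the
arithmetic is unambiguous and this package follows the arithmetic.)

Standard errors use a bootstrap over resampling units, by default whole
interfaces: the large published errors on the small tetraloop-restricted
columns indicate that between-interface variability dominates, which
atom-level resampling would hide. Units are drawn with replacement
`n_boot` times, the composition is recomputed on the pooled items, and the
SE is the population standard deviation (divisor `n_boot`) of each
category's bootstrap distribution. On toys small enough to enumerate all
resamples exactly, the estimate converges to the enumerated value (the
test suite checks a two-unit and a three-unit toy at `n_boot = 20000`;
the classical 35.355 two-unit value presumes equal-sized units).

## Tetraloop-anchored superposition

Standard tetraloops are rigid enough that all copies superpose onto a
reference to within 1 Å RMSD. Superposition uses Horn's closed-form
quaternion solution: the optimal rotation is the eigenvector of the largest
eigenvalue of the 4x4 quaternion matrix assembled from the cross-covariance
of the centred point sets. The solution is always a proper rotation
(det = +1); mirror fits are physically meaningless and rejected by
construction. Correspondence between loops is by backbone atom name and
loop position (`P, O5', C5', C4', C3', O3'` for nucleotides 1-4), with
missing atoms dropped pairwise; no sequence alignment is involved. An
independent Kabsch/SVD implementation serves as the test oracle (agreement
to 1e-9 in RMSD on random instances).

## Interaction maps

Each superposed interface is projected onto a sphere centred on the
reference loop: the frame origin is the backbone centroid; the axes are the
backbone's principal axes with signs fixed by two anatomical landmarks (the
nucleotide-1 phosphate and the loop apex), which makes the whole map
invariant under rigid motion of the input scene. Only the zenith/azimuth
angles are kept, so the sphere radius never matters.

The grid uses one shared quantization step for both angles, chosen as the
largest value from a candidate list (30° down to 0.5° in 0.5° decrements)
at which every atom of every single interface occupies its own cell. Cells
are half-open `[k·step, (k+1)·step)` anchored at zenith 0 and azimuth -pi.
With that anchoring, two atoms split into different cells at a step that
depends on their absolute azimuth, not just their separation -- the chosen
step is therefore checked against a brute-force scan in the tests rather
than against hand arithmetic.

Cells are coloured by a strict-majority rule over the residue classes of
their atoms (positive Arg/Lys/His, negative Asp/Glu, aromatic Phe/Trp/Tyr,
polar Ser/Thr/Asn/Gln/Cys, hydrophobic Ala/Val/Leu/Ile/Met/Gly, proline).
His is classed positive and Gly hydrophobic, matching the positive-patch
chemistry the maps are meant to expose; both choices are configurable in
`aa_class()` readers if a different convention is wanted. No strict
majority (ties, or cells dominated by nonstandard residues) gives a gap
cell. The four backbone regions are the cells hit by backbone-atom
projections of each nucleotide position, pooled over all superposed loops;
contested cells go to the majority position, ties to the lower position.

## The tripod search

A tripod is three amino acids whose convex "knobs" sit at the vertices of
a near-equilateral triangle (sides in (7, 10) Å, angles in (40°, 70°),
open intervals) cradling one extruded base. The search pipeline per
contact surface is: knob detection, per-nucleotide enumeration of knob
triplets, geometric fingerprint matching, and a composition filter.

*Knobs.* The original convex-patch method is not reproducible from its
description, so convexity is scored with a local-centroid heuristic: for a
P-CS atom at position *a*, let *m* be the centroid of all heavy atoms
within 6 Å and *u* the unit vector from the centroid of same-chain protein
atoms within 10 Å to *a* (a local outward direction). The convexity is
`||a - m||` signed by `sign((a - m)·u)`: protruding atoms displace away
from their surroundings along the outward direction; atoms pressed into
concave contact pits score negative. An atom is a knob candidate when it
is solvent-exposed (positive SASA) and its convexity exceeds 0.75 Å; one
knob is kept per amino acid (the maximum). The 6 Å / 10 Å / 0.75 Å
parameters are exposed in `knob_params()`.

*Matching.* Candidate triplets -- all 3-subsets of knobs of distinct amino
acids contacting the same nucleotide -- pass two gates: all sides and
angles inside the open fingerprint intervals, then best-permutation Horn
RMSD against the canonical fingerprint triangle at most 1.5 Å. The
canonical triangle is equilateral with side 8.5 Å (the midpoint of the
side range): the averaged knob coordinates of the originally curated
instances are not available, and any triangle inside both ranges matches
them to well under the RMSD threshold. Acceptance is invariant under rigid
motion and vertex permutation.

*Filter.* A candidate is accepted when its nucleotide's contact counts
satisfy B >= R, R >= P and B > P: extruded bases bind mostly through the
base, then ribose, then phosphate. Applied to the 27 published instances
this rule accepts 26 -- the single exception (counts 1-10-5) entered the
published list through manual curation, which this package deliberately
does not emulate: the output is the raw algorithmic list.

When motif annotations are supplied, candidate nucleotides are restricted
to residues not labelled as helix, the closest available proxy for
"single extruded nucleotide"; without annotations all contacted
nucleotides are candidates.

## Solvent accessibility

SASA is computed by Shrake-Rupley point sampling with deterministic
golden-spiral quadrature (960 points per atom by default) over van der
Waals radii C 1.70, N 1.55, O 1.52, P 1.80, S 1.80 Å; unknown elements
fall back to carbon with a warning. The probe radius defaults to 1.5 Å to
match the probe used in the interface-area computations this package
mirrors (not the more common 1.4 Å). An atom is a surface atom when its
area exceeds 0.1 Å² -- the source analyses never define "surface atom", so
the threshold is a package choice, kept small enough to be insensitive.
Contact-surface areas are reported as summed per-atom SASA of the contact
atoms in the whole-complex context; this approximates, but does not equal,
a rolled-probe contact area, so published absolute areas are context, not
a validation target.

## The synthetic generators

Real ribosome coordinates cannot ship with the package, so the test suite
and examples run on ground-truthed synthetic scenes built by
`make_tetraloop_scene()` and `make_tripod_scene()`. Their defaults are the
study conditions of the analyses: eleven tetraloop interfaces whose sizes
follow the published per-interface atom counts, coordinate jitter 0.2 Å
(the regime where all pairwise loop RMSDs stay below 1 Å), interface
amino-acid frequencies drawn from the published tetraloop contact-surface
composition, and three planted tripods (e.g. counts 2-4-11) plus one decoy
per violated gate: a 12 Å side, an 87° angle, an inverted P-R-B profile
(1-10-5), a two-amino-acid site, and non-protruding knobs.

The tetraloop template is an idealized geometric construction -- a rigid,
non-planar 24-atom backbone sweeping a semicircular band -- not a copy of
a crystallographic loop: the downstream analyses need rigidity and a
4-nucleotide layout, not chemical realism. Interface atoms are anchored to
distinct backbone atoms and offset radially outward from the loop centroid
by 2.2-4.0 Å with only a small tangential scatter. That radial anchoring
is forced by two contracts that pull in opposite directions: per-interface
cell injectivity (which favours coarse steps only if atoms are angularly
separated) and >= 90% of interface atoms inside the four backbone regions
(which requires atoms to share cells with backbone projections).
Tangentially scattered clouds satisfy neither. A consequence is that a
synthetic interface holds at most 24 atoms, so the two published interfaces
larger than that are truncated to 24 in the defaults.

Tripod sites place each contacted RNA atom on a narrow cone directly above
one apex, within 4.5 Å of that apex and of nothing else, so the requested
P-R-B counts are realized pair-for-pair; the generator verifies the
realized counts against the request and refuses inconsistent blueprints.
Every scene is fully deterministic given its seed, and the ground truth
(true transforms, planted counts, decoy tags) is machine-readable.

What the generators do *not* emulate: crystallographic bond geometry,
base stacking and pairing, protein fold context, atom-density profiles of
real interfaces, or contact networks where one atom touches many partners.
Green tests therefore demonstrate that the algorithms implement their
stated rules and recover planted structure under noise -- not that the
biological conclusions transfer to an arbitrary complex.

## Problem sizes and determinism

The shipped tests run tetraloop scenes of 3-11 loops (a few hundred atoms)
and tripod scenes of 8 sites (~700 atoms); the noise-sensitivity
experiment uses 50 replicate scenes per noise level at sigma 0, 0.3, 0.6
and 1.0 Å. These sizes exercise every code path while keeping a full test
run in the minutes range. All randomness flows through explicit seeds
(`withr::with_seed`), so every reported number is exactly reproducible;
the bootstrap requires its seed as a mandatory argument for the same
reason.

## Known limitations

- Contact rules are a documented approximation; archival composition
  tables match published ones in structure and ranking, not to the digit.
- De novo motif detection is out of scope: kink-turns, loop-E and junction
  inventories must be supplied as annotations (tetraloops can be detected
  from a dot-bracket secondary structure).
- Only the first model of multi-model files is read; no symmetry
  expansion.
- The knob heuristic is a stand-in for convex-patch extraction; on real
  surfaces the knob inventories of the two methods may differ in ways the
  source material does not allow us to quantify.
- The tripod list is unfiltered by visual inspection, so on real
  structures it may include geometrically valid sites a curator would
  discard.
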