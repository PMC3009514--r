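# ribomotif

Analysis of how ribosomal proteins bind structural motifs of ribosomal
RNA, for structural bioinformaticians working with protein–RNA complexes
(e.g. the ribosomal subunits 1S72, 2AWB, 1FJF).

From a PDB/mmCIF structure and a sidecar motif annotation file, the
package:

- extracts **protein–RNA contact surfaces** (R-CS / P-CS) with transparent
  distance rules: contact = heavy-atom pair ≤ 4.5 Å, hydrogen bond =
  N/O–N/O pair ≤ 3.5 Å;
- tabulates **interface composition** — atom types, the
  phosphate–ribose–base (P-R-B) partition of nucleotide atoms, amino-acid
  frequencies, structural-element frequencies — with interface-level
  **bootstrap standard errors**;
- superposes tetraloop-anchored interfaces into a common frame with
  **Horn's quaternion absolute-orientation** method (closed-form,
  reflection-free least squares) and builds discretized polar
  **interaction maps**: atom densities over (zenith θ, azimuth φ) cells,
  majority-rule physicochemical colouring, and the four
  nucleotide-backbone regions;
- searches protein surfaces for the **tripod** motif: three convex
  amino-acid knobs at the vertices of a near-equilateral triangle
  (sides l₁,l₂,l₃ ∈ (7,10) Å, angles α₁,α₂,α₃ ∈ (40°,70°)) cradling a
  single extruded nucleotide, accepted when the best-permutation rigid
  superposition onto the fingerprint triangle has RMSD ≤ 1.5 Å and the
  nucleotide's contact counts satisfy **B ≥ R, R ≥ P, B > P**;
- generates **ground-truthed synthetic scenes** (rigid tetraloop copies
  with backbone-hugging interfaces; planted tripods plus decoys violating
  each gate) on which the entire pipeline is tested.

## Worked example

Generate a synthetic complex with three planted tripods and five decoys,
then run the search:

```r
library(ribomotif)

scene <- make_tripod_scene(synthetic_spec(seed = 1, noise_sigma = 0))
hits  <- search_tripods(scene$model)
hits[, c("nt_resno", "base", "aa1", "aa2", "aa3", "prb", "hbond")]
#>   nt_resno base    aa1    aa2    aa3    prb hbond
#> 1      100    G Arg-11 Ser-12 Leu-13 2-4-11  TRUE
#> 2      200    A Gln-21 Lys-22 Glu-23  0-2-7  TRUE
#> 3      300    G Arg-31 Ala-32 Thr-33  1-5-9  TRUE
attr(hits, "stage_counts")
#>         knobs      triplets geometry_pass      accepted
#>            20             6             4             3
```

Exactly the three planted sites are recovered, with their engineered
P-R-B contact counts (`2-4-11` means 2 phosphate, 4 ribose, 11 base
contact pairs) and hydrogen-bond flags; the decoy with inverted
composition passes the geometry gates (`geometry_pass = 4`) and is
removed by the B ≥ R ≥ P filter.

Tetraloop superposition and the interaction map:

```r
scene <- make_tetraloop_scene(synthetic_spec(seed = 1))
res <- run_map(scene$model, scene$annotations)
round(res$rmsd, 2)
#>  TL101  TL201  TL301  TL401  TL501  TL601  TL701  TL801  TL901 TL1001 TL1101
#>   0.00   0.41   0.42   0.47   0.45   0.48   0.36   0.45   0.48   0.48   0.43
res$coverage
#> [1] 0.9898477
```

All eleven loop copies superpose onto the reference below 1 Å RMSD (the
rigid-tetraloop regime), and 99% of interface atoms fall inside the four
backbone regions of the map — the synthetic analogue of interfaces
concentrating along the tetraloop backbone.

The published P-R-B arithmetic:

```r
ref <- ribosome_rcs_composition()
prb_summary(composition_table(ref$atom, ref$rcs))
#> phosphate    ribose      base
#>     18.85     60.02     21.13
```

A thin command-line front end over the same functions lives at
`inst/scripts/ribomotif.R`
(`Rscript ribomotif.R composition|map|tripods --structure … --out …`).

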