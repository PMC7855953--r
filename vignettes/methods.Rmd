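---
title: "Surface reduction and complementarity search: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surface reduction and complementarity search: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppigrid)
```

`ppigrid` predicts the interaction interface of two partner proteins by
reducing each solvent-accessible surface to six 2D property images and
finding the placement of the two image sets with maximal property
complementarity. This vignette describes the model, its assumptions, every
tunable parameter, the numerical conventions, and what the synthetic test
conditions do and do not demonstrate.

## The model

The central assumption is that an interaction interface is a *patch* of
mutually complementary surface properties — opposite charges, mutually
hydrophobic residues, or mutually conserved residues — and that such a patch
survives a drastic reduction of the surface geometry. The reduction
deliberately discards shape detail: it keeps only which properties sit next
to which on the surface, which is why the search tolerates moderate
conformational difference between the unbound inputs and the bound complex.

### From atoms to faces

The accessible surface is a Shrake–Rupley point cloud: each heavy atom is
expanded by the probe radius and covered with quasi-uniform test points
(a golden-spiral construction); points inside any other expanded atom are
discarded. Atom depth is the minimum distance to a surviving point; residue
depth is the mean over the residue's heavy atoms; residues with depth below
`depth_cutoff` are the surface, and *all* heavy atoms of those residues are
carried forward. The generous 5 Å allowance intentionally keeps a shell of
sub-surface atoms whose charges still shape the electrostatic character of
the patch.

Surface atoms are partitioned by Lloyd's k-means from six *biased* seeds:
the atoms attaining the maximum and minimum of each coordinate. Seeding at
the axis extremes starts the faces on opposite sides of the protein and,
together with the absence of random restarts, makes the segmentation fully
deterministic. Because an interface can still straddle two faces, the entire
segmentation is recomputed after rotating the structure 45° about x and
then y, and the better of the two initializations is selected downstream
(by the top-10 score sum). With `use_pca_orientation` the structure is first
rotated onto its principal axes, which normalises the seeding across
arbitrarily posed inputs.

### From faces to grids

Each face is orthogonally projected onto its least-squares plane (first two
principal axes of the face's coordinate covariance, centred on the face
centroid). Ångström units are preserved, so a face's 2D extent remains
proportional to its 3D extent. The projected coordinates are binned into
`bin_size` × `bin_size` boxes anchored at the minimum corner; a box stores
the arithmetic mean of its atoms' property and a complete box→atom table for
mapping predictions back onto the structure.

Empty boxes hold 0, and the properties are arranged so that 0 is neutral:
charge is naturally centred, the Wimley–White interfacial scale is
approximately centred, and conservation grades (1–9) are shifted to
grade − 5 before gridding (switchable via `center_conservation`). A neutral
empty value matters because the cross-correlation would otherwise reward or
penalise placements that merely overlap empty space.

### The complementarity search

For each of the 36 face pairs the two grids are compared by *full* 2D
cross-correlation — the lag-indexed sum of element-wise products over every
overlapping placement, including partial corner overlaps — so patch size is
not fixed in advance: corner lags test small patches, central lags large
ones. Partner B's grids are additionally resampled over in-plane rotations
in `rotation_step_deg` steps. For hydrophobicity and conservation the best
score is the maximum (hydrophobic-with-hydrophobic, conserved-with-
conserved); for charge it is the minimum, because complementary charge
pairs values of opposite sign and their products are negative.

Two decision rules turn scores into a prediction:

* **Initialization choice.** The sum of the top `top_m` (= 10) scores is
  compared between the unrotated and the 45°/45°-rotated initialization;
  the larger sum wins (smaller for charge), ties keep the unrotated one.
* **Consistency.** A property's prediction is *consistent* when all
  `top_m` placements involve the same two faces — many different
  sub-placements of one face pair are strong evidence for that pair.
  Otherwise the modal pair is reported with `consistent = FALSE`.

Properties are scored independently; the final answer is the first
consistent property in `property_order` (default charge → conservation →
hydrophobicity). The order is a policy choice: charge complementarity is the
least ambiguous signal, conservation the most universal, hydrophobicity the
most promiscuous. In `antibody_mode` the top charge placement is used
unconditionally, since variable-region binding is captured poorly by
conservation or hydrophobicity. A `second_interface` flag repeats selection
with the winning face pair excluded, for proteins with multiple binding
sites.

The winning placement's overlapping occupied boxes are traced back through
the box→atom tables (partner B's through the rotation's cell map) to residue
sets on both partners.

### Significance and evaluation

The shuffle test permutes property values among each protein's surface atoms
(geometry, faces and box memberships fixed), rebuilds the grid values and
recomputes the *entire* observed statistic — both initializations, the
top-10-sum choice between them, and the resulting top score. Repeating this
`n_shuffles` times gives a null distribution; the empirical p is the
fraction of replicates at least as extreme as the observation. Recomputing
the full selection inside each replicate matters: the observation is the
better of two initializations, so replicates must be too, otherwise the null
p-values would be skewed low. With constant properties every permutation
reproduces the observation and p = 1 by construction. The plain empirical
fraction is reported (a 7/1000 tail gives p = 0.007); the
(count + 1)/(n + 1) correction is available via `corrected = TRUE`.

Predictions are evaluated against the bound complex as a residue-level
confusion matrix. A residue is a true interface residue when any of its
heavy atoms is within `interface_cutoff` of a heavy atom of the partner
(5 Å standard; 10 Å as a forgiving variant for whole-patch predictors whose
rim residues fall just outside 5 Å). The evaluation universe is every
residue of the subunit — not only surface residues — so accuracy reflects
the full classification problem. Partners are combined by macro-averaging
the metrics (pooling counts is available via `pooled = TRUE`); a metric
whose denominator is zero is reported as 0.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `probe_radius` | 1.4 | Å | water probe of the accessible surface |
| `n_sphere_points` | 240 | – | test points per atom sphere |
| `depth_cutoff` | 5 | Å | residue depth bound for surface membership |
| `k_faces` | 6 | – | number of k-means faces |
| `bin_size` | 5 | Å | grid box edge; larger trades resolution for robustness |
| `reinit_angles_deg` | (45, 45) | ° | rigid x/y rotation of the second initialization |
| `rotation_step_deg` | 10 | ° | in-plane rotation sampling of partner B's grids |
| `top_m` | 10 | – | placements inspected by both decision rules |
| `min_overlap_bins` | 4 | boxes | minimum occupied overlap of a scored placement |
| `n_shuffles` | 1000 | – | shuffle-test replicates |
| `interface_cutoff` | 5 | Å | true-interface heavy-atom distance |

`min_overlap_bins` is a guard of this implementation: raw (unnormalised)
correlation at one-box overlaps reduces to a single product and is
noise-prone; set it to 1 to score every placement.

## Numerical conventions

* **Determinism.** Everything outside the shuffle test is deterministic:
  biased seeding replaces random k-means restarts; k-means ties go to the
  lowest atom/centroid index; score ties are broken lexicographically by
  (face A, face B, rotation, lag); initialization ties keep the unrotated
  pose; projection axis signs are fixed by non-negative skewness of the
  projected coordinates. All randomness flows from `rng_seed`.
* **Rotation resampling.** Grid rotations use nearest-neighbour resampling
  into a bounding grid; multiples of 90° are exact cell permutations, and
  the cell map is retained so rotated boxes still trace back to atoms.
* **Cross-correlation.** The kernel is direct summation (via `arma::conv2`);
  the test suite holds it to exact agreement with a brute-force double loop
  on integer grids and 1e-8 on floats.
* **Degenerate inputs.** A single-atom face projects to a 1 × 1 grid; an
  emptied k-means cluster is re-seeded with the point farthest from its
  centroid (never emptying another cluster); collinear atom clouds make
  PCA orientation an error; structures with no heavy atoms, properties
  absent on a partner, and empty overlap regions are errors with named
  causes.

## The synthetic study conditions

The fixture generator builds "blob proteins": pseudo-atoms quasi-uniform on
a closed surface (sphere, ellipsoid, or two-lobed), with small seeded
jitter, grouped into contiguous residues, written as standard PDB/PQR/
conservation-table files. The default conditions — 80 residues × 4 atoms on
a 16 Å sphere, partners posed at a 1.5 Å surface gap, ±1 charges engineered
on the true contact patch at 5 Å — emulate the engineered-charge
proof-of-concept experiment at the scale of a small globular subunit, and
were chosen once as that: a realistic small-protein scale that leaves the
planted patch a minor fraction (roughly a tenth) of the surface.

`perturb_structure()` emulates the coherent low-frequency distortions
produced by normal-mode analysis with a sum of three seeded long-wavelength
sinusoidal displacement fields, scaled linearly so the first-atom-per-
residue (Cα-equivalent) RMSD hits the target exactly. It reproduces the
relevant stressor — smooth, correlated displacement at a controlled
amplitude — without an eigensolver; an elastic-network option would be the
natural extension.

What passing these conditions shows: the reduction preserves planted
complementarity patches; the search finds them; the shuffle p-value is
calibrated (uniform under null properties) and extreme under planted
signal; predictions survive 6 Å of smooth distortion. What it does not
show: performance on real protein geometry (side chains, cavities,
non-convex faces), on real charge distributions from force-field
assignment, or on real evolutionary-rate patterns — blob surfaces are
hollow shells on which every residue is a surface residue, and their
properties are engineered, not physical.

Problem sizes in the shipped tests and the acceptance script are chosen at
desk scale: ten seeded fixture pairs for recovery and distortion, 200
shuffle replicates for planted-signal p-values, and fifty 200-replicate
runs (at 30° rotation steps) for the null-uniformity check.

## Known limitations

* The 2D projection of a strongly non-convex face can fold distinct surface
  regions onto the same box; the PCA plane minimises but does not eliminate
  this, and no unfolding is attempted.
* In-plane grid rotation approximates the continuous orientation search;
  nearest-neighbour resampling can drop or duplicate boundary cells at
  non-right angles.
* Raw correlation scores scale with patch size and property magnitude, so
  scores are comparable within one property and protein pair but not across
  properties; the consistency rule, not the absolute score, carries the
  decision across properties.
* Hollow-shell fixtures leave the interior "accessible" to the surface
  construction; real (solidly packed) proteins do not have this issue, and
  the depth computation is exercised against analytic exterior surfaces in
  the tests.
* CAPRI-style docking-quality ranking and comparisons against external
  interface-prediction servers are out of scope.
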