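---
title: "Side-chain contact geometry in canonical polar frames"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Side-chain contact geometry in canonical polar frames}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scpolar)
```

## The question and the model

Arginine and lysine both carry a positive charge at the end of a long side
chain, but they solvate very differently: the planar, resonance-stabilized
guanidinium of arginine hydrogen-bonds only in its molecular plane and
presents two poorly solvated hydrophobic faces, while the lysine ammonium
is solvated roughly isotropically. `scpolar` measures the structural
signature of this difference in protein structures. For every arginine and
lysine residue it collects the neighbouring side chains, superposes each
(central, neighbour) pair into a residue-specific *canonical frame*, and
summarizes where neighbour atoms sit in spherical-polar coordinates. In
such a frame, contacts "above and below" the guanidinium plane (axial,
polar angle near 0 or 180 degrees) can be distinguished from in-plane
(equatorial, near 90 degrees) hydrogen-bonding positions.

The canonical frame is defined by three anchor atoms and fixed reference
coordinates:

* arginine — CZ pinned to the origin and (CZ, NH1, NH2) rotated onto
  ((0,0,0), (0.5, 0.87, 0), (0.5, -0.87, 0)): the guanidinium lies in the
  xy-plane, its NH nitrogens symmetric about +x, NH1 at positive y;
* lysine — NZ pinned to the origin and (NZ, CE, CD) rotated onto
  ((0,0,0), (-1, 0, 0), (-1.34, 0.94, 0)): the Cd–Ce–Nz plane is the
  xy-plane with the aliphatic tail along -x.

The transform is rigid: translate the origin atom to (0,0,0), then apply
the proper rotation that best aligns the translated anchor triple with the
reference triple, computed by the Kabsch SVD construction *about the
pinned origin* — no centroid re-centering. The same transform moves every
atom of both residues, so all internal geometry is preserved exactly.

Two deliberate geometric subtleties follow from the definitions. First,
the reference triples are *dimensionless frame coordinates*, not bond-
length-scaled positions; the rotation is applied without scaling, which
orients the plane and bisector correctly regardless of the ~1.33 Å real
C–N bond lengths. Second, distance *cutoffs* are measured against the
defining-atom set (Arg: NE, CZ, NH1, NH2; Lys: CD, CE, NZ) while polar
coordinates are measured from the origin atom alone; the two reference
points differ by construction, and the choice of origin atom does shape
the angular distributions.

## Pinned-origin versus centroid-centered superposition

Classical Kabsch superposition centres both point sets on their centroids
before solving for the rotation. Because the frame definition explicitly
translates the terminal atom to the origin *first* and then aligns the
anchors, the package's default rotates about that pinned origin: the
origin atom lands at (0,0,0) exactly, and the anchors land exactly on the
reference triple whenever the input anchors are a rigid motion of it. A
centroid-centered variant (`method = "centroid"` in
`to_canonical_frame()`) is kept for sensitivity analysis; for ideal
anchors the two agree, and for distorted real anchors they differ only in
how residual strain is distributed. Degenerate (collinear) anchor triples
are rejected with an explicit error rather than silently producing an
ill-conditioned rotation.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| extraction cutoff | 5 Å | a neighbour is kept when any of its side-chain heavy atoms is within this distance of the defining-atom set |
| polar cutoff | 6 Å | closest-atom points farther than this are dropped from polar maps |
| shell bounds | 3.5 / 3.75 / 4.0 / 4.5 Å | nested half-open shells `(d_min, d_max]` used for per-atom-class renderings |
| subsample cap | 4000, first-N | cap on pairs entering the visual stages; a seeded random policy is available |
| density bins | 5° × 5° | resolves the ~60°-separated guanidinium NH directions with ≥10 bins between them |
| axial cap | 45° | θ < 45° or > 135° counts as axial in `axial_fraction()` |

All are plumbed through `run_config()`, so a bare configuration reproduces
the survey protocol on real data. Shell intervals are half-open so nested
cutoffs partition atoms exactly once. Solid-angle weighting of density
maps is off by default — raw closest-atom counts are reported, with the
caveat that bins near θ = 0/180° represent smaller Cartesian volumes; the
optional weighting divides each bin by sin(θ-centre), guarded below by the
sine of half a bin width so pole bins are not divided by a vanishing
weight.

Other conventions fixed here because the protocol leaves them open:

* **Alternate locations** — the highest-occupancy conformer wins, ties
  broken by alphabetical altloc code; deterministic and conventional.
* **Multi-model files** — model 1 only.
* **Side chain** — every heavy atom except backbone N, CA, C, O, OXT; CB
  counts, so alanine contributes one atom and glycine none (glycine is
  excluded as a neighbour type).
* **Sequence-adjacent residues** — included (no |Δseq| exclusion); an
  `exclude_seq_window` flag exists for sensitivity checks.
* **NH1/NH2 labels** — taken as deposited, never swapped: NH1-specific
  in-plane signal is part of the analysis. An optional `symmetrize_nh`
  flag duplicates each arginine pair rotated half a turn about the CZ–NE
  axis (the label-exchanged alignment) for label-free densities.
* **Closest-atom ties** — broken by atom-name order, deterministically.
* **Neighbour search** — within the supplied chain, matching the
  single-chain parsing of the culled-list protocol; the residue-level
  bounding-sphere prune never changes the result, and an O(n²) scan is
  the test oracle for exactness.

## The synthetic generator

Real structures are neither shipped nor downloaded; correctness is
demonstrated on synthetic structures with known ground truth. The
generator emulates exactly the features the pipeline consumes:

* ideal central residues whose anchors sit exactly on the reference
  coordinates (scaled by 1.33 for arginine, giving realistic ~1.33 Å
  guanidinium bonds; 1.0 for lysine, the printed reference scale), under
  arbitrary seeded rigid poses (rotations uniform on SO(3) via normalized
  quaternions, translations uniform in a 20 Å box);
* one neighbour per structure whose designated contact atom is planted at
  a controlled (r, θ, ψ) in the canonical frame, with the remaining
  neighbour atoms strung radially outward so the contact atom is strictly
  the closest;
* mixtures of angular components — axial caps, equatorial bands with ψ
  modes along the CZ→NH1/CZ→NH2 directions (default ±60°, mimicking
  in-plane hydrogen-bond geometry), and uniform-sphere components — with
  contact distances uniform on 3.2–4.5 Å, the close-contact shells of the
  density analyses.

Placements that would bury the contact atom in the central side chain
(closer than 1.5 Å to any central atom, or any neighbour atom closer than
1.5 Å to the central residue) are rejected and redrawn inside the seeded
draw, so generation is deterministic and generated files contain no
inter-residue clash below 1.5 Å. Within a residue, covalently bonded
atoms follow the idealized template geometry (bonds shorter than 1.5 Å,
as in real guanidinium groups).

What the generator does *not* emulate — and therefore what passing tests
do not show about real data: rotamer realism and internal side-chain
flexibility (templates are planar and idealized), crystallographic noise
beyond isotropic Gaussian jitter, correlated packing of multiple
neighbours around one central residue, backbone context, waters, and any
enrichment statistics. The generator validates the *machinery* (frames,
distances, angles, counts, determinism), not the biology.

Two presets encode the qualitative contrast the machinery must resolve:
`arg_like_population()` (non-polar Leu carbons axial, Asp carboxylate
oxygens equatorial) and `lys_like_population()` (both contact classes
spherically uniform). The acceptance suite checks that the recovered
axial fraction of non-polar contacts differs between the two by more than
0.3.

## Numerical precision and problem sizes

In-memory pipeline results are exact to floating-point precision: planted
(r, θ, ψ) are recovered to better than 1e-6 (degrees/Å) at zero jitter,
rotations are proper orthogonal to 1e-9, and all pairwise distances are
preserved to 1e-9 Å through the transform. PDB-format text fixtures carry
fixed-width coordinates with 3 decimals, so anything round-tripped
through files is reproducible only to ~1e-3 Å (about 0.02° in recovered
angles); for this reason the synthetic pipeline consumes the generator's
full-precision in-memory residues, while the text files serve as on-disk
fixtures and for interoperability.

The shipped test suite uses population sizes of 2000 pairs for parameter
recovery (binomial 99% CI half-width ≈ 0.026 around an axial fraction of
0.7), 800 pairs per preset for the Arg/Lys contrast, 50 random structures
against the brute-force oracle, 1e5 points for the uniformity check of
solid-angle weighting, and 1000 randomized trials for the rigidity and
round-trip invariants — sizes chosen so each property is measured well
inside its tolerance.

## Known limitations

* mmCIF input, symmetry/assembly expansion and cross-chain contacts in
  multi-chain files are out of scope (cross-chain search exists as an
  option only in the sense that all residues handed to `extract_pairs()`
  are searched; the loaders are single-chain).
* Backbone carbonyl interactions are not analyzed; neighbour atoms are
  side-chain heavy atoms only.
* Density maps are binned histograms of closest-atom points; no kernel
  density estimation and no significance testing of enrichment.
* The chain list is trusted as culled; resolution and R-factor are not
  re-validated from PDB headers.
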