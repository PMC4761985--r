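# scpolar

Arginine and lysine are both positively charged, yet they behave very
differently as neighbours in folded proteins: the planar guanidinium group
of arginine hydrogen-bonds only in its molecular plane and stacks
non-polar groups against its two faces, while the lysine ammonium shows
little orientational preference. `scpolar` is an R package for measuring
that contact anisotropy in protein structures. It is written for
structural bioinformaticians who want to survey side-chain environments
across a non-redundant set of PDB chains — and for anyone who needs a
rigorously tested canonical-frame / spherical-polar toolkit with a
ground-truth synthetic generator.

## What it computes

For every central arginine or lysine in a chain, the package finds each
non-glycine residue whose side-chain heavy atoms come within 5 Å of the
central *defining-atom set* (Arg: NE, CZ, NH1, NH2; Lys: CD, CE, NZ), and
rigidly superposes each (central, neighbour) pair into a canonical frame:
the terminal atom (CZ or NZ) is translated to the origin and the anchor
triple rotated by a pinned-origin Kabsch rotation onto fixed reference
coordinates,

    Arg: (CZ, NH1, NH2) -> (0,0,0), (0.5, 0.87, 0), (0.5, -0.87, 0)
    Lys: (NZ, CE, CD)   -> (0,0,0), (-1, 0, 0),     (-1.34, 0.94, 0)

so the guanidinium (or Cδ–Cε–Nζ) plane becomes the xy-plane. Neighbour
atoms are then summarized in spherical-polar coordinates: r from the
origin atom, θ from +z (θ = 90° means in-plane), and ψ about z from +x.
The package reports closest-atom polar maps (6 Å cutoff), distance-shell
selections per atom class (carboxylate O, hydroxyl O, thioether S, …),
ψ × θ density grids, interaction count tables, and an axial-fraction
statistic (fraction of contacts with θ < 45° or θ > 135°) that quantifies
the above/below-plane versus in-plane segregation.

Real input is a Pisces-style culled chain list plus a directory of PDB
files. A synthetic mode generates structures with neighbours planted at
known (r, θ, ψ) under random rigid poses, so every stage is testable with
exact ground truth — no downloads needed.

## Worked example

An "Arg-like" synthetic population plants non-polar contacts (Leu side
chain carbons) above and below the guanidinium plane and polar contacts
(Asp carboxylate oxygens) in the plane:

```r
library(scpolar)

spec <- arg_like_population(n_pairs = 300, seed = 42)
cfg  <- run_config(mode = "synthetic", population = spec)
ex   <- run_extract(cfg)
pts  <- polar_points(ex$pairs)

ex$counts[ex$counts$n_pairs > 0, ]
#>    central_type neighbor_type n_pairs
#> 4           ARG           ASP     151
#> 10          ARG           LEU     149

axial_fraction(pts[pts$neighbor_type == "LEU", ], theta_cap = 45)
#> [1] 1
axial_fraction(pts[pts$neighbor_type == "ASP", ], theta_cap = 45)
#> [1] 0
```

All 300 planted pairs are recovered and tallied by residue-type cell; the
Leu carbon contacts are entirely axial (fraction 1) and the Asp oxygen
contacts entirely equatorial (fraction 0), the segregation pattern
characteristic of the guanidinium group.

The frame transform itself can be checked against the printed reference
coordinates — an ideal arginine under an arbitrary rigid pose comes back
with its anchors exactly on the reference triple, and the polar
conventions follow the frame captions:

```r
arg <- apply_transform(random_rigid_transform(7),
                       build_ideal_residue("ARG", bond_scale = 1))
residue_xyz(to_canonical_frame(arg)$central, c("CZ", "NH1", "NH2"))
#>       x     y z
#> CZ  0.0  0.00 0
#> NH1 0.5  0.87 0
#> NH2 0.5 -0.87 0

spherical_polar(c(1, 0, 0))
#>     r theta   psi
#>     1    90     0
```

See `vignettes/sidechain-contact-geometry.Rmd` for the methods account:
frame definitions, cutoff conventions, the synthetic generator's model
and its limits, and all numerical choices.

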