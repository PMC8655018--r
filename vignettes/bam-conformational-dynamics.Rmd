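---
title: "Quantifying BAM conformational dynamics: models, conventions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying BAM conformational dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bamdyn)
```

## The system and the quantities

The β-barrel assembly machinery (BAM) of Gram-negative bacteria folds
β-barrel proteins into the outer membrane. Its central component, BamA, is a
16-stranded β-barrel whose first and last strands (β1, β16) meet at a
*lateral seam* that opens and closes; four lipoproteins (BamB–E) hang below
the membrane plane and, together with BamA's periplasmic POTRA domains, form
a *periplasmic ring*. The machine's two principal conformations —
inward-open and outward-open — differ by an in-plane rotation of this ring
of roughly 60° and by whether the seam is zipped shut.

`bamdyn` implements the quantitative metrics used to characterise this
system from structures and trajectories:

1. **Ring rotation angle** — the order parameter separating the two states.
2. **Seam backbone hydrogen bonds** — per-frame counts, moving average, and
   an open/tenuous/closed classification.
3. **POTRA5 tracking** — in-plane position, displacement between states,
   and area explored.
4. **Superposition and RMSD** — Kabsch fitting with residue-identity
   pairing.
5. **Crosslink screening** — Cβ–Cβ distances for conformation-locking
   disulfide design.
6. **Nanodisc density averaging** — a seeded Monte-Carlo simulation, with
   an exact analytic oracle, of why the membrane-scaffold belt disappears
   from aligned single-particle averages.

A synthetic-structure generator produces complexes and trajectories with
known ground truth so that every metric is verifiable without downloading
anything.

## The rotation-angle metric

The angle is defined between two vectors in the membrane plane, both
anchored at the barrel center — the geometric center of the carbonyl
(backbone C) atoms of BamA residues 425–810. The reference vector points
from the barrel center to the combined carbonyl-carbon center of the
accessory lipoproteins in a designated reference structure (canonically the
inward-open complex, which defines 0°). The measured vector is the same
construction in the current frame. The signed angle from reference to
measurement, counterclockwise positive when viewed from the extracellular
side (the +normal of the membrane frame), is the rotation angle, wrapped to
(−180°, 180°] with optional unwrapping for continuous traces.

Two conventions matter and are fixed here:

* **Handedness.** The membrane normal points extracellular; with the
  right-handed in-plane triad this makes counterclockwise-from-outside
  positive. The outward-open state is then at *positive* ~60°.
* **Missing components.** If a complex lacks one accessory protein, that
  component is excluded from both the reference and the measurement, so
  reduced complexes remain comparable to the full one.

For trajectory frames, which share the simulation coordinate frame, the
angle is computed directly. Two independently deposited structures do not
share a frame, so the mobile structure's barrel Cα atoms (paired by author
residue number) are first Kabsch-superposed onto the reference barrel, and
the reference's membrane frame is used for both. This superpose-first rule
is this package's choice for static pairs; the trajectory definition needs
no such step.

The membrane frame itself has two modes. `z_axis` (default) takes the +z
axis of the input coordinates as the normal — the universal convention of
membrane simulation systems. `barrel_principal` derives the normal from the
barrel atoms' covariance. A cylindrically symmetric shell has two nearly
degenerate in-plane eigenvalues and one distinct axial eigenvalue, so we
take the *spectrally isolated* eigenvector (the side of the larger
eigenvalue gap) rather than blindly taking a smallest or largest moment:
the barrel of BamA is wider (~50 Å) than it is tall (~30 Å), so the
symmetry axis is not an extreme principal axis for every aspect ratio. The
sign is set so the normal points away from the POTRA5 side (periplasm).

## Seam hydrogen bonds

The structures and trajectories of interest report small integer numbers of
backbone hydrogen bonds between β1 and β16 — zero to about four. The
counting rules are:

* Donor–acceptor N···O distance ≤ 3.5 Å (configurable).
* An angular condition: with explicit amide hydrogens, D–H···A ≥ 150°;
  without hydrogens (deposited structures, the synthetic generator), the
  N···O=C angle at the acceptor must be ≥ 120°. These are the conventional
  geometric cutoffs; nothing in the analyses depends delicately on them,
  and both are exposed in `hbond_criteria()`.
* Both donor directions are scanned (β1→β16 and β16→β1), and each donor
  binds at most its nearest qualifying acceptor, which prevents a
  bifurcated contact from inflating the integer count.

The per-frame counts are smoothed with a centered moving average whose
window shrinks symmetrically at the series edges; the window (default 51
frames) is a visible parameter, because published "moving average" traces
rarely state one. Classification of the smoothed series uses two
thresholds: `closed` at ≥ 2 bonds, `open` below 1 bond *only if the frame
has no N···O contact within the distance cutoff at all*, and `tenuous`
otherwise — a seam that keeps brushing a single contact while averaging
under one bond is a tenuously closed seam, not an open one.

Default strand ranges are β1 = 424–435 and β16 = 800–810, anchored to the
seam residues repeatedly named in the literature (G424, Y432, I806, G807,
K808, W810); exact strand boundaries vary by annotation and are
configurable.

## POTRA5 tracking and explored area

POTRA5 sits immediately below the barrel. Its per-frame in-plane position
is the projection of its Cα geometric center, *relative to that frame's
barrel center*, so whole-complex drift and rotation do not masquerade as
domain motion. Displacement between two states superposes the barrels
first (Cα 425–810), then measures the distance between POTRA5 centers —
the inward-open and outward-open positions are ~13 Å apart.

"Area explored in the membrane plane" is estimated two ways: the convex
hull of the track (default — deterministic, and checkable against an
independent hull construction), and an occupancy grid (visited cells ×
cell area), which does not credit unvisited interior. The hull is the
default because it is parameter-free; for strongly non-convex tracks the
occupancy grid with a ~1–2 Å cell is the better summary. POTRA5's default
residue range is 344–421, bracketing the residues the domain is known to
contain (G393, E396, R421); the boundary is configurable because domain
annotations differ.

## Superposition and RMSD

`kabsch_superpose()` is the standard SVD Kabsch solution with the
determinant correction, returning the proper rotation, translation, and
post-fit RMSD. `rmsd_between_models()` pairs atoms by the intersection of
(chain, residue number, atom name) — no sequence alignment, since all BamA
structures of interest share author numbering — and reports the paired
count alongside the RMSD. The default atom class for whole-model
comparisons is Cα: deposition differences (missing side chains, modelled
loops) make all-atom RMSD between independently refined models unstable,
while Cα pairing is robust. Published RMSD figures for such comparisons
rarely state their selection; ours is documented here and reported with
`n_atoms` so any comparison is auditable.

## Crosslink screening

A disulfide can form when two cysteine Cβ atoms are within roughly 4–7 Å.
`screen_pairs()` therefore classifies a candidate pair in each state as
`compatible` (≤ 7 Å), `incompatible` (≥ 12 Å), or `marginal` between; the
thresholds are arguments. Glycine positions fall back to Cα with a flag.
The package ships the published BamA panels as data
(`bundled_mutant_panels()`): the inward-open locks S502C/V706C and
G431C/G807C, the outward-open locks D503C/N681C and S425C/K808C, the
POTRA5–turn-4 pairs E396C/R583C and G393C/G584C, and the BamA×EspP
hybrid-barrel sites (806/807 × 1226–1234). A pair designed to lock one
conformation sits 15–23 Å apart in the opposite conformation — far beyond
disulfide range, which is exactly what makes it a conformational lock.

## The nanodisc averaging simulation

Nanodisc-embedded particles show almost no scaffold-belt density in
aligned averages regardless of belt diameter. The simulation demonstrates
why: a ring with the nanodisc's outer diameter (110, 130, or 170 Å for the
common scaffold belts) is rasterized on a pixel grid, displaced by a
random in-plane shift, and averaged over 5000 copies. The maximum shift is
`disc_radius − core_radius − mask` (core 40 Å diameter, mask 10 Å): the
room the disc boundary has while the aligned protein core stays inside.

Numerical choices, all deliberate:

* **Shifts live on the pixel lattice.** Each copy is the *same* rasterized
  ring displaced by an integer pixel offset drawn uniformly from lattice
  points within the max-shift disk (or square). Re-rasterizing at
  continuous centers changes the pixel count of the annulus with subpixel
  position and breaks mass conservation at the 10⁻³ level; lattice
  displacement conserves the integrated intensity exactly, and the test
  suite holds it to 1 part in 10⁶ and better.
* **The analytic oracle is the exact expectation.** The averaged map's
  expectation is the ring convolved with the shift distribution's
  probability mass function, computed by FFT. Because the shift
  distribution is exactly the discrete lattice distribution the sampler
  draws from, the only discrepancy between Monte Carlo and oracle is
  sampling variance, which scales as 1/√n.
* **Map distance is min–max-normalized RMSE**: root-mean-square pixel
  difference divided by the intensity range of the reference — the
  normalization used by standard image-comparison toolkits. At n = 5000,
  1 Å/px, 130 Å disc, the expected value is ≈1.6% and the package's
  acceptance threshold is 2%. The Frobenius-ratio relative error is also
  available (`method = "rel_l2"`); it runs ≈2× larger on these maps
  because much of the reference's norm sits in low-intensity smeared
  regions.
* **Grid default is 320 px at 1 Å/px**, the smallest round size that
  contains the 170 Å disc at its maximum 55 Å excursion with margin;
  `rasterize_ring()` errors with the required size if the grid cannot
  contain disc plus shifts.
* **Both shift distributions are exposed** (`uniform_disk` default,
  `uniform_square` alternative) because "random shifts in x and y" is
  genuinely ambiguous; every conclusion tested — mass conservation,
  convergence to the oracle, and the flattening of the radial profile with
  disc diameter — holds under both.

The summary statistic for the "averaged out" conclusion is the
peak-to-mean ratio of the radial intensity profile over the averaged
ring's support: it decreases monotonically from the 110 Å to the 130 Å to
the 170 Å disc, i.e. larger belts smear into flatter, fainter halos, while
the strongest residual intensity always sits just outside the protected
core — matching what reconstructions show around the BamA barrel.

## The synthetic generator: what it emulates, and what it does not

`make_toy_complex()` builds the geometry the metrics actually consume: a
cylindrical shell of pseudo-residues with real backbone atom names and
BamA author numbering (chain A, 425–810, radius 25 Å so the widest
diameter is the ~50 Å quoted for the barrel), four compact accessory
bodies below the membrane plane spanning a 180° arc on one side (the
lipoprotein ring sits beside, not around, the barrel — this keeps its
combined center off the barrel axis, which the rotation metric requires),
and a POTRA5 cluster at a configurable offset. Trajectory generators
script a ground-truth rotation schedule, an exact per-frame seam
bond count, or a POTRA drift path, with fresh isotropic Gaussian noise per
atom per frame; a fixed seed reproduces every output bit for bit.

`make_state_pair()` produces a matched inward-open/outward-open pair: the
ring rotated 63° about the barrel axis, POTRA5 displaced 13 Å in-plane,
and seam/loop marker residues sliding along the barrel wall so each
published lock pair is within disulfide range in its intended state and
15–23 Å apart in the other. These are synthetic stand-ins whose
state-defining parameters are inputs; what the package verifies on them is
that its measurement pipelines — reference building, superposition,
projection, screening — recover those parameters through the same code
paths used on deposited coordinates. `perturb_model()` adds isotropic
coordinate noise (expected post-fit RMSD ≈ √3·σ) to emulate the coordinate
scatter between independently refined models of one conformation.

What the generator does *not* emulate: real β-strand register around the
barrel, side chains beyond Cβ, membrane or solvent, B-factors, or any
physical force field. Passing tests therefore demonstrate correctness of
the *metrics* under controlled geometry and noise, not fidelity of any
simulation engine; conclusions about real BAM dynamics still require real
trajectories and structures, to which these tools apply unchanged.

## Parameters at a glance

| Parameter | Default | Units | Why |
|---|---|---|---|
| barrel residue range | 425–810 | author numbering | membrane-embedded BamA barrel |
| POTRA5 range | 344–421 | author numbering | brackets G393/E396/R421 |
| seam strands β1 / β16 | 424–435 / 800–810 | author numbering | named seam residues |
| H-bond N···O cutoff | 3.5 | Å | conventional backbone criterion |
| H-bond angle (no H / with H) | 120 / 150 | deg | conventional criterion |
| moving-average window | 51 | frames | visible, odd, centered |
| seam closed / open thresholds | 2 / 1 | bonds | published count regimes |
| crosslink compatible / incompatible | 7 / 12 | Å | Cβ–Cβ disulfide range |
| disc diameters | 110, 130, 170 | Å | MSP1D1 / MSP1E3D1 / MSP2N2 |
| core diameter, mask | 40, 10 | Å | protected aligned core |
| ring width | 10 | Å | nominal belt width, configurable |
| copies, grid, pixel | 5000, 320 px, 1 Å | — | shift room for the largest disc |

## Degenerate inputs and tie-breaks

Alternate locations resolve to highest occupancy, first-listed on ties.
Residue-range selections skip residues a model lacks but error when the
whole selection is empty. An accessory center that projects onto the
barrel axis is a degenerate reference and errors rather than returning an
arbitrary angle. Hull area for fewer than three distinct non-collinear
points is 0 with a warning. Glycine Cβ requests fall back to Cα with a
flag. The angle wrap keeps its half-open interval even when the true angle
is numerically exactly 180°.

## Problem sizes used in the test suite

The suite and the acceptance script run entirely on synthetic inputs at
sizes chosen to exercise every code path while keeping a full run around a
minute on one core: 100-frame rotation recoveries at 0.5 Å noise, 100
random fixtures per oracle-equivalence family, the nanodisc simulation at
the full 5000 copies for all three disc diameters, and state-pair
comparisons over ~70 barrel residues. The generators scale to larger
systems linearly if heavier stress testing is wanted.

## Known limitations

* Trajectory input is multi-model PDB; binary MD formats (DCD/XTC) should
  be converted upstream (e.g. with standard trajectory tools) — the
  package deliberately avoids binary trajectory parsing.
* Pairing is strictly by author numbering; structures renumbered against
  BamA convention need renumbering before comparison.
* The H-bond model is geometric, not energetic, and ignores sidechain and
  water-mediated bonds by design.
* The nanodisc simulation is the 2D averaging argument only: no CTF, no
  projection geometry, no 3D reconstruction.
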