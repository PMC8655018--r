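# bamdyn

Conformational-dynamics analytics for the β-barrel assembly machinery
(BAM), the five-component complex (BamA–E) that folds β-barrel proteins
into the outer membrane of Gram-negative bacteria. The package is for
structural biologists and simulators who need the standard quantitative
readouts of BAM's two-state mechanics — from deposited structures or from
MD trajectories — as reproducible, tested code.

## What it computes

**Ring rotation angle.** BAM's periplasmic ring (lipoproteins BamB–E plus
the POTRA domains) rotates ~60° in the membrane plane between the
inward-open and outward-open states. The metric measures the signed angle
θ between two in-plane vectors anchored at the barrel center **c** (the
geometric center of carbonyl carbons of BamA residues 425–810):

```
v_ref = Π(a_ref − c_ref),   v = Π(a − c),   θ = atan2(v_ref × v, v_ref · v)
```

where **a** is the carbonyl-carbon center of the accessory lipoproteins and
Π projects onto the membrane plane; θ is counterclockwise-positive viewed
from the extracellular side, and the inward-open reference defines 0°.
Complexes missing an accessory protein drop it from both sides.

**Seam hydrogen bonds.** Per-frame backbone N···O bonds between strands β1
and β16 (distance ≤ 3.5 Å plus an angular criterion, one bond per donor),
a centered moving average, and an open / tenuous / closed classification of
the lateral seam.

**POTRA5 tracking.** Barrel-relative in-plane position of the POTRA5
domain, displacement between conformational states (~13 Å between
inward- and outward-open), and area explored (convex hull or occupancy
grid).

**Superposition / RMSD.** SVD Kabsch fit with residue-identity pairing and
reported atom counts; broom-style `tidy()`/`glance()` accessors.

**Crosslink screening.** Cβ–Cβ distances of candidate cysteine pairs per
state, classified compatible (≤ 7 Å) / incompatible (≥ 12 Å) / marginal;
the published BamA lock panels ship as data. A pair that locks one state
sits 15–23 Å apart in the other.

**Nanodisc density averaging.** A seeded Monte-Carlo simulation of a
nanodisc boundary ring (110 / 130 / 170 Å) under 5000 random in-plane
shifts bounded by `disc_radius − core_radius − mask`, with an exact
discrete-convolution expectation as oracle — the argument for why the
scaffold belt averages out around the aligned BamA core.

A synthetic generator (`make_toy_complex()`, `make_rotation_trajectory()`,
`make_seam_trajectory()`, `make_drift_trajectory()`, `make_state_pair()`)
provides ground-truth inputs for all of the above, so the whole package is
testable offline.

## Worked example

```r
library(bamdyn)
sel <- complex_selection()          # barrel 425-810, BamB-E, POTRA5, seam

# a 100-frame synthetic trajectory rotating the ring 0 -> 60 deg
spec <- toy_spec(seed = 42, noise_sigma = 0.5)
traj <- make_rotation_trajectory(spec, seq(0, 60, length.out = 100))
series <- rotation_series(traj, sel)
series
#> # A tibble: 100 x 2
#>   time_ns angle_deg
#> 1       0  5.16e-15
#> 2       1  1.15e+ 0
#> 3       2  1.50e+ 0
#> # i 97 more rows
sqrt(mean((series$angle_deg - seq(0, 60, length.out = 100))^2))
#> 0.56      # degrees RMSE against the scripted schedule, at 0.5 A noise

# two-state worked examples on the synthetic inward/outward stand-in pair
pair <- make_state_pair(toy_spec(seed = 42))
ref  <- build_reference(pair$inward_open, sel)
rotation_angle(pair$outward_open, sel, ref, superpose = TRUE)
#> 60.5      # deg, vs the 63 deg the pair encodes
displacement_between_states(pair$inward_open, pair$outward_open, sel)
#> 13.6      # A POTRA5 shift between states

screen_pairs(pair, bundled_mutant_panels("inward_lock"))
#>      pair        state distance classification
#> 1 502/706  inward_open     4.28     compatible
#> 2 431/807  inward_open     5.00     compatible
#> 3 502/706 outward_open    21.23   incompatible
#> 4 431/807 outward_open    16.57   incompatible

# nanodisc averaging: 5000 shifted copies of a 130 A ring vs the exact
# expectation
sp  <- ring_spec(disc_diameter = 130, n_copies = 5000, seed = 42)
avg <- simulate_average_map(sp)
100 * map_distance(avg, analytic_expected_map(sp))
#> 1.03      # % min-max-normalized RMSE (pure Monte-Carlo variance)
peak_to_mean_ratio(avg, sp)
#> 1.85      # falls to 1.68 for the 170 A disc: bigger belts average away
autoplot(avg)
```

The numbers above are what the code prints: the rotation recovery RMSE,
the rotation/displacement readouts of the state pair, the screening table,
and the Monte-Carlo error are all recomputed, not stored.

Interpretation: the rotation series recovers the scripted schedule to
about half a degree under realistic positional noise; the state pair
reproduces the outward-open geometry (ring rotated ~60°, POTRA5 moved
~13 Å, inward-open lock pairs pushed to 16–21 Å); and the 5000-copy
nanodisc average sits ~1% from its analytic expectation while the
peak-to-mean ratio of its radial profile drops with disc size — the
belt's density spreads into a faint halo around the protected core.

A shell entry point wrapping the same functions ships at
`system.file("cli", "bamdyn.R", package = "bamdyn")`, with subcommands
`ring-angle`, `seam-hbonds`, `potra-track`, `nanodisc-sim`,
`crosslink-screen`, `rmsd`, and `synth`.

## Documentation

The methods vignette
(`vignettes/bam-conformational-dynamics.Rmd`) documents the models,
conventions (handedness, frames, pairing), numerical choices (lattice
shifts and mass conservation, the map-distance definition, grid sizing),
the synthetic generator's scope, and known limitations.
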