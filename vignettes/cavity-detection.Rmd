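---
title: "Dual-probe grid detection of protein cavities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-probe grid detection of protein cavities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pocketgrid)
```

## The model

pocketgrid locates and measures protein cavities by mathematical morphology
on a regular 3D lattice. The structure is voxelized at spacing $h$; a grid
point is **occupied** when it lies within the van der Waals radius of any
atom. Two spherical probes then screen the empty space:

* the **Probe In** (radius $r_{in}$, default 1.40 Å — a water molecule)
  defines the inner extent of cavities. A grid point $c$ is a valid Probe In
  center when $\lVert c - a\rVert > r_{vdW}(a) + r_{in}$ for every atom $a$
  (the probe may touch but not overlap). The **covered** set is the
  morphological dilation of the centers by the probe ball: every point
  within $r_{in}$ of a valid center.
* the **Probe Out** (radius $r_{out}$, default 4.0 Å) is too large to
  descend into pockets; the region it covers defines the **cavity
  ceiling**, the boundary between cavity and bulk solvent.

A cavity point is a point reachable by the small probe but not by the large
one. Two inner-limit conventions are supported:

* `molecular_surface` (default): cavity $=$ covered$_{in}$ $\wedge\neg$
  covered$_{out}$ $\wedge\neg$ occupancy — the cavity wall is the van der
  Waals surface;
* `sas`: cavity $=$ centers$_{in}$ $\wedge\neg$ covered$_{out}$ — the wall
  is the solvent-accessible surface traced by the small probe's center.

Cavity points are partitioned into maximal **26-connected** components (two
voxels connect when each index coordinate differs by at most one), each
characterized by

* volume $=$ (number of voxels) $\times h^3$, exactly;
* area $= h^2 \times$ (number of voxel faces whose 6-neighbor across the
  face is outside the component). Faces shared with *another* cavity count
  for both sides, keeping per-cavity areas separable. Voxelized area
  overestimates a smooth surface by an orientation factor of up to 1.5 (a
  sphere's staircase surface), a known property of the convention, so areas
  are comparable between runs at one spacing but are not smooth-surface
  estimates;
* center of mass $=$ unweighted mean of the voxel coordinates (all voxels
  are identical — no occupancy weighting);
* lining residues: a residue contributes when any of its atoms is within
  $r_{vdW} + r_{in} + m$ of a cavity voxel, with contact margin $m$
  defaulting to one grid spacing.

Cavities below the volume threshold (default 5 Å$^3$) are suppressed;
survivors are ranked by volume, ties broken on the minimal $(i,j,k)$ index,
and tagged `KAA`, `KAB`, ... in rank order (676 tags maximum).

## Which probe placements count: the bulk rule

Placing probes at *every* non-overlapping grid point would let the Probe
Out sit inside any sealed void larger than itself, erasing exactly the
cavities it is supposed to bound. Because the Probe Out's role is to trace
the border between cavity and bulk — it "rolls in" from open solvent — the
pipeline keeps only Probe Out centers 26-connected to the grid boundary
(`bulk_centers()`); the grid's padding contract guarantees that boundary is
bulk. The Probe In is *not* restricted: a sealed interior void the small
probe can occupy is reported as a cavity. Users probing for true
solvent-accessible pockets only can compare against an `sas`-mode run or
inspect the cavity's lining.

## Grid construction and exactness guarantees

The lattice is axis-aligned with the input frame and anchored to the
protein: the origin sits at the van der Waals–inflated bounding box minus a
padding of $r_{out} + r_{in} + h$, so a full shell of bulk solvent
surrounds the structure and boundary voxels never need special casing.
When a box or ligand-adjacent search region reaches beyond the protein the
lattice is extended by *whole steps* only. Two exact consequences, both
enforced by tests:

* a box containing the protein plus padding reproduces the whole-protein
  result voxel-for-voxel;
* translating all atoms by integer multiples of $h$ translates every field
  exactly — volumes and areas are invariant.

Steered segmentation clips cavity *membership* to the search region after
morphology (which always sees all atoms) and before connectivity labeling,
so a cavity cut by a box splits into separately labeled, separately
measured sub-pockets, and segmentation is a pure restriction of the
whole-protein solution. Box faces are closed; a voxel layer exactly on a
cutting plane belongs to both halves, which bounds the double count when
sub-pocket volumes are compared with the uncut cavity.

Dilation is computed with an exact squared Euclidean distance transform
(separable lower-envelope algorithm) over the center field; on integer
lattice offsets it is bit-identical to the union-of-balls definition, and
the tests verify this against an independent shifted-OR implementation and
a literal double loop.

## Numerical behavior and its limits

Three idealized monotonicity statements hold in the continuum but pick up a
one-voxel boundary layer on a lattice, because probe centers are snapped to
grid points (a displacement of up to $\sqrt{3}h/2$):

* covered$_{out}$ $\subseteq$ covered$_{in}$: discrete violations are
  confined to the boundary layer of covered$_{out}$ and never affect cavity
  points (the cavity is a subset of covered$_{in}$ by construction);
* cavity sets grow with $r_{out}$: cavity *volumes* are non-decreasing
  across the 2–8 Å scan when the scan shares one lattice whose spacing
  divides the 0.5 Å radius step (`probe_out_scan()` shares the lattice;
  the tests use $h = 0.25$). When the radius step is *not* commensurate
  with $h$, the coverage depth $h\lceil (r_{vdW}+r)/h\rceil - r$
  oscillates with $r$ and whole one-voxel sheets appear and vanish over
  flat walls — volumes can then dip by a few percent between adjacent
  radii. Voxel-level set inclusion holds up to the one-voxel rim layer of
  the larger probe's covered field even at commensurate spacing;
* cavities shrink with $r_{in}$: voxel-exact in `sas` mode, where the
  cavity is a pointwise threshold of the atom-clearance field. In
  `molecular_surface` mode the two probes open any feature wider than both
  probes identically, so the entire difference is sub-probe crannies plus
  one-voxel phase noise of arbitrary sign ($-5.6$ Å$^3$ at $h=0.6$,
  $+7.4$ Å$^3$ at $h=0.25$ on the same fixture) — no exact inequality
  exists to assert there.

A genuine geometric fact, not a discretization artifact: a spherical probe
of radius $r$ nests exactly into a hemispherical pocket of mouth radius
$r$. With the default 4 Å Probe Out, a 4 Å hemispherical pocket is
therefore bulk-covered and essentially vanishes. The analytic-recovery test
for the 4 Å pocket consequently uses a 6 Å ceiling probe — large enough to
bridge the mouth, small enough that the rim fillet it cannot reach stays
a minor term; wide, shallow crevices genuinely require a larger ceiling
probe, and the probe-scan benchmark exists precisely to choose it.

## Synthetic fixtures: the stated world

All tests run on generated PDB-format toys with analytically known
geometry; nothing is downloaded.

* `make_hollow_sphere()`: Fibonacci-sphere shells (carbon-like atoms,
  radius 1.7 Å, lattice/layer spacing 1.0 Å) whose innermost layer is
  tangent to a void of radius 5 Å by default. Detected volume converges to
  $\tfrac43\pi r^3 \approx 523.6$ Å$^3$ from below (at $h=0.25$ Å the run
  reports within 3%).
* `make_slab_pocket()`: a dense atom slab whose top layer is at $z=0$ with
  a hemispherical pocket opening upward. Lattice atoms intruding into the
  pocket sphere are removed and the wall is **lined** with atoms placed
  exactly tangent to the analytic sphere; without lining the cut-lattice
  wall is craggy and the probe-in opening systematically undershoots the
  stated hemisphere (~15% at radius 4 Å). The pocket sphere is centered on
  the top lattice plane so the lining rim is flush and the void below
  $z=0$ is exactly a hemisphere.
* `make_channel()`: a block with a cylindrical through-tunnel, optionally
  widened into spherical chambers — the two-chamber variant plus a midplane
  box cut exercises sub-pocket segmentation.
* `make_receptor_ligand()`: slab-pocket receptor plus a small HETATM ligand
  placed within 2 Å of the pocket void's centroid (deterministic under a
  seed). Benchmark sets use pocket radii 3.0–3.8 Å, below the default
  Probe Out, so the 4 Å ceiling bridges their mouths and the pocket is the
  dominant cavity by construction.

Walls must be probe-tight: the generators reject atom spacings $s \ge
\sqrt3\,(r_{atom} + 1.4)$, the three-atom circumradius bound above which a
water-sized probe could pass between wall atoms; a labeling-based leak
check backs this up in the tests. These toys emulate wall curvature, probe
geometry and connectivity, but not protein chemistry, side-chain texture,
or crystallographic noise — a green suite establishes the morphology and
bookkeeping, not biological prediction accuracy.

## The benchmark protocol

A prediction for a structure is **correct at rank k** when any of the k
largest cavities has its center of mass within 4 Å (inclusive) of any
ligand atom. `probe_out_scan()` repeats whole-protein detection for
$r_{out} \in \{2.0, 2.5, \dots, 8.0\}$ (13 runs); `combine_predictions()`
aggregates a scan either as the **union** of per-radius successes (default
— the weakest rule that guarantees the combined rate is at least the best
single radius) or by pooling all cavities across radii and re-ranking by
volume (`rule = "pooled"`). `run_benchmark()` drives the protocol over a
tab-separated manifest of cases and emits per-case flags and success-rate
tables. On real drug-target sets this protocol is how the 4.0 Å default
ceiling was originally chosen; at desk scale the suite verifies the
protocol's mechanics on constructed cases where the answer is known by
design.

## Parameters that matter

| parameter | default | role |
|---|---|---|
| `probe_in` | 1.40 Å | water-sized; inner cavity extent |
| `probe_out` | 4.00 Å | cavity ceiling; raise for wide shallow sites |
| `spacing` | 0.6 Å | resolution/cost tradeoff; volume error scales with $h$ |
| `volume_threshold` | 5 Å$^3$ | suppresses voxel-noise cavities |
| `surface_mode` | molecular_surface | vdW vs SAS inner limit |
| `ligand_cutoff` | 5 Å | ligand-adjacent search zone |
| `contact_margin` | $h$ | residue-contact slack |
| `max_points` | $8\times10^6$ | step re-dimension budget (0.05 Å quantized) |

## Known limitations

* Areas carry the voxel-face convention (see above); they are not
  smooth-surface areas.
* Sealed voids are reported (see the bulk rule); depth, mouth, or
  druggability descriptors are out of scope, as is automatic sub-pocket
  decomposition — segmentation is deliberately user-steered.
* Grids are axis-aligned and uniform; absolute voxel counts depend on the
  input frame's orientation, though the translation-invariance guarantee
  removes any dependence on integer-step origin shifts.
* First model only for multi-model files; alternate locations keep the
  first conformer.

## A worked example

```{r example, eval = FALSE}
atoms <- make_hollow_sphere(void_radius = 5)
res <- detect_cavities(atoms, spacing = 0.25)
tidy(res)
autoplot(res)
```
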