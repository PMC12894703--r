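---
title: "Twist-vector neighborhood analysis of oriented cryo-ET particles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Twist-vector neighborhood analysis of oriented cryo-ET particles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tomotwist)
```

## The model

Subtomogram averaging and template matching produce *particle lists*:
tables of positions $p_i \in \mathbb{R}^3$ and orientations
$\omega_i \in \mathrm{SO}(3)$, one per particle instance found in a
tomogram. Each particle is therefore a rigid motion
$(\omega_i, p_i) \in \mathrm{SE}(3)$, with $\omega_i$ mapping the
canonical reference frame (the frame of the average or template) onto
the particle. tomotwist analyzes the *geometric interplay* between
particles through the relative pose of every neighbor within a support
radius of a query particle,

$$(\omega_1, p_1)^{-1}(\omega_2, p_2)
  = \left(\omega_1^{\mathsf T}\omega_2,\;
          \omega_1^{\mathsf T}(p_2 - p_1)\right),$$

i.e. the scene is shifted and rotated so that the query sits at the
origin in canonical orientation. The relative pose is encoded as a
*twist vector* $(\zeta, t)$: the rotational part
$\zeta = \log(\omega_1^{\mathsf T}\omega_2)^{\vee}$ is the rotation
axis scaled by the rotation angle, and the positional part
$t = \omega_1^{\mathsf T}(p_2-p_1)$ is the neighbor's location in the
query's intrinsic frame. The norms are the two natural distances:
$\lVert t\rVert$ is the Euclidean inter-particle distance and
$\lVert\zeta\rVert$ the geodesic (angular) distance between the
orientations. Because left-composition with any global rigid motion
cancels in the relative pose, every quantity derived from twist
records is invariant under rotations and translations of the whole
scene; the test suite verifies a drift below $10^{-8}$ over random
global motions. The absolute in-plane angles stored alongside each
record (the twist of each particle's own rotation about its intrinsic
z-axis) are intentionally *not* invariant — they feed the cyclic
angular score, which is invariant only under common in-plane rotations.

The `TwistDescriptor` is the table of twist records for all (query,
neighbor) pairs with distance in $(0, r]$ (a closed ball; boundary
pairs are kept). The neighbor search is exact: a blocked distance scan
whose result is tested against a brute-force double loop. The record
table doubles as a graph — particles are nodes, records are edges —
which is what object affiliation ("proximity clustering", connected
components) operates on.

## The angular score

A particle with $C_n$ or platonic-solid symmetry has several rotation
matrices describing the same physical orientation, which makes raw
angular distances between symmetric particles ambiguous. The angular
score resolves the ambiguity geometrically: the orientation acts on the
vertex set $V$ of the object fixed by the symmetry group (a regular
$n$-gon on $S^1$ for $C_n$, the solid's vertices on $S^2$ otherwise),
and two orientations are compared through the spherical Hausdorff
distance $\delta_V(\omega_1, \omega_2) = d_H(\omega_1 V, \omega_2 V)$
between the transported vertex sets. For the cyclic case each rotation
is first reduced to its in-plane part about the intrinsic z-axis by a
swing–twist decomposition; the cone part is discarded. The score is
normalized by the maximal attainable displacement,

$$\sigma_V = 1 - \delta_V / m_V \in [0, 1],$$

with $m_V = \pi/n$ in closed form for $C_n$ (36° for $C_5$) and a
numerically maximized constant for the solids (deterministic Euler
grid of $>10^4$ rotations, refined by Nelder–Mead in axis-angle
coordinates, cached per session). We implement the *symmetric*
Hausdorff distance (the maximum over both directed max–min distances);
for congruent vertex sets the two directed values agree, which the
tests assert. The score is invariant under common left rotation,
independent of the choice of representative $n$-gon, and equal to 1
exactly when the orientations agree modulo the group.

`symmetryScan()` computes score distributions under candidate $C_n$
assumptions and selects the highest median (ties toward the smallest
$n$), comparing the winner against every other candidate with a
two-sided Mann–Whitney rank-sum test. One caveat the tests document: on
a *noiseless* lattice whose orientations are exact multiples of
$60°$, $C_3$ ties with $C_6$ (half of all in-plane differences are
$C_3$ elements fold to zero), and the deterministic tie-break then
prefers the smaller $n$. Any realistic amount of orientational noise
breaks the tie in favor of the true fold order, because the $C_6$
window is twice as forgiving of small deviations.

## Supports, filters and features

Supports are bounded membership regions in the query's canonical frame
(never in extrinsic coordinates, which preserves invariance): spheres,
cylinders (symmetric or one-sided with an axial offset), ellipsoids,
cones (optionally mirrored into a double cone), tori and voxel masks.
Mask membership is a nearest-voxel lookup at threshold 0.5 with the
center voxel at the origin — bit-exact reproducibility was preferred
over interpolation. A support may not exceed the initial spherical
radius (neighbors outside were never collected; the package refuses
rather than silently under-reporting). All interval tests are closed,
so boundary records are kept. Filters remove records by closed
intervals on scalar record fields; angular fields are specified in
degrees at the interface (the community convention) and radians
internally. In the single-list case a failing pair is removed in both
directions so the descriptor stays symmetric.

Features map a (reduced) descriptor to fixed-length per-query vectors
so they can be concatenated into custom descriptors: occupancy,
distance statistics, shell decompositions, first-shell link statistics,
rotation-axis histograms, axis alignment, and cone-occupancy
footprints. Empty neighborhoods take documented fill values (occupancy
0, statistics `NA`, footprint all-empty) so the fixed-length contract
holds. Three constructions deserve detail:

* **Shells and links.** `decomposeShells()` groups the sorted pair
  distances into maximal runs whose spread stays below a tolerance
  fraction of the running mean; on an ideal triangular lattice with
  constant $a$ this recovers the shells $a, \sqrt3 a, 2a, \ldots$
  exactly. The *link* of a query is the graph of its first-shell
  neighbors with edges between neighbor pairs whose mutual distance
  also falls in the first-shell interval; vertex/edge counts, the Euler
  characteristic $V - E$, the link type (closed cycle / open chain /
  fragments / empty) and the central-angle statistics (60° at a
  hexagonal interior vertex, 72° at a fivefold vertex) are the
  lattice-defect features. This first-shell link construction is this
  package's documented variant of neighborhood topology and
  architecture features; it exposes the same observable surface
  (edge counts, central angles, Euler characteristic, link type).

* **Axis histograms.** Relative-rotation axes are sign-folded onto a
  hemisphere and binned with an equal-area scheme of
  $1 + (n_\mathrm{rings}-1) \times n_\mathrm{azimuth}$ bins. The polar
  cap is deliberately a *single* bin of the same solid angle as every
  sector: a tight axis population sitting exactly on the pole would
  otherwise be scattered across azimuth sectors by numerical noise in
  the azimuth of near-polar axes. The dominant axis is the normalized
  mean of the axes in the modal bin (ties to the lowest bin index),
  which estimates the population direction far better than the
  geometric bin center; both are reported.

* **Footprints.** The sphere around each query is divided into six
  cones along $(+y, -y, +x, -x, +z, -z)$ — the order starts with the
  intrinsic y-axis. A neighbor belongs to the cone of maximal cosine
  (ties to the lower index) provided that cosine exceeds
  $\cos(\text{half angle})$, so assigned neighbors are partitioned.
  The footprint id is the binary encoding of the occupancy pattern;
  footprints are ranked by frequency over queries. Whether occupancy
  is counted or binary, and the half-angle (default 30°), are exposed
  parameters.

## Analysis pipelines

**Affiliation and cleaning.** Optional intrinsic-axis shift (ring
subunits toward their center, which tightens clusters and lets smaller
supports work), descriptor computation, support reduction, edge
filtering, then connected components with a minimum size (e.g. three
subunits to accept a ring). Particles in no surviving component are
dropped. Evaluation against a ground-truth list matches positions
one-to-one greedily by ascending distance within half the ground
truth's median first-neighbor spacing (the tolerance is a parameter),
assigns each recovered cluster to the ground-truth object owning most
of its matches, and reports per-object $F_1 = 2TP/(2TP+FP+FN)$ and the
median over objects.

**Pentamer labeling.** Link features (median and standard deviation of
the central angles, vertex count) are standardized, reduced by PCA to
the components explaining 95% of variance, and split by 2-means. A
cluster is labeled pentamer only if its median central angle is
strictly nearer 72° than 60° — on degenerate data (a pure hexagonal
lattice) no cluster qualifies and everything stays hexamer with a
warning. The synthetic test system is a geodesic subdivision of the
icosahedron projected to a sphere: a closed hexagonal lattice with
exactly 12 planted fivefold vertices, the canonical capsid geometry.

**Stack classification.** A nucleosome pair is *stacked* when one
partner lies in the other's one-sided cylinder along the intrinsic +y
stacking axis (defaults: radius 4 nm, height 8 nm) with angular
distance inside the stack-twist window (default [5°, 25°] around the
15° twist). Both endpoints of every surviving record are labeled
stacked: the upper partner of a stack sees its mate at $-y$, so the
pair as a whole — not the one-sided query view — is the stacking
evidence. This endpoint labeling is what makes the per-class fractions
come out as the block arithmetic dictates (2 of 2 stack particles, 2
of 3 trinucleosome particles, 10 of 12 helix particles).

**Dinucleosome mining.** The descriptor is reduced to a double cone
along the intrinsic ±z axis (the DNA entry/exit direction; defaults:
half-angle 35°, height 25.5 nm inside a 32 nm support), the dominant
relative-rotation axis is found by hemispherical binning, and each
record contributes the feature triple (Euclidean distance, angular
distance, |cosine| deviation from the dominant axis). Records — not
per-query reductions — are clustered with seeded k-means ($k = 15$, 10
restarts, clusters relabeled by ascending center norm so the partition
is order-canonical). Clustering records keeps the pipeline robust at
realistic mononucleosome densities, where a random cone neighbor would
frequently displace the linker partner in any per-query
nearest-neighbor reduction; a particle is reported as contained in a
cluster when any of its records falls there. The alignment feature is
folded to |cos| so the two directions of each pair land in the same
cluster.

## The synthetic study systems

The generators define the study conditions; their defaults are chosen
once, from printed observables where available, and are not tuned:

* **Planar lattice** — triangular lattice (each interior vertex has six
  first-shell neighbors at the lattice constant, default 10 nm) with
  in-plane orientations sampled from $C_6$ multiples, identity, or
  uniform; the test system for shells, links and symmetry scans.
* **Ring** — $n$ subunits on a circle, intrinsic $-x$ toward the
  center, intrinsic $z$ along the ring axis; consecutive subunits
  differ by $360°/n$ in-plane (45° for the eightfold nuclear-pore
  geometry). Shifting subunits along intrinsic $-x$ by the radius
  collapses the ring onto its center, the construction used before
  affiliation.
* **Chromatin scene** — the default composition is 6 helices of 12
  particles, 350 stacked pairs, 340 trinucleosomes and 3200
  mononucleosomes (4992 particles) in a 400 × 400 × 120 nm slab with a
  6 nm minimum separation enforced by rejection sampling. The stacked
  pair translates 6 nm along intrinsic +y (the nucleosome height
  scale; a configuration value, not a literature claim) and twists 15°
  about it (the angular-distance peak printed for stacked nucleosomes).
  The trinucleosome adds a linker-connected third particle at 24.5 nm
  (the printed dinucleosome distance) whose relative rotation (36°, a
  configuration value) is about the intrinsic z-axis, with the
  displacement tilted 2° off +z so consecutive steps trace a discrete
  screw. The helix propagates a stacked pair six times along that same
  screw motion — a double-stranded twisted column, the
  tetranucleosome-fiber analogue — and exactly one pair (the third)
  has its stack twist inflated threefold to 45°, outside the
  classifier window. The widening is realized by counter-twisting the
  *bottom* particle of that pair about the stacking axis, which widens
  the pair's angular distance while leaving both strands' screw
  relations (and hence every particle's linker-type neighborhood)
  intact. Mononucleosomes are uniform in position and orientation; an
  optional density gradient along x is available but off by default.
* **Noise model** — positional noise adds a per-axis Gaussian with
  $\sigma = 0.8\,\ell/3$ nm at level $\ell$, reading the stated "up
  to" displacement bounds (0.8 nm at level 1, 4 nm at level 5) as
  effective $3\sigma$ bounds of the displacement magnitude; the chi-3
  99th percentile at level 5 is then 4.49 nm, which the tests assert
  against the chi-distribution oracle. Orientational noise adds
  $\ell \cdot N$ ($N$ a matrix of independent standard normals) to the
  rotation matrix and projects back to SO(3) by SVD, as the additive
  model prescribes; at level 1 the median angular deviation is close
  to 60°, and the level–deviation curve is monotone (both asserted).

What passing tests on these systems do **not** show: the generators
place rigid, noise-free blocks with exact geometry, so they probe the
pipelines' logic, not their tolerance of missing particles, lattice
incompleteness, per-particle alignment error correlated with local
density, or the missing-wedge anisotropy of real tomograms. The noise
sweeps (monotone degradation of recovery with positional and
orientational noise) are the desk-scale stand-in for that robustness
question.

## Numerical choices

* Rotation logarithm: first-order skew extraction below $10^{-7}$ rad;
  near $\pi$ (within $5\times10^{-4}$) the axis is recovered from the
  symmetric part $\tfrac12(R + R^{\mathsf T})$ — whose diagonal is
  $\cos\theta + (1-\cos\theta)a_i^2$ — with signs from its
  off-diagonals, because the standard formula divides by $\sin\theta$.
  The axis sign comes from the skew part when informative; at exactly
  $\pi$ the first nonzero axis component is made positive. Round-trip
  error stays below $10^{-8}$ including the band $[\pi-10^{-4},\pi]$.
* Angles are radians internally and degrees at every user-facing
  interface; lengths follow the particle list's unit (nm throughout
  the synthetic systems).
* Distances in the neighbor scan are recomputed by direct subtraction
  after the blocked quadratic-form scan, which suffers catastrophic
  cancellation for near-coincident points.
* Duplicate cleaning is a greedy score-descending sweep; missing
  scores rank last and ties break by ascending particle id, making the
  survivor set independent of row order for distinct scores.
* k-means runs are seeded with 10 restarts and clusters are relabeled
  by ascending center norm; re-running a pipeline with the same
  configuration and seed reproduces its outputs bit-identically.
* Degenerate inputs are first-class: empty lists and descriptors
  propagate as empty (not errors), identity relative rotations have no
  axis and count as deviation 0, single-particle tomograms are
  excluded from neighbor statistics with a warning, and gimbal
  degenerate swing–twist inputs are flagged with a documented
  convention.

## Problem sizes

The test suite and the acceptance analysis run at the sizes the
science dictates but no larger: the full 4992-particle chromatin scene
for the classification results, a scaled scene (2 helices, 60 stacks,
60 trinucleosomes, 400 mononucleosomes) over a 3 × 3 noise grid with 3
seeds for the robustness trend, $10^4$–$10^5$ random rotations for the
geometry properties, and frequency-3/4 geodesic shells (92/162
particles) for pentamer labeling. The complete suite runs in about a
minute on one CPU.

## Limitations

Affiliation assumes the assembly geometry is known well enough to
choose supports and filters; it is unsuited to particles without
repeating geometry. The cyclic angular score fixes the symmetry axis
to the intrinsic z-axis, so particle conventions with a different
symmetry axis must be re-seated first. Dihedral symmetries and
continuous symmetry detection are out of scope. The synthetic
chromatin blocks are parametric idealizations — block geometry beyond
the printed observables (stack translation, linker twist, screw tilt)
is a modeling choice, and conclusions about real chromatin require the
experimental pipelines upstream of this package.
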