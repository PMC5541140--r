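---
title: "Anatomy-driven multiple trajectory planning for SEEG electrodes"
author: "seegplan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anatomy-driven multiple trajectory planning for SEEG electrodes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seegplan)
```

## The planning problem

Stereo-electroencephalography (SEEG) localizes the epileptogenic zone by
recording from depth electrodes implanted through the skull along straight
trajectories. For each requested electrode the planner must choose a deep
*target point* inside an anatomically labelled region of interest (ROI) and
a skull-surface *entry point*, such that the trajectory is drillable,
avoids arteries, veins and sulci, samples grey matter (GM) well, and does
not collide with the other electrodes of the plan. `seegplan` solves this
jointly for all electrodes of a strategy in three stages: candidate target
selection, trajectory risk scoring, and implantation plan search.

All geometry is computed in world millimetres. Voxel indices are 0-based
and a point belongs to a voxel under half-open boundaries, so coordinates
round-trip exactly through the NIfTI affine.

## Candidate target selection

For each ROI a voxel-wise **target risk map** is computed:

$$
f(c) = \begin{cases}
1 & c \notin \Omega_\mathrm{roi} \\
1 & c \in \Omega_\mathrm{cri} \\
w_\mathrm{sp}\, f_\mathrm{sp}(c) + w_\mathrm{cri}\,(1 - f_\mathrm{cri}(c)) & \text{otherwise,}
\end{cases}
$$

where $\Omega_\mathrm{cri}$ is the union of artery and vein voxels,
$f_\mathrm{cri}$ is the distance to that union normalized by its grid-wide
maximum, and $f_\mathrm{sp}$ is a spatial prior. The two hard
1-assignments guarantee every candidate target lies strictly inside its
ROI and off the vessels. The weights default to $w_\mathrm{sp} = 0.25$ and
$w_\mathrm{cri} = 0.75$: vessel avoidance dominates, the prior breaks ties
among comparably safe voxels.

Two priors are offered, both mapped to $[0,1]$ with *low* values at
preferred voxels:

* **roi_centreline** — distance *to the ROI* is identically zero inside
  the ROI and cannot rank interior voxels, so the implementation uses the
  distance to the ROI's complement (the boundary distance), negated and
  normalized: the thickest portion of the ROI attains the lowest prior.
* **medial_surface** — one minus the normalized skull distance, so voxels
  *far* from the skull (the deep, medial side of the ROI) receive low
  values. The wording "prefer points near the medial surface" leaves the
  sign ambiguous on its own; the deep-side preference is the reading
  consistent with targeting deep GM, and it is pinned by a unit test on a
  ball ROI.

Distances are exact anisotropic Euclidean distance transforms on the voxel
grid (separable parabolic-envelope algorithm, implemented in C++), with
mesh structures rasterized onto the grid at half-voxel pitch first. At
voxel resolution this is equivalent to surface-based nearest-point queries
and considerably simpler.

Candidate targets are the **regional minima** of $f$ under
26-connectivity, restricted to $f < 1$; a plateau of equal values
contributes its lexicographically smallest voxel. The minima of an ROI
shared by $K$ electrodes are split by **K-means** into $K$ groups; each
electrode takes the $M = 10$ lowest-$f$ minima of its group. K-means runs
with deterministic farthest-point initial centres (first centre = the
lowest-$f$ minimum) so identical inputs always produce identical plans;
groups are matched to electrodes in strategy-file order after sorting
groups by their best $f$. If an ROI yields fewer minima than electrodes,
points are reassigned round-robin by $f$ rank (with reuse), a warning is
emitted, and the planner continues — targets may then coincide and the
pairwise-separation constraint decides downstream.

## Trajectory risk scoring

Every skull-mesh vertex is a potential entry point and carries its
outward vertex normal. A trajectory from target $T$ to entry $E$ is
discarded if (1) it is longer than $d_\mathrm{len} = 80$ mm, (2) its angle
to the skull normal exceeds $d_\mathrm{ang} = 15^\circ$, (3) a superficial
ROI is specified and never traversed, or (4) any point sampled along it at
1 mm lies inside arteries, veins or sulci. If nothing survives, the length
and angle limits are relaxed in lockstep by 10 mm / 10° per level up to
110 mm / 45°; an electrode with no trajectory at the caps raises a
distinct error and the remaining electrodes are still reported.

Surviving trajectories receive a vessel **risk score**

$$
R = \frac{1}{n}\sum_{x} \operatorname{clamp}\!\left(
  \frac{d_\mathrm{risk} - d(x)}{d_\mathrm{risk} - d_\mathrm{safe}},\, 0,\, 1\right),
$$

the mean over 1 mm samples of a clamped linear ramp of the *raw* vessel
distance $d(x)$ in millimetres ($d_\mathrm{safe} = 3$ mm,
$d_\mathrm{risk} = 10$ mm, trilinear interpolation of the distance field).
Two numerical choices deserve note. First, the unclamped integrand
$d_\mathrm{risk} - (d(x) - d_\mathrm{safe})$ sometimes quoted for this
score does not attain the model's own stated boundary values (it gives
$10/7$ at $d = d_\mathrm{safe}$ and $3/7$ at $d = d_\mathrm{risk}$ with
the defaults); the clamped form reproduces both endpoints exactly —
trajectories everywhere closer than $d_\mathrm{safe}$ score exactly 1,
everywhere farther than $d_\mathrm{risk}$ exactly 0 — and is the form
used throughout, with the unclamped one available as
`riskScore(form = "printed")` for comparison. Second, the distance entering
$R$ must be the raw distance in mm (it is compared against millimetre
thresholds), whereas the distance entering the target risk map is
normalized; the package keeps both fields. Sulci participate in hard
constraint (4) but not in the vessel-distance field: $R$ is a *vascular*
risk.

The **GM ratio** models a 10-contact electrode with 10 mm contact spacing
starting at the target: each contact is assessed at its centre $p_q$ and
both ends $p_q \pm 1.2$ mm along the trajectory by the Heaviside step of
the signed GM distance ($H(0) = 1$: the surface counts as inside), so each
contact scores $0, 1/3, 2/3$ or $1$ and
$G = \sum_q \big(H[f_\mathrm{gm}(p_q - p_r)] + H[f_\mathrm{gm}(p_q)] +
H[f_\mathrm{gm}(p_q + p_r)]\big) / 30$. Contacts past the entry keep their
nominal geometric positions and simply score zero outside the head — the
contact model places contacts by fixed spacing from the target, with no
truncation rule. The weighted score is $S = 10R + G$: one risk step of
$0.1$ outweighs the entire GM range, encoding safety-first triage.

## Implantation plan search

The plan minimizes the mean $S$ over one trajectory per electrode subject
to every pairwise segment distance exceeding $d_\mathrm{traj} = 10$ mm
(exact closed-form segment-segment distances). The search is depth-first
in strategy order, candidates ascending by $S$ within an electrode, with
two prunings:

* **branch and bound** — scores are non-negative, so a partial sum plus
  the per-electrode minima of the remaining electrodes bounds the subtree;
  this never discards an improving feasible solution.
* **diversity stepping** — after a conflict, candidates closer than
  0.5 mm to the conflicting candidate are skipped at that node, discarding
  spatially near-duplicate trajectories. With `diversityEpsilon = 0` the
  skipping is disabled entirely (a literal "distance $> 0$" rule would
  still drop candidates that intersect the conflicting one, e.g.
  same-target candidates, and would break exact optimality), and the
  search is then provably exhaustive: on random instances with $N \le 3$
  and $\le 10$ candidates it reproduces the brute-force enumeration
  optimum exactly, which the test suite asserts on 50 instances.

If no combination is feasible — or the node budget (default $10^6$
expansions) is exhausted — a **max-separation fallback** returns the plan
with the largest achievable minimum pairwise distance: greedy coordinate
ascent over the top 50 candidates per electrode from the rank-0 plan,
refined by single-electrode swaps, ties broken toward lower mean $S$. The
fallback's search strategy is a heuristic choice of this implementation;
its plan is marked infeasible and reports the separation it achieved.

## The synthetic head phantom

The phantom generator produces every input the planner consumes — label
volume, artery/vein/sulcus masks, watertight skull mesh, strategy file —
at clinical imaging scale: a 1 mm isotropic grid of $190^3$ voxels, a
spherical skull of 90 mm outer radius, a cortical GM ribbon between 72 and
80 mm, six deep ROIs at 55 mm from the centre on directions separated by
60° in azimuth with alternating ±35° elevation, a midline vertical artery,
deep (40 mm) and superficial (75 mm) equatorial vascular rings, and three
radial sulcal sheets. Two ROIs are two-lobed with lobes 22 mm apart and
carry two electrodes each (eight electrodes in total), exercising the
K-means split and the pairwise-separation constraint; one electrode also
carries a superficial ROI patch, exercising the traversal constraint. The
elevation offset keeps every declared corridor — a cone from each ROI
toward the skull — clear of the equatorial vessels, and corridor emptiness
is *verified after rasterization*, so the phantom carries ground-truth
safe trajectories by construction, not by hope.

What the phantom does *not* emulate: tissue contrast and segmentation
error, tortuous vessel trees, gyral/sulcal folding, oblique affines, and
the anatomical asymmetries of real heads. Passing tests therefore
demonstrate the correctness of the geometry, scoring and search machinery
under known ground truth — not clinical validity of planned trajectories
on patient imaging, which requires the upstream segmentation pipeline this
package deliberately assumes as given.

Test problem sizes were chosen to keep the full suite comfortably
desk-scale: most tests run on a 2 mm / $96^3$ replica of the phantom with
a coarser skull mesh (162 entry vertices), the search-oracle comparisons
use 50 random instances of at most 3 electrodes × 10 candidates, and one
end-to-end test runs the full default phantom with all 8 electrodes.

## Degenerate inputs and tie-breaking

* Empty structures (no vessel voxels, empty ROI, empty mesh) raise
  immediate errors rather than returning all-infinite fields.
* `normalizeField` refuses all-zero fields ("degenerate field").
* Equal-$f$ plateaus contribute one representative minimum each (lowest
  linear index); score ties are broken by lower $R$, then target rank,
  then entry index; K-means assignment ties by lowest point index.
* A GM mask covering the whole grid (or nothing) is rejected: the signed
  distance needs both phases.
* Non-axis-aligned affines are accepted with a warning; the distance
  transform then measures along voxel axes.

## Known limitations

* The distance transform is voxel-exact, not surface-exact: distances are
  measured to voxel centres, so sub-voxel structure geometry is rounded to
  the grid. At 1 mm resolution this is below the 3 mm safety margin.
* Entry points are restricted to skull-mesh vertices; a coarse mesh
  quantizes the entry-angle constraint.
* Electrode bolt hardware, brain shift and drilling mechanics are out of
  scope, as is any registration between modalities: all inputs must
  already be co-registered.
* With more than ~12 electrodes the combinatorial search grows quickly;
  the node budget then degrades gracefully to the fallback rather than
  hanging.
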