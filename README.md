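# seegplan

Anatomy-driven multiple trajectory planning for stereo-electroencephalography
(SEEG) depth electrodes.

Epilepsy surgery teams implant 7–12 depth electrodes along straight
trajectories through the skull to localize the epileptogenic zone. Planning
an implantation by hand means finding, for every electrode, a deep target
inside its region of interest (ROI) and a drillable skull entry such that
the trajectory stays clear of arteries, veins and sulci, samples grey
matter (GM) well, and keeps its distance from every other electrode.
`seegplan` automates this for users with a segmented head (a labelled
parcellation, vessel/sulcus/GM masks and a skull mesh, all co-registered):
neurosurgical planning researchers, image-analysis groups, and anyone who
needs a reproducible, testable reference implementation of
distance-transform-based multi-trajectory planning. No patient data is
required anywhere: a built-in phantom generator produces all inputs with
ground-truth safe corridors.

## The model

For each ROI a voxel-wise target risk map

f(c) = 1 outside the ROI or on a vessel, otherwise
f(c) = w_sp · f_sp(c) + w_cri · (1 − f_cri(c)),

combines a spatial prior f_sp (ROI centreline or medial surface) with the
normalized vessel distance f_cri (defaults w_sp = 0.25, w_cri = 0.75).
Candidate targets are the regional minima of f, split by K-means when
several electrodes share an ROI, M = 10 per electrode. Every skull-mesh
vertex is a candidate entry; trajectories longer than d_len = 80 mm,
more oblique than d_ang = 15° to the skull normal, missing a required
superficial ROI, or intersecting arteries/veins/sulci are discarded (with
stepwise relaxation to 110 mm / 45° when nothing survives). Survivors are
scored

R = mean over 1 mm samples of clamp((d_risk − d(x)) / (d_risk − d_safe), 0, 1),
G = Σ_q (H[f_gm(p_q − p_r)] + H[f_gm(p_q)] + H[f_gm(p_q + p_r)]) / 30,
S = 10 · R + G,

with d_safe = 3 mm, d_risk = 10 mm, and a 10-contact electrode model
(10 mm spacing, 1.2 mm contact radius). The joint plan minimizes the mean
S subject to pairwise trajectory separation > d_traj = 10 mm, by
depth-first search with branch-and-bound and 0.5 mm diversity pruning,
falling back to the maximum-separation plan when no feasible combination
exists. See `vignettes/trajectory-planning.Rmd` for the full account.

## Worked example

Generate a scaled-down head phantom (2 mm voxels, eight electrodes over
six ROIs) and plan the implantation:

```r
library(seegplan)
ph  <- generatePhantom(phantomSpec(gridShape = c(96, 96, 96),
                                   spacing = c(2, 2, 2),
                                   meshSubdivisions = 2))
res <- planImplantation(ph$parcellation, ph$masks, ph$skull, ph$strategy)
res$plan
#> ImplantationPlan: 8 electrodes, S_total = 0.2208, min separation = 21.02 mm, feasible
round(planTrajectories(res$plan)[, c("tx","ty","tz","length_mm","angle_deg","R","G","S")], 3)
#>    tx  ty  tz length_mm angle_deg R     G     S
#> 1  45 -11  31    37.191    17.736 0 0.300 0.300
#> 2  45  11  31    35.829    13.281 0 0.200 0.200
#> 3  21  35 -39    33.840     5.968 0 0.200 0.200
#> 4 -23  39  31    36.910    13.825 0 0.233 0.233
#> 5 -45 -11 -31    35.829    13.281 0 0.200 0.200
#> 6 -45  11 -31    35.829    13.281 0 0.200 0.200
#> 7 -21 -35  39    33.840     5.968 0 0.200 0.200
#> 8  23 -39 -31    36.910    13.825 0 0.233 0.233
```

Every trajectory ends at a target (tx, ty, tz) inside its ROI, at worst
37 mm long. R = 0 throughout: every sampled point is farther than 10 mm
from any vessel, so the vascular risk term vanishes and the ranking is
driven by GM capture (G, the fraction of the 30 contact sample points in
grey matter — 0.2 means 2 of 10 contacts fully captured). The plan is
feasible: the closest pair of trajectories is 21 mm apart, above the
10 mm separation constraint. Electrode 1 reports an 18° entry angle
because its superficial-ROI constraint required one relaxation step
(level 1 admits up to 25°). The same pipeline runs from files via
`runPlan()` or the CLI:

```sh
Rscript inst/cli/admtp.R phantom --out ph/ --small
Rscript inst/cli/admtp.R plan --config cfg.yaml
```

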