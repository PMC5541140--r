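# Shared fixtures, generated in code at test time and memoized per session.
.fixtures <- new.env(parent = emptyenv())

# Scaled-down head phantom (2 mm voxels, coarser skull mesh): same anatomy
# as the default phantom at a fraction of the cost; used by most tests.
smallPhantomSpec <- function(...) {
  phantomSpec(gridShape = c(96L, 96L, 96L), spacing = c(2, 2, 2),
              meshSubdivisions = 2L, ...)
}

smallPhantom <- function() {
  if (is.null(.fixtures$small))
    .fixtures$small <- generatePhantom(smallPhantomSpec())
  .fixtures$small
}

defaultPhantom <- function() {
  if (is.null(.fixtures$default))
    .fixtures$default <- generatePhantom(phantomSpec())
  .fixtures$default
}

# Minimal phantom with one straight vessel along z through the head centre:
# trajectories parallel to it at a known offset have an exactly known
# distance profile, pinning the risk-score boundary values.
tubePhantomSpec <- function(vesselRadius = 0.5) {
  rois <- list(list(label = 101L, name = "deep_a", lobes = list(
    list(centre = c(0, -20, 0), semiAxes = c(6, 6, 6)))))
  phantomSpec(
    gridShape = c(63L, 63L, 63L), spacing = c(1, 1, 1),
    skullOuterRadius = 30, skullInnerRadius = 28, gmRibbon = c(24, 27),
    rois = rois,
    vessels = list(list(type = "artery", radius = vesselRadius,
                        points = cbind(0, 0, seq(-25, 25, by = 5)))),
    sulci = list(),
    corridors = list(),
    strategy = data.frame(id = "E1", deep_roi_label = 101L,
                          superficial_roi_label = NA_integer_,
                          prior = "roi_centreline",
                          stringsAsFactors = FALSE),
    meshSubdivisions = 2L)
}

tubeVesselField <- function() {
  if (is.null(.fixtures$tube)) {
    ph <- generatePhantom(tubePhantomSpec())
    .fixtures$tube <- list(
      phantom = ph,
      raw = distanceField(ph$masks$arteries, ph$parcellation))
  }
  .fixtures$tube
}

# A constant-valued ScalarField on a small grid (for engineered distance
# profiles).
constantField <- function(value, dims = c(24, 24, 24), spacing = 1) {
  aff <- diag(4)
  diag(aff)[1:3] <- spacing
  aff[1:3, 4] <- -spacing * (dims - 1) / 2
  scalarField(array(value, dims), aff)
}
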