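#' ScalarField: a 3-D voxel grid of real values with a voxel-to-world affine
#'
#' Houses every scalar quantity the planner manipulates on the imaging grid:
#' distance fields, normalized risk components, signed grey-matter distance,
#' and the target risk map itself. Voxel indices are 0-based; world
#' coordinates are millimetres; `world = affine %*% c(i, j, k, 1)`.
#'
#' @slot values numeric 3-D array, finite everywhere.
#' @slot affine 4x4 voxel-index to world-mm matrix (invertible, positive
#'   spacing on all axes).
#' @slot name character scalar used in printing and NIfTI export.
#' @export
setClass("ScalarField",
  representation(values = "array", affine = "matrix", name = "character"),
  prototype(name = "field"))

setValidity("ScalarField", function(object) {
  msg <- character()
  if (length(dim(object@values)) != 3L)
    msg <- c(msg, "values must be a 3-D array")
  if (!all(is.finite(object@values)))
    msg <- c(msg, "values must be finite (no NaN/Inf)")
  if (!identical(dim(object@affine), c(4L, 4L)))
    msg <- c(msg, "affine must be 4x4")
  else {
    if (abs(det(object@affine)) < 1e-12)
      msg <- c(msg, "affine must be invertible")
    sp <- sqrt(colSums(object@affine[1:3, 1:3]^2))
    if (any(sp <= 0)) msg <- c(msg, "voxel spacing must be strictly positive")
  }
  if (length(msg)) msg else TRUE
})

#' LabelVolume: integer-labelled parcellation or mask volume
#'
#' @slot labels integer 3-D array of non-negative labels (0 = background).
#' @slot affine 4x4 voxel-index to world-mm matrix.
#' @slot legend named integer vector mapping region names to labels.
#' @export
setClass("LabelVolume",
  representation(labels = "array", affine = "matrix", legend = "integer"))

setValidity("LabelVolume", function(object) {
  msg <- character()
  if (length(dim(object@labels)) != 3L)
    msg <- c(msg, "labels must be a 3-D array")
  if (any(object@labels < 0L)) msg <- c(msg, "labels must be non-negative")
  if (!identical(dim(object@affine), c(4L, 4L)) ||
      abs(det(object@affine)) < 1e-12)
    msg <- c(msg, "affine must be an invertible 4x4 matrix")
  if (length(msg)) msg else TRUE
})

#' SurfaceMesh: triangulated surface with outward unit vertex normals
#'
#' @slot vertices n x 3 matrix of world-mm points.
#' @slot faces m x 3 integer matrix of 1-based vertex indices.
#' @slot vertexNormals n x 3 matrix of unit vectors.
#' @export
setClass("SurfaceMesh",
  representation(vertices = "matrix", faces = "matrix",
                 vertexNormals = "matrix"))

setValidity("SurfaceMesh", function(object) {
  msg <- character()
  nv <- nrow(object@vertices)
  if (ncol(object@vertices) != 3L) msg <- c(msg, "vertices must be n x 3")
  if (ncol(object@faces) != 3L) msg <- c(msg, "faces must be m x 3")
  if (nrow(object@faces) > 0 &&
      (min(object@faces) < 1L || max(object@faces) > nv))
    msg <- c(msg, "face indices out of range")
  if (nrow(object@vertexNormals) != nv)
    msg <- c(msg, "one normal per vertex required")
  else if (nv > 0) {
    nrm <- sqrt(rowSums(object@vertexNormals^2))
    if (any(abs(nrm - 1) > 1e-6))
      msg <- c(msg, "vertex normals must be unit length within 1e-6")
  }
  if (length(msg)) msg else TRUE
})

#' TargetRiskMap: per-ROI voxel-wise target risk
#'
#' The scalar field f combining the spatial prior and the critical-structure
#' distance, fixed to 1 outside the ROI and inside critical structures.
#'
#' @slot field ScalarField with values in [0, 1].
#' @slot roiLabel integer ROI label the map was computed for.
#' @slot weights numeric c(wSp, wCri).
#' @export
setClass("TargetRiskMap",
  representation(field = "ScalarField", roiLabel = "integer",
                 weights = "numeric"))

setValidity("TargetRiskMap", function(object) {
  msg <- character()
  if (length(object@weights) != 2L || any(object@weights < 0))
    msg <- c(msg, "weights must be two non-negative numbers")
  v <- object@field@values
  if (sum(object@weights) <= 1 + 1e-12 &&
      (min(v) < -1e-9 || max(v) > 1 + 1e-9))
    msg <- c(msg, "risk values must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' CandidateTargetSet: ranked candidate target points for one electrode
#'
#' @slot electrodeId character electrode identifier.
#' @slot targets k x 3 matrix of world-mm points, ascending in f.
#' @slot f numeric target-risk values, sorted ascending.
#' @slot clusterId integer K-means cluster the electrode was assigned.
#' @export
setClass("CandidateTargetSet",
  representation(electrodeId = "character", targets = "matrix",
                 f = "numeric", clusterId = "integer"))

setValidity("CandidateTargetSet", function(object) {
  msg <- character()
  if (nrow(object@targets) != length(object@f))
    msg <- c(msg, "one f value per target required")
  if (is.unsorted(object@f)) msg <- c(msg, "targets must be sorted ascending by f")
  if (length(msg)) msg else TRUE
})

#' ImplantationPlan: one trajectory per electrode plus separation summary
#'
#' @slot trajectories data.frame with one row per electrode (target/entry
#'   world coordinates, length, entry angle, R, G, S, relaxation level).
#' @slot STotal mean weighted score over electrodes.
#' @slot pairwiseDistances symmetric matrix of segment-segment distances (mm).
#' @slot minPairwiseDistance smallest off-diagonal pairwise distance (mm).
#' @slot feasible TRUE iff every pairwise distance exceeds d_traj.
#' @slot searchInfo list of search diagnostics (nodes, skips, fallback).
#' @export
setClass("ImplantationPlan",
  representation(trajectories = "data.frame", STotal = "numeric",
                 pairwiseDistances = "matrix",
                 minPairwiseDistance = "numeric", feasible = "logical",
                 searchInfo = "list"))

setValidity("ImplantationPlan", function(object) {
  msg <- character()
  n <- nrow(object@trajectories)
  if (n > 0 && abs(object@STotal - mean(object@trajectories$S)) > 1e-9)
    msg <- c(msg, "STotal must equal the mean of member S values")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ScalarField", function(object) {
  d <- dim(object@values)
  sp <- voxelSpacing(object@affine)
  cat(sprintf("ScalarField '%s': %d x %d x %d voxels, spacing %s mm, range [%.4g, %.4g]\n",
              object@name, d[1], d[2], d[3],
              paste(signif(sp, 4), collapse = " x "),
              min(object@values), max(object@values)))
})

setMethod("show", "LabelVolume", function(object) {
  d <- dim(object@labels)
  cat(sprintf("LabelVolume: %d x %d x %d voxels, %d labels present\n",
              d[1], d[2], d[3], length(setdiff(unique(as.vector(object@labels)), 0L))))
  if (length(object@legend))
    cat("  legend:", paste(sprintf("%s=%d", names(object@legend), object@legend),
                           collapse = ", "), "\n")
})

setMethod("show", "SurfaceMesh", function(object) {
  cat(sprintf("SurfaceMesh: %d vertices, %d faces\n",
              nrow(object@vertices), nrow(object@faces)))
})

setMethod("show", "TargetRiskMap", function(object) {
  cat(sprintf("TargetRiskMap (ROI label %d, wSp = %g, wCri = %g)\n",
              object@roiLabel, object@weights[1], object@weights[2]))
  show(object@field)
})

setMethod("show", "CandidateTargetSet", function(object) {
  cat(sprintf("CandidateTargetSet '%s': %d candidates (cluster %d), best f = %.4g\n",
              object@electrodeId, nrow(object@targets), object@clusterId,
              if (length(object@f)) object@f[1] else NA_real_))
})

setMethod("show", "ImplantationPlan", function(object) {
  cat(sprintf("ImplantationPlan: %d electrodes, S_total = %.4f, min separation = %.2f mm, %s\n",
              nrow(object@trajectories), object@STotal,
              object@minPairwiseDistance,
              if (object@feasible) "feasible" else "INFEASIBLE"))
})
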