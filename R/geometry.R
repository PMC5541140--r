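#' Construct a ScalarField
#'
#' @param values numeric 3-D array (finite everywhere).
#' @param affine 4x4 voxel-index (0-based) to world-mm matrix; defaults to
#'   1 mm isotropic with the origin at voxel (0,0,0).
#' @param name character label.
#' @return A \linkS4class{ScalarField}.
#' @export
scalarField <- function(values, affine = diag(4), name = "field") {
  storage.mode(values) <- "double"
  new("ScalarField", values = values, affine = affine, name = name)
}

#' Construct a LabelVolume
#'
#' @param labels integer 3-D array of non-negative labels.
#' @param affine 4x4 voxel-index to world-mm matrix.
#' @param legend named integer vector mapping region names to labels.
#' @return A \linkS4class{LabelVolume}.
#' @export
labelVolume <- function(labels, affine = diag(4), legend = integer()) {
  storage.mode(labels) <- "integer"
  new("LabelVolume", labels = labels, affine = affine,
      legend = as.integer(setNames(legend, names(legend))))
}

#' Voxel spacing of an affine (mm per voxel step along each axis)
#' @param affine 4x4 affine matrix.
#' @return numeric length-3 spacing.
#' @export
voxelSpacing <- function(affine) sqrt(colSums(affine[1:3, 1:3, drop = FALSE]^2))

#' Convert 0-based voxel indices to world mm
#' @param affine 4x4 affine.
#' @param ijk n x 3 matrix (or length-3 vector) of 0-based voxel indices.
#' @return n x 3 matrix of world-mm points.
#' @export
voxelToWorld <- function(affine, ijk) {
  ijk <- rbind2mat(ijk)
  t(affine %*% rbind(t(ijk), 1))[, 1:3, drop = FALSE]
}

#' Convert world mm to continuous 0-based voxel indices
#' @param affine 4x4 affine.
#' @param xyz n x 3 matrix (or length-3 vector) of world-mm points.
#' @return n x 3 matrix of continuous voxel indices.
#' @export
worldToVoxel <- function(affine, xyz) {
  xyz <- rbind2mat(xyz)
  t(solve(affine) %*% rbind(t(xyz), 1))[, 1:3, drop = FALSE]
}

rbind2mat <- function(x) {
  if (is.null(dim(x))) matrix(x, ncol = 3) else as.matrix(x)
}

.sameGeometry <- function(a, b, tol = 1e-6) {
  identical(dim(fieldValues(a)), dim(fieldValues(b))) &&
    max(abs(fieldAffine(a) - fieldAffine(b))) < tol
}

.gridOrigin <- function(affine) as.numeric(affine[1:3, 4])

.axisAligned <- function(affine) {
  R <- affine[1:3, 1:3]
  all(abs(R[row(R) != col(R)]) < 1e-9)
}

#' Unsigned Euclidean distance field to a structure
#'
#' Exact anisotropic Euclidean distance transform on the voxel grid:
#' distance in mm from every voxel centre to the nearest voxel of the
#' structure (0 on structure voxels). The structure may be a logical mask
#' array on the grid, a \linkS4class{LabelVolume} (optionally restricted to
#' one label), or a \linkS4class{SurfaceMesh}, which is rasterized onto the
#' grid first so distances are exact at voxel resolution.
#'
#' @param structure logical array, LabelVolume, or SurfaceMesh.
#' @param grid ScalarField or LabelVolume supplying geometry (dim + affine).
#' @param label for a LabelVolume structure, restrict to this label
#'   (default: any non-zero label).
#' @return A \linkS4class{ScalarField} of distances in mm.
#' @export
distanceField <- function(structure, grid, label = NULL) {
  dims <- gridDim(grid)
  affine <- fieldAffine(grid)
  if (is(structure, "SurfaceMesh")) {
    mask <- rasterizeMesh(structure, grid)
  } else if (is(structure, "LabelVolume")) {
    if (!.sameGeometry(structure, grid)) stop("mismatched affines")
    mask <- if (is.null(label)) structure@labels > 0L
            else structure@labels == as.integer(label)
  } else {
    mask <- structure
    if (!identical(dim(mask), as.integer(dims)) &&
        !identical(dim(mask), dims)) stop("mismatched grid dimensions")
  }
  mask <- as.logical(mask)
  if (!any(mask)) stop("empty structure")
  if (!.axisAligned(affine))
    warning("affine is not axis-aligned; distances computed along voxel axes")
  d <- cpp_edt3d(mask, as.integer(dims), voxelSpacing(affine))
  scalarField(array(d, dims), affine, name = "distance")
}

#' Normalize a distance field to [0, 1]
#'
#' Divides by the grid-wide maximum, so the farthest voxel maps exactly to 1.
#'
#' @param d a \linkS4class{ScalarField} with non-negative values.
#' @return A \linkS4class{ScalarField} with values in [0, 1], max exactly 1.
#' @export
normalizeField <- function(d) {
  m <- max(d@values)
  if (m <= 0) stop("degenerate field")
  scalarField(d@values / m, d@affine, name = paste0(d@name, "_norm"))
}

#' Signed distance from the grey-matter surface
#'
#' Positive inside GM, negative outside, so the Heaviside step H with
#' H(x) = 1 for x >= 0 reproduces the GM indicator (surface counts as
#' inside). At voxel resolution the magnitude equals the unsigned distance
#' to the nearest voxel across the mask boundary.
#'
#' @param gmMask logical array or LabelVolume of the GM mask.
#' @param grid ScalarField or LabelVolume supplying geometry; defaults to
#'   `gmMask` when that is a LabelVolume.
#' @param label optional label restriction for a LabelVolume mask.
#' @return A \linkS4class{ScalarField}, positive inside GM.
#' @export
signedGmDistance <- function(gmMask, grid = NULL, label = NULL) {
  if (is(gmMask, "LabelVolume")) {
    if (is.null(grid)) grid <- gmMask
    mask <- if (is.null(label)) gmMask@labels > 0L
            else gmMask@labels == as.integer(label)
  } else {
    if (is.null(grid)) stop("grid geometry required for a plain mask")
    mask <- as.logical(gmMask)
  }
  dims <- gridDim(grid)
  dim(mask) <- dims
  if (!any(mask)) stop("empty GM mask")
  if (all(mask)) stop("GM mask covers the full grid")
  sp <- voxelSpacing(fieldAffine(grid))
  dOut <- cpp_edt3d(!mask, as.integer(dims), sp)  # dist to nearest outside
  dIn <- cpp_edt3d(as.logical(mask), as.integer(dims), sp)
  signed <- ifelse(mask, dOut, -dIn)
  scalarField(array(signed, dims), fieldAffine(grid), name = "gm_signed")
}

#' Sample a scalar field at world-mm points
#'
#' @param field a \linkS4class{ScalarField}.
#' @param points n x 3 matrix of world-mm points.
#' @param method "trilinear" (default; clamped at the grid edge) or
#'   "nearest" (half-open voxel ownership; points outside the grid return
#'   `outside`).
#' @param outside value returned for out-of-grid points under "nearest".
#' @return numeric vector of sampled values.
#' @export
sampleField <- function(field, points,
                        method = c("trilinear", "nearest"), outside = 0) {
  method <- match.arg(method)
  ijk <- worldToVoxel(field@affine, points)
  dims <- as.integer(dim(field@values))
  if (method == "trilinear")
    cpp_sample_trilinear(as.vector(field@values), dims, ijk)
  else
    cpp_sample_nearest(as.vector(field@values), dims, ijk, outside)
}

.sampleMask <- function(mask, affine, points) {
  ijk <- worldToVoxel(affine, points)
  cpp_sample_nearest(as.double(mask), as.integer(dim(mask)), ijk, 0) > 0.5
}

#' Uniformly sample a segment from target to entry
#'
#' Discretizes a trajectory for line integrals and intersection tests:
#' points from target to entry inclusive, equally spaced at most `step`
#' apart.
#'
#' @param target,entry world-mm endpoints.
#' @param step maximum spacing in mm (> 0).
#' @return (n+1) x 3 matrix of points; row 1 is the target, the last row
#'   the entry.
#' @export
sampleSegment <- function(target, entry, step = 1) {
  stopifnot(step > 0)
  target <- as.numeric(target); entry <- as.numeric(entry)
  len <- sqrt(sum((entry - target)^2))
  if (len <= 0) stop("segment length must be > 0")
  n <- max(1L, ceiling(len / step))
  tt <- seq(0, 1, length.out = n + 1L)
  cbind(target[1] + tt * (entry[1] - target[1]),
        target[2] + tt * (entry[2] - target[2]),
        target[3] + tt * (entry[3] - target[3]))
}

#' Minimum distance between two 3-D line segments
#'
#' Closed-form clamped solution; symmetric, and 0 exactly when the closed
#' segments intersect.
#'
#' @param p1,q1 endpoints of the first segment (world mm).
#' @param p2,q2 endpoints of the second segment.
#' @return distance in mm.
#' @export
segmentSegmentDistance <- function(p1, q1, p2, q2) {
  .segToSegsDist(as.numeric(p1), as.numeric(q1),
                 matrix(as.numeric(p2), 1), matrix(as.numeric(q2), 1))[1]
}

# Distance from one segment (p1,q1) to each of many segments (rows of P2,Q2).
# Clamped closest-point parametrization (Ericson, Real-Time Collision
# Detection, 5.1.9), vectorized over the second operand.
.segToSegsDist <- function(p1, q1, P2, Q2) {
  d1 <- q1 - p1                       # length-3
  D2 <- Q2 - P2                       # n x 3
  R <- matrix(p1, nrow(P2), 3, byrow = TRUE) - P2   # p1 - p2
  a <- sum(d1 * d1)
  e <- rowSums(D2 * D2)
  f <- rowSums(D2 * R)
  c1 <- as.numeric(R %*% d1)          # dot(d1, r)
  b <- as.numeric(D2 %*% d1)          # dot(d1, d2)
  denom <- a * e - b * b
  s <- ifelse(denom > 1e-12, pmin(pmax((b * f - c1 * e) / denom, 0), 1), 0)
  t <- ifelse(e > 1e-12, (b * s + f) / e, 0)
  # re-clamp: if t clamped, recompute s
  tcl <- pmin(pmax(t, 0), 1)
  need <- tcl != t
  if (any(need)) {
    s2 <- ifelse(a > 1e-12, pmin(pmax((b * tcl - c1) / a, 0), 1), 0)
    s <- ifelse(need, s2, s)
  }
  t <- tcl
  if (a <= 1e-12) s <- rep(0, nrow(P2))
  cp1 <- matrix(p1, nrow(P2), 3, byrow = TRUE) + outer(s, d1)
  cp2 <- P2 + D2 * t
  sqrt(rowSums((cp1 - cp2)^2))
}
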