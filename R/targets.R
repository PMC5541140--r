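#' Normalized distance field to the critical structures
#'
#' Distance to the union of all critical vascular structures (arteries and
#' veins), normalized by its grid-wide maximum so the safest voxel scores 1
#' and vessel voxels score 0. Sulci take part in the hard trajectory
#' constraint, not in this field.
#'
#' @param criticalMask logical array: union of artery and vein masks.
#' @param grid ScalarField or LabelVolume supplying geometry.
#' @return A normalized \linkS4class{ScalarField} in [0, 1].
#' @export
computeCriticalField <- function(criticalMask, grid) {
  if (!any(criticalMask)) stop("empty structure")
  normalizeField(distanceField(criticalMask, grid))
}

#' Spatial prior over candidate target locations
#'
#' Two user-selectable priors, both normalized to [0, 1] with low values at
#' preferred locations:
#' \describe{
#'   \item{medial_surface}{1 - normalized distance to the skull surface:
#'     voxels deep in the head (far from the skull) receive low prior
#'     values, steering targets toward the medial, deep side of the ROI.}
#'   \item{roi_centreline}{1 - normalized distance to the ROI boundary
#'     (distance to the ROI's complement): the ROI's thickest portion,
#'     where the boundary distance peaks, receives the lowest prior.}
#' }
#'
#' @param mode "roi_centreline" or "medial_surface".
#' @param roiMask logical array of the ROI.
#' @param grid ScalarField or LabelVolume supplying geometry.
#' @param skull \linkS4class{SurfaceMesh} (medial_surface mode) — may be
#'   omitted when `skullDistance` is given.
#' @param skullDistance optional precomputed raw skull distance field (mm),
#'   reused across electrodes.
#' @return A \linkS4class{ScalarField} in [0, 1].
#' @export
computeSpatialPrior <- function(mode = c("roi_centreline", "medial_surface"),
                                roiMask, grid, skull = NULL,
                                skullDistance = NULL) {
  mode <- match.arg(mode)
  if (!any(roiMask)) stop("empty ROI")
  if (mode == "medial_surface") {
    if (is.null(skullDistance)) {
      if (is.null(skull)) stop("skull mesh or skullDistance required")
      skullDistance <- distanceField(skull, grid)
    }
    d <- normalizeField(skullDistance)
    scalarField(1 - d@values, fieldAffine(grid), name = "prior_medial")
  } else {
    compl <- !as.logical(roiMask)
    dim(compl) <- gridDim(grid)
    d <- normalizeField(distanceField(compl, grid))
    scalarField(1 - d@values, fieldAffine(grid), name = "prior_centreline")
  }
}

#' Target risk map for one ROI
#'
#' Voxel-wise risk f combining the spatial prior and the normalized
#' critical-structure distance:
#' f = 1 outside the ROI or inside a critical structure, and
#' f = wSp * f_sp + wCri * (1 - f_cri) elsewhere. Local minima of f are the
#' candidate target points.
#'
#' @param roiMask logical array of the ROI.
#' @param criticalMask logical array of critical (vascular) voxels.
#' @param criticalField normalized critical distance field
#'   ([computeCriticalField()]).
#' @param prior spatial prior field ([computeSpatialPrior()]).
#' @param wSp weight of the spatial prior (default 0.25).
#' @param wCri weight of critical-structure avoidance (default 0.75).
#' @param roiLabel integer label recorded in the result.
#' @return A \linkS4class{TargetRiskMap}.
#' @export
computeTargetRiskMap <- function(roiMask, criticalMask, criticalField, prior,
                                 wSp = 0.25, wCri = 0.75, roiLabel = 0L) {
  if (!.sameGeometry(criticalField, prior)) stop("geometry mismatch")
  dims <- gridDim(criticalField)
  stopifnot(identical(dim(roiMask), dims), identical(dim(criticalMask), dims))
  f <- wSp * prior@values + wCri * (1 - criticalField@values)
  f[!roiMask | criticalMask] <- 1
  new("TargetRiskMap",
      field = scalarField(f, fieldAffine(criticalField), name = "target_risk"),
      roiLabel = as.integer(roiLabel), weights = c(wSp, wCri))
}

#' Local minima of a target risk map by iterative flooding
#'
#' Regional-minima detection under 26-connectivity restricted to voxels
#' with f < 1 (voxels at the ceiling — outside the ROI or on critical
#' structures — can never be targets). A plateau of equal f yields one
#' representative: its lowest linear-index voxel, i.e. lexicographically
#' smallest (z, y, x).
#'
#' @param map a \linkS4class{TargetRiskMap}.
#' @return data.frame with 0-based voxel columns i, j, k and the f value,
#'   ordered by linear index; zero rows when no minimum lies below 1.
#' @export
findLocalMinima <- function(map) {
  vals <- map@field@values
  dims <- dim(vals)
  idx <- cpp_regional_minima(as.vector(vals), as.integer(dims), 1)
  if (!length(idx))
    return(data.frame(i = integer(), j = integer(), k = integer(),
                      f = numeric()))
  idx0 <- idx - 1L
  i <- idx0 %% dims[1]
  j <- (idx0 %/% dims[1]) %% dims[2]
  k <- idx0 %/% (dims[1] * dims[2])
  data.frame(i = i, j = j, k = k, f = vals[idx])
}

#' Cluster candidate minima into one group per electrode
#'
#' K-means over the minima's world coordinates with deterministic
#' farthest-point initialization: the first centre is the minimum with the
#' lowest f, each further centre the point maximizing its distance to the
#' centres already chosen (ties broken by lowest point index). With fewer
#' minima than electrodes, points are assigned round-robin by f rank (with
#' reuse once exhausted) and a warning is emitted.
#'
#' @param points n x 3 matrix of world-mm minima.
#' @param K number of electrodes sharing the ROI.
#' @param f target-risk values of the points.
#' @param seed integer seed recorded for reproducibility.
#' @return integer vector of cluster assignments in 1..K (length n, or
#'   length K with point indices when n < K — see Details).
#' @details When n >= K the return value has one cluster id per point.
#'   When n < K the round-robin fallback instead returns, per cluster
#'   1..K, the index of the point assigned to it (points are reused).
#' @export
clusterTargets <- function(points, K, f, seed = 1L) {
  points <- rbind2mat(points)
  n <- nrow(points)
  stopifnot(K >= 1, n >= 1, length(f) == n)
  if (n < K) {
    warning(sprintf("only %d local minima for %d electrodes; assigning round-robin by f rank", n, K))
    rank <- order(f, seq_len(n))
    return(structure(rank[((seq_len(K) - 1L) %% n) + 1L],
                     roundRobin = TRUE))
  }
  if (K == 1L) return(rep(1L, n))
  # farthest-point initial centres
  centres <- integer(K)
  centres[1] <- order(f, seq_len(n))[1]
  mind <- sqrt(colSums((t(points) - points[centres[1], ])^2))
  for (k in seq_len(K - 1L) + 1L) {
    centres[k] <- which.max(mind)
    dk <- sqrt(colSums((t(points) - points[centres[k], ])^2))
    mind <- pmin(mind, dk)
  }
  set.seed(seed)
  km <- tryCatch(
    stats::kmeans(points, centers = points[centres, , drop = FALSE],
                  iter.max = 100, algorithm = "Lloyd"),
    error = function(e) NULL,
    warning = function(w) NULL)
  if (is.null(km)) {
    # empty-cluster or non-convergence: nearest initial centre
    d2 <- sapply(centres, function(ci)
      colSums((t(points) - points[ci, ])^2))
    return(max.col(-d2, ties.method = "first"))
  }
  as.integer(km$cluster)
}

#' Select the ranked candidate targets of one cluster
#'
#' The M cluster points with the lowest f become the electrode's candidate
#' targets, ascending in f (ties broken by voxel linear index). Fewer than
#' M points are allowed.
#'
#' @param points k x 3 matrix of world-mm cluster minima.
#' @param f their target-risk values.
#' @param M maximum number of candidates (default 10).
#' @param electrodeId electrode identifier.
#' @param clusterId cluster index.
#' @return A \linkS4class{CandidateTargetSet}.
#' @export
selectCandidates <- function(points, f, M = 10L, electrodeId = "e",
                             clusterId = 1L) {
  points <- rbind2mat(points)
  stopifnot(nrow(points) >= 1)
  ord <- order(f, seq_along(f))
  keep <- head(ord, M)
  new("CandidateTargetSet", electrodeId = as.character(electrodeId),
      targets = points[keep, , drop = FALSE], f = as.numeric(f[keep]),
      clusterId = as.integer(clusterId))
}

#' Candidate targets for every electrode of a strategy
#'
#' Per (deep ROI label, prior) group: build the target risk map, extract
#' its regional minima, cluster them into as many groups as electrodes
#' share the ROI, and rank each cluster's minima by f. Clusters are ordered
#' by their best (lowest) f and matched to the group's electrodes in
#' strategy order.
#'
#' @param parcellation \linkS4class{LabelVolume} with the ROI labels.
#' @param criticalMask logical array (arteries | veins).
#' @param skull \linkS4class{SurfaceMesh}.
#' @param strategy data.frame from [readStrategy()].
#' @param M candidates per electrode (default 10).
#' @param wSp,wCri risk-map weights (defaults 0.25 / 0.75).
#' @param seed integer seed for the clustering initialization policy.
#' @param criticalField,skullDistance optional precomputed fields.
#' @return named list of \linkS4class{CandidateTargetSet}, one per
#'   electrode, plus attribute "riskMaps" (per-group TargetRiskMap list).
#' @export
candidateTargets <- function(parcellation, criticalMask, skull, strategy,
                             M = 10L, wSp = 0.25, wCri = 0.75, seed = 1L,
                             criticalField = NULL, skullDistance = NULL) {
  labs <- parcellation@labels
  present <- unique(as.vector(labs))
  for (lb in unique(c(strategy$deep_roi_label,
                      strategy$superficial_roi_label))) {
    if (!is.na(lb) && !(lb %in% present))
      stop(errorCondition(paste("unknown label:", lb),
                          class = c("seegplan_unknown_label", "error")))
  }
  if (is.null(criticalField))
    criticalField <- computeCriticalField(criticalMask, parcellation)
  if (is.null(skullDistance) &&
      any(strategy$prior == "medial_surface"))
    skullDistance <- distanceField(skull, parcellation)
  out <- vector("list", nrow(strategy))
  names(out) <- strategy$id
  maps <- list()
  groups <- split(seq_len(nrow(strategy)),
                  paste(strategy$deep_roi_label, strategy$prior))
  for (g in groups) {
    lb <- strategy$deep_roi_label[g[1]]
    prior_mode <- strategy$prior[g[1]]
    K <- length(g)
    roiMask <- labs == lb
    prior <- computeSpatialPrior(prior_mode, roiMask, parcellation,
                                 skull = skull, skullDistance = skullDistance)
    map <- computeTargetRiskMap(roiMask, criticalMask, criticalField, prior,
                                wSp = wSp, wCri = wCri, roiLabel = lb)
    maps[[as.character(lb)]] <- map
    mins <- findLocalMinima(map)
    if (nrow(mins) == 0)
      stop(errorCondition(
        paste0("no candidate targets in ROI ", lb,
               " (ROI fully covered by critical structures?)"),
        class = c("seegplan_no_trajectory", "error")))
    world <- voxelToWorld(parcellation@affine, as.matrix(mins[, c("i", "j", "k")]))
    cl <- clusterTargets(world, K, mins$f, seed = seed)
    if (isTRUE(attr(cl, "roundRobin"))) {
      for (e in seq_along(g)) {
        pt <- cl[e]
        out[[g[e]]] <- selectCandidates(world[pt, , drop = FALSE],
                                        mins$f[pt], M = M,
                                        electrodeId = strategy$id[g[e]],
                                        clusterId = e)
      }
    } else {
      bestf <- sapply(seq_len(K), function(k) min(mins$f[cl == k]))
      clOrder <- order(bestf)
      for (e in seq_along(g)) {
        k <- clOrder[e]
        sel <- cl == k
        out[[g[e]]] <- selectCandidates(world[sel, , drop = FALSE],
                                        mins$f[sel], M = M,
                                        electrodeId = strategy$id[g[e]],
                                        clusterId = k)
      }
    }
  }
  attr(out, "riskMaps") <- maps
  out
}
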