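.unitDir <- function(thetaDeg, phiDeg) {
  th <- thetaDeg * pi / 180
  ph <- phiDeg * pi / 180
  c(cos(ph) * cos(th), cos(ph) * sin(th), sin(ph))
}

.defaultRois <- function() {
  # Six deep ROIs on well-separated directions (azimuth every 60 degrees,
  # elevation alternating +/-35 so trajectories clear the equatorial
  # vessels), about 55 mm from the head centre. Labels 101 and 104 are
  # two-lobed (dumbbell) regions that receive two electrodes each; label
  # 201 is a superficial cortical patch over ROI 101 used as a traversal
  # constraint.
  mkLobe <- function(centre, semi) list(centre = centre, semiAxes = semi)
  u1 <- .unitDir(0, 35); t1 <- c(0, 1, 0)
  u4 <- .unitDir(180, -35); t4 <- c(0, -1, 0)
  list(
    list(label = 101L, name = "deep_a", lobes = list(
      mkLobe(55 * u1 + 11 * t1, c(7, 7, 7)),
      mkLobe(55 * u1 - 11 * t1, c(7, 7, 7)))),
    list(label = 102L, name = "deep_b", lobes = list(
      mkLobe(55 * .unitDir(60, -35), c(9, 9, 9)))),
    list(label = 103L, name = "deep_c", lobes = list(
      mkLobe(55 * .unitDir(120, 35), c(9, 9, 9)))),
    list(label = 104L, name = "deep_d", lobes = list(
      mkLobe(55 * u4 + 11 * t4, c(7, 7, 7)),
      mkLobe(55 * u4 - 11 * t4, c(7, 7, 7)))),
    list(label = 105L, name = "deep_e", lobes = list(
      mkLobe(55 * .unitDir(240, 35), c(9, 9, 9)))),
    list(label = 106L, name = "deep_f", lobes = list(
      mkLobe(55 * .unitDir(300, -35), c(9, 9, 9)))),
    list(label = 201L, name = "superficial_a", lobes = list(
      mkLobe(76 * u1, c(9, 22, 12)))))
}

.defaultVessels <- function() {
  circ <- function(r, z, n = 36) {
    th <- seq(0, 2 * pi, length.out = n + 1)
    cbind(r * cos(th), r * sin(th), z)
  }
  list(
    list(type = "artery", radius = 2.5,
         points = cbind(0, 0, seq(-70, 70, by = 10))),
    list(type = "artery", radius = 1.5, points = circ(40, 0)),
    list(type = "vein", radius = 2, points = circ(75, 0)))
}

.defaultSulci <- function() {
  lapply(c(30, 150, 270), function(th) {
    d <- .unitDir(th, 0)
    list(centre = 70 * d, normal = c(-d[2], d[1], 0),
         radius = 12, thickness = 1.6)
  })
}

.defaultCorridors <- function(rois) {
  out <- list()
  for (r in rois) {
    if (r$label >= 200L) next
    for (lb in r$lobes) {
      axis <- lb$centre / sqrt(sum(lb$centre^2))
      out[[length(out) + 1L]] <- list(apex = lb$centre, axis = axis,
                                      halfAngleDeg = 12, length = 40)
    }
  }
  out
}

.defaultStrategy <- function() {
  data.frame(
    id = paste0("E", 1:8),
    deep_roi_label = c(101L, 101L, 102L, 103L, 104L, 104L, 105L, 106L),
    superficial_roi_label = c(201L, NA, NA, NA, NA, NA, NA, NA),
    prior = c("roi_centreline", "roi_centreline", "medial_surface",
              "roi_centreline", "roi_centreline", "roi_centreline",
              "medial_surface", "roi_centreline"),
    stringsAsFactors = FALSE)
}

#' Specification of a synthetic head phantom
#'
#' The default phantom mimics clinical imaging scale: a 1 mm isotropic
#' grid, a spherical skull of 90 mm outer radius (~180 mm head diameter),
#' a cortical grey-matter ribbon, six deep ROIs (two of them two-lobed and
#' carrying two electrodes each, eight electrodes in total), a midline
#' artery, deep and superficial equatorial vascular rings, and three
#' sulcal sheets. Each ROI declares a vessel- and sulcus-free conical
#' corridor toward the skull; corridor emptiness is verified after
#' generation, so the phantom carries ground-truth safe trajectories.
#'
#' @param gridShape integer length-3 voxel counts (default c(190,190,190)).
#' @param spacing voxel size in mm (default 1 mm isotropic).
#' @param skullOuterRadius,skullInnerRadius skull shell radii, mm (90 / 84).
#' @param gmRibbon inner/outer radius of the cortical ribbon, mm (72 / 80).
#' @param rois list of ROI descriptors (label, name, lobes of
#'   centre/semiAxes ellipsoids).
#' @param vessels list of tubes (type, radius mm, polyline points).
#' @param sulci list of thin disks (centre, normal, radius, thickness).
#' @param corridors list of cones (apex, axis, halfAngleDeg, length)
#'   verified vessel- and sulcus-free.
#' @param strategy electrode strategy data.frame.
#' @param meshSubdivisions icosphere subdivision level for the skull mesh
#'   (3 gives 642 vertices).
#' @param seed integer seed recorded in the spec (generation is
#'   deterministic).
#' @return list of class "phantomSpec".
#' @export
phantomSpec <- function(gridShape = c(190L, 190L, 190L),
                        spacing = c(1, 1, 1),
                        skullOuterRadius = 90, skullInnerRadius = 84,
                        gmRibbon = c(72, 80),
                        rois = .defaultRois(),
                        vessels = .defaultVessels(),
                        sulci = .defaultSulci(),
                        corridors = .defaultCorridors(rois),
                        strategy = .defaultStrategy(),
                        meshSubdivisions = 3L,
                        seed = 42L) {
  spacing <- rep(as.numeric(spacing), length.out = 3)
  structure(list(gridShape = as.integer(gridShape), spacing = spacing,
                 skullOuterRadius = skullOuterRadius,
                 skullInnerRadius = skullInnerRadius,
                 gmRibbon = gmRibbon, rois = rois, vessels = vessels,
                 sulci = sulci, corridors = corridors, strategy = strategy,
                 meshSubdivisions = as.integer(meshSubdivisions),
                 seed = as.integer(seed)),
            class = "phantomSpec")
}

.phantomAffine <- function(spec) {
  aff <- diag(4)
  diag(aff)[1:3] <- spec$spacing
  # centre the grid on the origin (voxel centres symmetric about 0)
  aff[1:3, 4] <- -spec$spacing * (spec$gridShape - 1) / 2
  aff
}

.worldGrids <- function(spec) {
  aff <- .phantomAffine(spec)
  list(x = aff[1, 4] + (0:(spec$gridShape[1] - 1)) * spec$spacing[1],
       y = aff[2, 4] + (0:(spec$gridShape[2] - 1)) * spec$spacing[2],
       z = aff[3, 4] + (0:(spec$gridShape[3] - 1)) * spec$spacing[3])
}

.ellipsoidMask <- function(spec, centre, semi) {
  g <- .worldGrids(spec)
  dx <- (g$x - centre[1]) / semi[1]
  dy <- (g$y - centre[2]) / semi[2]
  dz <- (g$z - centre[3]) / semi[3]
  outer(outer(dx^2, dy^2, "+"), dz^2, "+") <= 1
}

.radiusGrid <- function(spec) {
  g <- .worldGrids(spec)
  sqrt(outer(outer(g$x^2, g$y^2, "+"), g$z^2, "+"))
}

.diskMask <- function(spec, centre, normal, radius, thickness) {
  g <- .worldGrids(spec)
  n <- normal / sqrt(sum(normal^2))
  dims <- spec$gridShape
  X <- array(g$x, dims)
  Y <- array(rep(g$y, each = dims[1]), dims)
  Z <- array(rep(g$z, each = dims[1] * dims[2]), dims)
  vx <- X - centre[1]; vy <- Y - centre[2]; vz <- Z - centre[3]
  dn <- vx * n[1] + vy * n[2] + vz * n[3]
  inplane2 <- vx^2 + vy^2 + vz^2 - dn^2
  abs(dn) <= thickness / 2 & inplane2 <= radius^2
}

#' Generate a synthetic head phantom
#'
#' Deterministically rasterizes the spec onto its voxel grid and builds
#' the skull mesh, then verifies every declared corridor is free of
#' vessel and sulcus voxels (error if not — the spec is inconsistent).
#'
#' @param spec a [phantomSpec()].
#' @return list of class "seegPhantom" with elements `parcellation`
#'   (\linkS4class{LabelVolume}: GM ribbon = 1, ROI labels as declared),
#'   `masks` (logical arrays gm, arteries, veins, sulci), `skull`
#'   (\linkS4class{SurfaceMesh}), `strategy` (data.frame) and `spec`.
#' @export
generatePhantom <- function(spec = phantomSpec()) {
  set.seed(spec$seed)
  aff <- .phantomAffine(spec)
  dims <- spec$gridShape
  origin <- aff[1:3, 4]

  r <- .radiusGrid(spec)
  gm <- r >= spec$gmRibbon[1] & r <= spec$gmRibbon[2]
  labels <- array(0L, dims)
  labels[gm] <- 1L
  for (roi in spec$rois) {
    for (lb in roi$lobes) {
      m <- .ellipsoidMask(spec, lb$centre, lb$semiAxes)
      labels[m] <- roi$label
      gm <- gm | m
    }
  }
  rm(r)

  emptyMask <- array(FALSE, dims)
  arteries <- emptyMask
  veins <- emptyMask
  for (v in spec$vessels) {
    m <- cpp_tube_mask(emptyMask, as.integer(dims), origin, spec$spacing,
                       as.matrix(v$points), v$radius)
    if (v$type == "artery") arteries <- arteries | array(m, dims)
    else veins <- veins | array(m, dims)
  }
  sulci <- emptyMask
  for (s in spec$sulci)
    sulci <- sulci | .diskMask(spec, s$centre, s$normal, s$radius, s$thickness)

  skull <- icosphere(spec$skullOuterRadius, spec$meshSubdivisions)

  legend <- c(background = 0L, grey_matter = 1L,
              setNames(vapply(spec$rois, function(x) x$label, integer(1)),
                       vapply(spec$rois, function(x) x$name, character(1))))
  parc <- labelVolume(labels, aff, legend = legend)

  phantom <- structure(list(parcellation = parc,
                            masks = list(gm = gm, arteries = arteries,
                                         veins = veins, sulci = sulci),
                            skull = skull, strategy = spec$strategy,
                            spec = spec),
                       class = "seegPhantom")
  .verifyCorridors(phantom)
  phantom
}

# every declared corridor must be free of vessel and sulcus voxels
.verifyCorridors <- function(phantom) {
  spec <- phantom$spec
  bad <- phantom$masks$arteries | phantom$masks$veins | phantom$masks$sulci
  if (!any(bad)) return(invisible(TRUE))
  idx <- which(bad, arr.ind = TRUE) - 1L
  pts <- voxelToWorld(phantom$parcellation@affine, idx)
  for (co in spec$corridors) {
    v <- sweep(pts, 2, co$apex)
    proj <- as.numeric(v %*% co$axis)
    lat2 <- rowSums(v^2) - proj^2
    inside <- proj >= 0 & proj <= co$length &
      lat2 <= (proj * tan(co$halfAngleDeg * pi / 180))^2
    if (any(inside))
      stop("phantom spec inconsistent: critical-structure voxels inside a declared corridor")
  }
  invisible(TRUE)
}

#' Rigidly translate the phantom's vessel tree
#'
#' Re-rasterizes every vessel polyline after adding `offset`; all other
#' structures are unchanged. Supports the monotonicity analysis of the
#' risk score (moving vessels away from a trajectory can only lower R).
#' Corridor verification is not re-run: a perturbed phantom makes no
#' corridor guarantee.
#'
#' @param phantom a "seegPhantom".
#' @param offset length-3 world-mm translation.
#' @return the perturbed phantom.
#' @export
perturbVessels <- function(phantom, offset) {
  stopifnot(all(is.finite(offset)), length(offset) == 3)
  spec <- phantom$spec
  spec$vessels <- lapply(spec$vessels, function(v) {
    v$points <- sweep(as.matrix(v$points), 2, -as.numeric(offset))
    v
  })
  dims <- spec$gridShape
  aff <- phantom$parcellation@affine
  origin <- aff[1:3, 4]
  emptyMask <- array(FALSE, dims)
  arteries <- emptyMask
  veins <- emptyMask
  for (v in spec$vessels) {
    m <- cpp_tube_mask(emptyMask, as.integer(dims), origin, spec$spacing,
                       as.matrix(v$points), v$radius)
    if (v$type == "artery") arteries <- arteries | array(m, dims)
    else veins <- veins | array(m, dims)
  }
  phantom$masks$arteries <- arteries
  phantom$masks$veins <- veins
  phantom$spec <- spec
  phantom
}

#' Write phantom volumes, skull mesh, and strategy to disk
#'
#' Emits exactly the formats the planner consumes: NIfTI parcellation and
#' masks, an ASCII PLY skull mesh, and a YAML strategy file.
#'
#' @param phantom a "seegPhantom".
#' @param dir output directory (created if needed).
#' @return named list of written paths.
#' @export
writePhantom <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  aff <- phantom$parcellation@affine
  paths <- list(parcellation = file.path(dir, "parcellation.nii.gz"))
  writeVolume(phantom$parcellation, paths$parcellation)
  for (m in names(phantom$masks)) {
    paths[[m]] <- file.path(dir, paste0(m, ".nii.gz"))
    writeVolume(scalarField(array(as.numeric(phantom$masks[[m]]),
                                  dim(phantom$masks[[m]])), aff, name = m),
                paths[[m]])
  }
  paths$skull <- file.path(dir, "skull.ply")
  writeMeshPLY(phantom$skull, paths$skull)
  paths$strategy <- file.path(dir, "strategy.yaml")
  writeStrategy(phantom$strategy, paths$strategy)
  paths
}
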