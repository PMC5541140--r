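test_that("target risk map follows the piecewise formula on a toy grid", {
  dims <- c(8, 8, 8)
  grid <- constantField(0, dims)
  aff <- fieldAffine(grid)
  set.seed(3)
  roi <- array(FALSE, dims); roi[3:6, 3:6, 3:6] <- TRUE
  cri <- array(FALSE, dims); cri[4, 4, 4] <- TRUE; cri[7, 2, 5] <- TRUE
  fcri <- scalarField(array(runif(prod(dims)), dims), aff)
  fsp <- scalarField(array(runif(prod(dims)), dims), aff)
  map <- computeTargetRiskMap(roi, cri, fcri, fsp, wSp = 0.25, wCri = 0.75,
                              roiLabel = 1L)
  f <- fieldValues(map)
  # hand-computed oracle, voxel by voxel
  expected <- 0.25 * fieldValues(fsp) + 0.75 * (1 - fieldValues(fcri))
  expected[!roi | cri] <- 1
  expect_equal(f, expected)
  expect_true(all(f[!roi] == 1))
  expect_true(all(f[cri] == 1))
  # boundary cases of the linear combination
  fsp0 <- scalarField(array(0, dims), aff)
  fcri1 <- scalarField(array(1, dims), aff)
  f0 <- fieldValues(computeTargetRiskMap(roi, array(FALSE, dims), fcri1, fsp0))
  expect_true(all(f0[roi] == 0))      # best possible voxel
  fsp1 <- scalarField(array(1, dims), aff)
  fcri0 <- scalarField(array(0, dims), aff)
  f1 <- fieldValues(computeTargetRiskMap(roi, array(FALSE, dims), fcri0, fsp1))
  expect_true(all(f1[roi] == 1))      # 0.25*1 + 0.75*(1-0) = 1
})

test_that("critical field is 0 on vessels, 1 at the farthest voxel, monotone under union", {
  dims <- c(20, 20, 20)
  grid <- constantField(0, dims)
  ves <- array(FALSE, dims); ves[5, 5, 5] <- TRUE
  f1 <- fieldValues(computeCriticalField(ves, grid))
  expect_identical(f1[5, 5, 5], 0)
  expect_identical(max(f1), 1)
  expect_identical(f1[20, 20, 20], 1)   # unique farthest corner
  ves2 <- ves; ves2[16, 16, 16] <- TRUE
  f2raw <- fieldValues(distanceField(ves2, grid))
  f1raw <- fieldValues(distanceField(ves, grid))
  expect_true(all(f2raw <= f1raw + 1e-12))  # adding a vessel never increases distance
  expect_error(computeCriticalField(array(FALSE, dims), grid), "empty")
})

test_that("spatial priors prefer the right locations in both modes", {
  dims <- c(33, 33, 33)
  grid <- constantField(0, dims)
  g <- seq(-16, 16)
  r <- sqrt(outer(outer(g^2, g^2, "+"), g^2, "+"))
  ball <- r <= 10
  # centreline mode: centre voxel attains the maximum raw boundary distance
  raw <- fieldValues(distanceField(!ball, grid))
  expect_identical(which.max(raw), which(r == 0))
  prior <- computeSpatialPrior("roi_centreline", ball, grid)
  pv <- fieldValues(prior)
  expect_identical(which.min(pv), which(r == 0))
  expect_gte(min(pv), 0); expect_identical(max(pv), 1)
  # medial-surface mode: deep voxels (far from the skull) get low prior
  skull <- icosphere(16, 2)
  pm <- computeSpatialPrior("medial_surface", ball, grid, skull = skull)
  pmv <- fieldValues(pm)
  expect_gte(min(pmv), 0); expect_identical(max(pmv), 1)
  expect_lt(pmv[17, 17, 17], pmv[17, 17, 26])  # centre deeper than near-skull
  expect_error(computeSpatialPrior("roi_centreline", array(FALSE, dims), grid),
               "empty ROI")
})

test_that("regional minima match an exhaustive neighbourhood scan", {
  # unimodal paraboloid: exactly one minimum at the basin bottom
  dims <- c(15, 15, 15)
  xx <- seq(-1, 1, length.out = 15)
  f <- array(pmin(outer(outer((xx + 0.2)^2, xx^2, "+"), xx^2, "+") / 4, 0.99),
             dims)
  map <- new("TargetRiskMap", field = scalarField(f), roiLabel = 1L,
             weights = c(0.25, 0.75))
  mins <- findLocalMinima(map)
  expect_identical(nrow(mins), 1L)
  expect_identical(unlist(mins[1, c("i", "j", "k")], use.names = FALSE),
                   c(which.min((xx + 0.2)^2) - 1L, 7L, 7L))
  # two separated basins -> 2 minima
  f2 <- f
  f2[3, 3, 3] <- 0.0001
  mins2 <- findLocalMinima(new("TargetRiskMap", field = scalarField(f2),
                               roiLabel = 1L, weights = c(0.25, 0.75)))
  expect_identical(nrow(mins2), 2L)
  # random continuous fields against the brute-force 26-neighbour scan
  set.seed(17)
  for (rep in 1:5) {
    fr <- array(runif(24^3), c(24, 24, 24))
    got <- findLocalMinima(new("TargetRiskMap", field = scalarField(fr),
                               roiLabel = 1L, weights = c(0.25, 0.75)))
    want <- bruteForceMinima(fr)
    expect_equal(as.matrix(got[, c("i", "j", "k")]), want,
                 ignore_attr = TRUE)
  }
  # field all at the ceiling -> empty set
  none <- findLocalMinima(new("TargetRiskMap",
                              field = scalarField(array(1, c(5, 5, 5))),
                              roiLabel = 1L, weights = c(0.25, 0.75)))
  expect_identical(nrow(none), 0L)
})

test_that("plateaus of equal value yield one representative each", {
  f <- array(0.9, c(7, 7, 7))
  f[2:3, 2:3, 2] <- 0.5           # 4-voxel plateau, one representative
  f[6, 6, 6] <- 0.2               # isolated minimum
  got <- findLocalMinima(new("TargetRiskMap", field = scalarField(f),
                             roiLabel = 1L, weights = c(0.25, 0.75)))
  expect_identical(nrow(got), 2L)
  # representative is the lexicographically smallest (z, y, x) voxel
  expect_identical(unlist(got[1, c("i", "j", "k")], use.names = FALSE),
                   c(1L, 1L, 1L))
  expect_identical(unlist(got[2, c("i", "j", "k")], use.names = FALSE),
                   c(5L, 5L, 5L))
})

test_that("clustering recovers separated groups and degrades gracefully", {
  set.seed(9)
  a <- matrix(rnorm(30, sd = 1), 10, 3)
  b <- matrix(rnorm(30, sd = 1), 10, 3) + 50
  pts <- rbind(a, b)
  f <- runif(20)
  cl <- clusterTargets(pts, 2, f)
  expect_identical(length(unique(cl[1:10])), 1L)
  expect_identical(length(unique(cl[11:20])), 1L)
  expect_false(cl[1] == cl[11])
  expect_true(all(clusterTargets(pts, 1, f) == 1L))       # K = 1
  clAll <- clusterTargets(a, 10, runif(10))               # K = n: singletons
  expect_identical(sort(unique(clAll)), 1:10)
  expect_warning(cl3 <- clusterTargets(a[1:2, ], 3, c(0.2, 0.1)),
                 "round-robin")
  expect_identical(length(cl3), 3L)
  expect_identical(cl3[1], 2L)    # lowest-f point first
})

test_that("candidate selection truncates at M, sorted ascending in f", {
  pts <- matrix(runif(15), 5, 3)
  f <- c(0.5, 0.1, 0.9, 0.3, 0.2)
  cs <- selectCandidates(pts, f, M = 10, electrodeId = "E1")
  expect_identical(nrow(candidateTargetPoints(cs)), 5L)   # fewer than M kept
  expect_identical(cs@f, sort(f))
  cs3 <- selectCandidates(pts, f, M = 3)
  expect_identical(cs3@f, c(0.1, 0.2, 0.3))
})

test_that("phantom candidate targets respect ROI membership and cluster disjointness", {
  ph <- smallPhantom()
  criticalVessels <- ph$masks$arteries | ph$masks$veins
  targets <- candidateTargets(ph$parcellation, criticalVessels, ph$skull,
                              ph$strategy)
  labs <- ph$parcellation@labels
  aff <- ph$parcellation@affine
  for (i in seq_len(nrow(ph$strategy))) {
    id <- ph$strategy$id[i]
    tp <- candidateTargetPoints(targets[[id]])
    ijk <- round(worldToVoxel(aff, tp)) + 1
    inRoi <- labs[ijk] == ph$strategy$deep_roi_label[i]
    expect_true(all(inRoi))
    expect_false(any(criticalVessels[ijk]))
  }
  # electrodes sharing an ROI get disjoint candidate sets
  k1 <- apply(candidateTargetPoints(targets[["E1"]]), 1, paste, collapse = ",")
  k2 <- apply(candidateTargetPoints(targets[["E2"]]), 1, paste, collapse = ",")
  expect_identical(length(intersect(k1, k2)), 0L)
  # unknown strategy label errors with the distinct condition class
  bad <- ph$strategy; bad$deep_roi_label[1] <- 999L
  expect_error(candidateTargets(ph$parcellation, criticalVessels, ph$skull,
                                bad),
               class = "seegplan_unknown_label")
})

test_that("medial-surface prior drives the top candidate to the deep side of the ROI", {
  # ROI abutting the skull on +x, vessels placed symmetrically about the
  # ROI centre so the vessel-avoidance term has no systematic lateral
  # gradient and the spatial prior decides the ranking
  dims <- c(41, 41, 41)
  aff <- diag(c(2, 2, 2, 1)); aff[1:3, 4] <- -40
  grid <- scalarField(array(0, dims), aff)
  skull <- icosphere(38, 3)
  g <- seq(-40, 40, by = 2)
  X <- array(g, dims)
  Y <- array(rep(g, each = 41), dims)
  Z <- array(rep(g, each = 41 * 41), dims)
  roi <- (X - 24)^2 + Y^2 + Z^2 <= 8^2
  vessels <- (abs(X - 10) <= 1 | abs(X - 38) <= 1) & Y^2 + Z^2 <= 2^2
  labels <- array(0L, dims); labels[roi] <- 101L
  parc <- labelVolume(labels, aff, legend = c(roi = 101L))
  strat <- data.frame(id = "E1", deep_roi_label = 101L,
                      superficial_roi_label = NA_integer_,
                      prior = "medial_surface", stringsAsFactors = FALSE)
  skullDist <- distanceField(skull, parc)
  targets <- candidateTargets(parc, vessels, skull, strat,
                              skullDistance = skullDist)
  top <- candidateTargetPoints(targets[[1]])[1, , drop = FALSE]
  topDist <- sampleField(skullDist, top)
  roiIdx <- which(roi, arr.ind = TRUE) - 1
  roiDist <- sampleField(skullDist, voxelToWorld(aff, roiIdx))
  expect_gte(topDist, median(roiDist))
})
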