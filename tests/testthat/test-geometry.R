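test_that("distance fields are exact: zero on the structure, Euclidean off it", {
  dims <- c(21, 21, 21)
  grid <- constantField(0, dims)
  m <- array(FALSE, dims)
  m[11, 11, 11] <- TRUE
  d <- fieldValues(distanceField(m, grid))
  expect_identical(d[11, 11, 11], 0)
  expect_identical(d[16, 11, 11], 5)           # 5 axis-aligned 1 mm steps
  expect_equal(d[14, 15, 11], 5)               # 3-4-5 triangle

  # random sparse masks against an exhaustive nearest-point scan,
  # isotropic and anisotropic
  set.seed(7)
  for (spacing in list(c(1, 1, 1), c(0.7, 1.1, 2.3))) {
    mask <- array(runif(32^3) < 0.004, c(32, 32, 32))
    mask[5, 5, 5] <- TRUE
    g <- scalarField(array(0, c(32, 32, 32)), diag(c(spacing, 1)))
    d <- fieldValues(distanceField(mask, g))
    expect_equal(max(abs(d - bruteForceDistance(mask, spacing))), 0,
                 tolerance = 1e-6)
  }
  expect_error(distanceField(array(FALSE, dims), grid), "empty structure")
})

test_that("distance fields are 1-Lipschitz with respect to world distance", {
  set.seed(11)
  mask <- array(runif(24^3) < 0.01, c(24, 24, 24))
  mask[2, 2, 2] <- TRUE
  sp <- c(0.9, 1.3, 1.7)
  g <- scalarField(array(0, c(24, 24, 24)), diag(c(sp, 1)))
  d <- fieldValues(distanceField(mask, g))
  for (r in 1:200) {
    a <- sample(24, 3, replace = TRUE)
    b <- sample(24, 3, replace = TRUE)
    w <- sqrt(sum(((a - b) * sp)^2))
    expect_lte(abs(d[a[1], a[2], a[3]] - d[b[1], b[2], b[3]]), w + 1e-9)
  }
})

test_that("normalizeField maps to [0,1] with max exactly 1 and is stable", {
  f <- constantField(0, c(8, 8, 8))
  v <- fieldValues(f)
  v[5, 5, 5] <- 20
  v[2, 2, 2] <- 10
  f <- scalarField(v, fieldAffine(f))
  n1 <- normalizeField(f)
  expect_identical(max(fieldValues(n1)), 1)
  expect_identical(fieldValues(n1)[2, 2, 2], 0.5)
  expect_gte(min(fieldValues(n1)), 0)
  # idempotent up to scaling: normalizing twice equals once
  expect_equal(fieldValues(normalizeField(n1)), fieldValues(n1))
  # constant positive field -> all 1
  expect_true(all(fieldValues(normalizeField(constantField(3))) == 1))
  expect_error(normalizeField(constantField(0)), "degenerate field")
})

test_that("sampleSegment spaces points uniformly, endpoints inclusive", {
  s <- sampleSegment(c(0, 0, 0), c(10, 0, 0), 1)
  expect_identical(nrow(s), 11L)
  expect_equal(s[1, ], c(0, 0, 0))
  expect_equal(s[11, ], c(10, 0, 0))
  gaps <- sqrt(rowSums(diff(s)^2))
  expect_lt(max(abs(gaps - gaps[1])), 1e-9)
  # non-divisible length: spacing never exceeds step
  s2 <- sampleSegment(c(0, 0, 0), c(0, 0, 7.3), 2)
  expect_lte(max(sqrt(rowSums(diff(s2)^2))), 2 + 1e-12)
  expect_error(sampleSegment(c(1, 1, 1), c(1, 1, 1), 1), "length")
})

test_that("segment-segment distance matches a dense-sampling oracle", {
  expect_identical(segmentSegmentDistance(c(0, 0, 0), c(1, 2, 3),
                                          c(0, 0, 0), c(1, 2, 3)), 0)
  expect_equal(segmentSegmentDistance(c(0, 0, 0), c(1, 0, 0),
                                      c(0, 10, 0), c(1, 10, 0)), 10)
  set.seed(21)
  for (r in 1:200) {
    p1 <- runif(3, -3, 3); q1 <- p1 + runif(3, -2, 2)
    p2 <- runif(3, -3, 3); q2 <- p2 + runif(3, -2, 2)
    if (sum((q1 - p1)^2) < 1e-4 || sum((q2 - p2)^2) < 1e-4) next
    a <- segmentSegmentDistance(p1, q1, p2, q2)
    b <- denseSegmentDistance(p1, q1, p2, q2, step = 0.01)
    expect_lte(abs(a - b), 0.02)
    expect_equal(a, segmentSegmentDistance(p2, q2, p1, q1))  # symmetry
  }
})

test_that("segment distances obey a diameter-relaxed triangle bound", {
  set.seed(5)
  for (r in 1:50) {
    segs <- lapply(1:3, function(i) {
      p <- runif(3, -20, 20); list(p = p, q = p + runif(3, -15, 15))
    })
    dab <- segmentSegmentDistance(segs[[1]]$p, segs[[1]]$q, segs[[2]]$p, segs[[2]]$q)
    dbc <- segmentSegmentDistance(segs[[2]]$p, segs[[2]]$q, segs[[3]]$p, segs[[3]]$q)
    dac <- segmentSegmentDistance(segs[[1]]$p, segs[[1]]$q, segs[[3]]$p, segs[[3]]$q)
    diamB <- sqrt(sum((segs[[2]]$q - segs[[2]]$p)^2))
    expect_lte(dac, dab + diamB + dbc + 1e-9)
  }
})

test_that("signed GM distance is positive inside, negative outside, with correct magnitude", {
  dims <- c(24, 24, 24)
  grid <- constantField(0, dims)
  g <- seq(-11.5, 11.5)
  r <- sqrt(outer(outer(g^2, g^2, "+"), g^2, "+"))
  ball <- r <= 7
  s <- fieldValues(signedGmDistance(ball, grid))
  expect_gt(s[12, 12, 12], 0)       # deep inside
  expect_lt(s[1, 1, 1], 0)          # far outside
  expect_true(all((s >= 0) == ball))  # Heaviside of the field is the mask
  # |signed| within one voxel diagonal of the unsigned distance to the
  # boundary layer (mask voxels adjacent to the complement)
  inner <- ball
  inner[2:23, 2:23, 2:23] <- ball[2:23, 2:23, 2:23] &
    ball[1:22, 2:23, 2:23] & ball[3:24, 2:23, 2:23] &
    ball[2:23, 1:22, 2:23] & ball[2:23, 3:24, 2:23] &
    ball[2:23, 2:23, 1:22] & ball[2:23, 2:23, 3:24]
  boundary <- ball & !inner
  dB <- bruteForceDistance(boundary, c(1, 1, 1))
  expect_lte(max(abs(abs(s) - dB)), sqrt(3) + 1e-9)
  expect_error(signedGmDistance(array(FALSE, dims), grid), "empty")
  expect_error(signedGmDistance(array(TRUE, dims), grid), "full")
})

test_that("voxel/world coordinates round-trip through the affine", {
  aff <- diag(c(0.8, 1.2, 2, 1))
  aff[1:3, 4] <- c(-10, 5, 3)
  ijk <- matrix(runif(30, 0, 20), 10, 3)
  xyz <- voxelToWorld(aff, ijk)
  expect_equal(worldToVoxel(aff, xyz), ijk)
  expect_equal(voxelSpacing(aff), c(0.8, 1.2, 2))
})
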