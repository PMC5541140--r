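# Independent oracles kept deliberately naive: exhaustive scans and dense
# sampling, never the code paths they check.

# Brute-force nearest-structure distance for every voxel of a grid.
bruteForceDistance <- function(mask, spacing) {
  dims <- dim(mask)
  idx <- which(mask, arr.ind = TRUE) - 1L
  pts <- idx * matrix(spacing, nrow(idx), 3, byrow = TRUE)
  g <- as.matrix(expand.grid((0:(dims[1] - 1)) * spacing[1],
                             (0:(dims[2] - 1)) * spacing[2],
                             (0:(dims[3] - 1)) * spacing[3]))
  array(apply(g, 1, function(p) sqrt(min(colSums((t(pts) - p)^2)))), dims)
}

# Dense point-sampling lower-resolution estimate of segment-segment
# distance (step in mm).
denseSegmentDistance <- function(p1, q1, p2, q2, step = 0.01) {
  n1 <- max(2L, ceiling(sqrt(sum((q1 - p1)^2)) / step) + 1L)
  n2 <- max(2L, ceiling(sqrt(sum((q2 - p2)^2)) / step) + 1L)
  t1 <- seq(0, 1, length.out = n1)
  t2 <- seq(0, 1, length.out = n2)
  A <- cbind(p1[1] + t1 * (q1[1] - p1[1]), p1[2] + t1 * (q1[2] - p1[2]),
             p1[3] + t1 * (q1[3] - p1[3]))
  B <- cbind(p2[1] + t2 * (q2[1] - p2[1]), p2[2] + t2 * (q2[2] - p2[2]),
             p2[3] + t2 * (q2[3] - p2[3]))
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  sqrt(max(0, min(d2)))
}

# Exhaustive 26-neighbourhood regional-minima scan. Assumes no ties among
# eligible voxels (the caller uses continuous random fields); strict
# inequality against every in-grid neighbour.
bruteForceMinima <- function(vals, below = 1) {
  dims <- dim(vals)
  out <- NULL
  for (k in seq_len(dims[3])) for (j in seq_len(dims[2])) for (i in seq_len(dims[1])) {
    v <- vals[i, j, k]
    if (v >= below) next
    nb <- expand.grid(i + (-1:1), j + (-1:1), k + (-1:1))
    nb <- nb[!(nb[, 1] == i & nb[, 2] == j & nb[, 3] == k), ]
    nb <- nb[nb[, 1] >= 1 & nb[, 1] <= dims[1] &
             nb[, 2] >= 1 & nb[, 2] <= dims[2] &
             nb[, 3] >= 1 & nb[, 3] <= dims[3], ]
    if (all(vals[as.matrix(nb)] > v))
      out <- rbind(out, c(i - 1L, j - 1L, k - 1L))
  }
  out
}

# Random per-electrode candidate lists for plan-search instances: short
# segments scattered in a box, scores sorted ascending.
randomCandidateLists <- function(N, maxCand = 10, spread = 30) {
  lapply(seq_len(N), function(n) {
    k <- sample(1:maxCand, 1)
    tgt <- matrix(runif(3 * k, -spread, spread), k, 3)
    dirs <- matrix(rnorm(3 * k), k, 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    len <- runif(k, 20, 60)
    ent <- tgt + dirs * len
    R <- runif(k); G <- runif(k)
    df <- data.frame(electrode = paste0("E", n), target_rank = 1L,
                     entry_index = seq_len(k),
                     tx = tgt[, 1], ty = tgt[, 2], tz = tgt[, 3],
                     ex = ent[, 1], ey = ent[, 2], ez = ent[, 3],
                     length_mm = len, angle_deg = 0,
                     R = R, G = G, S = 10 * R + G, relax_level = 0L)
    df <- df[order(df$S), ]
    rownames(df) <- NULL
    df
  })
}

# Exhaustive enumeration optimum of the joint plan.
bruteForcePlan <- function(candidateLists, dTraj) {
  N <- length(candidateLists)
  grid <- do.call(expand.grid,
                  lapply(candidateLists, function(d) seq_len(nrow(d))))
  bestS <- Inf; bestIdx <- NULL; anyFeasible <- FALSE
  for (r in seq_len(nrow(grid))) {
    idx <- as.integer(grid[r, ])
    ok <- TRUE
    if (N > 1) {
      for (a in 1:(N - 1)) {
        for (b in (a + 1):N) {
          da <- candidateLists[[a]][idx[a], ]
          db <- candidateLists[[b]][idx[b], ]
          d <- segmentSegmentDistance(
            c(da$tx, da$ty, da$tz), c(da$ex, da$ey, da$ez),
            c(db$tx, db$ty, db$tz), c(db$ex, db$ey, db$ez))
          if (d <= dTraj) { ok <- FALSE; break }
        }
        if (!ok) break
      }
    }
    if (!ok) next
    anyFeasible <- TRUE
    s <- mean(vapply(seq_len(N),
                     function(n) candidateLists[[n]]$S[idx[n]], numeric(1)))
    if (s < bestS) { bestS <- s; bestIdx <- idx }
  }
  list(feasible = anyFeasible, S = bestS, idx = bestIdx)
}
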