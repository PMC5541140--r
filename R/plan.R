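#' Plan-search configuration
#'
#' @param dTraj minimum pairwise trajectory separation, mm (default 10).
#' @param diversityEpsilon near-duplicate pruning radius, mm (default 0.5).
#'   After a conflict, candidates closer than this to the conflicting
#'   trajectory are skipped at that search node; 0 disables the pruning,
#'   making the search exactly optimal on small instances.
#' @param maxNodes search budget in candidate expansions (default 1e6);
#'   exhausting it triggers the max-separation fallback with a warning.
#' @return list of class "searchConfig".
#' @export
searchConfig <- function(dTraj = 10, diversityEpsilon = 0.5, maxNodes = 1e6) {
  stopifnot(dTraj > 0, diversityEpsilon >= 0, maxNodes > 0)
  structure(list(dTraj = dTraj, diversityEpsilon = diversityEpsilon,
                 maxNodes = maxNodes), class = "searchConfig")
}

.candSegments <- function(df) {
  list(P = as.matrix(df[, c("tx", "ty", "tz")]),
       Q = as.matrix(df[, c("ex", "ey", "ez")]))
}

#' Next candidate sufficiently different from a conflicting trajectory
#'
#' After candidate `fromRank` of an electrode conflicted with an already
#' chosen trajectory, the next candidate considered is the lowest-ranked
#' one after `fromRank` whose segment distance to the conflicting candidate
#' exceeds `eps`; near-duplicates in between are discarded.
#'
#' @param candidates data.frame of ranked candidates (as from
#'   [scoreTrajectories()]).
#' @param conflicting 1-row data.frame (or list) with tx..ez of the
#'   conflicting candidate.
#' @param fromRank rank (row index) of the conflicting candidate.
#' @param eps diversity radius, mm.
#' @return the row index of the next diverse candidate, or NA when
#'   exhausted.
#' @export
nextDiverseCandidate <- function(candidates, conflicting, fromRank, eps) {
  n <- nrow(candidates)
  if (fromRank >= n) return(NA_integer_)
  idx <- (fromRank + 1L):n
  seg <- .candSegments(candidates[idx, , drop = FALSE])
  p1 <- as.numeric(conflicting[c("tx", "ty", "tz")])
  q1 <- as.numeric(conflicting[c("ex", "ey", "ez")])
  d <- .segToSegsDist(p1, q1, seg$P, seg$Q)
  hit <- which(d > eps)
  if (!length(hit)) NA_integer_ else idx[hit[1]]
}

#' Solve the joint implantation plan
#'
#' Depth-first search over one candidate per electrode minimizing the mean
#' weighted score subject to every pairwise segment distance exceeding
#' d_traj. Electrodes are visited in input order; within an electrode,
#' candidates ascending by S. After a conflict, candidates within
#' `diversityEpsilon` of the conflicting candidate are skipped at that node
#' (the paper's 0.5 mm rule); with `diversityEpsilon = 0` no candidate is
#' skipped and the search is exactly optimal. A branch-and-bound cut on the
#' partial score sum (scores are non-negative) discards subtrees that
#' cannot beat the incumbent. If no feasible combination is found — or the
#' node budget is exhausted — the max-separation fallback is returned.
#'
#' @param candidateLists list of data.frames (one per electrode, each
#'   sorted ascending by S, as from [scoreTrajectories()]).
#' @param cfg a [searchConfig()].
#' @return An \linkS4class{ImplantationPlan}.
#' @export
solvePlan <- function(candidateLists, cfg = searchConfig()) {
  N <- length(candidateLists)
  for (n in seq_len(N)) {
    if (is.null(candidateLists[[n]]) || nrow(candidateLists[[n]]) == 0)
      stop(errorCondition(
        paste0("empty candidate list for electrode ",
               if (!is.null(names(candidateLists))) names(candidateLists)[n] else n),
        class = c("seegplan_no_trajectory", "error")))
  }
  segs <- lapply(candidateLists, .candSegments)
  Svals <- lapply(candidateLists, function(d) d$S)
  minS <- vapply(Svals, min, numeric(1))
  suffixMin <- rev(cumsum(rev(c(minS[-1], 0))))  # sum of minima after n

  env <- new.env()
  env$best <- NULL
  env$bestSum <- Inf
  env$nodes <- 0L
  env$skips <- 0L
  env$budgetHit <- FALSE
  eps <- cfg$diversityEpsilon

  chosenP <- matrix(NA_real_, N, 3)
  chosenQ <- matrix(NA_real_, N, 3)
  chosenIdx <- integer(N)

  conflictIdx <- function(level, i) {
    # index of first chosen trajectory (1..level-1) too close to candidate i
    if (level == 1L) return(0L)
    p1 <- segs[[level]]$P[i, ]
    q1 <- segs[[level]]$Q[i, ]
    d <- .segToSegsDist(p1, q1,
                        chosenP[seq_len(level - 1L), , drop = FALSE],
                        chosenQ[seq_len(level - 1L), , drop = FALSE])
    w <- which(d <= cfg$dTraj)
    if (length(w)) w[1] else 0L
  }

  recurse <- function(level, partial) {
    if (env$budgetHit) return()
    ncand <- nrow(candidateLists[[level]])
    lastConflict <- NULL
    i <- 1L
    while (i <= ncand) {
      if (env$nodes >= cfg$maxNodes) { env$budgetHit <- TRUE; return() }
      env$nodes <- env$nodes + 1L
      # diversity pruning against the most recent conflicting candidate
      if (!is.null(lastConflict) && eps > 0) {
        d0 <- .segToSegsDist(segs[[level]]$P[i, ], segs[[level]]$Q[i, ],
                             matrix(lastConflict$p, 1), matrix(lastConflict$q, 1))
        if (d0 < eps) { env$skips <- env$skips + 1L; i <- i + 1L; next }
      }
      s <- partial + Svals[[level]][i]
      if (s + suffixMin[level] >= env$bestSum) {
        # candidates are sorted by S: no later candidate can do better
        return()
      }
      cf <- conflictIdx(level, i)
      if (cf > 0L) {
        lastConflict <- list(p = segs[[level]]$P[i, ],
                             q = segs[[level]]$Q[i, ])
        i <- i + 1L
        next
      }
      chosenP[level, ] <<- segs[[level]]$P[i, ]
      chosenQ[level, ] <<- segs[[level]]$Q[i, ]
      chosenIdx[level] <<- i
      if (level == N) {
        if (s < env$bestSum) {
          env$bestSum <- s
          env$best <- chosenIdx
        }
      } else {
        recurse(level + 1L, s)
        if (env$budgetHit) return()
      }
      i <- i + 1L
    }
  }
  recurse(1L, 0)

  if (env$budgetHit)
    warning("plan search budget exhausted (", cfg$maxNodes,
            " nodes); falling back to max-separation plan")
  if (is.null(env$best)) {
    plan <- fallbackMaxSeparation(candidateLists, cfg)
    plan@searchInfo$nodes <- env$nodes
    plan@searchInfo$diversitySkips <- env$skips
    plan@searchInfo$budgetHit <- env$budgetHit
    return(plan)
  }
  .buildPlan(candidateLists, env$best, cfg,
             searchInfo = list(nodes = env$nodes, diversitySkips = env$skips,
                               fallback = FALSE, budgetHit = env$budgetHit))
}

.pairwiseDistances <- function(candidateLists, idx) {
  N <- length(idx)
  P <- t(vapply(seq_len(N), function(n)
    as.numeric(candidateLists[[n]][idx[n], c("tx", "ty", "tz")]), numeric(3)))
  Q <- t(vapply(seq_len(N), function(n)
    as.numeric(candidateLists[[n]][idx[n], c("ex", "ey", "ez")]), numeric(3)))
  D <- matrix(0, N, N)
  if (N > 1) {
    for (a in seq_len(N - 1)) {
      rows <- (a + 1):N
      d <- .segToSegsDist(P[a, ], Q[a, ], P[rows, , drop = FALSE],
                          Q[rows, , drop = FALSE])
      D[a, rows] <- d
      D[rows, a] <- d
    }
  }
  D
}

.buildPlan <- function(candidateLists, idx, cfg, searchInfo = list()) {
  N <- length(idx)
  rows <- do.call(rbind, lapply(seq_len(N), function(n) {
    r <- candidateLists[[n]][idx[n], , drop = FALSE]
    r$rank <- idx[n]
    r
  }))
  rownames(rows) <- NULL
  D <- .pairwiseDistances(candidateLists, idx)
  minD <- if (N > 1) min(D[upper.tri(D)]) else Inf
  new("ImplantationPlan", trajectories = rows, STotal = mean(rows$S),
      pairwiseDistances = D, minPairwiseDistance = minD,
      feasible = minD > cfg$dTraj, searchInfo = searchInfo)
}

#' Max-separation fallback plan
#'
#' When no combination satisfies the d_traj constraint, return the plan
#' maximizing the minimum pairwise trajectory distance: greedy
#' coordinate-ascent over the top candidates of each electrode (at most 50
#' per electrode), started from the rank-0 plan and refined by single-
#' electrode swaps until no improvement; ties in minimum distance are
#' broken toward the lower mean score.
#'
#' @param candidateLists list of ranked candidate data.frames.
#' @param cfg a [searchConfig()].
#' @return An \linkS4class{ImplantationPlan}; its `feasible` slot reports
#'   whether the achieved separation in fact exceeds d_traj.
#' @export
fallbackMaxSeparation <- function(candidateLists, cfg = searchConfig()) {
  N <- length(candidateLists)
  pools <- lapply(candidateLists, function(d)
    head(d, 50L))
  idx <- rep(1L, N)
  objective <- function(ix) {
    D <- .pairwiseDistances(pools, ix)
    minD <- if (N > 1) min(D[upper.tri(D)]) else Inf
    meanS <- mean(vapply(seq_len(N), function(n) pools[[n]]$S[ix[n]],
                         numeric(1)))
    c(minD, meanS)
  }
  cur <- objective(idx)
  improved <- TRUE
  iter <- 0L
  while (improved && iter < 100L) {
    improved <- FALSE
    iter <- iter + 1L
    for (n in seq_len(N)) {
      for (i in seq_len(nrow(pools[[n]]))) {
        if (i == idx[n]) next
        trial <- idx
        trial[n] <- i
        obj <- objective(trial)
        if (obj[1] > cur[1] + 1e-12 ||
            (abs(obj[1] - cur[1]) <= 1e-12 && obj[2] < cur[2] - 1e-12)) {
          idx <- trial
          cur <- obj
          improved <- TRUE
        }
      }
    }
  }
  plan <- .buildPlan(pools, idx, cfg,
                     searchInfo = list(fallback = TRUE, sweeps = iter))
  plan
}

#' Write an implantation plan to JSON and CSV
#'
#' JSON carries per-electrode target/entry world coordinates (3 decimal
#' places), R, G, S, entry angle, relaxation level, and the full pairwise
#' distance matrix; the CSV is the flat trajectory table.
#'
#' @param plan an \linkS4class{ImplantationPlan}.
#' @param jsonPath,csvPath output paths (NULL to skip either).
#' @param meta optional named list merged into the JSON (seed, config, ...).
#' @return invisible list of written paths.
#' @export
writePlan <- function(plan, jsonPath = NULL, csvPath = NULL, meta = list()) {
  tr <- plan@trajectories
  num <- vapply(tr, is.numeric, logical(1))
  tr[num] <- lapply(tr[num], round, 3)
  if (!is.null(csvPath)) write.csv(tr, csvPath, row.names = FALSE)
  if (!is.null(jsonPath)) {
    obj <- c(meta, list(
      feasible = plan@feasible,
      S_total = round(plan@STotal, 6),
      min_pairwise_distance_mm = round(plan@minPairwiseDistance, 3),
      electrodes = tr,
      pairwise_distances_mm = round(plan@pairwiseDistances, 3)))
    jsonlite::write_json(obj, jsonPath, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", pretty = TRUE)
  }
  invisible(list(json = jsonPath, csv = csvPath))
}
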