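#' Hard-constraint configuration with relaxation schedule
#'
#' The four hard constraints a trajectory must satisfy before scoring:
#' maximum length d_len, maximum angle to the skull normal d_ang, traversal
#' of the superficial ROI when one is specified, and no intersection with
#' arteries, veins, or sulci. When no trajectory survives, d_len and d_ang
#' are relaxed in lockstep: +10 mm per level up to 110 mm and +10 degrees
#' per level up to 45 degrees.
#'
#' @param dLen maximum trajectory length, mm (default 80).
#' @param dAng maximum angle to the skull surface normal, degrees (15).
#' @param dSafe minimum safe vessel distance, mm (3).
#' @param dRisk vessel distance beyond which risk is zero, mm (10).
#' @param relaxLenStep,relaxLenCap relaxation step and cap for dLen (10, 110).
#' @param relaxAngStep,relaxAngCap relaxation step and cap for dAng (10, 45).
#' @return list of class "hardConstraintConfig".
#' @export
hardConstraintConfig <- function(dLen = 80, dAng = 15, dSafe = 3, dRisk = 10,
                                 relaxLenStep = 10, relaxLenCap = 110,
                                 relaxAngStep = 10, relaxAngCap = 45) {
  stopifnot(dSafe < dRisk, relaxLenCap >= dLen, relaxAngCap >= dAng)
  structure(list(dLen = dLen, dAng = dAng, dSafe = dSafe, dRisk = dRisk,
                 relaxLenStep = relaxLenStep, relaxLenCap = relaxLenCap,
                 relaxAngStep = relaxAngStep, relaxAngCap = relaxAngCap),
            class = "hardConstraintConfig")
}

#' Depth-electrode contact model
#'
#' Contacts start at the target point and step toward the entry; each
#' contact is assessed at its centre and both ends (centre +/- radius along
#' the trajectory), so per-contact grey-matter capture is 0, 1/3, 2/3 or 1.
#'
#' @param QContacts number of contacts (default 10).
#' @param contactSpacing centre-to-centre spacing, mm (10).
#' @param contactRadius contact half-length p_r, mm (1.2).
#' @return list of class "electrodeModel".
#' @export
electrodeModel <- function(QContacts = 10L, contactSpacing = 10,
                           contactRadius = 1.2) {
  structure(list(QContacts = as.integer(QContacts),
                 contactSpacing = contactSpacing,
                 contactRadius = contactRadius),
            class = "electrodeModel")
}

#' Relax the hard constraints to a given level
#'
#' d_len and d_ang are loosened in lockstep: level L gives
#' min(dLen + L * 10 mm, 110 mm) and min(dAng + L * 10 deg, 45 deg); both
#' saturate at their caps.
#'
#' @param cfg a [hardConstraintConfig()].
#' @param level non-negative integer relaxation level.
#' @return the relaxed configuration.
#' @export
relaxConstraints <- function(cfg, level) {
  stopifnot(level >= 0)
  cfg$dLen <- min(cfg$dLen + cfg$relaxLenStep * level, cfg$relaxLenCap)
  cfg$dAng <- min(cfg$dAng + cfg$relaxAngStep * level, cfg$relaxAngCap)
  cfg
}

.maxRelaxLevel <- function(cfg) {
  max(ceiling((cfg$relaxLenCap - cfg$dLen) / cfg$relaxLenStep),
      ceiling((cfg$relaxAngCap - cfg$dAng) / cfg$relaxAngStep))
}

#' Entry points from the skull surface
#'
#' Every skull-mesh vertex is a potential entry, carrying its outward
#' vertex normal for the drilling-angle constraint.
#'
#' @param skull a \linkS4class{SurfaceMesh}.
#' @return list with `points` (P x 3) and `normals` (P x 3).
#' @export
enumerateEntryPoints <- function(skull) {
  if (nrow(skull@vertices) == 0) stop("empty mesh")
  list(points = skull@vertices, normals = skull@vertexNormals)
}

#' Check the hard constraints for one trajectory
#'
#' Fails on the first violated criterion, in order: (1) length > dLen;
#' (2) angle between the trajectory and the skull normal > dAng; (3) a
#' superficial ROI is specified and no sample point lies inside it; (4) a
#' sample point lies inside a critical structure (arteries, veins, or
#' sulci).
#'
#' @param target,entry world-mm endpoints.
#' @param entryNormal outward unit skull normal at the entry.
#' @param cfg a [hardConstraintConfig()] (possibly relaxed).
#' @param criticalMask logical array: arteries | veins | sulci.
#' @param grid geometry carrier for the masks.
#' @param superficialMask optional logical array of the superficial ROI.
#' @param step sampling step along the trajectory, mm.
#' @return list(pass = logical, reason = "" or one of "length", "angle",
#'   "superficial", "critical").
#' @export
checkHardConstraints <- function(target, entry, entryNormal, cfg,
                                 criticalMask, grid,
                                 superficialMask = NULL, step = 1) {
  dirv <- as.numeric(entry) - as.numeric(target)
  len <- sqrt(sum(dirv^2))
  if (len > cfg$dLen) return(list(pass = FALSE, reason = "length"))
  ang <- entryAngle(target, entry, entryNormal)
  if (ang > cfg$dAng) return(list(pass = FALSE, reason = "angle"))
  pts <- sampleSegment(target, entry, step)
  affine <- fieldAffine(grid)
  if (!is.null(superficialMask) &&
      !any(.sampleMask(superficialMask, affine, pts)))
    return(list(pass = FALSE, reason = "superficial"))
  if (any(.sampleMask(criticalMask, affine, pts)))
    return(list(pass = FALSE, reason = "critical"))
  list(pass = TRUE, reason = "")
}

#' Angle between a trajectory and the skull normal
#'
#' arccos of the absolute dot product between the unit trajectory direction
#' and the vertex normal, in degrees.
#'
#' @param target,entry world-mm endpoints.
#' @param normal outward unit normal at the entry vertex.
#' @return angle in degrees, in [0, 90].
#' @export
entryAngle <- function(target, entry, normal) {
  dirv <- as.numeric(entry) - as.numeric(target)
  dirv <- dirv / sqrt(sum(dirv^2))
  acos(pmin(1, abs(sum(dirv * as.numeric(normal))))) * 180 / pi
}

#' Cumulative vessel-risk score of a trajectory
#'
#' Mean over points sampled along the trajectory of the clamped linear ramp
#' clamp((dRisk - d(x)) / (dRisk - dSafe), 0, 1), where d(x) is the raw
#' vessel distance in mm, interpolated trilinearly. Segments everywhere
#' closer than dSafe score exactly 1; everywhere farther than dRisk score
#' exactly 0.
#'
#' The unclamped integrand printed alongside the model,
#' (dRisk - (d(x) - dSafe)) / (dRisk - dSafe), does not attain those two
#' stated boundary values (it gives 10/7 at d = dSafe and 3/7 at d = dRisk
#' with the defaults); it is available via `form = "printed"` for
#' comparison, but the clamped form is the one used throughout.
#'
#' @param target,entry world-mm endpoints.
#' @param rawVesselDistance ScalarField of unnormalized vessel distance (mm).
#' @param cfg a [hardConstraintConfig()] supplying dSafe and dRisk.
#' @param step sampling step, mm (default 1).
#' @param form "clamped" (default) or "printed".
#' @return risk R in [0, 1] ("clamped") or unclamped mean ("printed").
#' @export
riskScore <- function(target, entry, rawVesselDistance, cfg = hardConstraintConfig(),
                      step = 1, form = c("clamped", "printed")) {
  form <- match.arg(form)
  pts <- sampleSegment(target, entry, step)
  d <- sampleField(rawVesselDistance, pts)
  if (form == "clamped") {
    mean(pmin(pmax((cfg$dRisk - d) / (cfg$dRisk - cfg$dSafe), 0), 1))
  } else {
    mean((cfg$dRisk - (d - cfg$dSafe)) / (cfg$dRisk - cfg$dSafe))
  }
}

#' Grey-matter capture ratio of a trajectory
#'
#' Contacts sit at 0, 10, ..., 10*(Q-1) mm from the target along the
#' trajectory direction; each is assessed at its centre and both ends
#' (+/- the contact radius along the same direction) by the Heaviside step
#' of the signed GM distance (H(0) = 1: the surface counts as inside).
#' Contacts beyond the entry keep their nominal geometric positions and
#' simply score 0 outside the head.
#'
#' @param target,entry world-mm endpoints.
#' @param gmSigned signed GM distance field ([signedGmDistance()]).
#' @param model an [electrodeModel()].
#' @return G in [0, 1], an integer multiple of 1/(3*Q).
#' @export
gmRatio <- function(target, entry, gmSigned, model = electrodeModel()) {
  dirv <- as.numeric(entry) - as.numeric(target)
  dirv <- dirv / sqrt(sum(dirv^2))
  q <- (seq_len(model$QContacts) - 1) * model$contactSpacing
  off <- as.vector(outer(c(-model$contactRadius, 0, model$contactRadius),
                         q, "+"))
  pts <- matrix(as.numeric(target), length(off), 3, byrow = TRUE) +
    outer(off, dirv)
  h <- sampleField(gmSigned, pts) >= 0
  sum(h) / (3 * model$QContacts)
}

#' Score all (target, entry) pairs of one electrode
#'
#' Cartesian product of the electrode's candidate targets and the skull
#' entry points, filtered by the hard constraints at relaxation level 0;
#' if nothing survives, the level is raised until either trajectories
#' appear or both relaxation caps saturate (then an error of class
#' "seegplan_no_trajectory" is thrown). Survivors receive the weighted
#' score S = 10 * R + G and are returned ascending in S, ties broken by
#' lower R, then target rank, then entry index.
#'
#' @param candidates a \linkS4class{CandidateTargetSet}.
#' @param entries entry set from [enumerateEntryPoints()].
#' @param rawVesselDistance raw vessel distance field (mm).
#' @param gmSigned signed GM distance field.
#' @param criticalMask logical array: arteries | veins | sulci.
#' @param grid geometry carrier for the masks.
#' @param cfg a [hardConstraintConfig()].
#' @param superficialMask optional logical array of the superficial ROI.
#' @param model an [electrodeModel()].
#' @param step sampling step, mm.
#' @return data.frame sorted ascending by S with columns electrode,
#'   target_rank, entry_index, tx, ty, tz, ex, ey, ez, length_mm,
#'   angle_deg, R, G, S, relax_level.
#' @export
scoreTrajectories <- function(candidates, entries, rawVesselDistance,
                              gmSigned, criticalMask, grid,
                              cfg = hardConstraintConfig(),
                              superficialMask = NULL,
                              model = electrodeModel(), step = 1) {
  stopifnot(nrow(candidates@targets) >= 1)
  ep <- entries$points
  en <- entries$normals
  P <- nrow(ep)
  affine <- fieldAffine(grid)
  maxLevel <- .maxRelaxLevel(cfg)
  for (level in 0:maxLevel) {
    cfgL <- relaxConstraints(cfg, level)
    rows <- list()
    for (ti in seq_len(nrow(candidates@targets))) {
      tgt <- candidates@targets[ti, ]
      dv <- ep - matrix(tgt, P, 3, byrow = TRUE)
      len <- sqrt(rowSums(dv^2))
      u <- dv / len
      ang <- acos(pmin(1, abs(rowSums(u * en)))) * 180 / pi
      ok <- len <= cfgL$dLen & ang <= cfgL$dAng & len > 0
      for (j in which(ok)) {
        pts <- sampleSegment(tgt, ep[j, ], step)
        if (!is.null(superficialMask) &&
            !any(.sampleMask(superficialMask, affine, pts))) next
        if (any(.sampleMask(criticalMask, affine, pts))) next
        d <- sampleField(rawVesselDistance, pts)
        R <- mean(pmin(pmax((cfgL$dRisk - d) / (cfgL$dRisk - cfgL$dSafe), 0), 1))
        G <- gmRatio(tgt, ep[j, ], gmSigned, model)
        rows[[length(rows) + 1L]] <- data.frame(
          electrode = candidates@electrodeId, target_rank = ti,
          entry_index = j, tx = tgt[1], ty = tgt[2], tz = tgt[3],
          ex = ep[j, 1], ey = ep[j, 2], ez = ep[j, 3],
          length_mm = len[j], angle_deg = ang[j],
          R = R, G = G, S = 10 * R + G, relax_level = level)
      }
    }
    if (length(rows)) {
      out <- do.call(rbind, rows)
      out <- out[order(out$S, out$R, out$target_rank, out$entry_index), ]
      rownames(out) <- NULL
      return(out)
    }
  }
  stop(errorCondition(
    paste0("no feasible trajectory for electrode '", candidates@electrodeId,
           "' after maximal relaxation"),
    class = c("seegplan_no_trajectory", "error")))
}
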