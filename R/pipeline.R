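#' Full run configuration
#'
#' All planner parameters with their clinical-consensus defaults: M = 10
#' candidate targets, risk-map weights wSp = 0.25 / wCri = 0.75, length
#' limit 80 mm, angle limit 15 degrees, safe / no-risk vessel distances
#' 3 / 10 mm, inter-electrode separation 10 mm, plus the sampling step,
#' diversity radius, search budget and seed.
#'
#' @param M candidate targets per electrode.
#' @param wSp,wCri target risk-map weights.
#' @param dLen,dAng,dSafe,dRisk hard-constraint parameters
#'   (see [hardConstraintConfig()]).
#' @param dTraj minimum pairwise trajectory separation, mm.
#' @param step trajectory sampling step, mm.
#' @param diversityEpsilon diversity-pruning radius, mm.
#' @param maxNodes plan-search node budget.
#' @param seed global seed (clustering init and any sampling).
#' @param paths named list of input paths (parcellation, gm, arteries,
#'   veins, sulci, skull, strategy) and output directory `out` for
#'   file-based runs.
#' @return list of class "runConfig".
#' @export
runConfig <- function(M = 10L, wSp = 0.25, wCri = 0.75,
                      dLen = 80, dAng = 15, dSafe = 3, dRisk = 10,
                      dTraj = 10, step = 1, diversityEpsilon = 0.5,
                      maxNodes = 1e6, seed = 1L, paths = list()) {
  structure(list(M = as.integer(M), wSp = wSp, wCri = wCri,
                 dLen = dLen, dAng = dAng, dSafe = dSafe, dRisk = dRisk,
                 dTraj = dTraj, step = step,
                 diversityEpsilon = diversityEpsilon,
                 maxNodes = maxNodes, seed = as.integer(seed),
                 paths = paths),
            class = "runConfig")
}

#' Read a run configuration from YAML
#'
#' Unspecified keys keep the [runConfig()] defaults.
#' @param path YAML file.
#' @return list of class "runConfig".
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path))
    stop(errorCondition(paste("missing input file:", path),
                        class = c("seegplan_missing_input", "error")))
  raw <- yaml::read_yaml(path)
  cfg <- runConfig()
  for (k in names(raw)) cfg[[k]] <- raw[[k]]
  cfg$M <- as.integer(cfg$M)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' Plan an implantation from in-memory inputs
#'
#' Runs the three pipeline stages — candidate target selection, trajectory
#' risk scoring, implantation plan search — on a parcellation, masks,
#' skull mesh and strategy already in memory (e.g. a generated phantom).
#'
#' @param parcellation \linkS4class{LabelVolume} with ROI labels.
#' @param masks named list of logical arrays: gm, arteries, veins, sulci.
#' @param skull \linkS4class{SurfaceMesh}.
#' @param strategy strategy data.frame ([readStrategy()]).
#' @param config a [runConfig()].
#' @return list with `plan` (\linkS4class{ImplantationPlan}), `candidates`
#'   (per-electrode scored data.frames), `targets` (per-electrode
#'   CandidateTargetSet), `timing` (seconds per stage), `failures`
#'   (named list of per-electrode error messages, empty on full success).
#' @export
planImplantation <- function(parcellation, masks, skull, strategy,
                             config = runConfig()) {
  criticalVessels <- masks$arteries | masks$veins
  criticalAll <- criticalVessels | masks$sulci

  t0 <- proc.time()[["elapsed"]]
  rawVessel <- distanceField(criticalVessels, parcellation)
  criticalField <- normalizeField(rawVessel)
  needSkullDist <- any(strategy$prior == "medial_surface")
  skullDistance <- if (needSkullDist) distanceField(skull, parcellation)
                   else NULL
  targets <- candidateTargets(parcellation, criticalVessels, skull, strategy,
                              M = config$M, wSp = config$wSp,
                              wCri = config$wCri, seed = config$seed,
                              criticalField = criticalField,
                              skullDistance = skullDistance)
  t1 <- proc.time()[["elapsed"]]

  gmSigned <- signedGmDistance(masks$gm, parcellation)
  entries <- enumerateEntryPoints(skull)
  hcfg <- hardConstraintConfig(dLen = config$dLen, dAng = config$dAng,
                               dSafe = config$dSafe, dRisk = config$dRisk)
  labs <- parcellation@labels
  candidates <- list()
  failures <- list()
  for (i in seq_len(nrow(strategy))) {
    id <- strategy$id[i]
    sup <- strategy$superficial_roi_label[i]
    supMask <- if (!is.na(sup)) labs == sup else NULL
    res <- tryCatch(
      scoreTrajectories(targets[[id]], entries, rawVessel, gmSigned,
                        criticalAll, parcellation, cfg = hcfg,
                        superficialMask = supMask, step = config$step),
      seegplan_no_trajectory = function(e) e)
    if (inherits(res, "error")) failures[[id]] <- conditionMessage(res)
    else candidates[[id]] <- res
  }
  t2 <- proc.time()[["elapsed"]]

  plan <- NULL
  if (length(failures) == 0) {
    scfg <- searchConfig(dTraj = config$dTraj,
                         diversityEpsilon = config$diversityEpsilon,
                         maxNodes = config$maxNodes)
    plan <- solvePlan(candidates, scfg)
  }
  t3 <- proc.time()[["elapsed"]]

  list(plan = plan, candidates = candidates, targets = targets,
       timing = c(target_selection = t1 - t0,
                  trajectory_scoring = t2 - t1,
                  plan_computation = t3 - t2),
       failures = failures)
}

#' Run the planner end-to-end from files
#'
#' Loads the inputs named in the config's `paths`, runs the three stages,
#' and writes the plan (JSON + CSV), per-electrode candidate tables (CSV),
#' the resolved configuration, a timing report, and optionally the target
#' risk maps as NIfTI for visual QC. Electrode failures do not abort the
#' run: all other electrodes are still scored and reported, and the status
#' reflects the failure.
#'
#' @param config a [runConfig()], or the path of a YAML config file.
#' @param qcMaps write per-ROI target risk maps as NIfTI (default FALSE).
#' @return invisible list with `status` (0 on success, 3 unknown label,
#'   4 no feasible trajectory for some electrode, 2 missing input),
#'   `plan`, `timing`, `outputs` (paths written).
#' @export
runPlan <- function(config, qcMaps = FALSE) {
  if (is.character(config)) config <- readRunConfig(config)
  p <- config$paths
  outDir <- if (is.null(p$out)) "." else p$out
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  loaded <- tryCatch({
    parcellation <- readVolume(p$parcellation, as = "labels")
    masks <- lapply(p[c("gm", "arteries", "veins", "sulci")], function(path) {
      v <- readVolume(path)      # evaluated eagerly: keeps condition classes
      fieldValues(v) > 0.5
    })
    skull <- readMesh(p$skull)
    strategy <- readStrategy(p$strategy)
    list(parcellation = parcellation, masks = masks, skull = skull,
         strategy = strategy)
  }, seegplan_missing_input = function(e) e)
  if (inherits(loaded, "error")) {
    message(conditionMessage(loaded))
    return(invisible(list(status = 2L, plan = NULL)))
  }

  res <- tryCatch(
    planImplantation(loaded$parcellation, loaded$masks, loaded$skull,
                     loaded$strategy, config),
    seegplan_unknown_label = function(e) e)
  if (inherits(res, "error")) {
    message(conditionMessage(res))
    return(invisible(list(status = 3L, plan = NULL)))
  }

  outputs <- list()
  for (id in names(res$candidates)) {
    f <- file.path(outDir, paste0("candidates_", id, ".csv"))
    write.csv(res$candidates[[id]], f, row.names = FALSE)
    outputs[[paste0("candidates_", id)]] <- f
  }
  if (!is.null(res$plan)) {
    outputs$plan_json <- file.path(outDir, "plan.json")
    outputs$plan_csv <- file.path(outDir, "plan.csv")
    writePlan(res$plan, outputs$plan_json, outputs$plan_csv,
              meta = list(seed = config$seed))
  }
  cfgOut <- config[setdiff(names(config), "paths")]
  outputs$config <- file.path(outDir, "resolved_config.yaml")
  yaml::write_yaml(cfgOut, outputs$config)
  outputs$timing <- file.path(outDir, "timing.json")
  jsonlite::write_json(as.list(round(res$timing, 3)), outputs$timing,
                       auto_unbox = TRUE)
  if (qcMaps) {
    maps <- attr(res$targets, "riskMaps")
    for (lb in names(maps)) {
      f <- file.path(outDir, paste0("target_risk_", lb, ".nii.gz"))
      writeVolume(maps[[lb]]@field, f)
      outputs[[paste0("risk_", lb)]] <- f
    }
  }
  for (id in names(res$failures))
    message("electrode ", id, ": ", res$failures[[id]])
  status <- if (length(res$failures)) 4L else 0L
  invisible(list(status = status, plan = res$plan, timing = res$timing,
                 outputs = outputs, failures = res$failures))
}
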