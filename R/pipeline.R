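#' Default pipeline configuration
#'
#' Study-scale defaults: 23 subjects; the standard encoding/test design
#' (2 houses x 10 shown videos x 10 objects, 52 new items, 4 runs of 63
#' trials); published behavioral rates; 100-voxel ROIs with an integrative
#' left CA1, a separative left CA23DG, and null regimes everywhere else
#' (right hemisphere, ERC, SUB); direct pattern-to-beta mode (the BOLD +
#' LSS-GLM estimation stage can be switched on via \code{glm$useBold}).
#'
#' @param nSubjects number of simulated subjects.
#' @return a named list understood by \code{\link{runPipeline}}.
#' @export
defaultPipelineConfig <- function(nSubjects = 23) {
  mk <- function(name, hemi, regime)
    ROISpec(name = name, hemisphere = hemi, nVoxels = 100, regime = regime)
  list(
    nSubjects = nSubjects,
    design = list(nListsPerHouse = 12, nVideosShown = 10,
                  nObjectsPerVideo = 10, nNew = 52, nRuns = 4),
    behavior = BehaviorParams(),
    pattern = PatternParams(),
    rois = list(
      mk("CA1", "left", "integrative"),
      mk("CA23DG", "left", "separative"),
      mk("CA1", "right", "null"),
      mk("CA23DG", "right", "null"),
      mk("ERC", "left", "null"),
      mk("ERC", "right", "null"),
      mk("SUB", "left", "null"),
      mk("SUB", "right", "null")),
    glm = list(useBold = FALSE, tr = 2.01, trialDuration = 3,
               itiRange = c(2, 8), hrf = HRFParams(), noiseSd = 0.5,
               driftAmplitude = 1, zThreshold = 0.75,
               summaryStat = "mean_beta"),
    similarity = list(fisherZ = FALSE, scaleVoxels = FALSE),
    model = list(alpha = 0.05),
    controls = list(run = TRUE, nReps = 100, nDrop = 5,
                    criteria = c("abs_magnitude", "trial_sd",
                                 "condition_pair_msd"))
  )
}

#' Validate a pipeline configuration
#'
#' Checks structure and parameter validity before any stage runs.
#'
#' @param config a configuration list (see
#'   \code{\link{defaultPipelineConfig}}).
#' @return \code{config}, invisibly, or an error naming the offending field.
#' @export
validatePipelineConfig <- function(config) {
  need <- c("nSubjects", "design", "behavior", "pattern", "rois", "glm",
            "similarity", "model", "controls")
  miss <- setdiff(need, names(config))
  if (length(miss))
    stopf("config misses field(s): %s", paste(miss, collapse = ", "))
  if (config$nSubjects < 1) stopf("nSubjects must be >= 1")
  validObject(config$behavior)
  validObject(config$pattern)
  validObject(config$glm$hrf)
  keys <- character()
  for (roi in config$rois) {
    validObject(roi)
    keys <- c(keys, roiKey(roi))
  }
  if (anyDuplicated(keys))
    stopf("duplicate ROI x hemisphere entries: %s",
          paste(keys[duplicated(keys)], collapse = ", "))
  with(config$design, {
    if ((2 * nVideosShown * nObjectsPerVideo + nNew) %% nRuns != 0)
      stopf("design trial total not divisible by nRuns")
  })
  invisible(config)
}

## One subject: design -> behavior -> per-ROI patterns (-> optional BOLD +
## LSS GLM) -> outlier exclusion -> similarity -> labeled between-run pairs.
#' Simulate and analyze a single subject
#'
#' @param subject subject identifier.
#' @param config pipeline configuration.
#' @param seed RNG seed for this subject (stage substreams derived from it).
#' @param rois optional subset of ROI specs (defaults to
#'   \code{config$rois}).
#' @return list with \code{design}, \code{trials}, \code{betas} (named list
#'   of \linkS4class{BetaMatrix} per ROI key) and \code{pairs}.
#' @export
simulateSubject <- function(subject, config = defaultPipelineConfig(),
                            seed = 1, rois = NULL) {
  if (is.null(rois)) rois <- config$rois
  d <- do.call(generateDesign,
               c(config$design, list(seed = .deriveSeed(seed, 1))))
  trials <- simulateBehavior(d$trials, config$behavior,
                             seed = .deriveSeed(seed, 2))
  betas <- list()
  pairs <- list()
  for (k in seq_along(rois)) {
    roi <- rois[[k]]
    b <- simulatePatterns(trials, roi, config$pattern,
                          seed = .deriveSeed(seed, 10 + k))
    if (isTRUE(config$glm$useBold))
      b <- .boldEstimationStage(trials, b, roi, config$glm,
                                seed = .deriveSeed(seed, 50 + k))
    b <- excludeOutlierTrials(b, config$glm$zThreshold,
                              config$glm$summaryStat)
    sim <- correlationMatrix(b, scaleVoxels = config$similarity$scaleVoxels)
    p <- suppressWarnings(
      extractPairs(sim, trials, subject = subject,
                   fisherZ = config$similarity$fisherZ))
    betas[[roiKey(roi)]] <- b
    pairs[[roiKey(roi)]] <- p
  }
  list(design = d$design, trials = trials, betas = betas,
       pairs = do.call(rbind, c(pairs, list(make.row.names = FALSE))))
}

## BOLD + LSS estimation stage: forward-model the true betas to per-run
## time series, then re-estimate trial betas with the single-trial GLM.
.boldEstimationStage <- function(trials, trueBetas, roi, glmCfg, seed) {
  runs <- simulateBold(trials, trueBetas, tr = glmCfg$tr,
                       trialDuration = glmCfg$trialDuration,
                       itiRange = glmCfg$itiRange, hrf = glmCfg$hrf,
                       noiseSd = glmCfg$noiseSd,
                       driftAmplitude = glmCfg$driftAmplitude, seed = seed)
  est <- matrix(NA_real_, nrow(betaValues(trueBetas)), nrow(trials),
                dimnames = list(rownames(betaValues(trueBetas)),
                                trials$trial_id))
  for (r in names(runs)) {
    idx <- which(trials$run == as.integer(r))
    bm <- estimateSingleTrialBetas(runs[[r]]$bold, runs[[r]]$onsets,
                                   glmCfg$tr, trials[idx, , drop = FALSE],
                                   roi = roi, hrf = glmCfg$hrf)
    est[, trials$trial_id[idx]] <- betaValues(bm)
  }
  BetaMatrix(est, trials, roi = roi)
}

#' Run the full analysis pipeline on simulated subjects
#'
#' Executes design and behavior simulation, pattern generation (optionally
#' through the BOLD forward model and LSS GLM), outlier exclusion,
#' between-run pair extraction, the omnibus ROI x condition x hemisphere
#' interaction test, per-ROI episodic and spatial contrasts, and — when
#' enabled — the three robustness controls (trial-count-matched
#' subsampling, influential-voxel dropping, RT covariate model).
#'
#' @param config pipeline configuration
#'   (\code{\link{defaultPipelineConfig}}).
#' @param seed master seed; per-subject and per-stage substreams are
#'   derived deterministically from it.
#' @param verbose print stage progress.
#' @return a result bundle: list with \code{config}, \code{seed},
#'   \code{subjects}, \code{pairs}, \code{behavior}, \code{omnibus},
#'   \code{contrasts}, \code{conditionMeans}, \code{controls},
#'   \code{manifest}.
#' @export
runPipeline <- function(config = defaultPipelineConfig(), seed = 1,
                        verbose = FALSE) {
  validatePipelineConfig(config)
  say <- function(...) if (verbose) message(sprintf(...))
  subjects <- sprintf("s%02d", seq_len(config$nSubjects))

  say("simulating %d subjects", length(subjects))
  subjectData <- lapply(seq_along(subjects), function(i) {
    simulateSubject(subjects[i], config, seed = .deriveSeed(seed, 1000 + i))
  })
  names(subjectData) <- subjects
  pairs <- do.call(rbind, c(lapply(subjectData, `[[`, "pairs"),
                            list(make.row.names = FALSE)))

  behavior <- .behavioralSummary(subjectData)

  rois <- vapply(config$rois, function(r) r@name, character(1))
  hemis <- vapply(config$rois, function(r) r@hemisphere, character(1))

  say("fitting omnibus interaction model")
  omnibus <- if (all(c("CA1", "CA23DG") %in% rois))
    tryCatch(omnibusInteractionTest(pairs), error = function(e) e$message)
  else NULL

  say("fitting per-ROI contrasts")
  contrasts <- list()
  for (k in seq_along(config$rois)) {
    for (ctr in c("episodic", "spatial")) {
      key <- paste(rois[k], hemis[k], ctr, sep = "_")
      contrasts[[key]] <- tryCatch(
        conditionContrast(pairs, rois[k], hemis[k], ctr),
        error = function(e) e$message)
    }
  }

  conditionMeans <- stats::aggregate(
    similarity ~ roi + hemisphere + condition, data = pairs, FUN = mean)

  controls <- NULL
  if (isTRUE(config$controls$run)) {
    say("running control analyses")
    controls <- .pipelineControls(pairs, subjectData, config, seed)
  }

  bundle <- list(config = config, seed = seed, subjects = subjects,
                 subjectData = subjectData, pairs = pairs,
                 behavior = behavior, omnibus = omnibus,
                 contrasts = contrasts, conditionMeans = conditionMeans,
                 controls = controls)
  bundle$manifest <- .makeManifest(bundle)
  bundle
}

.behavioralSummary <- function(subjectData) {
  per <- lapply(subjectData, function(sd) {
    tr <- sd$trials
    old <- tr[tr$is_old, ]
    new <- tr[!tr$is_old, ]
    byHouse <- vapply(sort(unique(old$house)), function(h)
      mean(old$response[old$house == h] == "remember"), numeric(1))
    c(rememberHit = mean(old$response == "remember"),
      familiarHit = mean(old$response == "familiar"),
      correctRejection = mean(new$response == "new"),
      sourceHit = mean(old$source_correct),
      nEligible = nrow(eligibleTrials(tr)),
      rememberHouse1 = unname(byHouse[1L]),
      rememberHouse2 = unname(byHouse[2L]))
  })
  per <- do.call(rbind, per)
  out <- list(perSubject = per, groupMeans = colMeans(per))
  if (nrow(per) >= 3L)
    out$rememberByHouse <- pairedTDunlap(per[, "rememberHouse1"],
                                         per[, "rememberHouse2"])
  out
}

.pipelineControls <- function(pairs, subjectData, config, seed) {
  alpha <- config$model$alpha
  out <- list()
  roiNames <- vapply(config$rois, function(r) r@name, character(1))
  core <- pairs[pairs$roi %in% c("CA1", "CA23DG"), , drop = FALSE]
  haveCore <- all(c("CA1", "CA23DG") %in% roiNames) &&
    all(c("left", "right") %in% core$hemisphere)

  if (haveCore)
    out$subsample <- tryCatch(
      matchedSubsampleTest(core, nReps = config$controls$nReps,
                           alpha = alpha, seed = .deriveSeed(seed, 7001)),
      error = function(e) e$message)

  dropRois <- Filter(function(r)
    r@hemisphere == "left" && r@name %in% c("CA1", "CA23DG"), config$rois)
  vd <- list()
  for (roi in dropRois) {
    for (crit in config$controls$criteria) {
      key <- paste(roiKey(roi), crit, sep = "_")
      vd[[key]] <- tryCatch(
        .multiSubjectVoxelDrop(subjectData, roi, crit,
                               config$controls$nDrop, config, alpha),
        error = function(e) e$message)
    }
  }
  out$voxelDrop <- vd

  rt <- list()
  for (roi in dropRois) {
    rt[[roiKey(roi)]] <- tryCatch(
      rtCovariateModel(pairs, roi@name, roi@hemisphere, "episodic"),
      error = function(e) e$message)
  }
  out$rtControl <- rt
  out
}

## Influential-voxel control across subjects: voxels are ranked and dropped
## within each subject's own beta matrix, pairs are rebuilt, and the pooled
## episodic contrast is refitted on the pruned data.
.multiSubjectVoxelDrop <- function(subjectData, roi, criterion, nDrop,
                                   config, alpha = 0.05) {
  key <- roiKey(roi)
  rebuilt <- lapply(names(subjectData), function(s) {
    sd <- subjectData[[s]]
    b <- sd$betas[[key]]
    subPairs <- sd$pairs[sd$pairs$roi == roi@name &
                           sd$pairs$hemisphere == roi@hemisphere, ,
                         drop = FALSE]
    drop <- rankInfluentialVoxels(b, criterion, subPairs)[seq_len(nDrop)]
    pruned <- if (nDrop > 0) b[-drop, ] else b
    sim <- correlationMatrix(pruned,
                             scaleVoxels = config$similarity$scaleVoxels)
    suppressWarnings(extractPairs(sim, sd$trials, subject = s,
                                  fisherZ = config$similarity$fisherZ))
  })
  prunedPairs <- do.call(rbind, c(rebuilt, list(make.row.names = FALSE)))
  basePairs <- do.call(rbind, c(lapply(subjectData, `[[`, "pairs"),
                                list(make.row.names = FALSE)))
  baseline <- conditionContrast(basePairs, roi@name, roi@hemisphere,
                                "episodic")
  dropped <- conditionContrast(prunedPairs, roi@name, roi@hemisphere,
                               "episodic")
  ControlResult(
    analysis = "voxel_drop",
    replicates = list(baseline = baseline, dropped = dropped),
    summary = list(
      directionPreserved = identical(baseline$direction, dropped$direction),
      significancePreserved =
        (baseline$lrt@p < alpha) == (dropped$lrt@p < alpha)),
    config = list(criterion = criterion, n_drop = nDrop, roi = key))
}

.makeManifest <- function(bundle) {
  numeric_outputs <- list(
    similarity = round(bundle$pairs$similarity, 12),
    omnibus = if (is(bundle$omnibus, "LRTResult"))
      c(bundle$omnibus@chi2, bundle$omnibus@p) else NULL,
    contrasts = lapply(bundle$contrasts, function(x)
      if (is.list(x)) c(x$lrt@chi2, x$lrt@p, x$direction) else NULL))
  tf <- tempfile(fileext = ".rds")
  on.exit(unlink(tf))
  saveRDS(numeric_outputs, tf)
  resultsHash <- unname(tools::md5sum(tf))
  tf2 <- tempfile(fileext = ".txt")
  on.exit(unlink(tf2), add = TRUE)
  writeLines(deparse(bundle$config[c("nSubjects", "design", "model")]), tf2)
  list(package = "subfieldRSA",
       packageVersion = as.character(utils::packageVersion("subfieldRSA")),
       rVersion = paste(R.version$major, R.version$minor, sep = "."),
       seed = bundle$seed,
       configHash = unname(tools::md5sum(tf2)),
       resultsHash = resultsHash)
}
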