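#' Trial-count-matched subsampling control
#'
#' Within every subject x ROI x hemisphere cell, finds the condition with
#' the fewest trial pairs, samples that many pairs without replacement from
#' every other condition, refits the test of interest (by default the
#' omnibus ROI x condition x hemisphere interaction), and repeats. The
#' summary reports the fraction of replicates significant at \code{alpha}.
#' When all conditions already have equal counts, every replicate uses the
#' full table and the statistic is identical across replicates.
#'
#' @param pairs a pair table.
#' @param nReps number of subsampling replicates.
#' @param alpha significance threshold.
#' @param seed RNG seed.
#' @param refitFn function mapping a pair table to an
#'   \linkS4class{LRTResult}; default \code{\link{omnibusInteractionTest}}.
#' @return a \linkS4class{ControlResult} with per-replicate
#'   \code{(chi2, df, p)} and summary \code{fractionSignificant}.
#' @export
matchedSubsampleTest <- function(pairs, nReps = 1000, alpha = 0.05,
                                 seed = 1, refitFn = omnibusInteractionTest) {
  cellId <- interaction(pairs$subject, pairs$roi, pairs$hemisphere,
                        drop = TRUE)
  cells <- split(seq_len(nrow(pairs)), cellId)
  conds <- sort(unique(pairs$condition))
  empty <- character()
  for (nm in names(cells)) {
    have <- unique(pairs$condition[cells[[nm]]])
    if (length(setdiff(conds, have)))
      empty <- c(empty, sprintf("%s:{%s}", nm,
                                paste(setdiff(conds, have), collapse = ",")))
  }
  if (length(empty))
    stopf("empty subject x condition cell(s): %s",
          paste(empty, collapse = "; "))

  .withSeed(seed, {
    reps <- vector("list", nReps)
    for (k in seq_len(nReps)) {
      take <- unlist(lapply(cells, function(idx) {
        byCond <- split(idx, pairs$condition[idx])
        m <- min(lengths(byCond))
        ## sorted so that m-of-m sampling reproduces the cell verbatim
        unlist(lapply(byCond, function(ii)
          sort(ii[sample.int(length(ii), m)])), use.names = FALSE)
      }), use.names = FALSE)
      res <- refitFn(pairs[take, , drop = FALSE])
      reps[[k]] <- c(chi2 = res@chi2, df = res@df, p = res@p)
    }
    ps <- vapply(reps, `[[`, numeric(1), "p")
    ControlResult(
      analysis = "subsample", replicates = reps,
      summary = list(fractionSignificant = mean(ps < alpha),
                     meanChi2 = mean(vapply(reps, `[[`, numeric(1), "chi2"))),
      config = list(n_reps = nReps, alpha = alpha, seed = seed))
  })
}

#' Rank voxels by influence
#'
#' Deterministic voxel ranking used by the influential-voxel control:
#' \code{abs_magnitude} ranks by mean absolute beta over (included) trials,
#' \code{trial_sd} by the standard deviation of the response across trials,
#' and \code{condition_pair_msd} by the mean squared beta difference over
#' the trial pairs of the two episodic conditions (same-video/same-house
#' and different-video/same-house). Ties break toward the lowest voxel
#' index.
#'
#' @param betas a \linkS4class{BetaMatrix}.
#' @param criterion ranking criterion.
#' @param pairs pair table; required for \code{condition_pair_msd}.
#' @return integer voxel indices, most influential first.
#' @export
rankInfluentialVoxels <- function(betas,
                                  criterion = c("abs_magnitude", "trial_sd",
                                                "condition_pair_msd"),
                                  pairs = NULL) {
  criterion <- match.arg(criterion)
  vals <- betaValues(betas)[, !excludedTrials(betas), drop = FALSE]
  score <- switch(criterion,
    abs_magnitude = rowMeans(abs(vals)),
    trial_sd = apply(vals, 1L, sd),
    condition_pair_msd = {
      if (is.null(pairs))
        stopf("criterion 'condition_pair_msd' needs the pair table")
      ep <- pairs[pairs$condition %in% c("same_video_same_house",
                                         "diff_video_same_house"), ,
                  drop = FALSE]
      if (!nrow(ep)) stopf("no episodic-condition pairs to rank voxels by")
      all <- betaValues(betas)
      i <- match(ep$trial_i, colnames(all))
      j <- match(ep$trial_j, colnames(all))
      if (any(is.na(i)) || any(is.na(j)))
        stopf("pair table references trials absent from the beta matrix")
      rowMeans((all[, i, drop = FALSE] - all[, j, drop = FALSE])^2)
    })
  order(-score, seq_along(score))
}

#' Influential-voxel dropping control
#'
#' Ranks voxels by the chosen criterion, removes the top \code{nDrop}, and
#' re-runs the provided analysis closure (similarity, pair extraction and
#' contrast fitting) on the pruned data, reporting whether the effect's
#' direction and significance are preserved. With \code{nDrop = 0} the
#' result is identical to the uncontrolled analysis.
#'
#' @param betas a \linkS4class{BetaMatrix}.
#' @param recompute function mapping a \code{BetaMatrix} to a
#'   \code{\link{conditionContrast}}-style result (list with \code{lrt} and
#'   \code{direction}).
#' @param criterion see \code{\link{rankInfluentialVoxels}}.
#' @param nDrop number of voxels to drop.
#' @param pairs pair table, required for \code{condition_pair_msd}.
#' @param alpha significance threshold used for the preserved-significance
#'   summary.
#' @return a \linkS4class{ControlResult} with the baseline and pruned
#'   results and summary flags \code{directionPreserved},
#'   \code{significancePreserved}.
#' @export
influentialVoxelDrop <- function(betas, recompute,
                                 criterion = c("abs_magnitude", "trial_sd",
                                               "condition_pair_msd"),
                                 nDrop = 5, pairs = NULL, alpha = 0.05) {
  criterion <- match.arg(criterion)
  if (nDrop >= nrow(betas))
    stopf("nDrop (%d) must be smaller than the voxel count (%d)",
          nDrop, nrow(betas))
  baseline <- recompute(betas)
  if (nDrop > 0) {
    drop <- rankInfluentialVoxels(betas, criterion, pairs)[seq_len(nDrop)]
    pruned <- betas[-drop, ]
  } else {
    drop <- integer()
    pruned <- betas
  }
  dropped <- recompute(pruned)
  ControlResult(
    analysis = "voxel_drop",
    replicates = list(baseline = baseline, dropped = dropped),
    summary = list(
      directionPreserved = identical(baseline$direction, dropped$direction),
      significancePreserved =
        (baseline$lrt@p < alpha) == (dropped$lrt@p < alpha),
      droppedVoxels = drop),
    config = list(criterion = criterion, n_drop = nDrop, alpha = alpha))
}

#' Reaction-time covariate control model
#'
#' Refits the condition contrast with a by-subject random slope of the
#' pair-wise reaction-time difference, so the condition test is performed
#' after absorbing RT-difference effects. If \code{rt_diff} has zero
#' variance the random slope is unidentifiable and the model falls back to
#' the uncontrolled fit with a warning.
#'
#' @param pairs a pair table with finite \code{rt_diff}.
#' @param roi,hemisphere cell to analyze.
#' @param contrast \code{"episodic"} or \code{"spatial"}.
#' @return a \code{\link{conditionContrast}}-style list.
#' @export
rtCovariateModel <- function(pairs, roi, hemisphere,
                             contrast = c("episodic", "spatial")) {
  contrast <- match.arg(contrast)
  if (any(!is.finite(pairs$rt_diff)))
    stopf("rt_diff must be finite")
  sub <- pairs[pairs$roi == roi & pairs$hemisphere == hemisphere, ,
               drop = FALSE]
  if (contrast == "episodic") {
    sub <- sub[sub$condition %in% c("same_video_same_house",
                                    "diff_video_same_house"), , drop = FALSE]
    lev <- c("diff_video_same_house", "same_video_same_house")
  } else {
    sub <- spatialContrastPairs(sub)
    lev <- c("different_house", "same_house")
  }
  for (l in lev)
    if (!any(sub$condition == l)) stopf("empty contrast level '%s'", l)
  if (sd(sub$rt_diff) == 0) {
    warnf("rt_diff has zero variance; falling back to the uncontrolled fit")
    return(conditionContrast(pairs, roi, hemisphere, contrast))
  }
  sub$condition <- factor(sub$condition, levels = lev)
  full <- fitLmm(sub, similarity ~ condition + (1 + rt_diff | subject))
  reduced <- fitLmm(sub, similarity ~ 1 + (1 + rt_diff | subject))
  est <- unname(lme4::fixef(full)[2L])
  list(lrt = likelihoodRatioTest(full, reduced),
       direction = sign(est), estimate = est,
       term = paste0("condition", lev[2L]), n = nrow(sub))
}
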