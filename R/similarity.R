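#' Trial-by-trial Pearson correlation matrix
#'
#' Correlates every pair of non-excluded trial patterns over voxels,
#' spanning all runs, and sets the diagonal to 1. Optionally z-scores each
#' voxel across trials first (\code{scaleVoxels}), or leaves the betas raw
#' (the default).
#'
#' @param betas a \linkS4class{BetaMatrix}; outlier-excluded trials are
#'   dropped.
#' @param scaleVoxels z-score each voxel across trials before correlating.
#' @return a \linkS4class{SimilarityMatrix} over the included trials.
#' @export
correlationMatrix <- function(betas, scaleVoxels = FALSE) {
  vals <- betaValues(betas)
  cd <- SummarizedExperiment::colData(betas)
  keep <- !cd$excluded
  vals <- vals[, keep, drop = FALSE]
  ids <- cd$trial_id[keep]
  if (nrow(vals) < 2L) stopf("need >= 2 voxels to correlate patterns")
  if (ncol(vals) < 2L) stopf("need >= 2 included trials")
  ## constant patterns have zero variance over voxels: correlation undefined
  zeroVar <- colSums(vals != rep(vals[1L, ], each = nrow(vals))) == 0
  if (any(zeroVar))
    stopf("zero voxel variance in trial(s): %s (correlation undefined)",
          paste(ids[zeroVar], collapse = ", "))
  if (scaleVoxels) vals <- t(scale(t(vals)))
  C <- cor(vals)
  diag(C) <- 1
  SimilarityMatrix(values = C, trialIds = as.character(ids),
                   runs = as.integer(cd$run[keep]), roi = roiSpec(betas))
}

#' Label the context condition of a trial pair
#'
#' Exhaustive, mutually exclusive partition of old-old pairs: same video
#' (which implies the same house) -> \code{same_video_same_house};
#' different videos within the same house -> \code{diff_video_same_house};
#' different houses -> \code{diff_video_diff_house}. Vectorized.
#'
#' @param houseI,videoI house/video labels of the first trial.
#' @param houseJ,videoJ house/video labels of the second trial.
#' @return character vector of condition labels.
#' @export
labelPairCondition <- function(houseI, videoI, houseJ, videoJ) {
  if (any(is.na(houseI) | is.na(videoI) | is.na(houseJ) | is.na(videoJ)))
    stopf("new items (missing house/video) cannot be labeled")
  ifelse(videoI == videoJ, "same_video_same_house",
         ifelse(houseI == houseJ, "diff_video_same_house",
                "diff_video_diff_house"))
}

#' Extract condition-labeled between-run trial pairs
#'
#' Emits every unordered pair of trials that (a) come from different runs,
#' (b) are old items with a correct "remember" response and correct house
#' source memory, and (c) survived outlier exclusion (excluded trials never
#' enter the \linkS4class{SimilarityMatrix}). Each pair is labeled with its
#' context condition and the absolute reaction-time difference.
#'
#' @param sim a \linkS4class{SimilarityMatrix}.
#' @param trials the full trial table (for eligibility, labels and RTs).
#' @param subject subject identifier stamped on every row.
#' @param roi,hemisphere ROI name/hemisphere; default from the similarity
#'   matrix's \linkS4class{ROISpec}.
#' @param fisherZ apply the Fisher z transform (atanh) to similarities.
#' @return a pair table (data.frame) with columns \code{subject, roi,
#'   hemisphere, trial_i, trial_j, run_i, run_j, condition, similarity,
#'   rt_diff}; possibly empty, with a warning.
#' @export
extractPairs <- function(sim, trials, subject = "s01", roi = NULL,
                         hemisphere = NULL, fisherZ = FALSE) {
  spec <- sim@roi
  if (is.null(roi)) roi <- if (!is.null(spec)) spec@name else NA_character_
  if (is.null(hemisphere))
    hemisphere <- if (!is.null(spec)) spec@hemisphere else NA_character_

  rows <- trials[match(sim@trialIds, trials$trial_id), , drop = FALSE]
  if (any(is.na(rows$trial_id)))
    stopf("similarity matrix references trials absent from the trial table")
  eligible <- rows$is_old & !is.na(rows$response) &
    rows$response == "remember" & !is.na(rows$source_correct) &
    rows$source_correct

  n <- nrow(rows)
  pr <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  i <- pr[, 1L]; j <- pr[, 2L]
  keep <- eligible[i] & eligible[j] & (rows$run[i] != rows$run[j])
  i <- i[keep]; j <- j[keep]
  if (!length(i)) {
    warnf("no eligible between-run pairs")
    return(data.frame(subject = character(), roi = character(),
                      hemisphere = character(), trial_i = character(),
                      trial_j = character(), run_i = integer(),
                      run_j = integer(), condition = character(),
                      similarity = numeric(), rt_diff = numeric()))
  }
  simv <- sim@values[cbind(i, j)]
  if (fisherZ) simv <- atanh(pmin(pmax(simv, -1 + 1e-12), 1 - 1e-12))
  data.frame(
    subject = subject, roi = roi, hemisphere = hemisphere,
    trial_i = rows$trial_id[i], trial_j = rows$trial_id[j],
    run_i = as.integer(rows$run[i]), run_j = as.integer(rows$run[j]),
    condition = labelPairCondition(rows$house[i], rows$video[i],
                                   rows$house[j], rows$video[j]),
    similarity = simv,
    rt_diff = abs(rows$rt[i] - rows$rt[j]))
}

#' Reduce a pair table to the spatial-context contrast
#'
#' Drops same-video pairs (so any remaining same-house effect is
#' attributable to spatial, not episodic, context) and relabels the
#' conditions to the binary factor \code{same_house} vs
#' \code{different_house}.
#'
#' @param pairs a pair table from \code{\link{extractPairs}}.
#' @return the filtered, relabeled pair table.
#' @export
spatialContrastPairs <- function(pairs) {
  out <- pairs[pairs$condition != "same_video_same_house", , drop = FALSE]
  out$condition <- ifelse(out$condition == "diff_video_same_house",
                          "same_house", "different_house")
  rownames(out) <- NULL
  out
}

#' Write / read a pair table as tab-separated text
#'
#' Lossless round-trip of the pair table produced by
#' \code{\link{extractPairs}}.
#'
#' @param pairs a pair table.
#' @param path file path.
#' @return \code{path} invisibly (write); the pair table (read).
#' @export
writePairTable <- function(pairs, path) {
  utils::write.table(pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writePairTable
#' @export
readPairTable <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
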