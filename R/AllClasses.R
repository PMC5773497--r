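#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

## ---------------------------------------------------------------------------
## Parameter classes
## ---------------------------------------------------------------------------

#' Behavioral response parameters
#'
#' Probabilities governing simulated recognition responses and post-scan
#' spatial source memory, plus a truncated log-normal reaction-time model.
#' Defaults reproduce the published group rates for this paradigm:
#' "remember" hit rate 0.68, "familiar" hit rate 0.25, correct rejection
#' rate 0.90, and an overall spatial source hit rate of about 0.71 once the
#' conditional source rates are mixed over response types.
#'
#' @slot pRememberHit probability an old item receives a correct
#'   "remember" response.
#' @slot pFamiliarHit probability an old item receives a correct
#'   "familiar" response (remainder are misses).
#' @slot pCorrectRejection probability a new item is correctly called "new".
#' @slot pRememberFalseAlarm fraction of false alarms endorsed "remember"
#'   (the rest are "familiar").
#' @slot pSourceGivenRemember probability of a correct house source judgment
#'   given a "remember" response.
#' @slot pSourceGivenFamiliar same, given a "familiar" response.
#' @slot pSourceGivenMiss same, given a miss (chance-level by default).
#' @slot rtMeanlog,rtSdlog log-normal location/scale of reaction times (s).
#' @slot rtMax response window (s); RTs are truncated to (0, rtMax].
#' @export BehaviorParams
#' @exportClass BehaviorParams
BehaviorParams <- setClass(
  "BehaviorParams",
  representation(
    pRememberHit = "numeric",
    pFamiliarHit = "numeric",
    pCorrectRejection = "numeric",
    pRememberFalseAlarm = "numeric",
    pSourceGivenRemember = "numeric",
    pSourceGivenFamiliar = "numeric",
    pSourceGivenMiss = "numeric",
    rtMeanlog = "numeric",
    rtSdlog = "numeric",
    rtMax = "numeric"
  ),
  prototype(
    pRememberHit = 0.68,
    pFamiliarHit = 0.25,
    pCorrectRejection = 0.90,
    pRememberFalseAlarm = 0.30,
    pSourceGivenRemember = 0.79,
    pSourceGivenFamiliar = 0.55,
    pSourceGivenMiss = 0.50,
    rtMeanlog = log(1.2),
    rtSdlog = 0.4,
    rtMax = 3
  )
)

setValidity("BehaviorParams", function(object) {
  probs <- c(
    pRememberHit = object@pRememberHit,
    pFamiliarHit = object@pFamiliarHit,
    pCorrectRejection = object@pCorrectRejection,
    pRememberFalseAlarm = object@pRememberFalseAlarm,
    pSourceGivenRemember = object@pSourceGivenRemember,
    pSourceGivenFamiliar = object@pSourceGivenFamiliar,
    pSourceGivenMiss = object@pSourceGivenMiss
  )
  bad <- names(probs)[!is.finite(probs) | probs < 0 | probs > 1]
  if (length(bad))
    return(sprintf("probabilities out of [0, 1]: %s",
                   paste(bad, collapse = ", ")))
  if (object@pRememberHit + object@pFamiliarHit > 1 + 1e-12)
    return("pRememberHit + pFamiliarHit must not exceed 1")
  if (object@rtSdlog <= 0) return("rtSdlog must be > 0")
  if (object@rtMax <= 0) return("rtMax must be > 0")
  TRUE
})

#' Generative parameters for trial-wise voxel patterns
#'
#' Amplitudes of the house-level and video-level latent signals and the
#' trial-specific noise standard deviation in the additive pattern model
#' \code{x_t = aHouse * H_house + bVideo * c_t * V_video + e_t}.
#'
#' @slot aHouse amplitude of the per-house latent voxel vector (default 0:
#'   no spatial-context signal, matching the observed null spatial effects).
#' @slot bVideo amplitude of the per-video latent voxel vector.
#' @slot sigmaNoise standard deviation of trial-specific iid noise.
#' @slot nItemsPerVideo items per video, used for zero-sum separative
#'   loadings and in the closed-form expected-similarity formulas.
#' @export PatternParams
#' @exportClass PatternParams
PatternParams <- setClass(
  "PatternParams",
  representation(
    aHouse = "numeric",
    bVideo = "numeric",
    sigmaNoise = "numeric",
    nItemsPerVideo = "numeric"
  ),
  prototype(aHouse = 0, bVideo = 0.6, sigmaNoise = 1, nItemsPerVideo = 10)
)

setValidity("PatternParams", function(object) {
  if (object@aHouse < 0 || object@bVideo < 0)
    return("aHouse and bVideo must be >= 0")
  if (object@sigmaNoise <= 0) return("sigmaNoise must be > 0")
  if (object@nItemsPerVideo < 2) return("nItemsPerVideo must be >= 2")
  TRUE
})

#' Canonical double-gamma HRF parameters
#'
#' Difference-of-gammas hemodynamic response function with the usual
#' defaults (peak delay 6 s, undershoot delay 16 s, unit dispersions,
#' undershoot ratio 1/6, 32 s support).
#'
#' @slot peakDelay,undershootDelay gamma delays (s).
#' @slot peakDispersion,undershootDispersion gamma dispersions (s).
#' @slot undershootRatio relative amplitude of the undershoot gamma.
#' @slot length kernel support (s), at least 24 s.
#' @export HRFParams
#' @exportClass HRFParams
HRFParams <- setClass(
  "HRFParams",
  representation(
    peakDelay = "numeric",
    undershootDelay = "numeric",
    peakDispersion = "numeric",
    undershootDispersion = "numeric",
    undershootRatio = "numeric",
    length = "numeric"
  ),
  prototype(
    peakDelay = 6, undershootDelay = 16,
    peakDispersion = 1, undershootDispersion = 1,
    undershootRatio = 1 / 6, length = 32
  )
)

setValidity("HRFParams", function(object) {
  vals <- c(object@peakDelay, object@undershootDelay, object@peakDispersion,
            object@undershootDispersion, object@undershootRatio, object@length)
  if (any(!is.finite(vals)) || any(vals <= 0))
    return("all HRF parameters must be positive and finite")
  if (object@length < 24) return("kernel length must be >= 24 s")
  TRUE
})

#' Region-of-interest specification
#'
#' Names one hippocampal-formation ROI in one hemisphere, its voxel count,
#' and the context-coding regime its simulated patterns follow:
#' \code{"integrative"} (same-video trials share a video signal, the
#' CA1-like regime), \code{"separative"} (zero-sum within-video loadings,
#' the CA23DG-like regime), or \code{"null"} (no video signal).
#'
#' @slot name one of "CA1", "CA23DG", "ERC", "SUB".
#' @slot hemisphere "left" or "right".
#' @slot nVoxels number of voxels (>= 10).
#' @slot regime "integrative", "separative" or "null".
#' @export ROISpec
#' @exportClass ROISpec
ROISpec <- setClass(
  "ROISpec",
  representation(
    name = "character",
    hemisphere = "character",
    nVoxels = "numeric",
    regime = "character"
  ),
  prototype(name = "CA1", hemisphere = "left", nVoxels = 100,
            regime = "null")
)

setValidity("ROISpec", function(object) {
  if (!object@name %in% c("CA1", "CA23DG", "ERC", "SUB"))
    return("ROI name must be one of CA1, CA23DG, ERC, SUB")
  if (!object@hemisphere %in% c("left", "right"))
    return("hemisphere must be 'left' or 'right'")
  if (length(object@nVoxels) != 1L || object@nVoxels < 10)
    return("nVoxels must be a single count >= 10")
  if (!object@regime %in% c("integrative", "separative", "null"))
    return("regime must be integrative, separative or null")
  TRUE
})

#' @describeIn ROISpec short key "NAME_hemisphere" used to index ROI lists.
#' @param roi a \code{ROISpec}.
#' @export
roiKey <- function(roi) paste(roi@name, roi@hemisphere, sep = "_")

## ---------------------------------------------------------------------------
## Experiment design
## ---------------------------------------------------------------------------

#' Experimental design container
#'
#' Holds the two spatial contexts (houses), the candidate and shown videos
#' (episodic contexts), the object-to-(house, video) assignment, and the
#' house-alternating encoding order.
#'
#' @slot houses the 2 house identifiers.
#' @slot videoTable data.frame with columns \code{video}, \code{house},
#'   \code{shown}.
#' @slot objectAssignment data.frame with columns \code{object},
#'   \code{house}, \code{video}; one row per candidate object.
#' @slot encodingOrder shown videos in presentation order, alternating
#'   houses.
#' @slot listsPerHouse,videosShownPerHouse,nObjectsPerVideo design counts.
#' @export
#' @exportClass ExperimentDesign
ExperimentDesign <- setClass(
  "ExperimentDesign",
  representation(
    houses = "character",
    videoTable = "data.frame",
    objectAssignment = "data.frame",
    encodingOrder = "character",
    listsPerHouse = "numeric",
    videosShownPerHouse = "numeric",
    nObjectsPerVideo = "numeric"
  )
)

setValidity("ExperimentDesign", function(object) {
  if (length(object@houses) != 2L || anyDuplicated(object@houses))
    return("exactly 2 distinct houses required")
  vt <- object@videoTable
  if (!all(c("video", "house", "shown") %in% names(vt)))
    return("videoTable needs columns video, house, shown")
  if (!all(vt$house %in% object@houses))
    return("videoTable references unknown houses")
  if (anyDuplicated(vt$video))
    return("each video must appear once in videoTable")
  oa <- object@objectAssignment
  if (!all(c("object", "house", "video") %in% names(oa)))
    return("objectAssignment needs columns object, house, video")
  if (anyDuplicated(oa$object))
    return("each object must belong to exactly one (house, video)")
  vh <- vt$house[match(oa$video, vt$video)]
  if (any(is.na(vh)) || any(vh != oa$house))
    return("objectAssignment (house, video) pairs must match videoTable")
  eo <- object@encodingOrder
  if (!all(eo %in% vt$video[vt$shown]))
    return("encodingOrder must list shown videos")
  if (length(eo) >= 2L) {
    h <- vt$house[match(eo, vt$video)]
    if (any(h[-1L] == h[-length(h)]))
      return("encoding order must alternate houses across consecutive videos")
  }
  TRUE
})

setMethod("show", "ExperimentDesign", function(object) {
  vt <- object@videoTable
  cat("ExperimentDesign\n")
  cat(sprintf("  houses: %s\n", paste(object@houses, collapse = ", ")))
  cat(sprintf("  candidate videos: %d (%d lists/house); shown: %d\n",
              nrow(vt), object@listsPerHouse, sum(vt$shown)))
  cat(sprintf("  objects: %d candidate, %d studied (%d per video)\n",
              nrow(object@objectAssignment),
              sum(object@objectAssignment$video %in% vt$video[vt$shown]),
              object@nObjectsPerVideo))
})

## ---------------------------------------------------------------------------
## BetaMatrix: voxels x trials single-trial estimates
## ---------------------------------------------------------------------------

#' Single-trial beta container
#'
#' A \linkS4class{SummarizedExperiment} with one assay \code{"betas"}
#' (voxels in rows, trials in columns), the trial table in \code{colData}
#' (including the per-trial outlier-\code{excluded} flag), and the
#' \linkS4class{ROISpec} in \code{metadata(x)$roi}.
#'
#' @export
#' @exportClass BetaMatrix
setClass("BetaMatrix", contains = "SummarizedExperiment")

setValidity("BetaMatrix", function(object) {
  if (!"betas" %in% SummarizedExperiment::assayNames(object))
    return("assay 'betas' is required")
  cd <- SummarizedExperiment::colData(object)
  need <- c("trial_id", "run", "is_old", "excluded")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    return(sprintf("colData misses columns: %s", paste(miss, collapse = ", ")))
  if (!is.logical(cd$excluded)) return("'excluded' must be logical")
  v <- SummarizedExperiment::assay(object, "betas")
  if (ncol(v) > 1L) {
    constRow <- rowSums(v != v[, 1L]) == 0
    if (any(constRow))
      return(sprintf("all-constant voxel rows present (e.g. row %d)",
                     which(constRow)[1L]))
  }
  roi <- S4Vectors::metadata(object)$roi
  if (!is.null(roi) && !is(roi, "ROISpec"))
    return("metadata 'roi' must be a ROISpec (or NULL)")
  TRUE
})

#' Construct a BetaMatrix
#'
#' @param values numeric matrix, voxels x trials.
#' @param trials the trial table rows aligned with the columns of
#'   \code{values}; must contain \code{trial_id}, \code{run}, \code{is_old}.
#' @param roi optional \linkS4class{ROISpec} stored in metadata.
#' @param excluded optional logical per-trial exclusion flags (default all
#'   \code{FALSE}).
#' @return a \linkS4class{BetaMatrix}.
#' @export
BetaMatrix <- function(values, trials, roi = NULL, excluded = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stopf("'values' must be a numeric matrix")
  if (nrow(trials) != ncol(values))
    stopf("trials (%d rows) must align with value columns (%d)",
          nrow(trials), ncol(values))
  if (is.null(excluded)) excluded <- rep(FALSE, nrow(trials))
  cd <- S4Vectors::DataFrame(trials)
  cd$excluded <- excluded
  colnames(values) <- trials$trial_id
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("vox%04d", seq_len(nrow(values)))
  md <- if (is.null(roi)) list() else list(roi = roi)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(betas = values), colData = cd, metadata = md)
  new("BetaMatrix", se)
}

#' @describeIn BetaMatrix the voxels x trials beta matrix.
#' @param x a \code{BetaMatrix}.
#' @export
betaValues <- function(x) SummarizedExperiment::assay(x, "betas")

#' @describeIn BetaMatrix the aligned trial table as a data.frame.
#' @export
trialInfo <- function(x)
  as.data.frame(SummarizedExperiment::colData(x))

#' @describeIn BetaMatrix logical per-trial outlier-exclusion flags.
#' @export
excludedTrials <- function(x) SummarizedExperiment::colData(x)$excluded

#' @describeIn BetaMatrix the \linkS4class{ROISpec} (or NULL).
#' @export
roiSpec <- function(x) S4Vectors::metadata(x)$roi

setMethod("show", "BetaMatrix", function(object) {
  roi <- roiSpec(object)
  cat(sprintf("BetaMatrix: %d voxels x %d trials (%d excluded)\n",
              nrow(object), ncol(object), sum(excludedTrials(object))))
  if (!is.null(roi))
    cat(sprintf("  ROI: %s %s (%s regime)\n", roi@name, roi@hemisphere,
                roi@regime))
})

## ---------------------------------------------------------------------------
## SimilarityMatrix
## ---------------------------------------------------------------------------

#' Trial-by-trial Pearson similarity matrix
#'
#' Symmetric matrix of pairwise Pearson correlations between trial-wise
#' voxel patterns, spanning all runs, with unit diagonal.
#'
#' @slot values trials x trials correlation matrix.
#' @slot trialIds trial identifiers aligned with rows/columns.
#' @slot runs run label per trial.
#' @slot roi the originating \linkS4class{ROISpec}, or NULL.
#' @export
#' @exportClass SimilarityMatrix
SimilarityMatrix <- setClass(
  "SimilarityMatrix",
  representation(values = "matrix", trialIds = "character",
                 runs = "integer", roi = "ANY")
)

setValidity("SimilarityMatrix", function(object) {
  v <- object@values
  if (nrow(v) != ncol(v)) return("values must be square")
  if (length(object@trialIds) != nrow(v))
    return("trialIds must align with values")
  if (length(object@runs) != nrow(v)) return("runs must align with values")
  if (nrow(v) && max(abs(v - t(v))) > 1e-8) return("values must be symmetric")
  if (nrow(v) && (max(abs(diag(v) - 1)) > 1e-12))
    return("diagonal must be 1")
  if (nrow(v) && (min(v) < -1 - 1e-8 || max(v) > 1 + 1e-8))
    return("entries must lie in [-1, 1]")
  TRUE
})

setMethod("show", "SimilarityMatrix", function(object) {
  cat(sprintf("SimilarityMatrix: %d trials over %d runs\n",
              nrow(object@values), length(unique(object@runs))))
})

#' @describeIn SimilarityMatrix the correlation matrix.
#' @param x a \code{SimilarityMatrix}.
#' @export
similarityValues <- function(x) x@values

## ---------------------------------------------------------------------------
## LRTResult
## ---------------------------------------------------------------------------

#' Likelihood-ratio test result
#'
#' Chi-squared statistic, degrees of freedom and upper-tail p-value for a
#' nested maximum-likelihood mixed-model comparison.
#'
#' @slot chi2 test statistic, \code{2 * (LL_full - LL_reduced)} clamped at 0.
#' @slot df difference in estimated parameter counts.
#' @slot p upper-tail chi-squared probability.
#' @slot nObs number of observations both models were fitted to.
#' @slot converged whether both fits converged.
#' @export
#' @exportClass LRTResult
LRTResult <- setClass(
  "LRTResult",
  representation(chi2 = "numeric", df = "integer", p = "numeric",
                 nObs = "integer", converged = "logical"),
  prototype(chi2 = 0, df = 1L, p = 1, nObs = 0L, converged = TRUE)
)

setValidity("LRTResult", function(object) {
  if (object@chi2 < 0) return("chi2 must be >= 0")
  if (object@df < 0L) return("df must be a non-negative integer")
  if (object@p < 0 || object@p > 1) return("p must be in [0, 1]")
  TRUE
})

setMethod("show", "LRTResult", function(object) {
  cat(sprintf("LRT: chi2(%d) = %.3f, p = %.4g (n = %d%s)\n",
              object@df, object@chi2, object@p, object@nObs,
              if (object@converged) "" else "; NOT converged"))
})

## ---------------------------------------------------------------------------
## ControlResult
## ---------------------------------------------------------------------------

#' Robustness-control result
#'
#' Replicate-level results and a recomputable summary for one of the three
#' control analyses (trial-count-matched subsampling, influential-voxel
#' dropping, reaction-time covariate model).
#'
#' @slot analysis one of "subsample", "voxel_drop", "rt_control".
#' @slot replicates list of per-replicate results.
#' @slot summary named list of summary quantities.
#' @slot config echo of the configuration used (n_reps, criterion, ...).
#' @export
#' @exportClass ControlResult
ControlResult <- setClass(
  "ControlResult",
  representation(analysis = "character", replicates = "list",
                 summary = "list", config = "list")
)

setValidity("ControlResult", function(object) {
  if (!object@analysis %in% c("subsample", "voxel_drop", "rt_control"))
    return("analysis must be subsample, voxel_drop or rt_control")
  TRUE
})

setMethod("show", "ControlResult", function(object) {
  cat(sprintf("ControlResult [%s]: %d replicate(s)\n", object@analysis,
              length(object@replicates)))
  s <- object@summary
  for (nm in names(s))
    if (is.numeric(s[[nm]]) && length(s[[nm]]) == 1L)
      cat(sprintf("  %s: %.4g\n", nm, s[[nm]]))
})
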