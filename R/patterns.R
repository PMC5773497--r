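## Zero-sum loadings for the separative regime: for even n, half the items
## load +1 and half -1, which satisfies sum(c) = 0 and sum(c^2) = n exactly
## and keeps per-trial variance uniform (so the closed-form expected
## similarity is exact in the large-voxel limit). Odd n falls back to
## centered Gaussian loadings rescaled to sum(c^2) = n.
.videoLoadings <- function(n, regime) {
  switch(regime,
    integrative = rep(1, n),
    null = rep(0, n),
    separative = {
      if (n %% 2L == 0L) {
        sample(rep(c(-1, 1), each = n %/% 2L))
      } else {
        c0 <- rnorm(n)
        c0 <- c0 - mean(c0)
        c0 * sqrt(n / sum(c0^2))
      }
    },
    stopf("unknown regime '%s'", regime))
}

#' Simulate trial-wise multivoxel patterns for one ROI
#'
#' Generative model per old trial \code{t} (in video \code{v} of house
#' \code{h}): \deqn{x_t = a H_h + b c_t V_v + e_t,} where \code{H_h} and
#' \code{V_v} are independent standard-normal latent voxel vectors (one per
#' house / per shown video), \code{e_t} is iid noise with SD
#' \code{sigmaNoise}, and the loading \code{c_t} depends on the ROI regime:
#' all 1 (integrative, same-video patterns share the video signal), zero-sum
#' over the items of a video (separative, same-video patterns
#' anti-correlate), or 0 (null). New trials are pure noise.
#'
#' @param trials a trial table (old trials must carry house/video labels).
#' @param roi a \linkS4class{ROISpec} (voxel count and regime).
#' @param params a \linkS4class{PatternParams}.
#' @param seed RNG seed.
#' @return a \linkS4class{BetaMatrix} (voxels x trials).
#' @seealso \code{\link{expectedSimilarity}} for the closed-form pairwise
#'   Pearson expectations under this model.
#' @export
simulatePatterns <- function(trials, roi, params = PatternParams(),
                             seed = 1) {
  validObject(roi)
  validObject(params)
  if (any(trials$is_old & (is.na(trials$house) | is.na(trials$video))))
    stopf("old trials must carry house and video labels")
  .withSeed(seed, {
    nv <- as.integer(roi@nVoxels)
    n <- nrow(trials)
    houses <- sort(unique(trials$house[trials$is_old]))
    videos <- sort(unique(trials$video[trials$is_old]))
    H <- matrix(rnorm(nv * length(houses)), nv,
                dimnames = list(NULL, houses))
    V <- matrix(rnorm(nv * length(videos)), nv,
                dimnames = list(NULL, videos))

    loading <- numeric(n)
    for (v in videos) {
      idx <- which(trials$is_old & trials$video == v)
      loading[idx] <- .videoLoadings(length(idx), roi@regime)
    }

    X <- matrix(rnorm(nv * n, sd = params@sigmaNoise), nv, n)
    for (t in which(trials$is_old)) {
      X[, t] <- X[, t] + params@aHouse * H[, trials$house[t]] +
        params@bVideo * loading[t] * V[, trials$video[t]]
    }
    BetaMatrix(X, trials, roi = roi)
  })
}

#' Closed-form expected pairwise similarity under the generative model
#'
#' Expected Pearson correlation (large-voxel limit) between two old-trial
#' patterns as a function of their condition. With effective video
#' amplitude \code{b} (0 under the null regime), denominator
#' \code{D = a^2 + b^2 + sigma^2}, and mean same-video loading product
#' \code{rho_c} (1 integrative, \code{-1/(n-1)} separative):
#' same video \code{(a^2 + b^2 rho_c)/D}; different video, same house
#' \code{a^2/D}; different house 0.
#'
#' @param params a \linkS4class{PatternParams}.
#' @param regime "integrative", "separative" or "null".
#' @param condition one of \code{"same_video_same_house"},
#'   \code{"diff_video_same_house"}, \code{"diff_video_diff_house"}.
#' @return the expected correlation, in [-1, 1].
#' @examples
#' p <- PatternParams(aHouse = 0, bVideo = 1, sigmaNoise = 1)
#' expectedSimilarity(p, "separative", "same_video_same_house") # -1/18
#' @export
expectedSimilarity <- function(params, regime,
                               condition = c("same_video_same_house",
                                             "diff_video_same_house",
                                             "diff_video_diff_house")) {
  validObject(params)
  condition <- match.arg(condition)
  if (!regime %in% c("integrative", "separative", "null"))
    stopf("unknown regime '%s'", regime)
  a <- params@aHouse
  b <- if (regime == "null") 0 else params@bVideo
  rhoC <- switch(regime,
                 integrative = 1,
                 separative = -1 / (params@nItemsPerVideo - 1),
                 null = 0)
  D <- a^2 + b^2 + params@sigmaNoise^2
  switch(condition,
         same_video_same_house = (a^2 + b^2 * rhoC) / D,
         diff_video_same_house = a^2 / D,
         diff_video_diff_house = 0)
}
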