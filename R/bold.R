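#' Simulate per-run BOLD time series from ground-truth trial betas
#'
#' For each run, trial onsets accumulate the 3 s stimulus duration plus a
#' jittered inter-trial interval drawn uniformly on a 0.5 s grid over
#' \code{itiRange}. Each voxel's time series is the sum over trials of the
#' trial's beta times an HRF-convolved unit stick at its onset, plus
#' low-order Legendre polynomial drift and iid Gaussian noise.
#'
#' @param trials a trial table (the \code{run} column defines runs).
#' @param trueBetas a \linkS4class{BetaMatrix} aligned with \code{trials}
#'   (e.g. from \code{\link{simulatePatterns}}).
#' @param tr repetition time (s).
#' @param trialDuration stimulus duration (s).
#' @param itiRange inter-trial-interval range (s), jittered on a 0.5 s grid.
#' @param hrf an \linkS4class{HRFParams}.
#' @param noiseSd per-timepoint Gaussian noise SD.
#' @param driftAmplitude SD multiplier of random Legendre drift amplitudes.
#' @param leadIn rest before the first onset (s).
#' @param seed RNG seed.
#' @return named list (one element per run) of lists with \code{bold}
#'   (voxels x timepoints), \code{onsets} (s), \code{tr},
#'   \code{trialIds}, and \code{duration} (s).
#' @export
simulateBold <- function(trials, trueBetas, tr = 2.01, trialDuration = 3,
                         itiRange = c(2, 8), hrf = HRFParams(),
                         noiseSd = 1, driftAmplitude = 0, leadIn = 2,
                         seed = 1) {
  if (!is.numeric(tr) || tr <= 0) stopf("tr must be positive")
  if (nrow(trials) == 0L) stopf("empty trial table")
  vals <- betaValues(trueBetas)
  if (ncol(vals) != nrow(trials))
    stopf("trueBetas not aligned with trials")
  validObject(hrf)
  .withSeed(seed, {
    runs <- sort(unique(trials$run))
    out <- lapply(runs, function(r) {
      idx <- which(trials$run == r)
      nt <- length(idx)
      grid <- seq(itiRange[1], itiRange[2], by = 0.5)
      itis <- grid[sample.int(length(grid), nt, replace = TRUE)]
      onsets <- leadIn + cumsum(c(0, (trialDuration + itis)[-nt]))
      duration <- leadIn + sum(trialDuration + itis)
      nTR <- ceiling((duration + hrf@length) / tr)
      X <- vapply(onsets, .stickRegressor, numeric(nTR),
                  nTR = nTR, tr = tr, hrf = hrf)
      bold <- vals[, idx, drop = FALSE] %*% t(X)
      if (driftAmplitude > 0) {
        D <- .legendreDrift(nTR, 2)
        amps <- matrix(rnorm(nrow(bold) * ncol(D), sd = driftAmplitude),
                       nrow(bold))
        bold <- bold + tcrossprod(amps, D)
      }
      if (noiseSd > 0)
        bold <- bold + matrix(rnorm(length(bold), sd = noiseSd),
                              nrow(bold))
      list(bold = bold, onsets = onsets, tr = tr,
           trialIds = trials$trial_id[idx], duration = duration)
    })
    names(out) <- as.character(runs)
    out
  })
}
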