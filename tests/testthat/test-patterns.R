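# Closed-form expected similarities and Monte-Carlo checks of the pattern
# generator. Replicates are fully independent (fresh latents per draw), so
# the standard error of replicate means is a valid yardstick.

## Mean pairwise similarity per condition over independent replicate
## designs; returns per-replicate condition means.
mcConditionMeans <- function(regime, params, nVoxels, nReps, seed0,
                             nVideosShown = 2, nObjectsPerVideo = 4) {
  roi <- ROISpec(name = "CA1", hemisphere = "left", nVoxels = nVoxels,
                 regime = regime)
  out <- matrix(NA_real_, nReps, 3,
                dimnames = list(NULL, c("same_video_same_house",
                                        "diff_video_same_house",
                                        "diff_video_diff_house")))
  for (k in seq_len(nReps)) {
    d <- generateDesign(nListsPerHouse = 2, nVideosShown = nVideosShown,
                        nObjectsPerVideo = nObjectsPerVideo,
                        nNew = 4, nRuns = 2, seed = seed0 + k)
    tr <- d$trials[d$trials$is_old, ]
    b <- simulatePatterns(tr, roi, params, seed = seed0 + 1000 + k)
    C <- cor(betaValues(b))
    n <- nrow(tr)
    ut <- which(upper.tri(C), arr.ind = TRUE)
    cond <- labelPairCondition(tr$house[ut[, 1]], tr$video[ut[, 1]],
                               tr$house[ut[, 2]], tr$video[ut[, 2]])
    out[k, ] <- tapply(C[ut], cond, mean)[colnames(out)]
  }
  out
}

test_that("closed-form expected similarities match hand-derived values", {
  ## separative, a=0, b=1, sigma=1, n=10: same-video = -(1/9)/2 = -1/18
  p <- PatternParams(aHouse = 0, bVideo = 1, sigmaNoise = 1,
                     nItemsPerVideo = 10)
  expect_equal(expectedSimilarity(p, "separative", "same_video_same_house"),
               -1 / 18)
  expect_equal(expectedSimilarity(p, "separative", "diff_video_same_house"),
               0)
  ## integrative, a=1, b=1, sigma=sqrt(2): 2/4 and 1/4
  p2 <- PatternParams(aHouse = 1, bVideo = 1, sigmaNoise = sqrt(2))
  expect_equal(expectedSimilarity(p2, "integrative", "same_video_same_house"),
               0.5)
  expect_equal(expectedSimilarity(p2, "integrative", "diff_video_same_house"),
               0.25)
  ## different houses share no latent signal
  expect_equal(expectedSimilarity(p2, "integrative", "diff_video_diff_house"),
               0)
  ## near-noiseless shared house signal drives r -> 1
  p3 <- PatternParams(aHouse = 1, bVideo = 0, sigmaNoise = 1e-6)
  expect_gt(expectedSimilarity(p3, "integrative", "diff_video_same_house"),
            0.999999)
  ## no video signal: episodic conditions collapse
  p4 <- PatternParams(aHouse = 0.8, bVideo = 0, sigmaNoise = 1)
  expect_equal(
    expectedSimilarity(p4, "integrative", "same_video_same_house"),
    expectedSimilarity(p4, "integrative", "diff_video_same_house"))
  expect_error(expectedSimilarity(p4, "wiggly", "same_video_same_house"),
               "regime")
})

test_that("Monte-Carlo condition means match the closed form within 3 SE", {
  params <- PatternParams(aHouse = 0.7, bVideo = 0.8, sigmaNoise = 1,
                          nItemsPerVideo = 4)
  for (spec in list(list(regime = "integrative", nVoxels = 100, nReps = 120),
                    list(regime = "separative", nVoxels = 100, nReps = 120),
                    list(regime = "integrative", nVoxels = 1000, nReps = 40))) {
    m <- mcConditionMeans(spec$regime, params, spec$nVoxels, spec$nReps,
                          seed0 = 2000 + spec$nVoxels)
    for (cond in colnames(m)) {
      expct <- expectedSimilarity(params, spec$regime, cond)
      se <- sd(m[, cond]) / sqrt(nrow(m))
      expect_lt(abs(mean(m[, cond]) - expct), 3 * se + 2 / spec$nVoxels)
    }
  }
})

test_that("regimes order the conditions as pattern completion/separation", {
  params <- PatternParams(aHouse = 0.5, bVideo = 0.8, sigmaNoise = 1,
                          nItemsPerVideo = 4)
  ## integrative: diff-house < diff-video/same-house < same-video
  ei <- vapply(c("diff_video_diff_house", "diff_video_same_house",
                 "same_video_same_house"),
               function(cc) expectedSimilarity(params, "integrative", cc),
               numeric(1))
  expect_true(all(diff(ei) > 0))
  ## separative: same-video strictly below diff-video/same-house
  expect_lt(expectedSimilarity(params, "separative", "same_video_same_house"),
            expectedSimilarity(params, "separative", "diff_video_same_house"))

  ## and the generated data agree (pooled Monte-Carlo means)
  mi <- colMeans(mcConditionMeans("integrative", params, 100, 60, 5000))
  expect_true(mi["diff_video_diff_house"] < mi["diff_video_same_house"])
  expect_true(mi["diff_video_same_house"] < mi["same_video_same_house"])
  ms <- colMeans(mcConditionMeans("separative", params, 100, 60, 6000))
  expect_lt(ms["same_video_same_house"], ms["diff_video_same_house"])
})

test_that("pattern generation is deterministic and structurally sound", {
  d <- generateDesign(seed = 9)
  roi <- ROISpec(name = "ERC", hemisphere = "right", nVoxels = 25,
                 regime = "null")
  a <- simulatePatterns(d$trials, roi, seed = 4)
  b <- simulatePatterns(d$trials, roi, seed = 4)
  expect_identical(betaValues(a), betaValues(b))
  c <- simulatePatterns(d$trials, roi, seed = 5)
  expect_false(identical(betaValues(a), betaValues(c)))

  expect_equal(dim(betaValues(a)), c(25L, 252L))
  expect_false(any(excludedTrials(a)))
  expect_identical(roiSpec(a)@regime, "null")

  ## old trials without labels are rejected
  bad <- d$trials
  bad$video[bad$is_old][1] <- NA
  expect_error(simulatePatterns(bad, roi, seed = 1), "labels")
})

test_that("simulated BOLD runs have the expected length and determinism", {
  d <- generateDesign(seed = 2)
  tr <- d$trials
  roi <- ROISpec(name = "CA1", hemisphere = "left", nVoxels = 10,
                 regime = "null")
  tb <- simulatePatterns(tr, roi, seed = 3)
  runs <- simulateBold(tr, tb, seed = 8)
  ## 63 trials x (3 s stimulus + mean 5 s ITI) ~ 504 s per run
  durations <- vapply(runs, `[[`, numeric(1), "duration")
  expect_true(all(abs(durations - (2 + 63 * 8)) < 60))
  expect_equal(length(runs[["1"]]$onsets), 63)
  expect_true(all(diff(runs[["1"]]$onsets) >= 5))   # 3 s + minimum 2 s ITI

  runs2 <- simulateBold(tr, tb, seed = 8)
  expect_identical(runs[["2"]]$bold, runs2[["2"]]$bold)
  expect_identical(runs[["2"]]$onsets, runs2[["2"]]$onsets)

  expect_error(simulateBold(tr, tb, tr = -1), "tr must be positive")
})
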