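test_that("matched subsampling is invariant when counts are already equal", {
  pairs <- makeFactorialPairs(21, nSubj = 4, nPerCell = 5, effect = 0.1)
  res <- matchedSubsampleTest(pairs, nReps = 5, seed = 3)
  chi2 <- vapply(res@replicates, `[[`, numeric(1), "chi2")
  expect_equal(length(unique(chi2)), 1L)    # m-of-m sampling: same rows
  expect_true(res@summary$fractionSignificant %in% c(0, 1))
})

test_that("subsampling equalizes per-cell condition counts without replacement", {
  pairs <- makeFactorialPairs(22, nSubj = 3, nPerCell = 6)
  ## unbalance: drop rows so conditions differ per cell
  drop <- with(pairs, which(condition == "diff_video_diff_house" &
                              subject == "s01"))[1:3]
  pairs <- pairs[-drop, ]

  seen <- list()
  recorder <- function(tb) {
    key <- length(seen) + 1L
    seen[[key]] <<- tb
    LRTResult(chi2 = 0, df = 1L, p = 1, nObs = nrow(tb), converged = TRUE)
  }
  invisible(matchedSubsampleTest(pairs, nReps = 3, seed = 9,
                                 refitFn = recorder))
  for (tb in seen) {
    counts <- table(tb$subject, tb$roi, tb$hemisphere, tb$condition)
    perCell <- apply(counts, 1:3, function(x) length(unique(x)))
    expect_true(all(perCell == 1))          # equal counts per condition
    ## without replacement: no duplicated rows
    expect_false(any(duplicated(tb[, c("trial_i", "trial_j", "roi",
                                       "hemisphere")])))
  }

  ## determinism
  a <- matchedSubsampleTest(pairs, nReps = 3, seed = 4)
  b <- matchedSubsampleTest(pairs, nReps = 3, seed = 4)
  expect_identical(a@replicates, b@replicates)

  ## empty subject x condition cell is an error naming the cell
  gone <- pairs[!(pairs$subject == "s02" &
                    pairs$condition == "same_video_same_house"), ]
  expect_error(matchedSubsampleTest(gone, nReps = 2, seed = 1),
               "same_video_same_house")
})

test_that("voxel influence ranking finds spiked voxels deterministically", {
  trials <- makeBareTrials(nOld = 12)
  set.seed(31)
  vals <- matrix(rnorm(20 * 12, sd = 0.5), 20, 12)
  vals[7, ] <- vals[7, ] * 10 + 5     # large magnitude and variance
  b <- BetaMatrix(vals, trials)
  expect_equal(rankInfluentialVoxels(b, "abs_magnitude")[1], 7L)
  expect_equal(rankInfluentialVoxels(b, "trial_sd")[1], 7L)
  expect_identical(rankInfluentialVoxels(b, "abs_magnitude"),
                   rankInfluentialVoxels(b, "abs_magnitude"))
  expect_error(rankInfluentialVoxels(b, "condition_pair_msd"),
               "pair table")
})

test_that("dropping influential voxels preserves a robust effect", {
  study <- makeStudy(101, nSubjects = 5, nVoxels = 50)
  recompute <- function(keepIdx) {
    rebuilt <- lapply(names(study$data), function(s) {
      sd <- study$data[[s]]
      b <- sd$betas[["CA1_left"]]
      subPairs <- sd$pairs
      drop <- rankInfluentialVoxels(b, keepIdx$criterion,
                                    subPairs)[seq_len(keepIdx$nDrop)]
      pruned <- if (keepIdx$nDrop > 0) b[-drop, ] else b
      suppressWarnings(
        extractPairs(correlationMatrix(pruned), sd$trials, subject = s))
    })
    conditionContrast(do.call(rbind, rebuilt), "CA1", "left", "episodic")
  }
  baseline <- conditionContrast(study$pairs, "CA1", "left", "episodic")
  expect_equal(baseline$direction, 1)
  for (crit in c("abs_magnitude", "trial_sd", "condition_pair_msd")) {
    dropped <- recompute(list(criterion = crit, nDrop = 5))
    expect_equal(dropped$direction, baseline$direction)
    expect_lt(dropped$lrt@p, 0.05)
  }
  ## nDrop = 0 reproduces the baseline exactly
  same <- recompute(list(criterion = "abs_magnitude", nDrop = 0))
  expect_equal(same$lrt@chi2, baseline$lrt@chi2, tolerance = 1e-10)
})

test_that("single-subject voxel-drop closure works through the S4 interface", {
  study <- makeStudy(202, nSubjects = 4, nVoxels = 40)
  ## closure refits the pooled contrast with one subject's betas pruned
  target <- "s01"
  recompute <- function(b) {
    rebuilt <- lapply(names(study$data), function(s) {
      sd <- study$data[[s]]
      if (s == target)
        suppressWarnings(extractPairs(correlationMatrix(b), sd$trials,
                                      subject = s))
      else sd$pairs
    })
    conditionContrast(do.call(rbind, rebuilt), "CA1", "left", "episodic")
  }
  b1 <- study$data[[target]]$betas[["CA1_left"]]
  res <- influentialVoxelDrop(b1, recompute, "trial_sd", nDrop = 5)
  expect_s4_class(res, "ControlResult")
  expect_true(res@summary$directionPreserved)
  expect_length(res@summary$droppedVoxels, 5)

  res0 <- influentialVoxelDrop(b1, recompute, "abs_magnitude", nDrop = 0)
  expect_equal(res0@replicates$baseline$lrt@chi2,
               res0@replicates$dropped$lrt@chi2)
  expect_error(influentialVoxelDrop(b1, recompute, "trial_sd", nDrop = 40),
               "smaller than the voxel count")
})

test_that("the RT covariate model leaves an RT-independent effect intact", {
  pairs <- makeContrastPairs(55, nSubj = 10, nPer = 30, delta = 0.08)
  plain <- conditionContrast(pairs, "CA1", "left", "episodic")
  rt <- rtCovariateModel(pairs, "CA1", "left", "episodic")
  expect_equal(rt$direction, plain$direction)
  expect_equal(rt$lrt@p < 0.05, plain$lrt@p < 0.05)

  ## zero-variance rt_diff: warning + uncontrolled fallback
  flat <- pairs
  flat$rt_diff <- 0.5
  expect_warning(fb <- rtCovariateModel(flat, "CA1", "left", "episodic"),
                 "zero variance")
  expect_equal(fb$lrt@chi2, plain$lrt@chi2, tolerance = 1e-8)

  ## similarity driven purely by rt_diff, no condition effect: the
  ## condition test stays null after absorbing the RT slope
  rtOnly <- makeContrastPairs(56, nSubj = 10, nPer = 30, delta = 0,
                              rtEffect = 0.3)
  resNull <- rtCovariateModel(rtOnly, "CA1", "left", "episodic")
  expect_gt(resNull$lrt@p, 0.01)
})
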