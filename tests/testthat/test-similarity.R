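test_that("correlation matrices match hand values and the brute-force oracle", {
  trials <- makeBareTrials(nOld = 3)
  ## patterns over 3 voxels: A = (1,2,3), B = (3,2,1), C = (1,0,1)
  vals <- cbind(A = c(1, 2, 3), B = c(3, 2, 1), C = c(1, 0, 1))
  b <- BetaMatrix(vals, trials)
  sim <- correlationMatrix(b)
  M <- similarityValues(sim)
  expect_equal(M[1, 2], -1)
  expect_equal(M[1, 3], 0)
  expect_equal(unname(diag(M)), rep(1, 3))

  ## brute-force double-loop oracle on random <= 10-trial instances
  for (seed in c(1, 2)) {
    set.seed(seed)
    n <- sample(4:10, 1)
    tr2 <- makeBareTrials(nOld = n)
    v <- matrix(rnorm(5 * n), 5, n)
    S <- similarityValues(correlationMatrix(BetaMatrix(v, tr2)))
    expect_equal(unname(S), bruteCorMatrix(v), tolerance = 1e-12)
    expect_lt(max(abs(S - t(S))), 1e-12)
  }
})

test_that("degenerate correlation inputs are rejected with the trial named", {
  trials <- makeBareTrials(nOld = 3)
  vals <- cbind(c(1, 2, 3), c(2, 2, 2), c(1, 0, 1))  # trial 2 constant
  expect_error(correlationMatrix(BetaMatrix(vals, trials)),
               "trial00002")
  expect_error(correlationMatrix(BetaMatrix(matrix(1:3, 1), makeBareTrials(3))),
               ">= 2 voxels")
})

test_that("pair conditions partition old-old pairs", {
  expect_equal(labelPairCondition("house1", "v3", "house1", "v3"),
               "same_video_same_house")
  expect_equal(labelPairCondition("house1", "v3", "house1", "v5"),
               "diff_video_same_house")
  expect_equal(labelPairCondition("house1", "v3", "house2", "v4"),
               "diff_video_diff_house")
  expect_error(labelPairCondition("house1", "v3", NA, NA), "new items")
})

test_that("pair extraction applies the between-run and eligibility gates", {
  roi <- ROISpec(name = "CA23DG", hemisphere = "right", nVoxels = 10,
                 regime = "null")
  base <- makeBareTrials(nOld = 2)
  base$response <- "remember"; base$source_correct <- TRUE
  base$rt <- c(1, 2)

  ## same run: no pairs
  sameRun <- base; sameRun$run <- c(1, 1)
  b <- simulatePatterns(sameRun, roi, seed = 1)
  expect_warning(p0 <- extractPairs(correlationMatrix(b), sameRun),
                 "no eligible")
  expect_equal(nrow(p0), 0)

  ## different runs: exactly one pair, with rt_diff = 1
  diffRun <- base; diffRun$run <- c(1, 2)
  b2 <- simulatePatterns(diffRun, roi, seed = 1)
  p1 <- extractPairs(correlationMatrix(b2), diffRun, subject = "s09")
  expect_equal(nrow(p1), 1)
  expect_equal(p1$rt_diff, 1)
  expect_equal(p1$subject, "s09")
  expect_equal(p1$roi, "CA23DG")
  expect_equal(p1$hemisphere, "right")
})

test_that("pair counts match the combinatorial brute-force oracle", {
  roi <- ROISpec(name = "SUB", hemisphere = "left", nVoxels = 12,
                 regime = "null")
  for (seed in 1:4) {
    d <- generateDesign(nListsPerHouse = 3, nVideosShown = 3,
                        nObjectsPerVideo = 3, nNew = 6, nRuns = 4,
                        seed = seed)
    tr <- simulateBehavior(d$trials, seed = seed + 50)
    b <- simulatePatterns(tr, roi, seed = seed + 100)
    sim <- correlationMatrix(b)
    pairs <- extractPairs(sim, tr)

    eligible <- tr$is_old & tr$response == "remember" &
      !is.na(tr$source_correct) & tr$source_correct
    expect_equal(nrow(pairs), brutePairCount(tr$run, eligible))

    ## equivalently: sum over run pairs of k_a * k_b
    k <- table(factor(tr$run[eligible], levels = 1:4))
    expect_equal(nrow(pairs), (sum(k)^2 - sum(k^2)) / 2)

    ## no pair touches an ineligible or new trial; conditions partition
    bad <- tr$trial_id[!eligible]
    expect_false(any(pairs$trial_i %in% bad | pairs$trial_j %in% bad))
    expect_true(all(pairs$run_i != pairs$run_j))
    expect_equal(sum(table(pairs$condition)), nrow(pairs))
  }
})

test_that("excluded trials never reach the pair table", {
  roi <- ROISpec(name = "CA1", hemisphere = "left", nVoxels = 20,
                 regime = "integrative")
  d <- generateDesign(seed = 77)
  tr <- simulateBehavior(d$trials, seed = 78)
  b <- excludeOutlierTrials(simulatePatterns(tr, roi, seed = 79),
                            zThreshold = 0.75)
  excl <- tr$trial_id[excludedTrials(b)]
  expect_gt(length(excl), 0)
  pairs <- extractPairs(correlationMatrix(b), tr)
  expect_false(any(pairs$trial_i %in% excl | pairs$trial_j %in% excl))
})

test_that("spatial contrast keeps only cross-video pairs, relabeled", {
  p <- data.frame(
    subject = "s01", roi = "CA1", hemisphere = "left",
    trial_i = c("a", "b", "c"), trial_j = c("x", "y", "z"),
    run_i = 1L, run_j = 2L,
    condition = c("same_video_same_house", "diff_video_same_house",
                  "diff_video_diff_house"),
    similarity = c(0.5, 0.2, 0.1), rt_diff = 0.3)
  s <- spatialContrastPairs(p)
  expect_equal(nrow(s), 2)
  expect_setequal(s$condition, c("same_house", "different_house"))

  allSame <- p[rep(1, 3), ]
  expect_equal(nrow(spatialContrastPairs(allSame)), 0)

  mixed <- p[c(1, 1, 2, 3, 3), ]
  expect_equal(nrow(spatialContrastPairs(mixed)),
               nrow(mixed) - sum(mixed$condition == "same_video_same_house"))
})

test_that("pair tables round-trip and Fisher z is applied on request", {
  roi <- ROISpec(name = "CA1", hemisphere = "left", nVoxels = 15,
                 regime = "integrative")
  d <- generateDesign(nListsPerHouse = 3, nVideosShown = 2,
                      nObjectsPerVideo = 4, nNew = 4, nRuns = 2, seed = 5)
  tr <- simulateBehavior(d$trials, seed = 6)
  b <- simulatePatterns(tr, roi, seed = 7)
  sim <- correlationMatrix(b)
  pairs <- extractPairs(sim, tr)
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path))
  writePairTable(pairs, path)
  back <- readPairTable(path)
  expect_equal(back$similarity, pairs$similarity, tolerance = 1e-12)
  expect_identical(back$condition, pairs$condition)
  expect_identical(back$trial_i, pairs$trial_i)

  pz <- extractPairs(sim, tr, fisherZ = TRUE)
  expect_equal(pz$similarity, atanh(pairs$similarity), tolerance = 1e-12)
})
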