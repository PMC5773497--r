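#' Generate the encoding design and recognition-test trial table
#'
#' Builds the two-house virtual-tour design: each house has
#' \code{nListsPerHouse} candidate videos of \code{nObjectsPerVideo} objects
#' each; \code{nVideosShown} videos per house are sampled for encoding and
#' presented in a house-alternating order. The recognition test re-presents
#' every studied object exactly once, interleaved with \code{nNew} unstudied
#' objects, across \code{nRuns} equally sized runs. Old trials are
#' stratified so each run carries an approximately equal share (+/- 1) from
#' each house, keeping between-run pair counts balanced.
#'
#' @param nListsPerHouse candidate object lists (videos) per house.
#' @param nVideosShown videos actually encoded per house.
#' @param nObjectsPerVideo objects placed in each video.
#' @param nNew new (unstudied) objects at test.
#' @param nRuns recognition-test runs (>= 2, so between-run pairs exist).
#' @param seed RNG seed; the same seed reproduces the design bit-identically.
#' @return a list with elements \code{design} (\linkS4class{ExperimentDesign})
#'   and \code{trials} (the trial table, one row per test trial with columns
#'   \code{trial_id}, \code{trial_index}, \code{run}, \code{object},
#'   \code{is_old}, \code{house}, \code{video}, \code{response},
#'   \code{source_correct}, \code{rt}; response fields are \code{NA} until
#'   \code{\link{simulateBehavior}} fills them).
#' @examples
#' d <- generateDesign(seed = 1)
#' sum(d$trials$is_old)   # 200 studied objects
#' table(d$trials$run)    # 63 trials in each of 4 runs
#' @export
generateDesign <- function(nListsPerHouse = 12, nVideosShown = 10,
                           nObjectsPerVideo = 10, nNew = 52, nRuns = 4,
                           seed = 1) {
  if (nRuns < 2) stopf("nRuns must be >= 2 (between-run pairs must exist)")
  if (nVideosShown > nListsPerHouse)
    stopf("nVideosShown (%d) cannot exceed nListsPerHouse (%d)",
          nVideosShown, nListsPerHouse)
  nOld <- 2L * nVideosShown * nObjectsPerVideo
  total <- nOld + nNew
  if (total %% nRuns != 0)
    stopf("total trial count %d not divisible by nRuns = %d", total, nRuns)
  runSize <- total %/% nRuns

  .withSeed(seed, {
    houses <- c("house1", "house2")
    videoTable <- do.call(rbind, lapply(houses, function(h) {
      data.frame(video = sprintf("%s_v%02d", h, seq_len(nListsPerHouse)),
                 house = h, shown = FALSE)
    }))
    for (h in houses) {
      idx <- which(videoTable$house == h)
      videoTable$shown[sample(idx, nVideosShown)] <- TRUE
    }

    objectAssignment <- data.frame(
      object = sprintf("obj%03d", seq_len(2L * nListsPerHouse *
                                            nObjectsPerVideo)),
      house = rep(videoTable$house, each = nObjectsPerVideo),
      video = rep(videoTable$video, each = nObjectsPerVideo)
    )

    shown <- split(videoTable$video[videoTable$shown],
                   videoTable$house[videoTable$shown])
    first <- sample(houses, 1L)
    second <- setdiff(houses, first)
    encodingOrder <- as.character(
      rbind(sample(shown[[first]]), sample(shown[[second]])))

    design <- ExperimentDesign(
      houses = houses, videoTable = videoTable,
      objectAssignment = objectAssignment, encodingOrder = encodingOrder,
      listsPerHouse = nListsPerHouse, videosShownPerHouse = nVideosShown,
      nObjectsPerVideo = nObjectsPerVideo)
    validObject(design)

    ## -- test-phase layout: stratify old items by house across runs -------
    old <- objectAssignment[objectAssignment$video %in%
                              videoTable$video[videoTable$shown], ]
    runOf <- integer(nrow(old))
    for (h in houses) {
      idx <- sample(which(old$house == h))
      runOf[idx] <- rep_len(seq_len(nRuns), length(idx))
    }
    oldCounts <- tabulate(runOf, nRuns)
    newCounts <- runSize - oldCounts
    if (any(newCounts < 0))
      stopf("run size %d too small for stratified old trials", runSize)
    if (sum(newCounts) != nNew)
      stopf("internal error: new-item run allocation inconsistent")

    newObjects <- sprintf("new%03d", seq_len(nNew))
    newRun <- rep(seq_len(nRuns), newCounts)[sample.int(nNew)]

    trials <- rbind(
      data.frame(run = runOf, object = old$object, is_old = TRUE,
                 house = old$house, video = old$video),
      data.frame(run = newRun, object = newObjects, is_old = FALSE,
                 house = NA_character_, video = NA_character_)
    )
    trials <- trials[order(trials$run, sample.int(nrow(trials))), ]
    trials$trial_index <- seq_len(nrow(trials))
    trials$trial_id <- sprintf("trial%03d", trials$trial_index)
    trials$response <- NA_character_
    trials$source_correct <- NA
    trials$rt <- NA_real_
    rownames(trials) <- NULL
    trials <- trials[, c("trial_id", "trial_index", "run", "object",
                         "is_old", "house", "video", "response",
                         "source_correct", "rt")]
    list(design = design, trials = trials)
  })
}

#' Simulate recognition responses, source memory and reaction times
#'
#' Each old trial draws a response among "remember", "familiar" and "new"
#' (miss) with the configured hit probabilities; each new trial is a correct
#' rejection with probability \code{pCorrectRejection}, otherwise a false
#' alarm split between "remember" and "familiar". Post-scan house source
#' correctness is drawn conditional on the response (higher after
#' "remember" than "familiar", as observed empirically), and reaction times
#' come from a log-normal truncated to the (0, 3] s response window.
#'
#' @param trials a trial table from \code{\link{generateDesign}} with
#'   responses not yet assigned.
#' @param params a \linkS4class{BehaviorParams}.
#' @param seed RNG seed.
#' @return the trial table with \code{response}, \code{source_correct} and
#'   \code{rt} filled in (\code{source_correct} is \code{NA} for new items).
#' @export
simulateBehavior <- function(trials, params = BehaviorParams(), seed = 1) {
  validObject(params)
  if (!all(is.na(trials$response)))
    stopf("responses already assigned; simulateBehavior expects a fresh table")
  .withSeed(seed, {
    n <- nrow(trials)
    old <- trials$is_old
    resp <- character(n)

    u <- runif(sum(old))
    pR <- params@pRememberHit
    pF <- params@pFamiliarHit
    resp[old] <- ifelse(u < pR, "remember",
                        ifelse(u < pR + pF, "familiar", "new"))

    uNew <- runif(sum(!old))
    fa <- runif(sum(!old)) < params@pRememberFalseAlarm
    resp[!old] <- ifelse(uNew < params@pCorrectRejection, "new",
                         ifelse(fa, "remember", "familiar"))

    src <- rep(NA, n)
    pSrc <- rep(NA_real_, n)
    pSrc[old & resp == "remember"] <- params@pSourceGivenRemember
    pSrc[old & resp == "familiar"] <- params@pSourceGivenFamiliar
    pSrc[old & resp == "new"] <- params@pSourceGivenMiss
    src[old] <- runif(sum(old)) < pSrc[old]

    rt <- rlnorm(n, params@rtMeanlog, params@rtSdlog)
    for (k in seq_len(50)) {
      bad <- rt > params@rtMax
      if (!any(bad)) break
      rt[bad] <- rlnorm(sum(bad), params@rtMeanlog, params@rtSdlog)
    }
    rt <- pmin(rt, params@rtMax)

    trials$response <- resp
    trials$source_correct <- src
    trials$rt <- rt
    trials
  })
}

#' Filter trials eligible for pattern-similarity analysis
#'
#' Keeps only old trials with a correct "remember" response \emph{and} a
#' correct post-scan house source judgment — the recollection-plus-source
#' gate applied before any trial pair enters the similarity analyses.
#'
#' @param trials a trial table with responses assigned.
#' @return the eligible subset, original order preserved (possibly empty,
#'   with a message).
#' @export
eligibleTrials <- function(trials) {
  if (all(is.na(trials$response)))
    stopf("responses not assigned; run simulateBehavior first")
  keep <- trials$is_old & trials$response == "remember" &
    !is.na(trials$source_correct) & trials$source_correct
  out <- trials[keep, , drop = FALSE]
  if (nrow(out) == 0L)
    message("eligibleTrials: no trials pass the remember + source filter")
  out
}

#' Write / read a BIDS-style events table
#'
#' Serializes the trial table as a tab-separated events file with columns
#' \code{onset, duration, run, object_id, is_old, house, video, response,
#' source_correct, rt}. Onsets/durations are filled from \code{onsets} when
#' available (e.g. from \code{\link{simulateBold}}), otherwise written as
#' "n/a".
#'
#' @param trials a trial table.
#' @param path file path.
#' @param onsets optional named list mapping run to onset vectors (s).
#' @param trialDuration stimulus duration (s) written when onsets are given.
#' @return \code{path}, invisibly.
#' @export
writeEventsTable <- function(trials, path, onsets = NULL,
                             trialDuration = 3) {
  ev <- data.frame(
    onset = NA_real_, duration = NA_real_, run = trials$run,
    object_id = trials$object, is_old = trials$is_old,
    house = trials$house, video = trials$video,
    response = trials$response, source_correct = trials$source_correct,
    rt = trials$rt)
  if (!is.null(onsets)) {
    for (r in unique(ev$run)) {
      i <- which(ev$run == r)
      ons <- onsets[[as.character(r)]]
      if (length(ons) != length(i))
        stopf("onsets for run %s have length %d, expected %d",
              r, length(ons), length(i))
      ev$onset[i] <- ons
      ev$duration[i] <- trialDuration
    }
  }
  utils::write.table(ev, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "n/a")
  invisible(path)
}

#' @rdname writeEventsTable
#' @export
readEventsTable <- function(path) {
  ev <- utils::read.delim(path, na.strings = "n/a",
                          stringsAsFactors = FALSE)
  ev$is_old <- as.logical(ev$is_old)
  ev$source_correct <- as.logical(ev$source_correct)
  ev
}
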