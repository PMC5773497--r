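# Independent oracles and small fixture builders used across the suite.
# Every oracle here is coded from first principles, independently of the
# package's implementation paths.

## Brute-force Pearson correlation between two vectors, from the raw
## definition (no stats::cor).
bruteCor <- function(a, b) {
  am <- a - sum(a) / length(a)
  bm <- b - sum(b) / length(b)
  sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
}

## Brute-force trial-by-trial correlation matrix (double loop).
bruteCorMatrix <- function(vals) {
  n <- ncol(vals)
  M <- diag(1, n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
    M[i, j] <- bruteCor(vals[, i], vals[, j])
  M
}

## Direct marginal log-likelihood of the random-intercept LMM
## y = X beta + b_subject + e,  b ~ N(0, sb^2), e ~ N(0, se^2),
## computed per subject with the closed-form determinant/inverse of
## Sigma = se^2 I + sb^2 J, then maximized with a generic optimizer.
## Serves as the independent check on the ML log-likelihood.
lmmOracleLogLik <- function(y, X, subject) {
  groups <- split(seq_along(y), subject)
  negll <- function(par) {
    p <- ncol(X)
    beta <- par[seq_len(p)]
    sb2 <- exp(par[p + 1L])
    se2 <- exp(par[p + 2L])
    ll <- 0
    for (idx in groups) {
      r <- y[idx] - X[idx, , drop = FALSE] %*% beta
      ns <- length(idx)
      denom <- se2 + ns * sb2
      quad <- (sum(r^2) - sb2 * sum(r)^2 / denom) / se2
      logdet <- (ns - 1L) * log(se2) + log(denom)
      ll <- ll - 0.5 * (ns * log(2 * pi) + logdet + quad)
    }
    -ll
  }
  p <- ncol(X)
  start <- c(stats::coef(stats::lm.fit(X, y)), log(stats::var(y) / 4),
             log(stats::var(y) / 2))
  fits <- lapply(list(start, start + 0.5, start - 0.5), function(s)
    stats::optim(s, negll, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-12)))
  -min(vapply(fits, `[[`, numeric(1), "value"))
}

## Brute-force between-run eligible pair count: enumerate all unordered
## trial pairs and apply the filters one by one.
brutePairCount <- function(runs, eligible) {
  n <- length(runs)
  count <- 0L
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n))
    if (eligible[i] && eligible[j] && runs[i] != runs[j])
      count <- count + 1L
  count
}

## Minimal unlabeled trial table (columns simulateBehavior needs), without
## going through generateDesign.
makeBareTrials <- function(nOld, nNew = 0, nRuns = 2) {
  n <- nOld + nNew
  data.frame(
    trial_id = sprintf("trial%05d", seq_len(n)),
    trial_index = seq_len(n),
    run = rep_len(seq_len(nRuns), n),
    object = sprintf("o%05d", seq_len(n)),
    is_old = rep(c(TRUE, FALSE), c(nOld, nNew)),
    house = rep(c("house1", NA_character_), c(nOld, nNew)),
    video = rep(c("house1_v01", NA_character_), c(nOld, nNew)),
    response = NA_character_, source_correct = NA, rt = NA_real_)
}

## Synthetic pair table covering the full ROI x hemisphere x condition
## factorial, with a subject random intercept and (optionally) a
## three-way-interaction-like effect pattern.
makeFactorialPairs <- function(seed, nSubj = 8, nPerCell = 4,
                               sdSubj = 0.05, sdRes = 0.1,
                               effect = 0) {
  set.seed(seed)
  conds <- c("same_video_same_house", "diff_video_same_house",
             "diff_video_diff_house")
  grid <- expand.grid(roi = c("CA1", "CA23DG"),
                      hemisphere = c("left", "right"),
                      condition = conds, rep = seq_len(nPerCell),
                      subject = sprintf("s%02d", seq_len(nSubj)),
                      stringsAsFactors = FALSE)
  b <- stats::rnorm(nSubj, 0, sdSubj)
  names(b) <- sprintf("s%02d", seq_len(nSubj))
  ## effect: episodic shift whose sign flips between ROIs, left only
  mu <- with(grid, ifelse(
    hemisphere == "left" & condition == "same_video_same_house",
    ifelse(roi == "CA1", effect, -effect), 0))
  grid$similarity <- mu + b[grid$subject] +
    stats::rnorm(nrow(grid), 0, sdRes)
  grid$rt_diff <- abs(stats::rnorm(nrow(grid), 0.5, 0.3))
  grid$trial_i <- sprintf("trial%05d", seq_len(nrow(grid)))
  grid$trial_j <- sprintf("trial%05d", nrow(grid) + seq_len(nrow(grid)))
  grid
}

## Two-condition pair table with a known condition shift (episodic-style
## labels), used for contrast direction and null-calibration checks.
makeContrastPairs <- function(seed, nSubj = 12, nPer = 20, delta = 0,
                              sdSubj = 0.05, sdRes = 0.1,
                              rtEffect = 0) {
  set.seed(seed)
  subj <- rep(sprintf("s%02d", seq_len(nSubj)), each = 2 * nPer)
  b <- rep(stats::rnorm(nSubj, 0, sdSubj), each = 2 * nPer)
  condition <- rep(rep(c("same_video_same_house", "diff_video_same_house"),
                       each = nPer), nSubj)
  rt_diff <- abs(stats::rnorm(length(subj), 0.5, 0.3))
  data.frame(
    subject = subj, roi = "CA1", hemisphere = "left",
    condition = condition,
    similarity = b + delta * (condition == "same_video_same_house") +
      rtEffect * rt_diff + stats::rnorm(length(subj), 0, sdRes),
    rt_diff = rt_diff)
}

## Small seeded multi-subject dataset generated through the package's own
## subject-level simulator, for controls and end-to-end checks.
makeStudy <- function(seed, nSubjects = 6, rois = NULL, nVoxels = 60) {
  cfg <- defaultPipelineConfig(nSubjects = nSubjects)
  if (is.null(rois))
    rois <- list(ROISpec(name = "CA1", hemisphere = "left",
                         nVoxels = nVoxels, regime = "integrative"))
  cfg$rois <- rois
  subj <- sprintf("s%02d", seq_len(nSubjects))
  dat <- lapply(seq_along(subj), function(i)
    simulateSubject(subj[i], cfg, seed = seed + 13L * i, rois = rois))
  names(dat) <- subj
  list(config = cfg, data = dat,
       pairs = do.call(rbind, c(lapply(dat, `[[`, "pairs"),
                                list(make.row.names = FALSE))))
}
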