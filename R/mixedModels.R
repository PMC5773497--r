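## Convergence check for a lmerMod: no lme4 convergence warnings recorded.
.lmmConverged <- function(fit) {
  cc <- fit@optinfo$conv
  ok <- is.null(cc$opt) || cc$opt == 0L
  msgs <- cc$lme4$messages
  ok && (is.null(msgs) ||
           all(grepl("boundary|singular", msgs, ignore.case = TRUE)))
}

#' Fit a linear mixed model on pair-level similarities
#'
#' Thin wrapper around \code{lme4::lmer} that enforces maximum-likelihood
#' estimation (required for valid fixed-effect likelihood-ratio tests),
#' checks that a random subject intercept is identifiable (>= 2 subjects),
#' and retries from a few alternative starting values when the optimizer
#' reports non-convergence.
#'
#' @param pairs a pair table (or any data.frame with the model variables
#'   and a \code{subject} column).
#' @param formula an lme4 model formula, e.g.
#'   \code{similarity ~ condition + (1 | subject)}.
#' @param nStarts number of extra seeded starts on non-convergence.
#' @return a fitted \code{lmerMod} (ML). Attribute \code{"converged"}
#'   records the convergence status.
#' @export
fitLmm <- function(pairs, formula = similarity ~ condition + (1 | subject),
                   nStarts = 3) {
  if (!"subject" %in% names(pairs)) stopf("pairs must have a 'subject' column")
  nSubj <- length(unique(pairs$subject))
  if (nSubj < 2L)
    stopf("random subject intercept unidentifiable with %d subject(s)", nSubj)
  vars <- all.vars(formula)
  for (v in vars) {
    if (!v %in% names(pairs)) stopf("model variable '%s' not in data", v)
    lv <- pairs[[v]]
    if (is.character(lv) || is.factor(lv)) {
      if (length(unique(lv)) < 2L && v != "subject")
        stopf("factor '%s' has a single observed level", v)
    }
  }
  fit <- suppressMessages(
    lme4::lmer(formula, data = pairs, REML = FALSE,
               control = lme4::lmerControl(calc.derivs = FALSE)))
  k <- 0L
  while (!.lmmConverged(fit) && k < nStarts) {
    k <- k + 1L
    st <- lme4::getME(fit, "theta") * (0.5 * k + 0.25)
    fit2 <- try(suppressMessages(
      lme4::lmer(formula, data = pairs, REML = FALSE, start = st,
                 control = lme4::lmerControl(calc.derivs = FALSE))),
      silent = TRUE)
    if (!inherits(fit2, "try-error")) fit <- fit2
  }
  attr(fit, "converged") <- .lmmConverged(fit)
  fit
}

#' Chi-squared likelihood-ratio test between nested ML mixed models
#'
#' \code{chi2 = 2 (LL_full - LL_reduced)} clamped at zero, with degrees of
#' freedom equal to the difference in estimated parameter counts and an
#' upper-tail chi-squared p-value.
#'
#' @param full,reduced nested \code{lmerMod} fits on identical rows, both
#'   fitted by maximum likelihood.
#' @return an \linkS4class{LRTResult}.
#' @export
likelihoodRatioTest <- function(full, reduced) {
  for (m in list(full, reduced))
    if (lme4::isREML(m))
      stopf("REML fits are not valid for fixed-effect LRTs; refit with ML")
  nFull <- stats::nobs(full)
  if (nFull != stats::nobs(reduced))
    stopf("models were fitted to different numbers of rows (%d vs %d)",
          nFull, stats::nobs(reduced))
  llF <- stats::logLik(full)
  llR <- stats::logLik(reduced)
  df <- as.integer(attr(llF, "df") - attr(llR, "df"))
  if (df < 0L) stopf("models are not nested (full must add parameters)")
  .conv <- function(m) {
    a <- attr(m, "converged")
    if (is.null(a)) .lmmConverged(m) else isTRUE(a)
  }
  convF <- .conv(full)
  convR <- .conv(reduced)
  if (!convF || !convR)
    stopf("refusing LRT on non-converged fit(s)")
  chi2 <- max(0, 2 * (as.numeric(llF) - as.numeric(llR)))
  ## df = 0 only for identical specifications: nothing to test, p = 1
  p <- if (df == 0L) 1 else pchisq(chi2, df, lower.tail = FALSE)
  LRTResult(chi2 = chi2, df = df, p = p,
            nObs = as.integer(nFull), converged = convF && convR)
}

.requireLevels <- function(pairs, var, levels) {
  have <- unique(as.character(pairs[[var]]))
  miss <- setdiff(levels, have)
  if (length(miss))
    stopf("missing %s level(s): %s", var, paste(miss, collapse = ", "))
}

#' Omnibus ROI x condition x hemisphere interaction test
#'
#' Fits the full factorial model
#' \code{similarity ~ roi * condition * hemisphere + (1 | subject)} on the
#' CA1/CA23DG pairs and compares it against the model omitting the
#' three-way interaction. With 2 ROIs, 3 conditions and 2 hemispheres the
#' test has 2 degrees of freedom by construction.
#'
#' @param pairs a pair table spanning both ROIs, both hemispheres and all
#'   three context conditions.
#' @param rois the two ROIs entering the factorial model.
#' @return an \linkS4class{LRTResult}.
#' @export
omnibusInteractionTest <- function(pairs, rois = c("CA1", "CA23DG")) {
  pairs <- pairs[pairs$roi %in% rois, , drop = FALSE]
  .requireLevels(pairs, "roi", rois)
  .requireLevels(pairs, "hemisphere", c("left", "right"))
  .requireLevels(pairs, "condition",
                 c("same_video_same_house", "diff_video_same_house",
                   "diff_video_diff_house"))
  pairs$condition <- factor(pairs$condition,
                            levels = c("diff_video_diff_house",
                                       "diff_video_same_house",
                                       "same_video_same_house"))
  full <- fitLmm(pairs,
                 similarity ~ roi * condition * hemisphere + (1 | subject))
  reduced <- fitLmm(pairs,
                    similarity ~ (roi + condition + hemisphere)^2 +
                      (1 | subject))
  likelihoodRatioTest(full, reduced)
}

#' Episodic or spatial context contrast within one ROI and hemisphere
#'
#' The episodic contrast compares same-video/same-house against
#' different-video/same-house pairs; the spatial contrast compares
#' same-house (excluding same-video pairs) against different-house pairs.
#' Both are 1-df likelihood-ratio tests of the condition effect in a
#' random-subject-intercept model, with treatment coding whose reference
#' level is the less-similar-context condition, so a positive coefficient
#' means greater similarity for the shared context.
#'
#' @param pairs a pair table.
#' @param roi,hemisphere cell to analyze.
#' @param contrast \code{"episodic"} or \code{"spatial"}.
#' @return list with \code{lrt} (\linkS4class{LRTResult}),
#'   \code{direction} (sign of the condition coefficient),
#'   \code{estimate} (the coefficient), \code{term}, \code{n}.
#' @export
conditionContrast <- function(pairs, roi, hemisphere,
                              contrast = c("episodic", "spatial")) {
  contrast <- match.arg(contrast)
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
  sub$condition <- factor(sub$condition, levels = lev)
  full <- fitLmm(sub, similarity ~ condition + (1 | subject))
  reduced <- fitLmm(sub, similarity ~ 1 + (1 | subject))
  est <- unname(lme4::fixef(full)[2L])
  list(lrt = likelihoodRatioTest(full, reduced),
       direction = sign(est), estimate = est,
       term = paste0("condition", lev[2L]), n = nrow(sub))
}

#' Paired t-test with Dunlap-corrected Cohen's d
#'
#' Standard paired t-test on per-subject condition means, with the effect
#' size corrected for the correlation between the paired means:
#' \code{d = t * sqrt(2 (1 - r) / n)}, where \code{r} is the Pearson
#' correlation between the two sets of means.
#'
#' @param x,y paired per-subject means (equal length, n >= 3).
#' @return list with \code{t}, \code{df}, \code{p}, \code{d}, \code{r}.
#' @export
pairedTDunlap <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stopf("x and y must have equal length")
  if (n < 3L) stopf("need n >= 3 pairs")
  if (sd(x - y) == 0) {
    if (all(x == y))     # identical conditions: no effect by definition
      return(list(t = 0, df = n - 1L, p = 1, d = 0, r = cor(x, y)))
    stopf("zero-variance differences; t statistic undefined")
  }
  tt <- t.test(x, y, paired = TRUE)
  r <- cor(x, y)
  tval <- unname(tt$statistic)
  list(t = tval, df = unname(tt$parameter), p = tt$p.value,
       d = tval * sqrt(2 * (1 - r) / n), r = r)
}
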