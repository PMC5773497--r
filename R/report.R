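.fmtLrt <- function(x) {
  if (is(x, "LRTResult"))
    sprintf("chi2(%d) = %.2f, p = %.4g", x@df, x@chi2, x@p)
  else if (is.list(x) && is(x$lrt, "LRTResult"))
    sprintf("chi2(%d) = %.2f, p = %.4g, direction = %+d", x$lrt@df,
            x$lrt@chi2, x$lrt@p, as.integer(x$direction))
  else sprintf("unavailable (%s)", as.character(x)[1L])
}

#' Summarize a pipeline result bundle as a text report
#'
#' Tables of behavioral rates, the omnibus interaction test, every
#' ROI x hemisphere x contrast likelihood-ratio test, condition-mean
#' similarities (the bar-plot data), and control-analysis summaries.
#' Missing stages are flagged as skipped rather than failing.
#'
#' @param bundle a result bundle from \code{\link{runPipeline}}.
#' @param print print the report to the console.
#' @return the report lines, invisibly.
#' @export
makeReport <- function(bundle, print = TRUE) {
  ln <- character()
  add <- function(...) ln <<- c(ln, sprintf(...))
  add("subfieldRSA pipeline report")
  add("===========================")
  add("subjects: %d   master seed: %s", length(bundle$subjects),
      format(bundle$seed))
  add("")

  if (!is.null(bundle$behavior)) {
    g <- bundle$behavior$groupMeans
    add("Behavior (group means)")
    add("  remember hit rate:     %.3f", g[["rememberHit"]])
    add("  familiar hit rate:     %.3f", g[["familiarHit"]])
    add("  correct rejections:    %.3f", g[["correctRejection"]])
    add("  source memory hits:    %.3f", g[["sourceHit"]])
    add("  eligible trials/subj:  %.1f", g[["nEligible"]])
    if (!is.null(bundle$behavior$rememberByHouse)) {
      bh <- bundle$behavior$rememberByHouse
      add("  remember rate by house: t(%d) = %.2f, p = %.3f, d = %.3f",
          bh$df, bh$t, bh$p, bh$d)
    }
  } else add("Behavior: skipped")
  add("")

  add("Omnibus ROI x condition x hemisphere interaction")
  add("  %s", if (is.null(bundle$omnibus)) "skipped"
      else .fmtLrt(bundle$omnibus))
  add("")

  add("Context contrasts (LRT per ROI x hemisphere)")
  if (length(bundle$contrasts)) {
    for (key in names(bundle$contrasts))
      add("  %-26s %s", key, .fmtLrt(bundle$contrasts[[key]]))
  } else add("  skipped")
  add("")

  if (!is.null(bundle$conditionMeans)) {
    cm <- bundle$conditionMeans
    add("Condition-mean similarity (bar data)")
    for (i in seq_len(nrow(cm)))
      add("  %-8s %-6s %-24s %+.4f", cm$roi[i], cm$hemisphere[i],
          cm$condition[i], cm$similarity[i])
    add("")
  }

  add("Control analyses")
  if (is.null(bundle$controls)) {
    add("  skipped")
  } else {
    ctl <- bundle$controls
    if (!is.null(ctl$subsample) && is(ctl$subsample, "ControlResult")) {
      s <- ctl$subsample@summary
      add("  matched subsampling: %.3f of %d replicates significant",
          s$fractionSignificant, length(ctl$subsample@replicates))
    } else add("  matched subsampling: skipped")
    if (length(ctl$voxelDrop)) {
      for (key in names(ctl$voxelDrop)) {
        v <- ctl$voxelDrop[[key]]
        if (is(v, "ControlResult"))
          add("  voxel drop %-34s direction preserved: %s", key,
              v@summary$directionPreserved)
        else add("  voxel drop %-34s skipped", key)
      }
    }
    if (length(ctl$rtControl)) {
      for (key in names(ctl$rtControl))
        add("  RT covariate %-32s %s", key, .fmtLrt(ctl$rtControl[[key]]))
    }
  }

  if (print) cat(paste(ln, collapse = "\n"), "\n")
  invisible(ln)
}

#' Histogram of replicate chi-squared statistics
#'
#' Quick look at the distribution of the subsampling control's replicate
#' statistics.
#'
#' @param control a \linkS4class{ControlResult} from
#'   \code{\link{matchedSubsampleTest}}.
#' @param ... passed to \code{\link[graphics]{hist}}.
#' @return the histogram object, invisibly.
#' @export
plotReplicateChi2 <- function(control, ...) {
  chi2 <- vapply(control@replicates, `[[`, numeric(1), "chi2")
  invisible(graphics::hist(chi2, main = "Subsampling replicates",
                           xlab = expression(chi^2), ...))
}

#' Write a pipeline result bundle to disk
#'
#' Writes \code{pairs.tsv} (the pair table), \code{report.txt},
#' \code{results.json} (LRT statistics and condition means) and
#' \code{manifest.json} into \code{dir}.
#'
#' @param bundle a result bundle from \code{\link{runPipeline}}.
#' @param dir output directory (created if absent).
#' @return \code{dir}, invisibly.
#' @export
writeResultBundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  writePairTable(bundle$pairs, file.path(dir, "pairs.tsv"))
  writeLines(makeReport(bundle, print = FALSE),
             file.path(dir, "report.txt"))
  lrtJson <- function(x) {
    if (is(x, "LRTResult"))
      list(chi2 = x@chi2, df = x@df, p = x@p, n_obs = x@nObs)
    else if (is.list(x) && is(x$lrt, "LRTResult"))
      list(chi2 = x$lrt@chi2, df = x$lrt@df, p = x$lrt@p,
           direction = x$direction, estimate = x$estimate, n = x$n)
    else list(error = as.character(x)[1L])
  }
  res <- list(
    omnibus = if (is.null(bundle$omnibus)) NULL else lrtJson(bundle$omnibus),
    contrasts = lapply(bundle$contrasts, lrtJson),
    behavior = as.list(bundle$behavior$groupMeans),
    condition_means = bundle$conditionMeans)
  jsonlite::write_json(res, file.path(dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
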