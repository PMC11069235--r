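.checkSameChroms <- function(a, b) {
  if (!identical(names(a), names(b)) ||
      !identical(lengths(a), lengths(b)))
    stop("tracks are defined on different chromosome declarations")
}

#' Subtract a background control track
#'
#' Removes the non-specific signal measured in a control immunoprecipitation
#' (a no-tag strain for epitope-tag antibodies, or a deletion strain lacking
#' the target protein) by per-base subtraction.  Both tracks must already be
#' spike-in normalized (RPM) and declared on identical chromosomes.  The one
#' control track is subtracted from each replicate before replicates are
#' averaged; with clamping on, subtraction and averaging do not commute, so
#' that order is fixed.
#'
#' @param signal,control RPM [CoverageTrack-class] objects.
#' @param clamp Set negative residuals to zero (default `TRUE`, appropriate
#'   for heatmap/metagene tracks; use `FALSE` where near-zero occupancy may
#'   legitimately go slightly negative, e.g. scatter quantities).
#' @return A [CorrectedTrack-class].
#' @export
subtractBackground <- function(signal, control, clamp = TRUE) {
  stopifnot(is(signal, "CoverageTrack"), is(control, "CoverageTrack"))
  if (trackUnits(signal) != "RPM" || trackUnits(control) != "RPM")
    stop("both tracks must be in RPM units before subtraction")
  .checkSameChroms(trackSignal(signal), trackSignal(control))
  diff <- trackSignal(signal) - trackSignal(control)
  if (clamp)
    diff <- S4Vectors::endoapply(diff, function(x) {
      runValue(x)[runValue(x) < 0] <- 0
      x
    })
  new("CorrectedTrack", sampleId = sampleId(signal), signal = diff,
      units = "RPM", scaleFactor = scaleFactor(signal),
      controlId = sampleId(control), clamped = clamp)
}

#' Average replicate tracks
#'
#' Arithmetic per-base mean of two or more tracks with identical units and
#' chromosome declarations — the replicate-combining step applied after
#' background subtraction.
#'
#' @param tracks List of [CoverageTrack-class] (or [CorrectedTrack-class])
#'   objects, length >= 2.
#' @return A track of the same class as the inputs.
#' @export
averageReplicates <- function(tracks) {
  if (!is.list(tracks) || length(tracks) < 2)
    stop("need a list of at least two tracks")
  if (!all(vapply(tracks, is, logical(1), "CoverageTrack")))
    stop("all elements must be CoverageTrack objects")
  units <- vapply(tracks, trackUnits, character(1))
  if (length(unique(units)) != 1)
    stop("cannot average tracks with mixed units: ",
         paste(unique(units), collapse = ", "))
  for (t in tracks[-1])
    .checkSameChroms(trackSignal(tracks[[1]]), trackSignal(t))
  mean <- Reduce(`+`, lapply(tracks, trackSignal)) / length(tracks)
  ids <- paste(vapply(tracks, sampleId, character(1)), collapse = "+")
  allCorr <- all(vapply(tracks, is, logical(1), "CorrectedTrack"))
  if (allCorr) {
    new("CorrectedTrack", sampleId = ids, signal = mean, units = units[1],
        scaleFactor = 1,
        controlId = paste(unique(vapply(tracks, function(t) t@controlId,
                                        character(1))), collapse = "+"),
        clamped = all(vapply(tracks, function(t) t@clamped, logical(1))))
  } else {
    new("CoverageTrack", sampleId = ids, signal = mean, units = units[1],
        scaleFactor = if (units[1] == "raw") 1 else
          mean(vapply(tracks, scaleFactor, numeric(1))))
  }
}

#' Replicate pipeline: normalize, subtract, average
#'
#' The full per-condition track recipe: spike-in normalize each replicate,
#' subtract the (single, shared) normalized control from each, then average.
#'
#' @param replicates List of [ReadSet-class] replicates of one condition.
#' @param control A [ReadSet-class] for the background control.
#' @param chromSizes Experiment-genome chromosome lengths.
#' @param clamp Passed to [subtractBackground()].
#' @return A [CorrectedTrack-class] (replicate average).
#' @export
correctedConditionTrack <- function(replicates, control, chromSizes,
                                    clamp = TRUE) {
  ctrl <- spikeinNormalizedTrack(control, chromSizes)
  corr <- lapply(replicates, function(rs)
    subtractBackground(spikeinNormalizedTrack(rs, chromSizes), ctrl,
                       clamp = clamp))
  if (length(corr) == 1) corr[[1]] else averageReplicates(corr)
}
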