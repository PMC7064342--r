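#' Delta-F/F from raw fluorescence with a sliding-percentile baseline
#'
#' `signal = raw - neuropil` (when a neuropil trace is given); the baseline
#' `F0(t)` is a low percentile of the signal inside a centered sliding time
#' window (truncated at the trace edges); `dff = (signal - F0) / F0`.
#' Somatic ROIs conventionally use the 5th percentile, axonal boutons the
#' 50th (their baseline is a larger fraction of the trace).
#'
#' @param raw numeric vector or ROI x frame matrix of raw fluorescence.
#' @param neuropil optional matching neuropil ("donut") fluorescence.
#' @param frameRate frames per second.
#' @param windowS sliding window length in seconds (default 60).
#' @param percentile baseline percentile in `[0, 1]` (default 0.05).
#' @return delta-F/F with the same shape as `raw`.
#' @export
computeDff <- function(raw, neuropil = NULL, frameRate, windowS = 60,
                       percentile = 0.05) {
    if (is.matrix(raw)) {
        out <- raw
        for (i in seq_len(nrow(raw)))
            out[i, ] <- computeDff(raw[i, ],
                                   if (!is.null(neuropil)) neuropil[i, ],
                                   frameRate, windowS, percentile)
        return(out)
    }
    sig <- if (is.null(neuropil)) raw else raw - neuropil
    if (any(!is.finite(sig)))
        stop("non-finite fluorescence at frames: ",
             paste(utils::head(which(!is.finite(sig)), 5), collapse = ", "))
    n <- length(sig)
    half <- floor(windowS * frameRate / 2)
    f0 <- numeric(n)
    for (i in seq_len(n)) {
        lo <- max(1L, i - half)
        hi <- min(n, i + half)
        f0[i] <- stats::quantile(sig[lo:hi], percentile, names = FALSE,
                                 type = 7)
    }
    bad <- which(f0 <= 0)
    if (length(bad))
        stop("baseline F0 not positive at frames: ",
             paste(utils::head(bad, 5), collapse = ", "))
    (sig - f0) / f0
}

## baseline sample of a trace: the lowest `frac` of data points; the
## transient threshold is its mean + kSd * its s.d.
.baselineStats <- function(dff, frac = 0.7) {
    base <- dff[dff <= stats::quantile(dff, frac, names = FALSE)]
    list(mean = mean(base), sd = stats::sd(base))
}

## Shared event finder with hysteresis: a transient must exceed `thr_high`
## for at least `min_len` consecutive non-missing samples, and extends while
## the signal stays above `thr_rel` (release threshold). Without the release
## rule a noisy dip near threshold inside a decaying transient tail would
## split one event into several. Missing samples (unvisited bins) never
## count toward the qualifying high run, but do not terminate an ongoing
## event either — at high running speed single spatial bins can be skipped
## mid-transient.
.hysteresisRuns <- function(x, thr_high, thr_rel, min_len) {
    rel <- is.na(x) | x > thr_rel
    r <- rle(rel)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    out <- list()
    for (k in which(r$values)) {
        seg <- starts[k]:ends[k]
        high <- !is.na(x[seg]) & x[seg] > thr_high
        hr <- rle(high)
        if (!any(hr$values & hr$lengths >= min_len)) next
        pk <- seg[which.max(x[seg])]
        out[[length(out) + 1L]] <- c(onset = starts[k], offset = ends[k],
                                     peak = pk, peak_val = x[pk])
    }
    if (!length(out))
        return(data.frame(onset = integer(), offset = integer(),
                          peak = integer(), peak_val = numeric()))
    as.data.frame(do.call(rbind, out))
}

#' Detect calcium transients in the time domain
#'
#' A transient is a contiguous run of frames where delta-F/F exceeds
#' `kSd` standard deviations of the trace's baseline activity for at least
#' `minDurS` seconds. The baseline sample is the lowest 70% of data points
#' (`baseline = "lower70"`); thresholding is relative to the baseline mean,
#' so adding a constant to the trace does not change the result.
#'
#' @param dff numeric delta-F/F vector of one ROI.
#' @param frameRate frames per second.
#' @param kSd threshold in baseline standard deviations (default 6).
#' @param minDurS minimum duration in seconds (default 0.5); converted to
#'   frames by ceiling.
#' @param kRelease release threshold in baseline standard deviations
#'   (default 2): an event extends, without splitting, while the signal
#'   stays above this level.
#' @param baseline `"lower70"` (s.d. over the lowest 70% of points) or
#'   `"full"` (s.d. over the whole trace).
#' @return data.frame with one row per transient: `onset`, `offset` (frame
#'   indices), `peak_frame`, `peak_dff`.
#' @export
detectTransientsTime <- function(dff, frameRate, kSd = 6, minDurS = 0.5,
                                 kRelease = 2,
                                 baseline = c("lower70", "full")) {
    baseline <- match.arg(baseline)
    min_frames <- ceiling(minDurS * frameRate)
    if (length(dff) < min_frames)
        stop("trace shorter than the minimum transient duration")
    bs <- if (baseline == "lower70") .baselineStats(dff)
          else list(mean = mean(dff), sd = stats::sd(dff))
    thr <- bs$mean + kSd * bs$sd
    thr_rel <- bs$mean + kRelease * bs$sd
    runs <- .hysteresisRuns(dff, thr, thr_rel, min_frames)
    data.frame(onset = as.integer(runs$onset),
               offset = as.integer(runs$offset),
               peak_frame = as.integer(runs$peak),
               peak_dff = runs$peak_val)
}

#' Transient rate of each ROI (transients per minute)
#'
#' Convenience wrapper used by the activity prefilter (`> 0.5` transients per
#' minute).
#'
#' @param session a [LandmarkSession-class].
#' @param rois ROI indices or ids (default all).
#' @inheritParams detectTransientsTime
#' @return numeric vector of rates.
#' @export
transientRate <- function(session, rois = NULL, kSd = 6, minDurS = 0.5) {
    if (is.null(rois)) rois <- seq_len(nRois(session))
    rois <- .resolveRois(session, rois)
    dff <- dffMatrix(session)
    minutes <- ncol(session) / frameRate(session) / 60
    vapply(rois, function(i)
        nrow(detectTransientsTime(dff[i, ], frameRate(session), kSd,
                                  minDurS)) / minutes,
        numeric(1))
}

#' Detect calcium transients in anchor-aligned space
#'
#' Bins each trial's delta-F/F into `binCm` spatial bins of anchor-aligned
#' distance and detects runs of at least `minBins` consecutive bins above
#' `kSd` standard deviations of the neuron's baseline activity (lowest 70%
#' of the session's delta-F/F points). Unvisited bins break runs. Transients
#' whose peak lies outside `+- windowCm` of the neuron's mean-trace peak
#' during virtual navigation are excluded.
#'
#' @inheritParams meanAlignedTrace
#' @param vrMeanPeak the neuron's mean-trace peak location (cm, aligned)
#'   during virtual navigation.
#' @param binCm spatial bin width (default 2).
#' @param kSd threshold in baseline standard deviations (default 6).
#' @param minBins minimum run length in bins (default 2).
#' @param kRelease release threshold in baseline standard deviations
#'   (default 2; see [detectTransientsTime()]).
#' @param windowCm inclusion window around `vrMeanPeak` (default 60).
#' @return data.frame with one row per transient: `trial_id`,
#'   `peak_dist_cm`, `peak_dff`, `onset_cm`, `offset_cm`.
#' @export
detectTransientsSpatial <- function(session, roi, anchor, vrMeanPeak,
                                    binCm = 2, kSd = 6, minBins = 2,
                                    kRelease = 2, windowCm = 60,
                                    trialType = NULL,
                                    landmarkRef = "onset") {
    ab <- alignedBinnedActivity(session, rois = roi, anchor = anchor,
                                binCm = binCm, trialType = trialType,
                                landmarkRef = landmarkRef)
    act <- ab$activity[, , 1, drop = FALSE]
    dim(act) <- dim(ab$activity)[1:2]
    roi <- .resolveRois(session, roi)
    bs <- .baselineStats(dffMatrix(session)[roi, ])
    thr <- bs$mean + kSd * bs$sd
    thr_rel <- bs$mean + kRelease * bs$sd
    res <- list()
    for (i in seq_len(nrow(act))) {
        runs <- .hysteresisRuns(act[i, ], thr, thr_rel, minBins)
        if (!nrow(runs)) next
        res[[length(res) + 1L]] <- data.frame(
            trial_id = ab$trial_ids[i],
            peak_dist_cm = ab$centers[runs$peak],
            peak_dff = runs$peak_val,
            onset_cm = ab$centers[runs$onset],
            offset_cm = ab$centers[runs$offset])
    }
    out <- if (length(res)) do.call(rbind, res)
           else data.frame(trial_id = integer(), peak_dist_cm = numeric(),
                           peak_dff = numeric(), onset_cm = numeric(),
                           offset_cm = numeric())
    out[abs(out$peak_dist_cm - vrMeanPeak) <= windowCm, , drop = FALSE]
}

#' Summary statistics of a neuron's spatial transients
#'
#' @param transients output of [detectTransientsSpatial()].
#' @param nTrials number of trials the transients were detected over.
#' @param vrMeanPeak the neuron's VR mean-trace peak location (cm).
#' @param sessionMinutes optional session duration for `rate_per_min`.
#' @return list with `transients_per_trial`, `mean_amplitude`, `jitter_cm`
#'   (standard error of the transient-peak distance from the mean peak),
#'   `robustness` (fraction of trials with at least one in-window
#'   transient), `n_transients`, and `rate_per_min` when `sessionMinutes`
#'   is given. Amplitude and jitter are `NA` when no transients exist.
#' @export
transientStats <- function(transients, nTrials, vrMeanPeak,
                           sessionMinutes = NULL) {
    n <- nrow(transients)
    d <- transients$peak_dist_cm - vrMeanPeak
    list(
        transients_per_trial = n / nTrials,
        mean_amplitude = if (n) mean(transients$peak_dff) else NA_real_,
        jitter_cm = if (n > 1) stats::sd(d) / sqrt(n) else NA_real_,
        robustness = length(unique(transients$trial_id)) / nTrials,
        n_transients = n,
        rate_per_min = if (is.null(sessionMinutes)) NA_real_
                       else n / sessionMinutes)
}
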