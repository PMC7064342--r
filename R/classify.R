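## Internal: peaks of the coverage-masked mean trace for shifted copies of a
## dff vector. `aw` comes from .alignWeights(); `offsets` are circular frame
## shifts (0 = unshifted).
.shiftedPeaks <- function(dff, aw, offsets) {
    n <- length(dff)
    k <- length(offsets)
    idx <- ((rep(seq_len(n), times = k) -
             rep(offsets, each = n) - 1L) %% n) + 1L
    S <- matrix(dff[idx], n, k)
    M <- as.matrix(aw$W %*% S)
    apply(M[aw$valid, , drop = FALSE], 2, max)
}

#' Shuffle-based peak z-score of a neuron's mean aligned trace
#'
#' Builds a null distribution by circularly shifting the neuron's delta-F/F
#' time course relative to behavior by a uniform random offset (`nShuffles`
#' times, minimum shift `minShiftS` seconds to avoid near-identity
#' shuffles), recomputing the peak of the coverage-masked mean aligned trace
#' each time. Returns `(true peak - null mean) / null sd`. Circular shifting
#' preserves the trace's autocorrelation, so slow calcium dynamics do not
#' inflate the z-score.
#'
#' @inheritParams meanAlignedTrace
#' @param nShuffles number of circular shifts (default 500).
#' @param seed RNG seed.
#' @param minShiftS minimum shift in seconds (default 10).
#' @return list with `z`, `true_peak`, `null_mean`, `null_sd`.
#' @export
shufflePeakZscore <- function(session, roi,
                              anchor = c("trial_onset", "landmark",
                                         "reward"),
                              trialType = NULL, nShuffles = 500, seed = 1,
                              binCm = 5, minShiftS = 10,
                              landmarkRef = "onset") {
    anchor <- match.arg(anchor)
    aw <- .alignWeights(session, anchor, binCm, trialType,
                        landmarkRef = landmarkRef)
    roi <- .resolveRois(session, roi)
    dff <- dffMatrix(session)[roi, ]
    n <- length(dff)
    min_shift <- ceiling(minShiftS * frameRate(session))
    if (2 * min_shift >= n)
        stop("trace too short for a ", minShiftS, " s minimum shift")
    set.seed(as.integer(seed) %% .Machine$integer.max)
    offsets <- sample(seq(min_shift, n - min_shift), nShuffles,
                      replace = TRUE)
    true_peak <- .shiftedPeaks(dff, aw, 0L)
    null_peaks <- .shiftedPeaks(dff, aw, offsets)
    s <- stats::sd(null_peaks)
    if (!is.finite(s) || s == 0)
        stop("zero-variance shuffle null (constant trace?)")
    list(z = (true_peak - mean(null_peaks)) / s, true_peak = true_peak,
         null_mean = mean(null_peaks), null_sd = s)
}

#' Assign a neuron's best task anchor
#'
#' Computes the coverage-masked mean aligned trace under all three anchors
#' (trial onset, landmark, reward) and assigns the anchor whose mean trace
#' has the largest peak. Ties (equal peaks within `1e-9`) are broken with
#' priority landmark > reward > trial onset and flagged.
#'
#' @inheritParams meanAlignedTrace
#' @param trialType `"short"`, `"long"`, or `NULL` (default) to pool both
#'   trial types. Pooled assignment is the more powerful discriminator of
#'   landmark- vs reward-anchored activity: within one trial type the reward
#'   zone sits at a fixed offset from the landmark, so those two alignments
#'   differ only through per-trial reward-event variability, while pooling
#'   exploits the 120 vs 180 cm offset difference between types.
#' @return list with `category`, `peak_dist_cm`, `peak_amp`, `tie`
#'   (logical), and `peaks` (named per-anchor peak amplitudes).
#' @export
assignAlignment <- function(session, roi, trialType = NULL, binCm = 5,
                            landmarkRef = "onset", minCoverage = 0.5) {
    anchors <- c("landmark", "reward", "trial_onset")  # tie-break priority
    peaks <- peak_dist <- stats::setNames(numeric(3), anchors)
    tt <- trialTable(session)
    types <- if (is.null(trialType)) unique(tt$trial_type) else trialType
    for (a in anchors) {
        ab <- alignedBinnedActivity(session, rois = roi, anchor = a,
                                    binCm = binCm, trialType = trialType,
                                    landmarkRef = landmarkRef)
        act <- ab$activity[, , 1, drop = FALSE]
        dim(act) <- dim(ab$activity)[1:2]
        ## In pooled mode a bin must be covered within *every* trial type:
        ## regions traversed by only one type (e.g. past the short-trial
        ## reward) would otherwise escape cross-type averaging and bias the
        ## anchor comparison.
        ty <- tt$trial_type[match(ab$trial_ids, tt$trial_id)]
        valid <- rep(TRUE, ncol(act))
        for (k in types) {
            cov_k <- colMeans(!is.na(act[ty == k, , drop = FALSE]))
            valid <- valid & cov_k >= minCoverage
        }
        m <- colMeans(act, na.rm = TRUE)
        m[!valid | is.nan(m)] <- NA_real_
        if (all(is.na(m)))
            stop("all spatial bins masked under anchor '", a, "'")
        i <- which.max(m)
        peaks[a] <- m[i]
        peak_dist[a] <- ab$centers[i]
    }
    best <- which.max(peaks)  # first max wins -> priority order above
    tie <- sum(abs(peaks - peaks[best]) < 1e-9) > 1
    list(category = anchors[best], peak_dist_cm = unname(peak_dist[best]),
         peak_amp = unname(peaks[best]), tie = tie, peaks = peaks)
}

#' Task-engagement test for one neuron
#'
#' A neuron is task engaged on a trial type when all four criteria hold:
#' \enumerate{
#'   \item activity prefilter: more than 0.5 time-domain transients/min over
#'     the session;
#'   \item trial reliability: delta-F/F exceeds 3 standard deviations of the
#'     ROI's overall activity (full-session s.d., threshold relative to the
#'     full-session mean) on at least 25\% of trials;
#'   \item significance: shuffle peak z-score above 3 at the neuron's best
#'     anchor;
#'   \item effect size: the mean-trace amplitude (highest minus lowest
#'     value) exceeds 0.2 delta-F/F (0.1 for axonal boutons).
#' }
#'
#' @inheritParams shufflePeakZscore
#' @param trialType `"short"` or `"long"`.
#' @param ratePrefilter minimum transients/min (default 0.5).
#' @param zThreshold engagement z threshold (default 3).
#' @param ampThreshold mean-trace amplitude threshold; default 0.2 for
#'   somata, 0.1 for boutons (taken from the ROI's `roi_kind`).
#' @return list with `engaged`, per-criterion logicals and the underlying
#'   numbers, plus the best-anchor assignment.
#' @export
isTaskEngaged <- function(session, roi, trialType, nShuffles = 500,
                          seed = 1, binCm = 5, ratePrefilter = 0.5,
                          zThreshold = 3, ampThreshold = NULL,
                          landmarkRef = "onset") {
    roi <- .resolveRois(session, roi)
    if (is.null(ampThreshold))
        ampThreshold <- if (identical(roiInfo(session)$roi_kind[roi],
                                      "bouton")) 0.1 else 0.2
    dff <- dffMatrix(session)[roi, ]
    rate <- transientRate(session, roi)

    thr3 <- mean(dff) + 3 * stats::sd(dff)
    tr <- trialTable(session)
    tr <- tr[tr$trial_type == trialType, , drop = FALSE]
    hit <- vapply(tr$trial_id, function(id)
        any(dff[trialFrames(session, id)] > thr3), logical(1))
    frac_trials <- mean(hit)

    assign <- assignAlignment(session, roi, trialType, binCm = binCm,
                              landmarkRef = landmarkRef)
    z <- tryCatch(
        shufflePeakZscore(session, roi, assign$category,
                          trialType = trialType, nShuffles = nShuffles,
                          seed = seed, binCm = binCm,
                          landmarkRef = landmarkRef)$z,
        error = function(e) NA_real_)
    mt <- meanAlignedTrace(session, roi, assign$category, binCm = binCm,
                           trialType = trialType, landmarkRef = landmarkRef)
    amp <- diff(range(mt$mean, na.rm = TRUE))

    crit <- c(rate = rate > ratePrefilter,
              trial_fraction = frac_trials >= 0.25,
              peak_z = !is.na(z) && z > zThreshold,
              amplitude = amp > ampThreshold)
    list(engaged = all(crit), criteria = crit, rate_per_min = rate,
         trial_fraction = frac_trials, peak_z = z, mean_trace_amp = amp,
         assignment = assign)
}

#' Landmark modulation index
#'
#' `LMI = (LM_short - LM_long) / (LM_short + LM_long)` where `LM_x` is the
#' neuron's peak mean response to the respective landmark. Ranges over
#' `[-1, 1]`; 0 means no cue-identity preference.
#'
#' @param lmShort,lmLong non-negative peak responses on short / long trials.
#' @return the index, or `NA` when both peaks are zero.
#' @export
landmarkModulationIndex <- function(lmShort, lmLong) {
    stopifnot(lmShort >= 0, lmLong >= 0)
    if (lmShort + lmLong == 0) return(NA_real_)
    (lmShort - lmLong) / (lmShort + lmLong)
}

#' Classify every neuron of a session
#'
#' Runs the engagement test and anchor assignment for each ROI and trial
#' type, and computes the landmark modulation index for neurons classified
#' as landmark-aligned on at least one trial type.
#'
#' @inheritParams isTaskEngaged
#' @return data.frame with one row per ROI: engagement and category per
#'   trial type, peak location/amplitude/z, tie flags, transient rate, and
#'   `lmi`.
#' @export
classifySession <- function(session, nShuffles = 500, seed = 1, binCm = 5,
                            ratePrefilter = 0.5, zThreshold = 3,
                            landmarkRef = "onset") {
    out <- vector("list", nRois(session))
    for (i in seq_len(nRois(session))) {
        row <- list(roi_id = roiInfo(session)$roi_id[i])
        for (tt in c("short", "long")) {
            eng <- isTaskEngaged(session, i, tt, nShuffles = nShuffles,
                                 seed = seed + i, binCm = binCm,
                                 ratePrefilter = ratePrefilter,
                                 zThreshold = zThreshold,
                                 landmarkRef = landmarkRef)
            row[[paste0("engaged_", tt)]] <- eng$engaged
            row[[paste0("category_", tt)]] <-
                if (eng$engaged) eng$assignment$category else "none"
            row[[paste0("peak_dist_", tt)]] <- eng$assignment$peak_dist_cm
            row[[paste0("peak_amp_", tt)]] <- eng$assignment$peak_amp
            row[[paste0("peak_z_", tt)]] <- eng$peak_z
            row[[paste0("tie_", tt)]] <- eng$assignment$tie
        }
        pooled <- assignAlignment(session, i, trialType = NULL,
                                  binCm = binCm, landmarkRef = landmarkRef)
        row$category_pooled <- pooled$category
        row$peak_dist_pooled <- pooled$peak_dist_cm
        row$rate_per_min <- eng$rate_per_min
        out[[i]] <- as.data.frame(row)
    }
    rec <- do.call(rbind, out)
    rec$lmi <- NA_real_
    is_lm <- rec$category_short == "landmark" |
        rec$category_long == "landmark"
    for (i in which(is_lm)) {
        lm_s <- meanAlignedTrace(session, i, "landmark", binCm = binCm,
                                 trialType = "short",
                                 landmarkRef = landmarkRef)
        lm_l <- meanAlignedTrace(session, i, "landmark", binCm = binCm,
                                 trialType = "long",
                                 landmarkRef = landmarkRef)
        rec$lmi[i] <- landmarkModulationIndex(
            max(0, max(lm_s$mean, na.rm = TRUE)),
            max(0, max(lm_l$mean, na.rm = TRUE)))
    }
    rec
}

#' Activity split by behavioral accuracy
#'
#' Ranks licked trials by accuracy — the distance of the trial's first lick
#' from the reward-zone start — and compares the neuron's mean single-trial
#' response (peak within `windowCm` of its peak location) between the most
#' and least accurate `quantile` of trials.
#'
#' @inheritParams meanAlignedTrace
#' @param quantile fraction of trials in each extreme group (default 0.25).
#' @param anchor,peakDist the neuron's classified anchor and peak location;
#'   computed via [assignAlignment()] over all trials when omitted.
#' @param windowCm response window around the peak (default 20).
#' @return list with `amp_best`, `amp_worst`, `difference`, `n_best`,
#'   `n_worst`, `ties` (accuracy ties across the quantile boundary, broken
#'   by trial order).
#' @export
accuracySplitActivity <- function(session, roi, quantile = 0.25,
                                  anchor = NULL, peakDist = NULL,
                                  windowCm = 20, binCm = 5,
                                  landmarkRef = "onset") {
    if (sessionCondition(session) != "VR")
        stop("accuracy split requires a VR session")
    licks <- firstLickLocations(session, landmarkRef = landmarkRef)
    tr <- trialTable(session)
    licked <- which(!is.na(licks$first_lick_track_cm))
    if (length(licked) < 8)
        stop("need at least 8 licked trials for an accuracy split")
    if (is.null(anchor)) {
        whole <- assignAlignment(session, roi, trialType = NULL,
                                 binCm = binCm, landmarkRef = landmarkRef)
        anchor <- whole$category
        peakDist <- whole$peak_dist_cm
    }
    acc <- abs(licks$first_lick_track_cm[licked] - tr$rz_start_cm[licked])
    ord <- order(acc)  # stable: ties broken by trial order
    k <- max(2L, floor(length(licked) * quantile))
    best <- licked[ord[seq_len(k)]]
    worst <- licked[ord[seq(length(ord) - k + 1, length(ord))]]
    resp <- .singleTrialResponses(session, roi, anchor, peakDist,
                                  trialIds = tr$trial_id[c(best, worst)],
                                  windowCm = windowCm, binCm = binCm,
                                  landmarkRef = landmarkRef)
    amp_best <- mean(resp[seq_len(k)], na.rm = TRUE)
    amp_worst <- mean(resp[seq(k + 1, 2 * k)], na.rm = TRUE)
    list(amp_best = amp_best, amp_worst = amp_worst,
         difference = amp_best - amp_worst, n_best = k, n_worst = k,
         ties = anyDuplicated(acc) > 0)
}
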