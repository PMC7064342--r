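#' Peak response in the decoupled condition at the VR peak location
#'
#' Aligns the decoupled-condition activity to the neuron's preferred anchor
#' from virtual navigation and takes the peak of the mean aligned trace
#' within `+- windowCm` of the VR peak location, allowing small shifts of
#' the receptive field between conditions.
#'
#' @inheritParams meanAlignedTrace
#' @param vrPeakDist the neuron's VR mean-trace peak location (cm, aligned).
#' @param windowCm half-width of the search window (default 20).
#' @param trialIds optional trial subset (e.g. running trials only).
#' @return peak delta-F/F within the window, or `NA` when no bin in the
#'   window has coverage.
#' @export
dcPeakResponse <- function(session, roi, anchor, vrPeakDist, windowCm = 20,
                           binCm = 5, trialIds = NULL, trialType = NULL,
                           landmarkRef = "onset", minCoverage = 0.5) {
    mt <- tryCatch(
        meanAlignedTrace(session, roi, anchor, binCm = binCm,
                         trialIds = trialIds, trialType = trialType,
                         landmarkRef = landmarkRef,
                         minCoverage = minCoverage),
        error = function(e) NULL)
    if (is.null(mt)) return(NA_real_)
    inwin <- abs(mt$centers - vrPeakDist) <= windowCm & !is.na(mt$mean)
    if (!any(inwin)) return(NA_real_)
    max(mt$mean[inwin])
}

#' Label decoupled-condition trials as running or resting
#'
#' A trial is a running trial when the animal's mean treadmill speed exceeds
#' 3 cm/s (strictly) within `+- windowCm` of the neuron's VR peak response
#' location in corridor-flow coordinates; a mean speed of exactly 3 cm/s is
#' labeled resting.
#'
#' @param session a DC [LandmarkSession-class].
#' @param peakDistCm the neuron's VR peak location, landmark-aligned (cm).
#' @param speedThresh locomotion threshold (cm/s, default 3).
#' @param windowCm half-width of the spatial window (default 50).
#' @param landmarkRef landmark edge used for alignment.
#' @return data.frame with `trial_id`, `mean_speed`, `label`
#'   ("running"/"resting").
#' @export
labelMotorTrials <- function(session, peakDistCm, speedThresh = 3,
                             windowCm = 50, landmarkRef = "onset") {
    fr <- frameData(session)
    if (all(is.na(fr$speed_cmps)))
        stop("treadmill speed not recorded")
    tr <- trialTable(session)
    lm <- anchorPosition(tr, "landmark", landmarkRef = landmarkRef)
    out <- data.frame(trial_id = tr$trial_id, mean_speed = NA_real_,
                      label = NA_character_)
    for (i in seq_len(nrow(tr))) {
        idx <- trialFrames(session, tr$trial_id[i])
        d <- fr$position_cm[idx] - (lm[i] + peakDistCm)
        sel <- idx[abs(d) <= windowCm]
        if (!length(sel)) next
        ms <- mean(fr$speed_cmps[sel])
        out$mean_speed[i] <- ms
        out$label[i] <- if (ms > speedThresh) "running" else "resting"
    }
    out
}

#' Black-box responses split by locomotion
#'
#' The neuron's response is its delta-F/F at 1.5 s after black-box onset
#' (the frame nearest that time point). Epochs are partitioned into motor /
#' no-motor by whether mean treadmill speed within `+- motorWindowS` of the
#' response time exceeds 3 cm/s. Responses are averaged within each class.
#'
#' @inheritParams meanAlignedTrace
#' @param responseDelayS response time after black-box onset (s, default
#'   1.5).
#' @param motorWindowS half-width of the locomotion test window (s, default
#'   1).
#' @param speedThresh locomotion threshold (cm/s, default 3).
#' @return list with `amp_bb_motor`, `amp_bb_no_motor` (NA when a class has
#'   no epochs), `n_motor`, `n_no_motor`.
#' @export
blackboxResponse <- function(session, roi, responseDelayS = 1.5,
                             motorWindowS = 1, speedThresh = 3) {
    fr <- frameData(session)
    if (!any(fr$blackbox)) stop("session contains no black-box epochs")
    roi <- .resolveRois(session, roi)
    dff <- dffMatrix(session)[roi, ]
    rate <- frameRate(session)
    r <- rle(fr$blackbox)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    onsets <- starts[r$values]
    delay_f <- round(responseDelayS * rate)
    win_f <- round(motorWindowS * rate)
    resp <- motor <- rep(NA, length(onsets))
    for (k in seq_along(onsets)) {
        f <- onsets[k] + delay_f
        if (f > length(dff)) next
        resp[k] <- dff[f]
        sel <- max(1L, f - win_f):min(length(dff), f + win_f)
        motor[k] <- mean(fr$speed_cmps[sel]) > speedThresh
    }
    ok <- !is.na(resp)
    list(amp_bb_motor = if (any(ok & motor %in% TRUE))
             mean(resp[ok & motor %in% TRUE]) else NA_real_,
         amp_bb_no_motor = if (any(ok & motor %in% FALSE))
             mean(resp[ok & motor %in% FALSE]) else NA_real_,
         n_motor = sum(ok & motor %in% TRUE),
         n_no_motor = sum(ok & motor %in% FALSE))
}

#' Condition-wise response amplitudes for a VR / DC session pair
#'
#' For each classified neuron: peak VR response (`amp_vr`), decoupled
#' landmark response split by locomotion (`amp_lm_motor`,
#' `amp_lm_no_motor`), and black-box responses split by locomotion
#' (`amp_bb_motor`, `amp_bb_no_motor`). Neurons need at least `minTrials`
#' running and resting trials to enter the motor-split columns.
#'
#' @param vrSession,dcSession a matched VR / DC session pair (identical ROI
#'   ordering).
#' @param classification output of [classifySession()] on the VR session.
#' @param category anchor category to analyze (default `"landmark"`).
#' @param windowCm DC peak search window (default 20).
#' @param minTrials minimum running and resting trials (default 3).
#' @param binCm spatial bin width (default 5).
#' @param landmarkRef landmark edge used for alignment.
#' @return data.frame (one row per neuron) with amplitudes, trial counts and
#'   normalized (`/ amp_vr`) variants.
#' @export
conditionResponse <- function(vrSession, dcSession, classification,
                              category = "landmark", windowCm = 20,
                              minTrials = 3, binCm = 5,
                              landmarkRef = "onset") {
    if (!identical(roiInfo(vrSession)$roi_id, roiInfo(dcSession)$roi_id))
        stop("VR and DC sessions carry different ROI ids")
    sel <- which(classification$category_short == category |
                 classification$category_long == category)
    rows <- vector("list", length(sel))
    for (k in seq_along(sel)) {
        i <- sel[k]
        tt <- if (classification$category_short[i] == category) "short"
              else "long"
        pk <- if (tt == "short") classification$peak_dist_short[i]
              else classification$peak_dist_long[i]
        ## VR amplitude recomputed with the same estimator as the DC side
        ## (peak of the pooled mean aligned trace in the same window), so
        ## identical VR/DC inputs give identical amplitudes
        amp_vr <- dcPeakResponse(vrSession, i, category, pk, windowCm,
                                 binCm, landmarkRef = landmarkRef)
        labels <- labelMotorTrials(dcSession, pk,
                                   landmarkRef = landmarkRef)
        run_ids <- labels$trial_id[labels$label %in% "running"]
        rest_ids <- labels$trial_id[labels$label %in% "resting"]
        enough <- length(run_ids) >= minTrials &&
            length(rest_ids) >= minTrials
        amp_lm_motor <- if (enough)
            dcPeakResponse(dcSession, i, category, pk, windowCm, binCm,
                           trialIds = run_ids, landmarkRef = landmarkRef,
                           minCoverage = 0)
        else NA_real_
        amp_lm_no_motor <- if (enough)
            dcPeakResponse(dcSession, i, category, pk, windowCm, binCm,
                           trialIds = rest_ids, landmarkRef = landmarkRef,
                           minCoverage = 0)
        else NA_real_
        bb <- blackboxResponse(dcSession, i)
        rows[[k]] <- data.frame(
            roi_id = classification$roi_id[i],
            amp_vr = amp_vr,
            amp_dc = dcPeakResponse(dcSession, i, category, pk, windowCm,
                                    binCm, landmarkRef = landmarkRef),
            amp_lm_motor = amp_lm_motor,
            amp_lm_no_motor = amp_lm_no_motor,
            amp_bb_motor = bb$amp_bb_motor,
            amp_bb_no_motor = bb$amp_bb_no_motor,
            n_running = length(run_ids), n_resting = length(rest_ids),
            n_bb_motor = bb$n_motor, n_bb_no_motor = bb$n_no_motor)
    }
    out <- do.call(rbind, rows)
    for (col in c("amp_dc", "amp_lm_motor", "amp_lm_no_motor",
                  "amp_bb_motor", "amp_bb_no_motor"))
        out[[paste0(col, "_norm")]] <- out[[col]] / out$amp_vr
    out
}

#' Supralinearity test of visuo-motor integration
#'
#' Compares each neuron's combined landmark-plus-locomotion response
#' (`amp_lm_motor`) with the linear sum of its landmark-only
#' (`amp_lm_no_motor`) and motor-only (`amp_bb_motor`) responses. Negative
#' component amplitudes are kept (no clipping). The population-level call
#' uses a one-sided paired Wilcoxon signed-rank test of
#' `combined > linear sum`.
#'
#' @param condResp output of [conditionResponse()].
#' @param alpha significance level for the supralinear flag (default 0.01).
#' @return list with `supralinear` (logical flag), `p_value`, `n` (neurons
#'   with all components defined), `n_excluded`, `linear_sum`, `combined`
#'   and per-neuron `difference` (combined - linear sum).
#' @export
linearityTest <- function(condResp, alpha = 0.01) {
    lin <- condResp$amp_lm_no_motor + condResp$amp_bb_motor
    comb <- condResp$amp_lm_motor
    ok <- is.finite(lin) & is.finite(comb)
    n <- sum(ok)
    if (n < 3)
        stop("too few neurons with all components defined (", n, ")")
    test <- stats::wilcox.test(comb[ok], lin[ok], paired = TRUE,
                               alternative = "greater", exact = FALSE)
    list(supralinear = test$p.value < alpha, p_value = test$p.value,
         n = n, n_excluded = sum(!ok),
         linear_sum = lin[ok], combined = comb[ok],
         difference = comb[ok] - lin[ok])
}

#' Correlation of running speed with transient amplitude
#'
#' Pearson correlation between the mean running speed during each transient
#' and the transient's peak amplitude. Neurons with fewer than `minTransients`
#' transients are excluded (returned with `included = FALSE`).
#'
#' @param session a [LandmarkSession-class].
#' @param roi ROI index or id.
#' @param transients optional time-domain transient table (from
#'   [detectTransientsTime()]); detected if omitted.
#' @param minTransients inclusion threshold (default 10).
#' @return list with `included`, `r`, `p`, `n`, and `reason` when excluded.
#' @export
speedAmplitudeCorrelation <- function(session, roi, transients = NULL,
                                      minTransients = 10) {
    roi <- .resolveRois(session, roi)
    if (is.null(transients))
        transients <- detectTransientsTime(dffMatrix(session)[roi, ],
                                           frameRate(session))
    n <- nrow(transients)
    if (n < minTransients)
        return(list(included = FALSE, r = NA_real_, p = NA_real_, n = n,
                    reason = paste0("fewer than ", minTransients,
                                    " transients (", n, ")")))
    sp <- frameData(session)$speed_cmps
    mean_speed <- vapply(seq_len(n), function(i)
        mean(sp[transients$onset[i]:transients$offset[i]]), numeric(1))
    ct <- stats::cor.test(mean_speed, transients$peak_dff)
    list(included = TRUE, r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' VR vs DC amplitude comparison across ROI groups
#'
#' Per-neuron VR and DC response amplitudes and their difference, supporting
#' group comparisons between ROI kinds (e.g. RSC somata vs V1 axonal
#' boutons, which are less modulated by active navigation).
#'
#' @inheritParams conditionResponse
#' @return data.frame with `roi_id`, `roi_kind`, `amp_vr`, `amp_dc`,
#'   `difference` (VR - DC) and normalized difference.
#' @export
conditionSummary <- function(vrSession, dcSession, classification,
                             category = "landmark", windowCm = 20,
                             binCm = 5, landmarkRef = "onset") {
    cr <- conditionResponse(vrSession, dcSession, classification,
                            category = category, windowCm = windowCm,
                            binCm = binCm, landmarkRef = landmarkRef)
    kind <- roiInfo(vrSession)$roi_kind[match(cr$roi_id,
                                              roiInfo(vrSession)$roi_id)]
    data.frame(roi_id = cr$roi_id, roi_kind = kind, amp_vr = cr$amp_vr,
               amp_dc = cr$amp_dc, difference = cr$amp_vr - cr$amp_dc,
               difference_norm = (cr$amp_vr - cr$amp_dc) / cr$amp_vr)
}
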