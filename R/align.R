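#' Anchor positions for each trial
#'
#' Each trial defines three anchor points: trial onset (`start_cm`), the
#' landmark, and the reward (`rz_start_cm`, the fixed start of the reward
#' zone). The landmark is a 40 cm wide cue; which edge serves as the anchor is
#' configurable (`"onset"` = first visual contact, the default).
#'
#' @param trials a trial table (see [LandmarkSession()]).
#' @param anchor one of `"trial_onset"`, `"landmark"`, `"reward"`.
#' @param landmarkRef `"onset"`, `"center"` or `"offset"` edge of the cue.
#' @param rewardRef `"event"` anchors at the actual reward-delivery location
#'   (trial column `reward_cm`, falling back to `rz_start_cm` where absent);
#'   `"zone_start"` always uses `rz_start_cm`. Because the zone start sits at
#'   a fixed offset from the landmark within a trial type, `"zone_start"`
#'   alignment is a rigid shift of landmark alignment; the per-trial reward
#'   event is what distinguishes reward-anchored activity.
#' @return numeric vector of anchor track coordinates, one per trial row.
#' @export
anchorPosition <- function(trials,
                           anchor = c("trial_onset", "landmark", "reward"),
                           landmarkRef = c("onset", "center", "offset"),
                           rewardRef = c("event", "zone_start")) {
    anchor <- match.arg(anchor)
    landmarkRef <- match.arg(landmarkRef)
    rewardRef <- match.arg(rewardRef)
    switch(anchor,
        trial_onset = trials$start_cm,
        landmark = switch(landmarkRef,
            onset = trials$landmark_on_cm,
            center = (trials$landmark_on_cm + trials$landmark_off_cm) / 2,
            offset = trials$landmark_off_cm),
        reward = {
            a <- trials$rz_start_cm
            if (rewardRef == "event" && !is.null(trials$reward_cm)) {
                ok <- !is.na(trials$reward_cm)
                a[ok] <- trials$reward_cm[ok]
            }
            a
        })
}

#' Anchor-aligned distance for the frames of one trial
#'
#' Re-expresses track position as signed distance from a per-trial anchor
#' point (negative before the anchor).
#'
#' @param session a [LandmarkSession-class].
#' @param trialId trial id.
#' @inheritParams anchorPosition
#' @return numeric vector of distances (cm) over the trial's frames.
#' @examples
#' sess <- generateSession(genConfig(n_trials = 2), behaviorPolicy("expert"),
#'                         neuronSpecs(1), seed = 1)$session
#' d <- alignedDistance(sess, trialTable(sess)$trial_id[1], "landmark")
#' @export
alignedDistance <- function(session, trialId,
                            anchor = c("trial_onset", "landmark", "reward"),
                            landmarkRef = c("onset", "center", "offset"),
                            rewardRef = c("event", "zone_start")) {
    anchor <- match.arg(anchor)
    landmarkRef <- match.arg(landmarkRef)
    rewardRef <- match.arg(rewardRef)
    tr <- trialTable(session)
    row <- match(trialId, tr$trial_id)
    if (is.na(row)) stop("unknown trial id: ", trialId)
    idx <- trialFrames(session, trialId)
    fr <- SummarizedExperiment::colData(session)
    if (any(fr$blackbox[idx]))
        stop("black-box frames cannot be aligned to a spatial anchor")
    fr$position_cm[idx] - anchorPosition(tr[row, , drop = FALSE],
                                         anchor, landmarkRef, rewardRef)
}

## Internal: frame -> (trial, bin) assignment on a common half-open grid
## [lo, lo + binCm) with edges at integer multiples of binCm in aligned
## coordinates. Returns everything binning consumers need.
.alignIndex <- function(session, anchor, binCm, trialIds = NULL,
                        landmarkRef = "onset", rewardRef = "event") {
    tr <- trialTable(session)
    if (!is.null(trialIds)) tr <- tr[tr$trial_id %in% trialIds, , drop = FALSE]
    if (!nrow(tr)) stop("no trials selected")
    fr <- SummarizedExperiment::colData(session)
    keep <- !is.na(fr$trial_id) & fr$trial_id %in% tr$trial_id
    f <- which(keep)
    trial_row <- match(fr$trial_id[f], tr$trial_id)
    d <- fr$position_cm[f] -
        anchorPosition(tr, anchor, landmarkRef, rewardRef)[trial_row]
    b <- floor(d / binCm)
    bmin <- min(b); bmax <- max(b)
    nbins <- bmax - bmin + 1L
    bin <- b - bmin + 1L
    ntr <- nrow(tr)
    cell <- (trial_row - 1L) * nbins + bin
    counts <- matrix(tabulate(cell, ntr * nbins), nrow = ntr, ncol = nbins,
                     byrow = TRUE)
    list(frames = f, trial_row = trial_row, bin = bin, cell = cell,
         n_trials = ntr, n_bins = nbins, counts = counts,
         centers = (seq(bmin, bmax) + 0.5) * binCm,
         trial_ids = tr$trial_id, trials = tr)
}

#' Anchor-aligned, spatially binned single-trial activity
#'
#' Bins each selected trial's delta-F/F into half-open spatial bins
#' `[lo, lo + binCm)` of anchor-aligned distance, averaging all frames that
#' fall in a bin (occupancy-weighted mean). Bins a trial never visited are
#' `NA` and break runs in downstream transient detection.
#'
#' @inheritParams alignedDistance
#' @param rois ROI indices or ids (default: all).
#' @param binCm bin width in cm (5 for population analyses, 2 for spatial
#'   transient detection).
#' @param trialIds optional subset of trials (default: all).
#' @param trialType optional `"short"`/`"long"` filter.
#' @return list with `centers` (bin centers, cm), `trial_ids`, and `activity`,
#'   an array `trials x bins x rois` of mean delta-F/F (`NA` = unvisited).
#' @export
alignedBinnedActivity <- function(session, rois = NULL,
                                  anchor = c("trial_onset", "landmark",
                                             "reward"),
                                  binCm = 5, trialIds = NULL,
                                  trialType = NULL,
                                  landmarkRef = c("onset", "center",
                                                  "offset"),
                                  rewardRef = c("event", "zone_start")) {
    anchor <- match.arg(anchor)
    landmarkRef <- match.arg(landmarkRef)
    rewardRef <- match.arg(rewardRef)
    tr <- trialTable(session)
    if (!is.null(trialType))
        tr <- tr[tr$trial_type == trialType, , drop = FALSE]
    if (!is.null(trialIds)) tr <- tr[tr$trial_id %in% trialIds, , drop = FALSE]
    ai <- .alignIndex(session, anchor, binCm, tr$trial_id, landmarkRef,
                      rewardRef)
    if (is.null(rois)) rois <- seq_len(nRois(session))
    rois <- .resolveRois(session, rois)
    dff <- dffMatrix(session)[rois, ai$frames, drop = FALSE]
    sums <- rowsum(t(dff), group = ai$cell, reorder = FALSE)
    cells <- as.integer(rownames(sums))
    cnt <- ai$counts
    act <- array(NA_real_,
                 dim = c(ai$n_trials, ai$n_bins, length(rois)),
                 dimnames = list(NULL, NULL,
                                 roiInfo(session)$roi_id[rois]))
    tr_of <- (cells - 1L) %/% ai$n_bins + 1L
    bn_of <- (cells - 1L) %% ai$n_bins + 1L
    nc <- cnt[cbind(tr_of, bn_of)]
    for (k in seq_along(rois))
        act[cbind(tr_of, bn_of, k)] <- sums[, k] / nc
    list(centers = ai$centers, trial_ids = ai$trial_ids, activity = act,
         counts = cnt)
}

.resolveRois <- function(session, rois) {
    if (is.character(rois)) {
        idx <- match(rois, roiInfo(session)$roi_id)
        if (anyNA(idx)) stop("unknown roi ids: ",
                             paste(rois[is.na(idx)], collapse = ", "))
        idx
    } else as.integer(rois)
}

#' Across-trial mean of the anchor-aligned trace of one neuron
#'
#' Spatially bins each trial's delta-F/F in anchor-aligned coordinates and
#' averages across trials. To avoid edge artefacts from the randomized start
#' locations, a bin enters the mean only if at least `minCoverage` of trials
#' visited it; other bins are masked (`NA`).
#'
#' @inheritParams alignedBinnedActivity
#' @param roi one ROI index or id.
#' @param minCoverage minimum fraction of trials that must cover a bin
#'   (default 0.5).
#' @return list with `centers`, `mean` (masked per-bin mean), `coverage`
#'   (fraction of trials per bin), `n_trials`.
#' @export
meanAlignedTrace <- function(session, roi,
                             anchor = c("trial_onset", "landmark", "reward"),
                             binCm = 5, trialType = NULL, trialIds = NULL,
                             landmarkRef = c("onset", "center", "offset"),
                             rewardRef = c("event", "zone_start"),
                             minCoverage = 0.5) {
    ab <- alignedBinnedActivity(session, rois = roi, anchor = anchor,
                                binCm = binCm, trialIds = trialIds,
                                trialType = trialType,
                                landmarkRef = landmarkRef,
                                rewardRef = rewardRef)
    act <- ab$activity[, , 1, drop = FALSE]
    dim(act) <- dim(ab$activity)[1:2]
    coverage <- colMeans(!is.na(act))
    m <- colMeans(act, na.rm = TRUE)
    m[coverage < minCoverage] <- NA_real_
    m[is.nan(m)] <- NA_real_
    if (all(is.na(m)))
        stop("all spatial bins masked (coverage < ", minCoverage, ")")
    list(centers = ab$centers, mean = m, coverage = coverage,
         n_trials = nrow(act))
}

## Internal: sparse weight matrix W (bins x session frames) such that
## W %*% dff equals the coverage-masked mean aligned trace. Invariant under
## circular shifts of dff, so the shuffle null reuses it.
.alignWeights <- function(session, anchor, binCm = 5, trialType = NULL,
                          trialIds = NULL, landmarkRef = "onset",
                          rewardRef = "event", minCoverage = 0.5) {
    tr <- trialTable(session)
    if (!is.null(trialType))
        tr <- tr[tr$trial_type == trialType, , drop = FALSE]
    if (!is.null(trialIds)) tr <- tr[tr$trial_id %in% trialIds, , drop = FALSE]
    ai <- .alignIndex(session, anchor, binCm, tr$trial_id, landmarkRef,
                      rewardRef)
    ncover <- colSums(ai$counts > 0)
    valid <- ncover / ai$n_trials >= minCoverage
    w <- 1 / (ai$counts[cbind(ai$trial_row, ai$bin)] * ncover[ai$bin])
    W <- Matrix::sparseMatrix(i = ai$bin, j = ai$frames, x = w,
                              dims = c(ai$n_bins, ncol(session)))
    list(W = W, centers = ai$centers, valid = valid, n_trials = ai$n_trials)
}
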