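#' Per-trial first-lick locations
#'
#' For every trial, the landmark-aligned location of the chronologically
#' first lick (black-box licks cannot occur: licks are defined on track
#' frames only). Licks anywhere on the corridor count, including before the
#' landmark — novice animals lick early. Trials without licks (default-reward
#' trials) get `NA` and are excluded from first-lick statistics but remain in
#' the success-fraction denominator.
#'
#' @param session a VR [LandmarkSession-class].
#' @param landmarkRef landmark edge used for alignment (see
#'   [anchorPosition()]).
#' @return data.frame with `trial_id`, `trial_type`, `first_lick_cm`
#'   (landmark-aligned), `first_lick_track_cm` (raw track coordinate),
#'   `start_cm`, `success`, `stim`.
#' @export
firstLickLocations <- function(session, landmarkRef = "onset") {
    if (sessionCondition(session) != "VR")
        stop("first-lick statistics are defined for VR sessions only ",
             "(no behavioral task in the decoupled condition)")
    fr <- frameData(session)
    tr <- trialTable(session)
    lick_idx <- which(fr$lick & !fr$blackbox)
    first_track <- rep(NA_real_, nrow(tr))
    for (i in seq_len(nrow(tr))) {
        idx <- lick_idx[fr$trial_id[lick_idx] == tr$trial_id[i]]
        if (length(idx)) first_track[i] <- fr$position_cm[idx[1]]
    }
    lm <- anchorPosition(tr, "landmark", landmarkRef = landmarkRef)
    data.frame(trial_id = tr$trial_id, trial_type = tr$trial_type,
               first_lick_cm = first_track - lm,
               first_lick_track_cm = first_track,
               start_cm = tr$start_cm,
               success = tr$success, stim = tr$stim)
}

#' Task score: landmark-relative separation of first licks by trial type
#'
#' `median(first lick, long trials) - median(first lick, short trials)` in
#' landmark-aligned cm. An animal licking at a fixed distance from the
#' landmark scores near the difference of the two reward-zone offsets
#' (60 cm); random licking scores near 0. Supports trial subsets (e.g.
#' optogenetic stimulation vs mask-only trials).
#'
#' @param lickSummary output of [firstLickLocations()].
#' @param subset optional logical vector over trials (rows of `lickSummary`),
#'   e.g. `lickSummary$stim` to restrict to stimulation trials.
#' @return numeric task score (cm).
#' @export
taskScore <- function(lickSummary, subset = NULL) {
    if (!is.null(subset)) lickSummary <- lickSummary[subset, , drop = FALSE]
    licked <- lickSummary[!is.na(lickSummary$first_lick_cm), , drop = FALSE]
    ms <- licked$first_lick_cm[licked$trial_type == "short"]
    ml <- licked$first_lick_cm[licked$trial_type == "long"]
    if (!length(ms) || !length(ml))
        stop("task score undefined: a trial type has no licked trials ",
             "in the subset")
    stats::median(ml) - stats::median(ms)
}

#' Fraction of successful (operantly rewarded) trials
#'
#' @inheritParams taskScore
#' @param session a VR [LandmarkSession-class].
#' @export
successFraction <- function(session, subset = NULL) {
    if (sessionCondition(session) != "VR")
        stop("success fraction is defined for VR sessions only")
    tr <- trialTable(session)
    if (!is.null(subset)) tr <- tr[subset, , drop = FALSE]
    if (!nrow(tr)) stop("empty trial subset")
    mean(tr$success)
}

#' Spatial modulation z-score (SMZ) of licking behavior
#'
#' Tests whether reward triggering depends on where the animal licks. The
#' true statistic is the fraction of trials with at least one lick inside
#' the reward zone. The null rotates each trial's lick positions circularly
#' within that trial's full operant extent (from the start through the
#' reward-zone end, or the traversed extent if longer) by an independent
#' uniform offset, recomputes the session success fraction, and repeats
#' `nShuffles` times. Returned is
#' `(true - mean(null)) / sd(null)`.
#'
#' @param session a VR [LandmarkSession-class].
#' @param nShuffles number of rotations (default 1000).
#' @param seed RNG seed.
#' @return list with `z`, `true_fraction`, `null_mean`, `null_sd`.
#' @export
spatialModulationZscore <- function(session, nShuffles = 1000, seed = 1) {
    if (sessionCondition(session) != "VR")
        stop("SMZ is defined for VR sessions only")
    fr <- frameData(session)
    tr <- trialTable(session)
    if (!nrow(tr)) stop("session has no trials")
    if (!any(fr$lick, na.rm = TRUE))
        stop("degenerate licking: session contains no licks")
    set.seed(as.integer(seed) %% .Machine$integer.max)
    lick_idx <- which(fr$lick & !fr$blackbox)
    lick_trial <- fr$trial_id[lick_idx]
    lick_pos <- fr$position_cm[lick_idx]
    null_succ <- matrix(FALSE, nShuffles, nrow(tr))
    true_succ <- logical(nrow(tr))
    for (i in seq_len(nrow(tr))) {
        tfr <- trialFrames(session, tr$trial_id[i])
        lo <- tr$start_cm[i]
        ## rotation support: the trial's full operant extent, through the
        ## reward-zone end. Successful trials teleport at the rewarded lick,
        ## so the traversed extent alone would under-represent the zone and
        ## bias the null downward (inflating z even for random licking).
        hi <- max(max(fr$position_cm[tfr]), tr$rz_end_cm[i])
        ext <- hi - lo
        L <- lick_pos[lick_trial == tr$trial_id[i]]
        true_succ[i] <- any(L >= tr$rz_start_cm[i] & L <= tr$rz_end_cm[i])
        if (!length(L) || ext <= 0) next
        off <- stats::runif(nShuffles, 0, ext)
        ## rotated positions: (L - lo + off) mod ext + lo
        rot <- outer(off, L - lo, `+`) %% ext + lo
        null_succ[, i] <- rowSums(rot >= tr$rz_start_cm[i] &
                                  rot <= tr$rz_end_cm[i]) > 0
    }
    true_frac <- mean(true_succ)
    null_frac <- rowMeans(null_succ)
    s <- stats::sd(null_frac)
    if (!is.finite(s) || s == 0)
        stop("degenerate licking: null distribution has zero variance")
    list(z = (true_frac - mean(null_frac)) / s,
         true_fraction = true_frac,
         null_mean = mean(null_frac), null_sd = s)
}

#' Regression of first-lick location on trial start location
#'
#' Ordinary least squares of the first-lick track coordinate on the start
#' track coordinate (both unaligned). Landmark-guided animals show slope near
#' 0 (licks anchored to the cue, independent of start); an animal probing a
#' fixed distance after the start ("internal odometer") shows slope near 1.
#'
#' @param lickSummary output of [firstLickLocations()].
#' @return list with `slope`, `intercept`, `r` (Pearson), `n`.
#' @export
startVsFirstLickRegression <- function(lickSummary) {
    d <- lickSummary[!is.na(lickSummary$first_lick_track_cm), , drop = FALSE]
    if (nrow(d) < 3)
        stop("need at least 3 licked trials for the regression")
    if (stats::var(d$start_cm) == 0)
        stop("degenerate start locations: no variance across trials")
    fit <- stats::lm(first_lick_track_cm ~ start_cm, data = d)
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r = stats::cor(d$start_cm, d$first_lick_track_cm),
         n = nrow(d))
}
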