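# Session builders used across tests. All fixtures are constructed in code.

# A fully hand-specified session: constant speed, explicit lick/dff control.
# starts: track coordinate of each trial's onset (landmark fixed at 200).
# licks_cm: list of per-trial lick positions (track coordinates).
# dffFun: function(position_cm, trial_row) -> delta-F/F value per frame,
#   evaluated on non-blackbox frames (blackbox frames get 0); one ROI per
#   element of dffFun list.
manualSession <- function(starts = c(100, 120), types = c("short", "long"),
                          licks_cm = NULL, dffFun = list(),
                          speed = 20, frameRate = 15.5, blackboxS = 3,
                          rewardAtLick = TRUE, condition = "VR") {
    step <- speed / frameRate
    frames <- list(); trials <- list()
    for (i in seq_along(starts)) {
        lm_on <- 200; lm_off <- 240
        rz_s <- lm_off + c(short = 80, long = 140)[[types[i]]]
        rz_e <- rz_s + 20
        L <- if (!is.null(licks_cm) && length(licks_cm) >= i)
            sort(licks_cm[[i]]) else numeric()
        in_zone <- L[L >= rz_s & L <= rz_e]
        if (condition == "VR" && rewardAtLick && length(in_zone)) {
            reward_cm <- in_zone[1]; success <- TRUE
        } else {
            reward_cm <- rz_e; success <- FALSE
        }
        L <- L[L <= reward_cm]
        pos <- seq(starts[i] + step, reward_cm + step, by = step)
        nf <- length(pos)
        lick <- rep(FALSE, nf)
        if (length(L)) lick[pmin(nf, findInterval(L, pos) + 1L)] <- TRUE
        reward <- rep(FALSE, nf)
        if (condition == "VR") reward[nf] <- TRUE
        frames[[2 * i - 1]] <- data.frame(
            position_cm = pos, speed_cmps = speed, lick = lick,
            reward = reward, trial_id = i, blackbox = FALSE)
        nbb <- round(blackboxS * frameRate) + 1
        frames[[2 * i]] <- data.frame(
            position_cm = NA_real_, speed_cmps = speed, lick = FALSE,
            reward = FALSE, trial_id = NA_integer_, blackbox = TRUE)[
                rep(1, nbb), ]
        trials[[i]] <- data.frame(
            trial_id = i, trial_type = types[i], start_cm = starts[i],
            landmark_on_cm = lm_on, landmark_off_cm = lm_off,
            rz_start_cm = rz_s, rz_end_cm = rz_e,
            reward_cm = if (condition == "VR") reward_cm else NA_real_,
            success = success, stim = FALSE)
    }
    frames <- do.call(rbind, frames)
    rownames(frames) <- NULL
    frames <- cbind(time_s = (seq_len(nrow(frames)) - 1) / frameRate, frames)
    trials <- do.call(rbind, trials)
    nroi <- length(dffFun)
    dff <- matrix(0, max(1, nroi), nrow(frames))
    trow <- match(frames$trial_id, trials$trial_id)
    ok <- !frames$blackbox
    for (j in seq_len(nroi))
        dff[j, ok] <- mapply(dffFun[[j]], frames$position_cm[ok], trow[ok])
    LandmarkSession(frames = frames, trials = trials, dff = dff,
                    condition = condition, frameRate = frameRate)
}

# Gaussian bump in track coordinates
bump <- function(center, width = 10, amp = 1) {
    function(pos, trial) amp * exp(-(pos - center)^2 / (2 * width^2))
}

# A generator config with all behavioral randomness collapsed: fixed start,
# constant speed, deterministic licking; used for exact noise-free limits.
deterministicConfig <- function(n_trials = 10, noise_sd = 0)
    genConfig(n_trials = n_trials, start_jitter = c(100, 100),
              speed_sd_cmps = 0, noise_sd = noise_sd)

deterministicPolicy <- function() behaviorPolicy("expert",
                                                 lick_offset_mean_cm = 8,
                                                 lick_offset_sd_cm = 0)

expect_sessions_identical <- function(a, b) {
    expect_identical(dffMatrix(a), dffMatrix(b))
    expect_identical(frameData(a), frameData(b))
    expect_identical(trialTable(a), trialTable(b))
    expect_identical(roiInfo(a), roiInfo(b))
    expect_identical(sessionCondition(a), sessionCondition(b))
    expect_identical(frameRate(a), frameRate(b))
}
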