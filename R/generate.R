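#' Generator configuration for synthetic sessions
#'
#' Defines the task geometry and signal model used by [generateSession()].
#' Defaults emulate the experimental design: trials start at a uniformly
#' randomized distance 50-150 cm before a 40 cm wide landmark cue; an
#' unmarked 20 cm reward zone starts 80 cm (short trials) or 140 cm (long
#' trials) past the landmark end; trials are separated by a black box of at
#' least 3 s; GCaMP6f-like transients decay exponentially.
#'
#' @param n_trials number of corridor traversals.
#' @param trial_type_schedule `"random"` (i.i.d. coin flip) or
#'   `"blocks_of_5"`.
#' @param start_jitter range (cm) of the randomized start distance before the
#'   landmark.
#' @param landmark_pos_cm fixed track coordinate of the landmark onset.
#' @param blackbox_s minimum black-box duration between trials (s); actual
#'   durations are `blackbox_s` plus up to 0.5 s.
#' @param frame_rate_hz imaging/behavior frame rate (15.5 or 31).
#' @param speed_mean_cmps,speed_sd_cmps mean and innovation s.d. of the
#'   bounded AR(1) running-speed process during virtual navigation.
#' @param gcamp_decay_tau_s exponential decay constant of the transient
#'   kernel (s); 0.6 s approximates GCaMP6f offset kinetics.
#' @param noise_sd i.i.d. Gaussian noise s.d. on delta-F/F.
#' @param dc_flow_speeds fixed corridor flow speeds (cm/s) in the decoupled
#'   condition, interleaved across trials.
#' @param dc_bout_run_s,dc_bout_rest_s mean durations (s) of spontaneous
#'   locomotion / rest bouts in the decoupled condition (exponential
#'   semi-Markov process; the experiments report no locomotion statistics for
#'   this condition, so these are declared generator choices).
#' @param dc_run_speed_cmps mean treadmill speed during decoupled locomotion
#'   bouts.
#' @return a list of class `"genConfig"`.
#' @export
genConfig <- function(n_trials = 40,
                      trial_type_schedule = c("random", "blocks_of_5"),
                      start_jitter = c(50, 150),
                      landmark_pos_cm = 200,
                      blackbox_s = 3,
                      frame_rate_hz = 15.5,
                      speed_mean_cmps = 20,
                      speed_sd_cmps = 4,
                      gcamp_decay_tau_s = 0.6,
                      noise_sd = 0.1,
                      dc_flow_speeds = c(10, 30),
                      dc_bout_run_s = 8,
                      dc_bout_rest_s = 8,
                      dc_run_speed_cmps = 15) {
    trial_type_schedule <- match.arg(trial_type_schedule)
    stopifnot(n_trials >= 1, length(start_jitter) == 2,
              start_jitter[1] >= 50, start_jitter[2] <= 150,
              start_jitter[1] <= start_jitter[2],
              blackbox_s >= 3, frame_rate_hz > 0, gcamp_decay_tau_s > 0,
              noise_sd >= 0)
    if (landmark_pos_cm - start_jitter[2] < 0)
        stop("infeasible geometry: trials would start at negative track ",
             "coordinates; increase landmark_pos_cm")
    structure(as.list(environment()), class = "genConfig")
}

#' Behavioral licking policy for synthetic sessions
#'
#' @param policy `"expert"` (first lick placed relative to the reward-zone
#'   start), `"naive"` (broadly scattered anchored licks plus baseline),
#'   `"random_licker"` (uniform Poisson licking, no spatial knowledge) or
#'   `"odometer"` (first lick a fixed distance past the trial start,
#'   ignoring the landmark).
#' @param lick_offset_mean_cm,lick_offset_sd_cm location of the planned first
#'   lick relative to its anchor (reward-zone start for `"expert"`/`"naive"`,
#'   `start + odometer_distance_cm` for `"odometer"`).
#' @param baseline_lick_rate_per_cm rate of stray licks per cm of track.
#' @param odometer_distance_cm fixed probing distance of the odometer policy.
#' @return a list of class `"behaviorPolicy"`.
#' @export
behaviorPolicy <- function(policy = c("expert", "naive", "random_licker",
                                      "odometer"),
                           lick_offset_mean_cm = NULL,
                           lick_offset_sd_cm = NULL,
                           baseline_lick_rate_per_cm = NULL,
                           odometer_distance_cm = 200) {
    policy <- match.arg(policy)
    defaults <- switch(policy,
        expert = list(mean = 8, sd = 6, base = 0),
        naive = list(mean = 0, sd = 40, base = 0.04),
        random_licker = list(mean = NA_real_, sd = NA_real_, base = 0.05),
        odometer = list(mean = 0, sd = 10, base = 0))
    if (is.null(lick_offset_mean_cm)) lick_offset_mean_cm <- defaults$mean
    if (is.null(lick_offset_sd_cm)) lick_offset_sd_cm <- defaults$sd
    if (is.null(baseline_lick_rate_per_cm))
        baseline_lick_rate_per_cm <- defaults$base
    stopifnot(is.na(lick_offset_sd_cm) || lick_offset_sd_cm >= 0,
              baseline_lick_rate_per_cm >= 0)
    structure(list(policy = policy,
                   lick_offset_mean_cm = lick_offset_mean_cm,
                   lick_offset_sd_cm = lick_offset_sd_cm,
                   baseline_lick_rate_per_cm = baseline_lick_rate_per_cm,
                   odometer_distance_cm = odometer_distance_cm),
              class = "behaviorPolicy")
}

#' Ground-truth tuning specifications for synthetic neurons
#'
#' One row per neuron. Transients are placed in distance-from-anchor space
#' (Gaussian jitter of s.d. `width_cm` around `pref_dist_cm`) and mapped to
#' frames through each trial's position series; occurrence is Bernoulli per
#' trial with probability `p_transient` (`p_transient_dc` in the decoupled
#' condition, where tuning width `width_dc_cm` also applies).
#'
#' @param n number of neurons (arguments are recycled to length `n`).
#' @param anchor `"trial_onset"`, `"landmark"` or `"reward"`. Reward-anchored
#'   neurons place transients relative to the trial's actual reward-delivery
#'   location.
#' @param pref_dist_cm peak offset from the anchor (cm). Default: evenly
#'   tiled over an anchor-appropriate span.
#' @param width_cm,width_dc_cm placement jitter s.d. (cm) in VR / decoupled
#'   conditions.
#' @param p_transient,p_transient_dc per-trial transient probability.
#' @param amp_mean,amp_sd transient peak delta-F/F amplitude distribution.
#' @param motor_gain multiplicative factor on `p_transient` when the animal
#'   is locomoting (> 3 cm/s) at the transient time (`motor_mode =
#'   "multiplicative"`).
#' @param motor_drive tonic additive delta-F/F while locomoting
#'   (`motor_mode = "additive"` integration).
#' @param motor_mode `"multiplicative"` or `"additive"` visuo-motor
#'   combination rule.
#' @param lmi_target trial-type amplitude asymmetry: mean amplitude is scaled
#'   by `(1 + lmi_target)` on short and `(1 - lmi_target)` on long trials, so
#'   the landmark modulation index of the mean responses equals `lmi_target`.
#' @param roi_kind `"soma"` or `"bouton"`.
#' @return data.frame of class `"neuronSpecs"`.
#' @export
neuronSpecs <- function(n, anchor = "landmark", pref_dist_cm = NULL,
                        width_cm = 8, width_dc_cm = width_cm,
                        p_transient = 0.6, p_transient_dc = p_transient,
                        amp_mean = 1.5, amp_sd = 0.3,
                        motor_gain = 1, motor_drive = 0,
                        motor_mode = "multiplicative",
                        lmi_target = 0, roi_kind = "soma") {
    anchor <- rep_len(anchor, n)
    if (is.null(pref_dist_cm)) {
        span <- list(trial_onset = c(10, 110), landmark = c(-20, 100),
                     reward = c(-60, 0))
        pref_dist_cm <- numeric(n)
        for (a in unique(anchor)) {
            i <- which(anchor == a)
            pref_dist_cm[i] <- seq(span[[a]][1], span[[a]][2],
                                   length.out = length(i) + 2)[-c(1, length(i) + 2)]
        }
    }
    out <- data.frame(
        anchor = anchor,
        pref_dist_cm = rep_len(pref_dist_cm, n),
        width_cm = rep_len(width_cm, n),
        width_dc_cm = rep_len(width_dc_cm, n),
        p_transient = rep_len(p_transient, n),
        p_transient_dc = rep_len(p_transient_dc, n),
        amp_mean = rep_len(amp_mean, n),
        amp_sd = rep_len(amp_sd, n),
        motor_gain = rep_len(motor_gain, n),
        motor_drive = rep_len(motor_drive, n),
        motor_mode = rep_len(motor_mode, n),
        lmi_target = rep_len(lmi_target, n),
        roi_kind = rep_len(roi_kind, n)
    )
    stopifnot(all(out$p_transient >= 0 & out$p_transient <= 1),
              all(out$p_transient_dc >= 0 & out$p_transient_dc <= 1),
              all(out$width_cm > 0), all(out$amp_mean > 0),
              all(out$anchor %in% c("trial_onset", "landmark", "reward")))
    class(out) <- c("neuronSpecs", "data.frame")
    out
}

## bounded AR(1) speed sampler (cm/s)
.arSpeed <- function(n, mean, sd, v0 = mean, lo = 5, hi = 45, phi = 0.95) {
    v <- numeric(n)
    innov <- stats::rnorm(n, 0, sd)
    prev <- v0
    for (i in seq_len(n)) {
        prev <- mean + phi * (prev - mean) + innov[i]
        prev <- min(max(prev, lo), hi)
        v[i] <- prev
    }
    v
}

#' Generate a synthetic session with known ground truth
#'
#' Simulates frame-resolved behavior (bounded AR(1) running speed during
#' navigation, policy-driven licking, reward delivery, black-box gaps) and
#' renders neuron delta-F/F as anchored transients (amplitude x exponential
#' decay kernel) on a zero baseline plus i.i.d. Gaussian noise. In the
#' decoupled condition (`"DC"`) the corridor flows at fixed speeds while
#' treadmill locomotion follows an independent on/off bout process, no licks
#' or rewards occur, and the DC-specific tuning parameters of the specs
#' apply.
#'
#' @param config a [genConfig()].
#' @param policy a [behaviorPolicy()] (ignored for `condition = "DC"`).
#' @param specs a [neuronSpecs()] data.frame (may have zero rows for
#'   behavior-only sessions).
#' @param condition `"VR"` or `"DC"`.
#' @param seed integer seed; identical inputs and seed give identical
#'   sessions. Per-neuron sub-seeds are derived deterministically, so a
#'   neuron's trace does not depend on how many neurons are simulated.
#' @return list with `session` (a validated [LandmarkSession-class]) and
#'   `truth` (placement table, per-trial first planned lick, per-frame
#'   locomotion indicator, the inputs used).
#' @export
generateSession <- function(config = genConfig(),
                            policy = behaviorPolicy("expert"),
                            specs = neuronSpecs(0), condition = c("VR", "DC"),
                            seed = 1) {
    condition <- match.arg(condition)
    stopifnot(inherits(config, "genConfig"))
    set.seed(as.integer(seed) %% .Machine$integer.max)
    fr <- config$frame_rate_hz
    dt <- 1 / fr

    types <- switch(config$trial_type_schedule,
        random = sample(c("short", "long"), config$n_trials, replace = TRUE),
        blocks_of_5 = rep(rep(c("short", "long"),
                              length.out = ceiling(config$n_trials / 5)),
                          each = 5)[seq_len(config$n_trials)])

    frames_list <- vector("list", config$n_trials * 2)
    trials <- vector("list", config$n_trials)
    first_lick_truth <- rep(NA_real_, config$n_trials)
    v_prev <- config$speed_mean_cmps

    ## DC locomotion bouts are generated as one session-long process and
    ## consumed frame-by-frame
    dc_speed_pool <- NULL
    if (condition == "DC") {
        pool_n <- ceiling(config$n_trials *
                          (max(350 / min(config$dc_flow_speeds),
                               35) + config$blackbox_s + 2) * fr)
        st <- numeric(0); running <- stats::runif(1) < 0.5
        while (length(st) < pool_n) {
            dur <- stats::rexp(1, 1 / (if (running) config$dc_bout_run_s
                                       else config$dc_bout_rest_s))
            k <- max(1L, round(dur * fr))
            sp <- if (running)
                .arSpeed(k, config$dc_run_speed_cmps, 2, lo = 5, hi = 35)
            else pmax(0, stats::rnorm(k, 0.5, 0.4))
            st <- c(st, sp)
            running <- !running
        }
        dc_speed_pool <- st
    }
    pool_at <- 1L

    for (t in seq_len(config$n_trials)) {
        type <- types[t]
        lm_on <- config$landmark_pos_cm
        start <- lm_on - stats::runif(1, config$start_jitter[1],
                                      config$start_jitter[2])
        lm_off <- lm_on + LANDMARK_WIDTH
        rz_s <- lm_off + RZ_OFFSETS[[type]]
        rz_e <- rz_s + RZ_WIDTH

        ## --- licking plan (track coordinates), VR only ---
        licks <- numeric(0)
        if (condition == "VR") {
            planned <- switch(policy$policy,
                expert = rz_s + stats::rnorm(1, policy$lick_offset_mean_cm,
                                             policy$lick_offset_sd_cm),
                naive = rz_s + stats::rnorm(1, policy$lick_offset_mean_cm,
                                            policy$lick_offset_sd_cm),
                odometer = start + policy$odometer_distance_cm +
                    stats::rnorm(1, policy$lick_offset_mean_cm,
                                 policy$lick_offset_sd_cm),
                random_licker = NA_real_)
            if (!is.na(planned)) {
                bout <- planned + cumsum(c(0, stats::rexp(3, 1 / 4)))
                licks <- bout
                first_lick_truth[t] <- planned
            }
            span <- rz_e + 20 - start
            n_base <- stats::rpois(1, policy$baseline_lick_rate_per_cm * span)
            if (n_base > 0)
                licks <- c(licks, stats::runif(n_base, start, rz_e + 20))
            licks <- sort(licks[licks > start])
        }

        ## --- position/speed series, reward from frame-recorded licks ---
        ## Licks are assigned to the nearest frame; success and the reward
        ## event are then decided from the *recorded* lick positions so that
        ## the stored behavior is self-consistent under frame quantization.
        if (condition == "VR") {
            dist <- rz_e + 2 - start
            v <- numeric(0)
            while (sum(v) * dt < dist) {
                chunk <- .arSpeed(256, config$speed_mean_cmps,
                                  config$speed_sd_cmps, v0 = v_prev)
                v <- c(v, chunk)
                v_prev <- chunk[length(chunk)]
            }
            pos <- start + cumsum(v) * dt
        } else {
            flow <- config$dc_flow_speeds[(t - 1) %% 2 + 1]
            dist <- rz_e + 2 - start
            nf0 <- ceiling(dist / (flow * dt))
            pos <- start + seq_len(nf0) * flow * dt
        }
        lick_frames <- integer(0)
        if (length(licks)) {
            lick_frames <- vapply(licks, function(L)
                which.min(abs(pos - L)), integer(1))
            lick_frames <- sort(unique(lick_frames))
        }
        rec_lick <- pos[lick_frames]
        in_zone <- lick_frames[rec_lick >= rz_s & rec_lick <= rz_e]
        if (condition == "VR" && length(in_zone)) {
            nf <- in_zone[1]
            reward_cm <- pos[nf]
            success <- TRUE
        } else {
            nf <- which(pos >= rz_e)[1]
            reward_cm <- pos[nf]
            success <- FALSE
        }
        pos <- pos[seq_len(nf)]
        if (condition == "VR") {
            speed <- v[seq_len(nf)]
        } else {
            speed <- dc_speed_pool[pool_at:(pool_at + nf - 1)]
            pool_at <- pool_at + nf
        }
        lick_flag <- rep(FALSE, nf)
        lick_flag[lick_frames[lick_frames <= nf]] <- TRUE
        reward_flag <- rep(FALSE, nf)
        if (condition == "VR") reward_flag[nf] <- TRUE

        frames_list[[2 * t - 1]] <- data.frame(
            position_cm = pos, speed_cmps = speed, lick = lick_flag,
            reward = reward_flag, trial_id = t, blackbox = FALSE)

        ## --- black box ---
        nbb <- round((config$blackbox_s + stats::runif(1, 0, 0.5)) * fr)
        if (condition == "VR") {
            bb_speed <- .arSpeed(nbb, config$speed_mean_cmps,
                                 config$speed_sd_cmps, v0 = v_prev)
            v_prev <- bb_speed[nbb]
        } else {
            bb_speed <- dc_speed_pool[pool_at:(pool_at + nbb - 1)]
            pool_at <- pool_at + nbb
        }
        frames_list[[2 * t]] <- data.frame(
            position_cm = NA_real_, speed_cmps = bb_speed, lick = FALSE,
            reward = FALSE, trial_id = NA_integer_, blackbox = TRUE)

        trials[[t]] <- data.frame(
            trial_id = t, trial_type = type, start_cm = start,
            landmark_on_cm = lm_on, landmark_off_cm = lm_off,
            rz_start_cm = rz_s, rz_end_cm = rz_e,
            reward_cm = if (condition == "VR") reward_cm else NA_real_,
            success = success, stim = FALSE)
    }

    frames <- do.call(rbind, frames_list)
    frames <- cbind(time_s = (seq_len(nrow(frames)) - 1) * dt, frames)
    trials <- do.call(rbind, trials)
    n_frames <- nrow(frames)
    running <- frames$speed_cmps > 3

    ## --- neural traces ---
    n_roi <- nrow(specs)
    dff <- matrix(0, n_roi, n_frames)
    placements <- vector("list", n_roi)
    tau_f <- config$gcamp_decay_tau_s * fr
    klen <- ceiling(5 * tau_f)
    kernel <- exp(-(0:klen) / tau_f)
    tid <- frames$trial_id
    trial_start_frame <- vapply(trials$trial_id, function(id)
        which(!is.na(tid) & tid == id)[1], numeric(1))
    trial_end_frame <- vapply(trials$trial_id, function(id)
        max(which(!is.na(tid) & tid == id)), numeric(1))

    for (j in seq_len(n_roi)) {
        set.seed((as.integer(seed) %% 1000003L) * 2017L + j)
        sp <- specs[j, ]
        p <- if (condition == "VR") sp$p_transient else sp$p_transient_dc
        wd <- if (condition == "VR") sp$width_cm else sp$width_dc_cm
        anchors <- anchorPosition(trials, sp$anchor)
        amp_scale <- ifelse(trials$trial_type == "short",
                            1 + sp$lmi_target, 1 - sp$lmi_target)
        d <- stats::rnorm(config$n_trials, sp$pref_dist_cm, wd)
        u <- stats::runif(config$n_trials)
        amps <- pmax(0.05, stats::rnorm(config$n_trials,
                                        sp$amp_mean * amp_scale, sp$amp_sd))
        rec <- data.frame(roi = j, trial_id = trials$trial_id,
                          aligned_cm = d, frame = NA_integer_,
                          amp = amps, occurred = FALSE)
        for (t in seq_len(config$n_trials)) {
            target <- anchors[t] + d[t]
            f0 <- trial_start_frame[t]; f1 <- trial_end_frame[t]
            seg <- frames$position_cm[f0:f1]
            if (target < seg[1] || target > seg[length(seg)]) next
            f <- f0 + which(seg >= target)[1] - 1L
            p_eff <- p
            if (sp$motor_mode == "multiplicative" && running[f])
                p_eff <- min(1, p * sp$motor_gain)
            if (u[t] >= p_eff) next
            rec$frame[t] <- f
            rec$occurred[t] <- TRUE
            idx <- f:min(n_frames, f + klen)
            dff[j, idx] <- dff[j, idx] + amps[t] * kernel[seq_along(idx)]
        }
        if (sp$motor_mode == "additive" && sp$motor_drive != 0)
            dff[j, ] <- dff[j, ] + sp$motor_drive * running
        if (config$noise_sd > 0)
            dff[j, ] <- dff[j, ] + stats::rnorm(n_frames, 0, config$noise_sd)
        placements[[j]] <- rec
    }

    roi_info <- data.frame(
        roi_id = if (n_roi) sprintf("roi_%03d", seq_len(n_roi))
                 else character(),
        roi_kind = specs$roi_kind,
        layer_label = rep(NA_character_, n_roi))

    session <- LandmarkSession(
        frames = frames, trials = trials, dff = dff, roiInfo = roi_info,
        condition = condition, frameRate = fr,
        dcFlowSpeeds = if (condition == "DC") config$dc_flow_speeds
                       else numeric())

    truth <- list(
        specs = specs,
        placements = if (n_roi) do.call(rbind, placements)
                     else data.frame(),
        first_lick_cm = first_lick_truth,
        running = running,
        condition = condition, seed = seed)
    list(session = session, truth = truth)
}

#' Generate a matched VR / decoupled session pair
#'
#' Same neurons (same specs, same ROI ordering and per-neuron sub-seeds) are
#' rendered in a closed-loop navigation session and in a decoupled open-loop
#' session, emulating recordings of one field of view under both conditions.
#'
#' @inheritParams generateSession
#' @return list with `vr` and `dc`, each a `generateSession()` result.
#' @export
generateConditionPair <- function(config = genConfig(),
                                  policy = behaviorPolicy("expert"),
                                  specs = neuronSpecs(0), seed = 1) {
    vr <- generateSession(config, policy, specs, condition = "VR",
                          seed = seed)
    dc <- generateSession(config, policy, specs, condition = "DC",
                          seed = seed + 77003L)
    list(vr = vr, dc = dc)
}
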