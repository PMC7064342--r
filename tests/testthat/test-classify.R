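test_that("mean aligned trace of identical trials equals a single trial", {
    f <- bump(260, width = 12, amp = 1.5)
    s <- manualSession(starts = c(100, 100, 100), rep("short", 3),
                       licks_cm = list(c(325), c(325), c(325)),
                       dffFun = list(f))
    mt <- meanAlignedTrace(s, 1, "landmark")
    one <- alignedBinnedActivity(s, 1, "landmark")
    expect_equal(mt$mean, one$activity[1, , 1], tolerance = 1e-12)
    expect_equal(mt$coverage[!is.na(mt$mean)],
                 rep(1, sum(!is.na(mt$mean))))
    # peak near the bump center, landmark-aligned (260 - 200 = 60)
    expect_equal(mt$centers[which.max(mt$mean)], 60, tolerance = 5)
})

test_that("bins covered by fewer than half the trials are masked", {
    g <- generateSession(genConfig(n_trials = 60),
                         behaviorPolicy("expert"),
                         neuronSpecs(1, pref_dist_cm = 30), seed = 31)
    mt <- meanAlignedTrace(g$session, 1, "landmark")
    first_valid <- min(mt$centers[!is.na(mt$mean)])
    # starts are uniform 50-150 cm before the landmark: the median start is
    # 100 cm out, so coverage crosses 50% near -100 cm (sampling noise of
    # the 60 drawn starts shifts the boundary by a bin or two)
    expect_gte(first_valid, -115)
    expect_lte(first_valid, -85)
    expect_error(meanAlignedTrace(g$session, 1, "landmark",
                                  minCoverage = 1.01), "masked")
})

test_that("LMI follows its closed form and symmetry", {
    expect_equal(landmarkModulationIndex(2, 2), 0)
    expect_equal(landmarkModulationIndex(1, 0), 1)
    expect_equal(landmarkModulationIndex(0.3, 0.1), 0.5)
    expect_true(is.na(landmarkModulationIndex(0, 0)))
    for (ab in list(c(1.3, 0.2), c(0.5, 2), c(0.01, 0.9))) {
        expect_equal(landmarkModulationIndex(ab[1], ab[2]),
                     -landmarkModulationIndex(ab[2], ab[1]))
        expect_lte(abs(landmarkModulationIndex(ab[1], ab[2])), 1)
    }
})

test_that("shuffle z-score separates tuned neurons from noise", {
    specs <- rbind(neuronSpecs(1, anchor = "landmark", pref_dist_cm = 20,
                               p_transient = 0.9, width_cm = 5),
                   neuronSpecs(1, p_transient = 0))
    g <- generateSession(genConfig(n_trials = 30),
                         behaviorPolicy("expert"), specs, seed = 32)
    z_tuned <- shufflePeakZscore(g$session, 1, "landmark",
                                 nShuffles = 300, seed = 1)$z
    expect_gt(z_tuned, 3)
    z_noise <- vapply(1:5, function(s)
        shufflePeakZscore(g$session, 2, "landmark", nShuffles = 300,
                          seed = s)$z, numeric(1))
    expect_true(all(abs(z_noise) < 4))
})

test_that("a constant trace yields a zero-variance null error", {
    s <- manualSession(starts = c(100, 100), rep("short", 2),
                       dffFun = list(function(pos, trial) 1))
    expect_error(shufflePeakZscore(s, 1, "landmark", nShuffles = 50),
                 "zero-variance")
})

test_that("anchor categories are recovered on a mixed population", {
    specs <- neuronSpecs(12, anchor = rep(c("trial_onset", "landmark",
                                            "reward"), each = 4),
                         p_transient = 0.7, width_cm = 8)
    g <- generateSession(genConfig(n_trials = 50),
                         behaviorPolicy("expert"), specs, seed = 33)
    got <- vapply(seq_len(12), function(i)
        assignAlignment(g$session, i)$category, character(1))
    expect_gte(sum(got == specs$anchor), 10)
})

test_that("zone-start reward alignment ties with landmark alignment and is
           tie-broken to landmark", {
    # without per-trial reward events the reward anchor is a rigid shift of
    # the landmark anchor within one trial type
    specs <- neuronSpecs(1, anchor = "landmark", pref_dist_cm = 40,
                         p_transient = 0.9)
    g <- generateSession(genConfig(n_trials = 20),
                         behaviorPolicy("expert"), specs,
                         condition = "DC", seed = 34)
    a <- assignAlignment(g$session, 1, trialType = "short")
    expect_true(a$tie)
    expect_equal(a$category, "landmark")
    expect_equal(unname(a$peaks["landmark"]), unname(a$peaks["reward"]),
                 tolerance = 1e-12)
})

test_that("engagement requires all four criteria", {
    specs <- rbind(
        neuronSpecs(1, anchor = "landmark", pref_dist_cm = 30,
                    p_transient = 0.8, amp_mean = 2),      # engaged
        neuronSpecs(1, p_transient = 0),                   # silent
        neuronSpecs(1, anchor = "landmark", pref_dist_cm = 30,
                    p_transient = 0.1, amp_mean = 2))      # unreliable
    g <- generateSession(genConfig(n_trials = 40),
                         behaviorPolicy("expert"), specs, seed = 35)
    strong <- isTaskEngaged(g$session, 1, "short", nShuffles = 300)
    expect_true(strong$engaged)
    silent <- isTaskEngaged(g$session, 2, "short", nShuffles = 300)
    expect_false(silent$engaged)
    expect_false(silent$criteria[["rate"]])
    sparse <- isTaskEngaged(g$session, 3, "short", nShuffles = 300)
    expect_false(sparse$criteria[["trial_fraction"]])
    expect_false(sparse$engaged)
})

test_that("classifySession assembles records with LMI for landmark cells", {
    specs <- neuronSpecs(3, anchor = "landmark",
                         pref_dist_cm = c(10, 40, 70),
                         p_transient = 0.8, amp_mean = 2,
                         lmi_target = c(0.5, 0, -0.5))
    g <- generateSession(genConfig(n_trials = 50),
                         behaviorPolicy("expert"), specs, seed = 36)
    rec <- classifySession(g$session, nShuffles = 200, seed = 2)
    expect_equal(nrow(rec), 3)
    expect_true(all(rec$category_pooled == "landmark"))
    expect_true(all(is.finite(rec$lmi)))
    expect_gt(rec$lmi[1], rec$lmi[2])
    expect_gt(rec$lmi[2], rec$lmi[3])
    expect_lt(abs(rec$lmi[2]), 0.3)
    expect_lt(abs(rec$lmi[1] - 0.5), 0.3)
})

test_that("accuracy split recovers amplitude/accuracy coupling", {
    specs <- neuronSpecs(1, anchor = "landmark", pref_dist_cm = 30,
                         p_transient = 1, width_cm = 4, amp_sd = 0)
    g <- generateSession(genConfig(n_trials = 40),
                         behaviorPolicy("expert",
                                        lick_offset_sd_cm = 10), specs,
                         seed = 37)
    s <- g$session
    # couple amplitude to accuracy after the fact: double the trace on the
    # most accurate half of trials
    licks <- firstLickLocations(s)
    acc <- abs(licks$first_lick_track_cm - trialTable(s)$rz_start_cm)
    hi <- trialTable(s)$trial_id[!is.na(acc) & acc <= median(acc,
                                                             na.rm = TRUE)]
    dff <- dffMatrix(s)
    tid <- frameData(s)$trial_id
    dff[1, !is.na(tid) & tid %in% hi] <- 2 * dff[1, !is.na(tid) &
                                                 tid %in% hi]
    s2 <- LandmarkSession(frameData(s), trialTable(s), dff = dff,
                          frameRate = frameRate(s))
    res <- accuracySplitActivity(s2, 1)
    expect_gt(res$difference, 0.5)
    # and the uncoupled neuron shows no material difference
    res0 <- accuracySplitActivity(s, 1)
    expect_lt(abs(res0$difference), 0.5)
})

test_that("accuracy split needs enough licked trials", {
    s <- manualSession(starts = rep(100, 3), rep("short", 3),
                       licks_cm = list(c(325), c(326), c(327)),
                       dffFun = list(bump(260)))
    expect_error(accuracySplitActivity(s, 1), "at least 8")
})
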