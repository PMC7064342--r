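test_that("identical trials give identical split halves", {
    f1 <- bump(230); f2 <- bump(280); f3 <- bump(320)
    s <- manualSession(starts = rep(100, 4), rep("short", 4),
                       licks_cm = rep(list(c(325)), 4),
                       dffFun = list(f1, f2, f3))
    pv <- buildPopulationVectors(s, anchor = "landmark", seed = 5)
    expect_equal(pv$matrix_A, pv$matrix_B, tolerance = 1e-12)
    pv2 <- buildPopulationVectors(s, anchor = "landmark", seed = 5)
    expect_identical(pv$split, pv2$split)  # same seed, same split
})

test_that("even tiling produces monotone peak locations", {
    n <- 10
    specs <- neuronSpecs(n, anchor = "landmark",
                         pref_dist_cm = seq(-60, 120, length.out = n),
                         p_transient = 1, width_cm = 1e-6, amp_sd = 0)
    g <- generateSession(deterministicConfig(n_trials = 8),
                         deterministicPolicy(), specs, seed = 51)
    pv <- buildPopulationVectors(g$session, anchor = "landmark", seed = 1)
    expect_true(all(diff(pv$peak_bin_A) > 0))
})

test_that("cross-correlation matches a brute-force two-split oracle", {
    mkbump <- function(center) function(pos, trial)
        (1 + 0.2 * trial) * exp(-(pos - center)^2 / (2 * 25^2))
    s <- manualSession(starts = rep(100, 4), rep("short", 4),
                       licks_cm = rep(list(c(325)), 4),
                       dffFun = list(mkbump(160), mkbump(230), mkbump(300)))
    binCm <- 60  # 4 coarse bins across the traversal
    cc <- crosscorrMatrix(s, anchor = "landmark", binCm = binCm,
                          nSplits = 2, seed = 99)

    ## ---- independent oracle ----
    fr <- frameData(s); tr <- trialTable(s)
    keep <- !fr$blackbox
    d <- fr$position_cm[keep] - 200
    trial <- fr$trial_id[keep]
    b <- floor(d / binCm)
    bins <- min(b):max(b)
    binned <- array(NA_real_, c(4, length(bins), 3))
    dff <- dffMatrix(s)[, keep, drop = FALSE]
    for (t in 1:4) for (k in seq_along(bins)) {
        sel <- trial == t & b == bins[k]
        if (any(sel))
            for (j in 1:3) binned[t, k, j] <- mean(dff[j, sel])
    }
    set.seed(99)
    oracle <- 0
    for (split in 1:2) {
        perm <- sample.int(4)
        half <- function(idx) {
            M <- matrix(NA_real_, 3, length(bins))
            for (j in 1:3) for (k in seq_along(bins)) {
                v <- binned[idx, k, j]
                if (mean(!is.na(v)) >= 0.5) M[j, k] <- mean(v, na.rm = TRUE)
            }
            for (j in 1:3) M[j, ] <- M[j, ] / max(M[j, ], na.rm = TRUE)
            M
        }
        A <- half(perm[1:2]); B <- half(perm[3:4])
        C <- matrix(NA_real_, length(bins), length(bins))
        for (i in seq_along(bins)) for (j in seq_along(bins)) {
            ok <- !is.na(A[, i]) & !is.na(B[, j])
            if (sum(ok) >= 2 && sd(A[ok, i]) > 0 && sd(B[ok, j]) > 0)
                C[i, j] <- cor(A[ok, i], B[ok, j])
        }
        oracle <- oracle + C / 2
    }
    expect_equal(dim(cc$mean), dim(oracle))
    expect_lt(max(abs(cc$mean - oracle), na.rm = TRUE), 1e-12)
})

test_that("cross-correlation is invariant to per-neuron positive scaling", {
    specs <- neuronSpecs(5, anchor = "landmark", p_transient = 0.9)
    g <- generateSession(genConfig(n_trials = 16),
                         behaviorPolicy("expert"), specs, seed = 52)
    s <- g$session
    cc1 <- crosscorrMatrix(s, anchor = "landmark", nSplits = 3, seed = 4)
    dff <- dffMatrix(s) * c(0.5, 2, 7, 1, 0.1)
    s2 <- LandmarkSession(frameData(s), trialTable(s), dff = dff,
                          frameRate = frameRate(s))
    cc2 <- crosscorrMatrix(s2, anchor = "landmark", nSplits = 3, seed = 4)
    expect_equal(cc1$mean, cc2$mean, tolerance = 1e-9)
})

test_that("reconstruction error is exact arithmetic on the matrix", {
    ident <- diag(6)
    expect_equal(reconstructionError(ident, binCm = 5)$mean_cm, 0)
    # argmax two bins off on the first four rows, exact elsewhere
    off <- diag(6)
    for (i in 1:4) { off[i, ] <- 0; off[i, i + 2] <- 1 }
    expect_equal(reconstructionError(off, binCm = 5)$mean_cm,
                 (4 * 10 + 0 + 0) / 6)
})

test_that("noise-free deterministic populations reconstruct exactly", {
    n <- 12
    specs <- neuronSpecs(n, anchor = "landmark",
                         pref_dist_cm = seq(-90, 130, length.out = n),
                         p_transient = 1, width_cm = 1e-6, amp_sd = 0)
    g <- generateSession(deterministicConfig(n_trials = 10),
                         deterministicPolicy(), specs, seed = 53)
    cc <- crosscorrMatrix(g$session, anchor = "landmark",
                          trialType = "short", nSplits = 4, seed = 2)
    err <- suppressWarnings(reconstructionError(cc))
    expect_equal(err$mean_cm, 0)
    lp <- localCorrelationProfile(cc)
    expect_true(all(abs(lp$correlation[!is.na(lp$correlation)] - 1) <
                    1e-9))
})

test_that("landmark alignment reconstructs better than trial onset", {
    n <- 36
    specs <- neuronSpecs(n, anchor = "landmark",
                         pref_dist_cm = seq(-100, 140, length.out = n),
                         p_transient = 0.6, width_cm = 8)
    g <- generateSession(genConfig(n_trials = 40),
                         behaviorPolicy("expert"), specs, seed = 54)
    e_lm <- suppressWarnings(reconstructionError(
        crosscorrMatrix(g$session, anchor = "landmark",
                        trialType = "short", seed = 1))$mean_cm)
    e_on <- suppressWarnings(reconstructionError(
        crosscorrMatrix(g$session, anchor = "trial_onset",
                        trialType = "short", seed = 1))$mean_cm)
    expect_lt(e_lm, e_on)
})

test_that("degenerate untuned populations yield missing correlations", {
    s <- manualSession(starts = rep(100, 4), rep("short", 4),
                       dffFun = list(function(p, t) 1,
                                     function(p, t) 1,
                                     function(p, t) 1))
    cc <- crosscorrMatrix(s, anchor = "landmark", nSplits = 2, seed = 1)
    expect_true(all(is.na(cc$mean)))
})
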