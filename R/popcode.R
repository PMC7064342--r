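## Internal: split-half population vector matrices from a trials x bins x
## rois activity array. Half A receives the extra trial when the count is
## odd; A determines each neuron's peak bin (for ordering), each matrix is
## normalized to its own per-neuron maximum.
.popVectorsFromArray <- function(act, idxA, idxB, minCoverage = 0.5) {
    halfMean <- function(idx) {
        sub <- act[idx, , , drop = FALSE]
        m <- apply(sub, c(2, 3), function(x) {
            cov <- mean(!is.na(x))
            if (cov < minCoverage) NA_real_ else mean(x, na.rm = TRUE)
        })
        t(m)  # rois x bins
    }
    A <- halfMean(idxA)
    B <- halfMean(idxB)
    norm <- function(M) {
        mx <- apply(M, 1, function(r) if (all(is.na(r))) NA_real_
                                      else max(r, na.rm = TRUE))
        bad <- is.na(mx) | mx <= 0
        M[bad, ] <- NA_real_
        M[!bad, ] <- M[!bad, , drop = FALSE] / mx[!bad]
        M
    }
    peakA <- apply(A, 1, function(r) if (all(is.na(r))) NA_integer_
                                     else which.max(r))
    list(A = norm(A), B = norm(B), peak_bin_A = peakA)
}

#' Split-half population vectors
#'
#' Randomly splits trials into two halves (half A gets the extra trial when
#' the count is odd). For each neuron and half, activity is binned at
#' `binCm` in anchor-aligned distance (coverage rule: a bin needs data from
#' at least half the trials of its half), averaged across trials, and
#' normalized to the neuron's own maximum. Half A also determines each
#' neuron's peak bin, used for ordering population plots — determining peak
#' location and plotted activity from independent halves avoids introducing
#' artifactual spatial structure.
#'
#' @inheritParams alignedBinnedActivity
#' @param seed RNG seed for the trial split.
#' @param minCoverage per-half minimum fraction of trials covering a bin.
#' @return list with `matrix_A`, `matrix_B` (neurons x bins, normalized),
#'   `bin_centers_cm`, `peak_bin_A`, `anchor`, `split` (the half-A trial
#'   ids).
#' @export
buildPopulationVectors <- function(session, rois = NULL,
                                   anchor = c("landmark", "trial_onset",
                                              "reward"),
                                   binCm = 5, trialType = NULL, seed = 1,
                                   landmarkRef = "onset",
                                   minCoverage = 0.5) {
    anchor <- match.arg(anchor)
    ab <- alignedBinnedActivity(session, rois = rois, anchor = anchor,
                                binCm = binCm, trialType = trialType,
                                landmarkRef = landmarkRef)
    n <- length(ab$trial_ids)
    if (n < 2) stop("need at least 2 trials for a split-half analysis")
    set.seed(as.integer(seed) %% .Machine$integer.max)
    perm <- sample.int(n)
    idxA <- perm[seq_len(ceiling(n / 2))]
    idxB <- perm[seq(ceiling(n / 2) + 1, n)]
    pv <- .popVectorsFromArray(ab$activity, idxA, idxB, minCoverage)
    list(matrix_A = pv$A, matrix_B = pv$B, bin_centers_cm = ab$centers,
         peak_bin_A = pv$peak_bin_A, anchor = anchor,
         split = ab$trial_ids[idxA])
}

#' Split-half population-vector cross-correlation matrix
#'
#' Element `(i, j)` is the Pearson correlation between the half-A population
#' vector at spatial bin `i` and the half-B vector at bin `j` (correlating
#' across neurons), averaged over `nSplits` independent random trial splits
#' to suppress spurious structure from any single split. Bins supported by
#' fewer than 2 neurons in a split are missing for that split.
#'
#' @inheritParams buildPopulationVectors
#' @param nSplits number of random splits averaged (default 10).
#' @return an object of class `"crossCorrMatrix"`: list with `mean`
#'   (bins x bins), `splits` (per-split matrices), `bin_centers_cm`,
#'   `bin_cm`, `anchor`, `n_splits`.
#' @export
crosscorrMatrix <- function(session, rois = NULL,
                            anchor = c("landmark", "trial_onset", "reward"),
                            binCm = 5, trialType = NULL, nSplits = 10,
                            seed = 1, landmarkRef = "onset",
                            minCoverage = 0.5) {
    anchor <- match.arg(anchor)
    if (nRois(session) < 2 && (is.null(rois) || length(rois) < 2))
        stop("need at least 2 neurons")
    ab <- alignedBinnedActivity(session, rois = rois, anchor = anchor,
                                binCm = binCm, trialType = trialType,
                                landmarkRef = landmarkRef)
    n <- length(ab$trial_ids)
    if (n < 2) stop("need at least 2 trials for a split-half analysis")
    set.seed(as.integer(seed) %% .Machine$integer.max)
    splits <- vector("list", nSplits)
    for (s in seq_len(nSplits)) {
        perm <- sample.int(n)
        idxA <- perm[seq_len(ceiling(n / 2))]
        idxB <- perm[seq(ceiling(n / 2) + 1, n)]
        pv <- .popVectorsFromArray(ab$activity, idxA, idxB, minCoverage)
        suppressWarnings(
            cc <- stats::cor(pv$A, pv$B, use = "pairwise.complete.obs"))
        ## bins supported by < 2 neurons are meaningless
        nA <- colSums(!is.na(pv$A)); nB <- colSums(!is.na(pv$B))
        cc[nA < 2, ] <- NA_real_
        cc[, nB < 2] <- NA_real_
        splits[[s]] <- cc
    }
    mean_cc <- Reduce(`+`, lapply(splits, function(m) {
        m[is.na(m)] <- 0; m
    })) / pmax(1, Reduce(`+`, lapply(splits, function(m) !is.na(m))))
    mean_cc[Reduce(`+`, lapply(splits, function(m) !is.na(m))) == 0] <- NA
    structure(list(mean = mean_cc, splits = splits,
                   bin_centers_cm = ab$centers, bin_cm = binCm,
                   anchor = anchor, n_splits = nSplits),
              class = "crossCorrMatrix")
}

#' Location reconstruction error from a cross-correlation matrix
#'
#' For each row (the animal's actual spatial bin) the reconstructed location
#' is the column with the highest cross-correlation; the error is the
#' distance between the two bins in cm. Errors are computed per split map
#' and averaged over splits. Argmax ties are broken toward the actual
#' location (conservative) and all-missing rows are skipped with a warning.
#'
#' @param cc a `"crossCorrMatrix"` object (or a plain bins x bins matrix,
#'   with `binCm` giving the bin width).
#' @param binCm bin width when `cc` is a plain matrix.
#' @return list with `mean_cm`, `per_bin_cm` (profile over actual
#'   locations, averaged over splits), `bin_centers_cm`.
#' @export
reconstructionError <- function(cc, binCm = 5) {
    if (inherits(cc, "crossCorrMatrix")) {
        mats <- cc$splits
        centers <- cc$bin_centers_cm
    } else {
        mats <- list(cc)
        centers <- (seq_len(nrow(cc)) - 0.5) * binCm
    }
    per_split <- matrix(NA_real_, length(mats), length(centers))
    skipped <- 0L
    for (s in seq_along(mats)) {
        m <- mats[[s]]
        for (i in seq_len(nrow(m))) {
            x <- m[i, ]
            if (all(is.na(x))) { skipped <- skipped + 1L; next }
            mx <- max(x, na.rm = TRUE)
            cand <- which(!is.na(x) & x == mx)
            j <- cand[which.min(abs(centers[cand] - centers[i]))]
            per_split[s, i] <- abs(centers[j] - centers[i])
        }
    }
    if (skipped) warning(skipped, " all-missing rows skipped")
    list(mean_cm = mean(rowMeans(per_split, na.rm = TRUE), na.rm = TRUE),
         per_bin_cm = colMeans(per_split, na.rm = TRUE),
         bin_centers_cm = centers)
}

#' Cross-correlation at the animal's actual location
#'
#' The diagonal of the mean cross-correlation matrix: how well the
#' population vector at each position correlates with itself across
#' independent trial halves. Comparing profiles across anchors or conditions
#' (navigation vs decoupled presentation, naive vs expert) shows where and
#' how sharply the population encodes position.
#'
#' @param cc a `"crossCorrMatrix"` object.
#' @return data.frame with `position_cm` and `correlation`.
#' @export
localCorrelationProfile <- function(cc) {
    stopifnot(inherits(cc, "crossCorrMatrix"))
    data.frame(position_cm = cc$bin_centers_cm, correlation = diag(cc$mean))
}
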