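## Internal: single-trial response scalar of one neuron — the peak (or mean)
## of its aligned, binned single-trial trace within `windowCm` of its
## classified peak location.
.singleTrialResponses <- function(session, roi, anchor, peakDist,
                                  trialIds = NULL, windowCm = 20, binCm = 5,
                                  stat = c("peak", "mean"),
                                  landmarkRef = "onset") {
    stat <- match.arg(stat)
    ab <- alignedBinnedActivity(session, rois = roi, anchor = anchor,
                                binCm = binCm, trialIds = NULL,
                                landmarkRef = landmarkRef)
    act <- ab$activity[, , 1, drop = FALSE]
    dim(act) <- dim(ab$activity)[1:2]
    inwin <- abs(ab$centers - peakDist) <= windowCm
    sel <- if (is.null(trialIds)) seq_along(ab$trial_ids)
           else match(trialIds, ab$trial_ids)
    vapply(sel, function(i) {
        x <- act[i, inwin]
        if (all(is.na(x))) return(NA_real_)
        if (stat == "peak") max(x, na.rm = TRUE) else mean(x, na.rm = TRUE)
    }, numeric(1))
}

#' Per-trial population response vectors for decoding
#'
#' For each trial, the response of every included neuron: the peak of its
#' aligned, binned single-trial trace within `windowCm` of its classified
#' peak location. Negative values (delta-F/F noise) are kept.
#'
#' @param session a [LandmarkSession-class].
#' @param classification output of [classifySession()].
#' @param category restrict to neurons of this anchor category
#'   (`"trial_onset"`, `"landmark"`, `"reward"`); a neuron is included when
#'   it carries the category on either trial type.
#' @param windowCm response window around the classified peak (default 20).
#' @param binCm spatial bin width (default 5).
#' @param stat `"peak"` or `"mean"` response within the window.
#' @param landmarkRef landmark edge used for alignment.
#' @return list with `responses` (trials x neurons matrix), `trial_type`,
#'   `trial_ids`, `roi_ids`.
#' @export
trialResponseMatrix <- function(session, classification, category,
                                windowCm = 20, binCm = 5, stat = "peak",
                                landmarkRef = "onset") {
    sel <- which(classification$category_short == category |
                 classification$category_long == category)
    if (!length(sel))
        stop("no neurons classified as '", category, "'")
    tr <- trialTable(session)
    resp <- matrix(NA_real_, nrow(tr), length(sel),
                   dimnames = list(NULL, classification$roi_id[sel]))
    for (k in seq_along(sel)) {
        i <- sel[k]
        pk <- if (classification$category_short[i] == category)
            classification$peak_dist_short[i]
        else classification$peak_dist_long[i]
        resp[, k] <- .singleTrialResponses(session,
                                           classification$roi_id[i],
                                           category, pk,
                                           windowCm = windowCm,
                                           binCm = binCm, stat = stat,
                                           landmarkRef = landmarkRef)
    }
    list(responses = resp, trial_type = tr$trial_type,
         trial_ids = tr$trial_id, roi_ids = colnames(resp))
}

#' Trial-type templates: mean population response per type
#'
#' @param responses trials x neurons response matrix.
#' @param trialType character vector of trial types per row.
#' @param excludeTrial optional row index excluded from its own type's
#'   template (leave-one-out).
#' @return list of named template vectors, one per trial type.
#' @export
buildTemplates <- function(responses, trialType, excludeTrial = NULL) {
    types <- sort(unique(trialType))
    out <- list()
    for (ty in types) {
        rows <- which(trialType == ty)
        if (!is.null(excludeTrial)) rows <- setdiff(rows, excludeTrial)
        if (length(rows) < 1)
            stop("no trials left to build the '", ty, "' template")
        out[[ty]] <- colMeans(responses[rows, , drop = FALSE], na.rm = TRUE)
    }
    out
}

#' Cosine similarity between a single-trial vector and a template
#'
#' `theta = sum(r_t * r_template) / (||r_t|| * ||r_template||)`.
#'
#' @param trialVector,template numeric vectors of equal length.
#' @return similarity in `[-1, 1]` (`[0, 1]` for non-negative vectors).
#' @export
similarityIndex <- function(trialVector, template) {
    stopifnot(length(trialVector) == length(template))
    ok <- !is.na(trialVector) & !is.na(template)
    a <- trialVector[ok]; b <- template[ok]
    na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
    if (na == 0 || nb == 0)
        stop("similarity undefined for a zero-norm vector")
    sum(a * b) / (na * nb)
}

#' Template-matching decoder of trial type
#'
#' Decodes each trial's type as the template with the higher cosine
#' similarity to the trial's population response vector, using neurons of
#' one anchor category. With `holdout = "loo"` (default) the decoded trial
#' is excluded from its own type's template, avoiding optimistic bias; the
#' `"all"` mode uses all trials for both templates.
#'
#' @inheritParams trialResponseMatrix
#' @param holdout `"loo"` or `"all"`.
#' @param seed seed for random tie-breaks (equal similarities).
#' @return list with `fraction_correct`, per-trial `theta` matrix, `decoded`,
#'   `truth`, `ties` (count of randomly broken ties), `n_neurons`.
#' @export
decodeSession <- function(session, classification, category = "landmark",
                          holdout = c("loo", "all"), seed = 1,
                          windowCm = 20, binCm = 5, stat = "peak",
                          landmarkRef = "onset") {
    holdout <- match.arg(holdout)
    rm_ <- trialResponseMatrix(session, classification, category,
                               windowCm = windowCm, binCm = binCm,
                               stat = stat, landmarkRef = landmarkRef)
    resp <- rm_$responses
    types <- sort(unique(rm_$trial_type))
    if (length(types) != 2)
        stop("trial-type decoding requires exactly two trial types")
    set.seed(as.integer(seed) %% .Machine$integer.max)
    n <- nrow(resp)
    theta <- matrix(NA_real_, n, 2, dimnames = list(NULL, types))
    decoded <- character(n)
    ties <- 0L
    for (t in seq_len(n)) {
        tmpl <- buildTemplates(resp, rm_$trial_type,
                               excludeTrial = if (holdout == "loo") t)
        for (ty in types)
            theta[t, ty] <- similarityIndex(resp[t, ], tmpl[[ty]])
        if (abs(theta[t, 1] - theta[t, 2]) < 1e-12) {
            ties <- ties + 1L
            decoded[t] <- types[sample.int(2, 1)]
        } else decoded[t] <- types[which.max(theta[t, ])]
    }
    list(fraction_correct = mean(decoded == rm_$trial_type),
         theta = theta, decoded = decoded, truth = rm_$trial_type,
         ties = ties, n_neurons = ncol(resp))
}
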