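#' Construct a LandmarkSession
#'
#' @param frames data.frame with one row per imaging frame and columns
#'   `time_s`, `position_cm`, `speed_cmps`, `lick`, `reward`, `trial_id`,
#'   `blackbox`. `position_cm` and `trial_id` are `NA` exactly on black-box
#'   frames.
#' @param trials data.frame with columns `trial_id`, `trial_type`
#'   ("short"/"long"), `start_cm`, `landmark_on_cm`, `landmark_off_cm`,
#'   `rz_start_cm`, `rz_end_cm`, `success`, `stim`.
#' @param dff,raw,neuropil ROI x frame matrices (at least one of `dff`/`raw`).
#' @param roiInfo optional data.frame with columns `roi_id` and optionally
#'   `roi_kind` ("soma"/"bouton") and `layer_label`; defaults are generated.
#' @param condition `"VR"` or `"DC"`.
#' @param frameRate imaging frame rate (Hz).
#' @param dcFlowSpeeds corridor flow speeds for DC sessions (cm/s).
#' @param positionEps tolerance (cm) for backwards position steps within a
#'   trial.
#' @param validate run the validity checks (default `TRUE`).
#' @return a [LandmarkSession-class] object.
#' @examples
#' sess <- generateSession(genConfig(n_trials = 4), behaviorPolicy("expert"),
#'                         neuronSpecs(2), seed = 1)$session
#' sess
#' @export
LandmarkSession <- function(frames, trials, dff = NULL, raw = NULL,
                            neuropil = NULL, roiInfo = NULL,
                            condition = c("VR", "DC"), frameRate = 15.5,
                            dcFlowSpeeds = numeric(), positionEps = 0.5,
                            validate = TRUE) {
    condition <- match.arg(condition)
    frames <- as.data.frame(frames)
    trials <- as.data.frame(trials)
    assays <- list()
    if (!is.null(dff)) assays$dff <- as.matrix(dff)
    if (!is.null(raw)) assays$raw <- as.matrix(raw)
    if (!is.null(neuropil)) assays$neuropil <- as.matrix(neuropil)
    if (!length(assays))
        assays$dff <- matrix(numeric(), nrow = 0, ncol = nrow(frames))
    nroi <- nrow(assays[[1]])
    if (is.null(roiInfo)) {
        roiInfo <- data.frame(
            roi_id = if (nroi) paste0("roi_", seq_len(nroi)) else character(),
            roi_kind = rep("soma", nroi),
            layer_label = rep(NA_character_, nroi)
        )
    } else {
        roiInfo <- as.data.frame(roiInfo)
        if (is.null(roiInfo$roi_kind)) roiInfo$roi_kind <- "soma"
        if (is.null(roiInfo$layer_label))
            roiInfo$layer_label <- NA_character_
    }
    assays <- lapply(assays, function(m) {
        rownames(m) <- roiInfo$roi_id
        m
    })
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = assays,
        colData = S4Vectors::DataFrame(frames),
        rowData = S4Vectors::DataFrame(roiInfo)
    )
    obj <- methods::new("LandmarkSession", se, trials = trials,
                        condition = condition, frameRate = frameRate,
                        dcFlowSpeeds = as.numeric(dcFlowSpeeds))
    S4Vectors::metadata(obj)$position_eps <- positionEps
    if (validate) {
        msg <- validateSession(obj)
        if (length(msg))
            stop("invalid session:\n  ", paste(msg, collapse = "\n  "),
                 call. = FALSE)
    }
    obj
}

#' @describeIn LandmarkSession frame-resolved behavior as a data.frame.
#' @param x a `LandmarkSession`.
#' @export
frameData <- function(x) as.data.frame(SummarizedExperiment::colData(x))

#' @describeIn LandmarkSession the trial table.
#' @export
trialTable <- function(x) x@trials

#' @describeIn LandmarkSession the delta-F/F matrix (ROI x frame).
#' @export
dffMatrix <- function(x) SummarizedExperiment::assay(x, "dff")

#' @describeIn LandmarkSession ROI metadata as a data.frame.
#' @export
roiInfo <- function(x) as.data.frame(SummarizedExperiment::rowData(x))

#' @describeIn LandmarkSession `"VR"` or `"DC"`.
#' @export
sessionCondition <- function(x) x@condition

#' @describeIn LandmarkSession imaging frame rate (Hz).
#' @export
frameRate <- function(x) x@frameRate

#' @describeIn LandmarkSession number of trials.
#' @export
nTrials <- function(x) nrow(x@trials)

#' @describeIn LandmarkSession number of ROIs.
#' @export
nRois <- function(x) nrow(x)

#' Frame indices belonging to one trial
#'
#' @param x a `LandmarkSession`.
#' @param trialId a trial id present in `trialTable(x)`.
#' @return integer vector of frame indices (in order).
#' @export
trialFrames <- function(x, trialId) {
    tid <- SummarizedExperiment::colData(x)$trial_id
    which(!is.na(tid) & tid == trialId)
}

setMethod("show", "LandmarkSession", function(object) {
    cat("LandmarkSession (", object@condition, ")\n", sep = "")
    cat("  ", nrow(object), " ROIs x ", ncol(object), " frames @ ",
        object@frameRate, " Hz (",
        round(ncol(object) / object@frameRate / 60, 1), " min)\n", sep = "")
    tr <- object@trials
    if (nrow(tr)) {
        cat("  ", nrow(tr), " trials (",
            sum(tr$trial_type == "short"), " short / ",
            sum(tr$trial_type == "long"), " long)\n", sep = "")
    } else cat("  0 trials\n")
    cat("  assays:", paste(SummarizedExperiment::assayNames(object),
                           collapse = ", "), "\n")
})
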