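#' LandmarkSession: one imaging/behavior session on the virtual linear track
#'
#' `LandmarkSession` extends [SummarizedExperiment::SummarizedExperiment].
#' Rows are ROIs (somata or axonal boutons), columns are imaging frames.
#' Assays hold ROI x frame matrices: `"dff"` (delta-F/F, always present once a
#' session is analysis-ready) and optionally `"raw"` and `"neuropil"`
#' fluorescence. `colData` carries the frame-resolved behavior
#' (`time_s`, `position_cm`, `speed_cmps`, `lick`, `reward`, `trial_id`,
#' `blackbox`); `rowData` carries ROI metadata (`roi_id`, `roi_kind`,
#' `layer_label`).
#'
#' Track coordinates are continuous cm with the landmark cue at a fixed
#' position; each trial starts 50-150 cm before the landmark onset. Black-box
#' frames (screens dark, between trials) have `blackbox = TRUE`,
#' `trial_id = NA` and undefined position.
#'
#' @slot trials `data.frame`, one row per corridor traversal with columns
#'   `trial_id`, `trial_type` ("short"/"long"), `start_cm`, `landmark_on_cm`,
#'   `landmark_off_cm`, `rz_start_cm`, `rz_end_cm`, `success`, `stim`.
#' @slot condition `"VR"` (closed-loop navigation) or `"DC"` (decoupled /
#'   open-loop stimulus presentation).
#' @slot frameRate imaging frame rate in Hz (15.5 and 31 supported).
#' @slot dcFlowSpeeds corridor flow speeds (cm/s) used in DC sessions,
#'   typically `c(10, 30)`; empty for VR sessions.
#'
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @exportClass LandmarkSession
#' @aliases LandmarkSession-class
setClass("LandmarkSession",
    contains = "SummarizedExperiment",
    slots = c(
        trials = "data.frame",
        condition = "character",
        frameRate = "numeric",
        dcFlowSpeeds = "numeric"
    ),
    prototype = prototype(
        trials = data.frame(),
        condition = "VR",
        frameRate = 15.5,
        dcFlowSpeeds = numeric()
    )
)

FRAME_COLUMNS <- c("time_s", "position_cm", "speed_cmps", "lick", "reward",
                   "trial_id", "blackbox")
TRIAL_COLUMNS <- c("trial_id", "trial_type", "start_cm", "landmark_on_cm",
                   "landmark_off_cm", "rz_start_cm", "rz_end_cm", "success",
                   "stim")

## Reward-zone start distances from the landmark *end*, and fixed cue/zone
## widths, as defined by the task geometry.
RZ_OFFSETS <- c(short = 80, long = 140)
LANDMARK_WIDTH <- 40
RZ_WIDTH <- 20
START_RANGE <- c(50, 150)

#' Validate a LandmarkSession against the task-geometry invariants
#'
#' Checks frame-series invariants (strictly increasing time, position defined
#' exactly off the black box, per-trial monotone position up to `positionEps`),
#' trial-geometry invariants (40 cm landmark, 20 cm reward zone at 80/140 cm
#' from the landmark end, start 50-150 cm before the landmark), trace shape,
#' and the frame/trial mapping. Returns a character vector of human-readable
#' violations naming frame/trial indices; `character(0)` if valid.
#'
#' @param object a `LandmarkSession`.
#' @param positionEps tolerance (cm) for backwards position steps within a
#'   trial (treadmill sensor noise). Defaults to `metadata(object)$position_eps`
#'   or 0.5.
#' @return character vector of violation messages (empty if valid).
#' @export
validateSession <- function(object, positionEps = NULL) {
    msg <- character()
    fr <- as.data.frame(SummarizedExperiment::colData(object))
    if (is.null(positionEps)) {
        positionEps <- S4Vectors::metadata(object)$position_eps
        if (is.null(positionEps)) positionEps <- 0.5
    }
    missing_cols <- setdiff(FRAME_COLUMNS, names(fr))
    if (length(missing_cols))
        return(paste("frame table missing columns:",
                     paste(missing_cols, collapse = ", ")))
    tr <- object@trials
    missing_tc <- setdiff(TRIAL_COLUMNS, names(tr))
    if (length(missing_tc))
        return(paste("trial table missing columns:",
                     paste(missing_tc, collapse = ", ")))

    n <- nrow(fr)
    if (n > 1) {
        bad <- which(diff(fr$time_s) <= 0)
        if (length(bad))
            msg <- c(msg, paste0("time_s not strictly increasing at frames: ",
                                 paste(utils::head(bad, 5), collapse = ", ")))
    }
    bad_pos <- which(is.na(fr$position_cm) != fr$blackbox)
    if (length(bad_pos))
        msg <- c(msg, paste0("position_cm must be defined exactly where ",
                             "blackbox is FALSE; offending frames: ",
                             paste(utils::head(bad_pos, 5), collapse = ", ")))
    bad_tid <- which(is.na(fr$trial_id) != fr$blackbox)
    if (length(bad_tid))
        msg <- c(msg, paste0("trial_id must be defined exactly where ",
                             "blackbox is FALSE; offending frames: ",
                             paste(utils::head(bad_tid, 5), collapse = ", ")))
    if (!all(is.na(fr$trial_id) | fr$trial_id %in% tr$trial_id)) {
        orphan <- unique(fr$trial_id[!is.na(fr$trial_id) &
                                     !(fr$trial_id %in% tr$trial_id)])
        msg <- c(msg, paste0("frames reference unknown trial ids: ",
                             paste(utils::head(orphan, 5), collapse = ", ")))
    }
    ## per-trial monotone position up to sensor tolerance
    ok_frames <- which(!fr$blackbox)
    if (length(ok_frames)) {
        sp <- split(fr$position_cm[ok_frames], fr$trial_id[ok_frames])
        for (tid in names(sp)) {
            d <- diff(sp[[tid]])
            if (length(d) && any(d < -positionEps, na.rm = TRUE))
                msg <- c(msg, paste0("position_cm decreases by more than ",
                                     positionEps, " cm within trial ", tid))
        }
    }
    if (nrow(tr)) {
        if (anyDuplicated(tr$trial_id))
            msg <- c(msg, "duplicated trial_id in trial table")
        bad <- which(abs(tr$landmark_off_cm - tr$landmark_on_cm -
                         LANDMARK_WIDTH) > 1e-9)
        if (length(bad))
            msg <- c(msg, paste0("landmark extent != ", LANDMARK_WIDTH,
                                 " cm for trials: ",
                                 paste(tr$trial_id[bad], collapse = ", ")))
        bad <- which(abs(tr$rz_end_cm - tr$rz_start_cm - RZ_WIDTH) > 1e-9)
        if (length(bad))
            msg <- c(msg, paste0("reward zone width != ", RZ_WIDTH,
                                 " cm for trials: ",
                                 paste(tr$trial_id[bad], collapse = ", ")))
        off <- tr$rz_start_cm - tr$landmark_off_cm
        expected <- unname(RZ_OFFSETS[as.character(tr$trial_type)])
        bad <- which(is.na(expected) | abs(off - expected) > 1e-9)
        if (length(bad))
            msg <- c(msg, paste0("reward-zone offset from landmark end must ",
                                 "be 80 (short) / 140 (long) cm; offending ",
                                 "trials: ",
                                 paste(tr$trial_id[bad], collapse = ", ")))
        d0 <- tr$landmark_on_cm - tr$start_cm
        bad <- which(d0 < START_RANGE[1] - 1e-9 | d0 > START_RANGE[2] + 1e-9)
        if (length(bad))
            msg <- c(msg, paste0("trial start must lie 50-150 cm before the ",
                                 "landmark; offending trials: ",
                                 paste(tr$trial_id[bad], collapse = ", ")))
    }
    if (!(length(object@condition) == 1L &&
          object@condition %in% c("VR", "DC")))
        msg <- c(msg, "condition must be one of 'VR', 'DC'")
    if (!(length(object@frameRate) == 1L && object@frameRate > 0))
        msg <- c(msg, "frameRate must be a single positive number")
    for (a in SummarizedExperiment::assayNames(object)) {
        m <- SummarizedExperiment::assay(object, a)
        if (ncol(m) != n)
            msg <- c(msg, paste0("assay '", a, "' has ", ncol(m),
                                 " frames; behavior has ", n))
    }
    if (all(c("raw", "dff") %in% SummarizedExperiment::assayNames(object))) {
        raw <- SummarizedExperiment::assay(object, "raw")
        dff <- SummarizedExperiment::assay(object, "dff")
        if (any(is.finite(raw) & !is.finite(dff)))
            msg <- c(msg, "dff must be finite wherever raw is finite")
    }
    msg
}

setValidity("LandmarkSession", function(object) {
    msg <- validateSession(object)
    if (length(msg)) msg else TRUE
})
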