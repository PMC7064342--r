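## Plain-text session container
##
## A session directory holds:
##   frames.csv   time_s, position_cm, speed_cmps, lick, reward, trial_id,
##                blackbox
##   trials.csv   trial_id, trial_type, start_cm, landmark_on_cm,
##                landmark_off_cm, rz_start_cm, rz_end_cm, reward_cm,
##                success, stim
##   rois.csv     roi_id, roi_kind, layer_label
##   dff.csv / raw.csv / neuropil.csv   ROI x frame matrices, first column
##                roi_id (files present only when the assay exists)
##   meta.json    condition, frame_rate_hz, dc_flow_speeds, position_eps
##
## Numeric values are serialized with "%.17g" so that write -> read is the
## identity on doubles, and the byte layout is a pure function of the session
## (no timestamps), so identical sessions produce identical files.

.fmtCol <- function(x) {
    if (is.double(x)) {
        out <- sprintf("%.17g", x)
        out[is.na(x)] <- "NA"
        out
    } else if (is.logical(x)) {
        out <- ifelse(x, "TRUE", "FALSE")
        out[is.na(x)] <- "NA"
        out
    } else {
        out <- as.character(x)
        out[is.na(x)] <- "NA"
        out
    }
}

.writeTable <- function(df, path) {
    out <- as.data.frame(lapply(df, .fmtCol), optional = TRUE)
    names(out) <- names(df)
    data.table::fwrite(out, path, quote = FALSE, sep = ",", eol = "\n",
                       na = "NA")
}

#' Write a session to its plain-text container
#'
#' Writes a directory of CSV tables plus `meta.json` (see the package
#' vignette for the documented layout). The byte layout is deterministic
#' given identical input: rewriting the same session produces identical
#' checksums.
#'
#' @param session a [LandmarkSession-class].
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
writeSession <- function(session, path) {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    fr <- frameData(session)[, FRAME_COLUMNS]
    .writeTable(fr, file.path(path, "frames.csv"))
    tr <- trialTable(session)
    if (is.null(tr$reward_cm)) tr$reward_cm <- NA_real_
    cols <- c(TRIAL_COLUMNS[1:7], "reward_cm", "success", "stim")
    .writeTable(tr[, cols], file.path(path, "trials.csv"))
    .writeTable(roiInfo(session)[, c("roi_id", "roi_kind", "layer_label")],
                file.path(path, "rois.csv"))
    for (a in SummarizedExperiment::assayNames(session)) {
        m <- SummarizedExperiment::assay(session, a)
        df <- data.frame(roi_id = roiInfo(session)$roi_id)
        if (ncol(m)) {
            vals <- as.data.frame(matrix(sprintf("%.17g", t(m)),
                                         nrow = nrow(m), byrow = TRUE),
                                  optional = TRUE)
            names(vals) <- sprintf("f%06d", seq_len(ncol(m)))
            df <- cbind(df, vals)
        }
        data.table::fwrite(df, file.path(path, paste0(a, ".csv")),
                           quote = FALSE, sep = ",", eol = "\n", na = "NA")
    }
    meta <- list(format = "landmark-session/1",
                 condition = sessionCondition(session),
                 frame_rate_hz = frameRate(session),
                 dc_flow_speeds = session@dcFlowSpeeds,
                 position_eps = S4Vectors::metadata(session)$position_eps,
                 assays = SummarizedExperiment::assayNames(session))
    writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA),
               file.path(path, "meta.json"))
    invisible(path)
}

.readTable <- function(path, classes) {
    if (!file.exists(path))
        stop("schema error: missing file ", path, call. = FALSE)
    dt <- data.table::fread(path, sep = ",", na.strings = "NA",
                            colClasses = classes, data.table = FALSE)
    missing <- setdiff(names(classes), names(dt))
    if (length(missing))
        stop("schema error: ", basename(path), " missing columns: ",
             paste(missing, collapse = ", "), call. = FALSE)
    dt[names(classes)]
}

#' Read a session from its plain-text container
#'
#' Reads the layout written by [writeSession()], validates all session
#' invariants, and reports violations with frame/trial indices.
#'
#' @param path session directory.
#' @return a validated [LandmarkSession-class].
#' @export
readSession <- function(path) {
    metapath <- file.path(path, "meta.json")
    if (!file.exists(metapath))
        stop("schema error: missing file ", metapath, call. = FALSE)
    meta <- jsonlite::fromJSON(metapath)
    frames <- .readTable(file.path(path, "frames.csv"),
                         c(time_s = "numeric", position_cm = "numeric",
                           speed_cmps = "numeric", lick = "logical",
                           reward = "logical", trial_id = "integer",
                           blackbox = "logical"))
    trials <- .readTable(file.path(path, "trials.csv"),
                         c(trial_id = "integer", trial_type = "character",
                           start_cm = "numeric", landmark_on_cm = "numeric",
                           landmark_off_cm = "numeric",
                           rz_start_cm = "numeric", rz_end_cm = "numeric",
                           reward_cm = "numeric", success = "logical",
                           stim = "logical"))
    rois <- .readTable(file.path(path, "rois.csv"),
                       c(roi_id = "character", roi_kind = "character",
                         layer_label = "character"))
    assays <- list()
    for (a in meta$assays) {
        f <- file.path(path, paste0(a, ".csv"))
        if (!file.exists(f))
            stop("schema error: meta.json lists assay '", a,
                 "' but ", f, " is missing", call. = FALSE)
        dt <- data.table::fread(f, sep = ",", na.strings = "NA",
                                data.table = FALSE)
        m <- as.matrix(dt[, -1, drop = FALSE])
        dimnames(m) <- NULL
        storage.mode(m) <- "double"
        assays[[a]] <- m
    }
    if (!length(assays))
        assays$dff <- matrix(numeric(), 0, nrow(frames))
    LandmarkSession(frames = frames, trials = trials,
                    dff = assays$dff, raw = assays$raw,
                    neuropil = assays$neuropil, roiInfo = rois,
                    condition = meta$condition,
                    frameRate = meta$frame_rate_hz,
                    dcFlowSpeeds = unlist(meta$dc_flow_speeds),
                    positionEps = if (is.null(meta$position_eps)) 0.5
                                  else meta$position_eps)
}
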