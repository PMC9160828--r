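# File interchange: BrainVision triplets for recordings, CSV for subject
# tables, JSON for validation reports and selection artifacts.

#' Write a recording as a BrainVision triplet
#'
#' Produces `<basename>.vhdr` (text header), `<basename>.vmrk` (marker
#' file) and `<basename>.eeg` (little-endian IEEE float32, multiplexed,
#' microvolts, resolution 1).
#'
#' @param rec an [eeg_recording()]
#' @param basename file basename without extension
#' @param dir output directory (created if needed)
#' @return the .vhdr path, invisibly
#' @export
write_brainvision <- function(rec, basename, dir = ".") {
  stopifnot(inherits(rec, "eeg_recording"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vhdr <- file.path(dir, paste0(basename, ".vhdr"))
  vmrk <- file.path(dir, paste0(basename, ".vmrk"))
  eegf <- file.path(dir, paste0(basename, ".eeg"))
  nch <- nrow(rec$data)
  header <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    sprintf("; subject=%s condition=%s", rec$subject_id, rec$condition),
    "",
    "[Common Infos]",
    "Codepage=UTF-8",
    sprintf("DataFile=%s.eeg", basename),
    sprintf("MarkerFile=%s.vmrk", basename),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    sprintf("NumberOfChannels=%d", nch),
    sprintf("SamplingInterval=%g", 1e6 / rec$fs),
    "",
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,uV", seq_len(nch), rec$channel_labels)
  )
  writeLines(header, vhdr)
  writeLines(c(
    "Brain Vision Data Exchange Marker File, Version 1.0",
    "",
    "[Common Infos]",
    sprintf("DataFile=%s.eeg", basename),
    "",
    "[Marker Infos]",
    "Mk1=New Segment,,1,1,0,0"
  ), vmrk)
  con <- file(eegf, "wb")
  on.exit(close(con))
  writeBin(as.numeric(rec$data), con, size = 4, endian = "little")
  invisible(vhdr)
}

#' Read a BrainVision triplet
#'
#' Supports the subset this package writes: binary multiplexed IEEE float32
#' or 16-bit signed integers, with per-channel resolution applied.
#'
#' @param vhdr_path path to the .vhdr header
#' @param subject_id,condition metadata not carried by the format
#' @return an [eeg_recording()]
#' @export
read_brainvision <- function(vhdr_path, subject_id = NULL,
                             condition = "eyes-closed") {
  lines <- readLines(vhdr_path, warn = FALSE)
  getval <- function(key) {
    hit <- grep(paste0("^", key, "="), lines, value = TRUE)
    if (length(hit) == 0) stop("missing header key: ", key, call. = FALSE)
    sub(paste0("^", key, "="), "", hit[1])
  }
  datafile <- getval("DataFile")
  nch <- as.integer(getval("NumberOfChannels"))
  fs <- 1e6 / as.numeric(getval("SamplingInterval"))
  fmt <- getval("BinaryFormat")
  orientation <- getval("DataOrientation")
  if (orientation != "MULTIPLEXED") {
    stop("only MULTIPLEXED orientation is supported", call. = FALSE)
  }
  ch_lines <- grep("^Ch[0-9]+=", lines, value = TRUE)
  ch_parts <- strsplit(sub("^Ch[0-9]+=", "", ch_lines), ",")
  labels <- vapply(ch_parts, `[`, character(1), 1)
  resolution <- vapply(ch_parts, function(p) {
    r <- suppressWarnings(as.numeric(p[3]))
    if (is.na(r)) 1 else r
  }, numeric(1))
  eegf <- file.path(dirname(vhdr_path), datafile)
  sz <- file.info(eegf)$size
  con <- file(eegf, "rb")
  on.exit(close(con))
  raw_vals <- if (fmt == "IEEE_FLOAT_32") {
    readBin(con, "numeric", n = sz / 4, size = 4, endian = "little")
  } else if (fmt == "INT_16") {
    readBin(con, "integer", n = sz / 2, size = 2, signed = TRUE,
            endian = "little")
  } else {
    stop("unsupported BinaryFormat: ", fmt, call. = FALSE)
  }
  ns <- length(raw_vals) %/% nch
  data <- matrix(raw_vals[seq_len(ns * nch)], nrow = nch) * resolution
  eeg_recording(data, fs, labels,
                subject_id = subject_id %||% sub("\\.vhdr$", "", basename(vhdr_path)),
                condition = condition)
}

#' Write / read the subject metadata table
#'
#' CSV with columns subject_id, mmse_pre, mmse_post, condition; labels are
#' derived, not stored (see [label_subjects()]).
#'
#' @param subjects subjects data.frame
#' @param path CSV path
#' @return the path, invisibly
#' @export
write_subject_table <- function(subjects, path) {
  write.csv(subjects[, c("subject_id", "mmse_pre", "mmse_post", "condition")],
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_subject_table
#' @export
read_subject_table <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Serialize a validation report to JSON
#'
#' The report embeds its configuration snapshot (including the seed) and a
#' fingerprint of that configuration, so a run can be reproduced from the
#' artifact alone.
#'
#' @param report a `validation_report`
#' @param path output path
#' @return the path, invisibly
#' @export
write_validation_report <- function(report, path) {
  stopifnot(inherits(report, "validation_report"))
  payload <- list(
    config = report$config,
    config_fingerprint = config_fingerprint(report$config),
    overall = report$overall,
    sd_trials = report$sd_trials,
    n_trials_total = report$n_trials_total,
    per_subject = report$per_subject,
    skipped_folds = report$skipped_folds
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# md5 of the canonical JSON encoding of a configuration list
config_fingerprint <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Serialize a fitted SVM model to JSON (exact reload)
#'
#' @param model an `svm_model`
#' @param path output path
#' @return the path, invisibly
#' @export
write_svm_model <- function(model, path) {
  stopifnot(inherits(model, "svm_model"))
  payload <- list(sv = model$sv, coef = model$coef, b = model$b,
                  params = unclass(model$params),
                  n_features = model$n_features,
                  levels = as.list(model$levels),
                  train_majority = model$train_majority)
  if (!is.null(model$scaling)) payload$scaling <- unclass(model$scaling)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_svm_model
#' @export
read_svm_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  lv <- unlist(p$levels)
  sv <- p$sv
  if (!is.matrix(sv)) sv <- matrix(sv, nrow = length(p$coef), byrow = TRUE)
  structure(
    list(sv = sv, coef = p$coef,
         alpha = abs(p$coef), sv_labels = sign(p$coef), b = p$b,
         params = structure(p$params, class = "svm_params"),
         n_sv = length(p$coef), n_features = p$n_features,
         levels = lv, train_majority = p$train_majority,
         scaling = if (length(p$scaling) > 0)
           structure(p$scaling, class = "standardizer")),
    class = "svm_model"
  )
}
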