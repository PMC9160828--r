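#' Construct a continuous multichannel EEG recording
#'
#' A light container for a continuous scalp EEG segment: a channels x samples
#' matrix in microvolts plus sampling rate and montage metadata.
#'
#' @param data numeric matrix, channels x samples (microvolts)
#' @param fs sampling rate in Hz
#' @param channel_labels character vector of unique 10-20 electrode names,
#'   one per row of `data`
#' @param subject_id subject identifier
#' @param condition recording condition, `"eyes-closed"` or `"eyes-open"`
#' @return object of class `eeg_recording`
#' @export
eeg_recording <- function(data, fs, channel_labels,
                          subject_id = "unknown",
                          condition = c("eyes-closed", "eyes-open")) {
  condition <- match.arg(condition)
  data <- as.matrix(data)
  if (!is.numeric(data) || nrow(data) < 1L) {
    stop("data must be a numeric channels x samples matrix with >= 1 channel",
         call. = FALSE)
  }
  if (anyNA(data)) stop("recording contains NA samples", call. = FALSE)
  if (!(is.numeric(fs) && length(fs) == 1L && fs > 0)) {
    stop("fs must be a positive scalar", call. = FALSE)
  }
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != nrow(data)) {
    stop("channel_labels length must match the number of channels", call. = FALSE)
  }
  if (anyDuplicated(channel_labels)) {
    stop("channel labels must be unique", call. = FALSE)
  }
  structure(
    list(data = data, fs = fs, channel_labels = channel_labels,
         subject_id = subject_id, condition = condition),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s (%s): %d channels x %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, x$condition, nrow(x$data), ncol(x$data), x$fs,
              ncol(x$data) / x$fs))
  invisible(x)
}

# Default 30-electrode scalp montage (10-20 extended), i.e. a 32-channel cap
# with reference/ground/EOG excluded from analysis channels.
default_montage <- function(n_channels = 30L) {
  labels <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
              "FC5", "FC1", "FC2", "FC6", "T7", "C3", "Cz", "C4", "T8",
              "TP9", "CP5", "CP1", "CP2", "CP6", "TP10",
              "P7", "P3", "Pz", "P4", "P8", "O1", "Oz", "O2")
  if (n_channels <= length(labels)) {
    labels[seq_len(n_channels)]
  } else {
    c(labels, sprintf("CH%02d", seq_len(n_channels - length(labels))))
  }
}
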