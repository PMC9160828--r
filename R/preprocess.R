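# Automated preprocessing: band-pass + notch filtering, fixed-length
# epoching, amplitude-threshold artifact rejection. This is a deterministic
# stand-in for interactive preprocessing (manual epoch review, ICA blink
# correction), which cannot be reproduced in software.

#' Band-pass and notch filter a recording
#'
#' Zero-phase (forward-backward) IIR filtering per channel: order-4
#' Butterworth high-pass at `low_hz`, order-4 Butterworth low-pass at
#' `high_hz`, and a second-order notch at `notch_hz` (Q = 30 by default).
#'
#' @param rec an [eeg_recording()]
#' @param low_hz high-pass cutoff in Hz (default 0.1)
#' @param high_hz low-pass cutoff in Hz (default 60)
#' @param notch_hz mains notch frequency in Hz (default 50); `NULL` disables
#' @param notch_q notch quality factor
#' @return filtered [eeg_recording()] of the same shape
#' @export
bandpass_notch <- function(rec, low_hz = 0.1, high_hz = 60, notch_hz = 50,
                           notch_q = 30) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < rec$fs / 2)) {
    stop("cutoffs must satisfy 0 < low_hz < high_hz < fs/2 (Nyquist = ",
         rec$fs / 2, " Hz)", call. = FALSE)
  }
  if (!is.null(notch_hz) && !(notch_hz > low_hz && notch_hz < high_hz)) {
    stop("notch_hz must lie inside (low_hz, high_hz)", call. = FALSE)
  }
  # each filter gets its own zero-phase pass, notch first: the high-pass has
  # a very slow settling mode at a 0.1 Hz cutoff, and running the notch on
  # its output would pass that edge transient straight through
  X <- t(rec$data)
  if (!is.null(notch_hz)) {
    X <- filtfilt_sos(notch_sos(notch_hz, rec$fs, notch_q), X)
  }
  X <- filtfilt_sos(butter_sos(4, low_hz, rec$fs, "high"), X)
  X <- filtfilt_sos(butter_sos(4, high_hz, rec$fs, "low"), X)
  out <- rec
  out$data <- t(X)
  dimnames(out$data) <- dimnames(rec$data)
  out
}

#' Cut a recording into fixed-length non-overlapping epochs
#'
#' @param rec an [eeg_recording()]
#' @param epoch_length_s epoch length in seconds (default 1)
#' @return an object of class `epoch_set` with fields `epochs`
#'   (n_epochs x channels x samples array), `fs`, `epoch_length_s`,
#'   `channel_labels`, `kept_mask`, `subject_id`, `condition`
#' @export
segment_epochs <- function(rec, epoch_length_s = 1) {
  stopifnot(inherits(rec, "eeg_recording"), epoch_length_s > 0)
  spe <- round(rec$fs * epoch_length_s)
  n <- ncol(rec$data)
  n_epochs <- n %/% spe
  if (n_epochs < 1) {
    stop(sprintf("recording is %.3f s long; at least %.3f s required for one epoch",
                 n / rec$fs, epoch_length_s), call. = FALSE)
  }
  x <- rec$data[, seq_len(n_epochs * spe), drop = FALSE]
  arr <- aperm(array(x, c(nrow(x), spe, n_epochs)), c(3, 1, 2))
  structure(
    list(epochs = arr, fs = rec$fs, epoch_length_s = epoch_length_s,
         channel_labels = rec$channel_labels,
         kept_mask = rep(TRUE, n_epochs),
         subject_id = rec$subject_id, condition = rec$condition),
    class = "epoch_set"
  )
}

#' Reject epochs exceeding an absolute amplitude threshold
#'
#' An epoch is removed when any sample on any channel exceeds
#' `amp_threshold_uv` in magnitude. `kept_mask` keeps track of which of the
#' originally segmented epochs survive, so repeated application is a no-op.
#'
#' @param epochs an `epoch_set`
#' @param amp_threshold_uv rejection threshold in microvolts (default 100)
#' @return an `epoch_set` containing only the surviving epochs
#' @export
reject_artifacts <- function(epochs, amp_threshold_uv = 100) {
  stopifnot(inherits(epochs, "epoch_set"), amp_threshold_uv > 0)
  ne <- dim(epochs$epochs)[1]
  m <- abs(matrix(epochs$epochs, nrow = ne))
  amax <- apply(m, 1, max)
  keep <- amax <= amp_threshold_uv
  if (!any(keep)) {
    stop("all epochs exceed the ", amp_threshold_uv,
         " uV threshold; nothing left to analyze", call. = FALSE)
  }
  out <- epochs
  out$epochs <- epochs$epochs[keep, , , drop = FALSE]
  idx <- which(out$kept_mask)
  out$kept_mask[idx[!keep]] <- FALSE
  out
}

#' Concatenate the kept epochs back into a continuous recording
#'
#' Inverse of [segment_epochs()] restricted to surviving epochs; for an
#' un-rejected epoch set of an exact-multiple-length recording this recovers
#' the original samples.
#'
#' @param epochs an `epoch_set`
#' @return an [eeg_recording()]
#' @export
concatenate_epochs <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  d <- dim(epochs$epochs)
  x <- matrix(aperm(epochs$epochs, c(2, 3, 1)), nrow = d[2])
  eeg_recording(x, epochs$fs, epochs$channel_labels,
                subject_id = epochs$subject_id, condition = epochs$condition)
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$epochs)
  cat(sprintf("<epoch_set> %s: %d epochs x %d channels x %d samples (%g s each, %d/%d kept)\n",
              x$subject_id, d[1], d[2], d[3], x$epoch_length_s,
              sum(x$kept_mask), length(x$kept_mask)))
  invisible(x)
}
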