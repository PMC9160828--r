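# Windowed band-power feature representation.
#
# For every analysis channel and frequency band, the cleaned signal is
# band-limited by zeroing FFT bins outside the band and inverse-transforming,
# then its instantaneous power (squared amplitude) is averaged in consecutive
# non-overlapping windows. The resulting per-window power series -- not the
# single scalar band power -- is the feature vector, preserving temporal
# structure and the multi-source (per-electrode) organisation of the data:
# transforms never cross channel boundaries.

#' Band-limit a single-channel signal by FFT masking
#'
#' Discrete Fourier bins with |f| outside `[f_low, f_high]` are zeroed and the
#' inverse transform returned. Output is real to within numerical roundoff.
#'
#' @param signal numeric vector of samples
#' @param fs sampling rate in Hz
#' @param band one-row band table (see [band_definition()])
#' @return band-limited signal, same length
#' @export
band_filter_fft <- function(signal, fs, band) {
  n <- length(signal)
  stopifnot(n >= 2)
  if (band$f_high >= fs / 2) {
    stop("band extends beyond the Nyquist frequency (", fs / 2, " Hz)",
         call. = FALSE)
  }
  H <- fft(signal)
  keep <- band_bin_indices(n, fs, band$f_low, band$f_high)
  mask <- rep(FALSE, n)
  mask[keep] <- TRUE
  H[!mask] <- 0
  Re(fft(H, inverse = TRUE)) / n
}

#' Average power in consecutive non-overlapping windows
#'
#' Element w of the result is the mean squared sample value over window w; a
#' trailing partial window is dropped.
#'
#' @param signal numeric vector (typically band-limited)
#' @param fs sampling rate in Hz
#' @param window_length_s window length in seconds
#' @return numeric vector of window powers (uV^2)
#' @export
windowed_power <- function(signal, fs, window_length_s) {
  L <- round(fs * window_length_s)
  nw <- length(signal) %/% L
  if (nw < 1) {
    stop(sprintf("signal (%d samples) is shorter than one %g s window (%d samples)",
                 length(signal), window_length_s, L), call. = FALSE)
  }
  colMeans(matrix(signal[seq_len(nw * L)]^2, L, nw))
}

#' Extract the windowed band-power feature vector of one subject
#'
#' The kept epochs are concatenated into one continuous signal per channel;
#' each channel is FFT-mask filtered into each requested band and the
#' windowed power series computed. Features are laid out channel-major
#' (channel, then band, then window) with a complete provenance index.
#'
#' @param epochs an `epoch_set` of cleaned epochs
#' @param bands band table, defaults to [eeg_bands()]
#' @param window_length_s feature window length in seconds (default 2)
#' @param band_subset optional character vector restricting to named bands
#' @return object of class `band_power_series` with fields `features`
#'   (numeric vector), `provenance` (data.frame channel/band/window),
#'   `window_length_s`, `n_windows`, `fs`, `subject_id`
#' @export
extract_features <- function(epochs, bands = eeg_bands(), window_length_s = 2,
                             band_subset = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  bands <- match_bands(bands, band_subset)
  rec <- concatenate_epochs(epochs)
  X <- t(rec$data)                       # samples x channels
  L <- round(epochs$fs * window_length_s)
  nw <- nrow(X) %/% L
  if (nw < 1) {
    stop("cleaned signal is shorter than one feature window", call. = FALSE)
  }
  # the trailing partial window never contributes features; restricting the
  # band-limiting transform to the whole-window prefix keeps the FFT length
  # a multiple of the window length (fast mixed-radix factorizations)
  X <- X[seq_len(nw * L), , drop = FALSE]
  n <- nrow(X); nch <- ncol(X)
  # channels are packed in pairs (x1 + i*x2) and kept packed throughout:
  # the band mask is symmetric in +/- frequency, so masking the packed
  # spectrum masks both Hermitian components exactly
  npair <- nch %/% 2L
  P <- if (npair > 0) {
    mvfft(matrix(complex(real = X[, seq(1, 2 * npair, by = 2)],
                         imaginary = X[, seq(2, 2 * npair, by = 2)]),
                 n, npair))
  } else matrix(complex(real = 0), n, 0)
  podd <- if (nch %% 2L == 1L) fft(X[, nch]) else NULL
  powers <- vector("list", nrow(bands))
  for (b in seq_len(nrow(bands))) {
    keep <- band_bin_indices(n, epochs$fs, bands$f_low[b], bands$f_high[b])
    Pw <- matrix(0, nw, nch)
    if (npair > 0) {
      Pb <- matrix(complex(real = 0), n, npair)
      Pb[keep, ] <- P[keep, ]
      W <- mvfft(Pb, inverse = TRUE) / n
      Pw[, seq(1, 2 * npair, by = 2)] <- colMeans(array(Re(W)^2, c(L, nw, npair)))
      Pw[, seq(2, 2 * npair, by = 2)] <- colMeans(array(Im(W)^2, c(L, nw, npair)))
    }
    if (!is.null(podd)) {
      hb <- complex(real = numeric(n)); hb[keep] <- podd[keep]
      xb <- Re(fft(hb, inverse = TRUE)) / n
      Pw[, nch] <- colMeans(matrix(xb^2, L, nw))
    }
    powers[[b]] <- Pw                                     # nw x nch
  }
  # channel-major layout: for each channel, for each band, windows 1..nw
  features <- numeric(nch * nrow(bands) * nw)
  prov <- data.frame(
    channel = rep(epochs$channel_labels, each = nrow(bands) * nw),
    band = rep(rep(bands$name, each = nw), times = nch),
    window = rep(seq_len(nw), times = nch * nrow(bands)),
    stringsAsFactors = FALSE
  )
  pos <- 1L
  for (ch in seq_len(nch)) {
    for (b in seq_len(nrow(bands))) {
      features[pos:(pos + nw - 1L)] <- powers[[b]][, ch]
      pos <- pos + nw
    }
  }
  structure(
    list(features = features, provenance = prov,
         window_length_s = window_length_s, n_windows = nw, fs = epochs$fs,
         subject_id = epochs$subject_id),
    class = "band_power_series"
  )
}

#' Collapse a windowed band-power series to scalar band powers
#'
#' The scalar baseline representation: one mean power per (channel, band),
#' i.e. the average of the window series.
#'
#' @param series a `band_power_series` or a `feature_set`
#' @return for a series, a data.frame (channel, band, power); for a feature
#'   set, a new `feature_set` with one feature per (channel, band)
#' @export
scalar_band_power <- function(series) {
  UseMethod("scalar_band_power")
}

#' @export
scalar_band_power.band_power_series <- function(series) {
  stopifnot(length(series$features) > 0)
  key <- paste(series$provenance$channel, series$provenance$band, sep = ".")
  agg <- tapply(series$features, factor(key, levels = unique(key)), mean)
  first <- !duplicated(key)
  data.frame(channel = series$provenance$channel[first],
             band = series$provenance$band[first],
             power = as.numeric(agg), stringsAsFactors = FALSE)
}

#' @export
scalar_band_power.feature_set <- function(series) {
  prov <- series$provenance
  key <- paste(prov$channel, prov$band, sep = ".")
  ukey <- unique(key)
  grp <- factor(key, levels = ukey)
  Xs <- t(apply(series$X, 1, function(r) tapply(r, grp, mean)))
  first <- !duplicated(key)
  out <- series
  out$X <- unname(Xs)
  out$provenance <- data.frame(channel = prov$channel[first],
                               band = prov$band[first],
                               window = 1L, stringsAsFactors = FALSE)
  out$window_length_s <- NA_real_
  out
}
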