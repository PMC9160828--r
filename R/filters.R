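# IIR filter design and zero-phase application.
#
# Filters are designed and applied as cascades of second-order sections
# (biquads): an order-4 Butterworth band-pass in transfer-function form is
# numerically unusable at a 0.1 Hz cutoff and 500 Hz sampling (poles crowd
# z = 1), while the biquad cascade is stable.

#' Design a digital Butterworth filter as second-order sections
#'
#' Bilinear-transform design with frequency prewarping. Only even orders are
#' supported (poles come in conjugate pairs, one biquad each).
#'
#' @param order filter order (even)
#' @param f cutoff frequency in Hz
#' @param fs sampling rate in Hz
#' @param type `"low"` or `"high"`
#' @return numeric matrix with one row per biquad, columns b0 b1 b2 1 a1 a2
#' @export
butter_sos <- function(order, f, fs, type = c("low", "high")) {
  type <- match.arg(type)
  stopifnot(order >= 2, order %% 2 == 0, f > 0, f < fs / 2)
  n <- as.integer(order)
  w0 <- tan(pi * f / fs)                       # prewarped analog cutoff
  k <- seq_len(n)
  proto <- exp(1i * pi * (2 * k + n - 1) / (2 * n))  # unit-cutoff LP poles
  if (type == "low") {
    poles <- w0 * proto
    gain <- w0^n
    zero_z <- -1                               # zeros at infinity -> z = -1
  } else {
    poles <- w0 / proto
    gain <- 1
    zero_z <- 1                                # zeros at s = 0 -> z = 1
  }
  zpoles <- (1 + poles) / (1 - poles)          # bilinear transform
  gain <- gain * Re(1 / prod(1 - poles))       # conjugate pairs: product is real > 0
  # pair conjugate poles: take those with positive imaginary part
  upper <- zpoles[Im(zpoles) > 0]
  if (length(upper) != n / 2) {                # fully real poles edge case
    upper <- zpoles[seq(1, n, by = 2)]
  }
  sos <- t(vapply(upper, function(p) {
    a1 <- -2 * Re(p); a2 <- Mod(p)^2
    b <- c(1, -2 * zero_z, zero_z^2)
    c(b, 1, a1, a2)
  }, numeric(6)))
  # split the overall gain evenly across sections for dynamic range
  sos[, 1:3] <- sos[, 1:3] * gain^(1 / (n / 2))
  sos
}

#' Design a second-order IIR notch filter
#'
#' Constrained biquad notch with unity gain away from the notch frequency.
#'
#' @param f0 notch frequency in Hz
#' @param fs sampling rate in Hz
#' @param Q quality factor (notch width = f0 / Q)
#' @return one-row SOS matrix
#' @export
notch_sos <- function(f0, fs, Q = 30) {
  stopifnot(f0 > 0, f0 < fs / 2, Q > 0)
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  matrix(c(b / a[1], 1, a[2] / a[1], a[3] / a[1]), nrow = 1)
}

#' Frequency response of an SOS cascade
#'
#' @param sos SOS matrix as returned by [butter_sos()]
#' @param f frequencies in Hz at which to evaluate
#' @param fs sampling rate in Hz
#' @return complex response at each frequency
#' @export
sos_freq_response <- function(sos, f, fs) {
  z <- exp(-1i * 2 * pi * f / fs)
  h <- rep(complex(real = 1), length(f))
  for (s in seq_len(nrow(sos))) {
    num <- sos[s, 1] + sos[s, 2] * z + sos[s, 3] * z^2
    den <- 1 + sos[s, 5] * z + sos[s, 6] * z^2
    h <- h * num / den
  }
  h
}

#' Zero-phase filtering with an SOS cascade
#'
#' Forward-backward application (squared magnitude response, zero phase).
#' The line through each channel's endpoints is subtracted first so the
#' odd-reflection padding carries no DC block into low-cutoff high-pass
#' sections, and is restored scaled by the cascade's squared DC gain; the
#' padded extensions let start-up transients decay outside the data.
#'
#' @param sos SOS matrix
#' @param x numeric vector or samples x channels matrix
#' @param pad reflection padding length in samples; capped at `n - 1`
#' @return filtered data, same shape as `x`
#' @export
filtfilt_sos <- function(sos, x, pad = 10000L) {
  vec <- is.null(dim(x))
  X <- if (vec) matrix(x, ncol = 1) else x
  n <- nrow(X)
  ramp <- if (n > 1) (seq_len(n) - 1) / (n - 1) else rep(0, n)
  base <- outer(1 - ramp, X[1, ]) + outer(ramp, X[n, ])
  Y <- sosfiltfilt_cpp(sos, X - base, as.integer(pad))
  g0 <- prod(rowSums(sos[, 1:3, drop = FALSE]) /
               (1 + rowSums(sos[, 5:6, drop = FALSE])))
  Y <- Y + g0^2 * base
  if (vec) drop(Y) else Y
}
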