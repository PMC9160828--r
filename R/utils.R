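#' @useDynLib rtmseeg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats fft mvfft rnorm runif sd var qbinom pt
#' @importFrom utils head read.csv write.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child RNG seed from a master seed
#'
#' Deterministic counter-offset derivation so that cohorts are reproducible
#' subject-by-subject and independent experiments can share one master seed.
#' Result is always a valid positive 32-bit integer seed.
#'
#' @param seed master integer seed
#' @param index non-negative counter offset
#' @return an integer seed
#' @export
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(index)) %% 2147483646L + 1)
}

# Evaluate expr with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# --- feature standardization ------------------------------------------------

#' Fit a z-score standardizer on training rows
#'
#' Column means and standard deviations are computed on the training rows only;
#' zero-variance columns get unit scale so they map to constant zero rather
#' than NaN.
#'
#' @param X numeric matrix (rows = samples)
#' @return an object of class `standardizer`
#' @export
fit_standardizer <- function(X) {
  center <- colMeans(X)
  scale <- sqrt(colMeans(X^2) - center^2) * sqrt(nrow(X) / max(1, nrow(X) - 1))
  scale[scale < .Machine$double.eps] <- 1
  structure(list(center = center, scale = scale), class = "standardizer")
}

#' Apply a fitted standardizer to rows
#' @param obj a `standardizer`
#' @param X numeric matrix with the same columns as the training matrix
#' @return standardized matrix
#' @export
apply_standardizer <- function(obj, X) {
  stopifnot(inherits(obj, "standardizer"), ncol(X) == length(obj$center))
  sweep(sweep(X, 2, obj$center), 2, obj$scale, "/")
}

# --- FFT helpers ------------------------------------------------------------

# Forward FFTs of the columns of a real matrix. Columns are packed in pairs
# into complex signals (x1 + i*x2) so that half the transforms suffice; the
# two Hermitian spectra are unpacked exactly afterwards.
fft_real_cols <- function(X) {
  n <- nrow(X); q <- ncol(X)
  out <- matrix(complex(real = 0), n, q)
  rev_idx <- c(1L, n:2L)
  npair <- q %/% 2L
  if (npair > 0) {
    Z <- mvfft(matrix(complex(real = X[, seq(1, 2 * npair, by = 2)],
                              imaginary = X[, seq(2, 2 * npair, by = 2)]),
                      n, npair))
    for (j in seq_len(npair)) {
      zj <- Z[, j]; zc <- Conj(zj[rev_idx])
      out[, 2 * j - 1] <- (zj + zc) / 2
      out[, 2 * j] <- (zj - zc) / (2i)
    }
  }
  if (q %% 2L == 1L) out[, q] <- fft(X[, q])
  out
}

# Inverse FFTs of Hermitian spectra columns, returning real signals. Pairs of
# Hermitian columns are combined as H1 + i*H2 whose inverse transform is
# exactly x1 + i*x2.
ifft_hermitian_cols <- function(Z) {
  n <- nrow(Z); q <- ncol(Z)
  out <- matrix(0, n, q)
  npair <- q %/% 2L
  if (npair > 0) {
    W <- mvfft(Z[, seq(1, 2 * npair, by = 2), drop = FALSE] +
                 1i * Z[, seq(2, 2 * npair, by = 2), drop = FALSE],
               inverse = TRUE) / n
    out[, seq(1, 2 * npair, by = 2)] <- Re(W)
    out[, seq(2, 2 * npair, by = 2)] <- Im(W)
  }
  if (q %% 2L == 1L) out[, q] <- Re(fft(Z[, q], inverse = TRUE)) / n
  out
}

# Indices (1-based) of FFT bins whose frequency lies in [f_low, f_high],
# including the negative-frequency mirror, for a length-n transform at fs.
band_bin_indices <- function(n, fs, f_low, f_high) {
  k <- 0:(n %/% 2)                     # non-negative frequencies
  f <- k * fs / n
  pos <- k[f >= f_low & f <= f_high]
  mirror <- (n - pos)[pos > 0 & pos < n / 2]
  sort(unique(c(pos, mirror))) + 1L
}
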