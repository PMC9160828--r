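# Orthonormal Daubechies-4 discrete wavelet transform with periodized
# boundary handling. Periodization keeps the transform exactly orthonormal
# (perfect reconstruction, exact energy bookkeeping), which the
# coefficient-selection route relies on. Filter taps follow the standard
# Daubechies construction (8-tap db4).

db4_dec_lo <- c(-0.010597401785069032, 0.0328830116668852,
                0.030841381835560764, -0.18703481171909309,
                -0.027983769416859854, 0.6308807679298589,
                0.7148465705529157, 0.2303778133088965)
db4_dec_hi <- c(-0.2303778133088965, 0.7148465705529157,
                -0.6308807679298589, -0.027983769416859854,
                0.18703481171909309, 0.030841381835560764,
                -0.0328830116668852, -0.010597401785069032)

# one analysis step: x (even length) -> list(a, d), periodized convolution
dwt_step <- function(x) {
  n <- length(x)
  stopifnot(n %% 2 == 0)
  h <- n %/% 2L
  a <- numeric(h); d <- numeric(h)
  j2 <- 2 * (0:(h - 1L))
  for (m in 0:7) {
    idx <- ((j2 - m + 4L) %% n) + 1L
    a <- a + db4_dec_lo[m + 1L] * x[idx]
    d <- d + db4_dec_hi[m + 1L] * x[idx]
  }
  list(a = a, d = d)
}

# one synthesis step (adjoint of dwt_step; exact inverse by orthonormality)
idwt_step <- function(a, d) {
  h <- length(a)
  n <- 2L * h
  x <- numeric(n)
  j2 <- 2 * (0:(h - 1L))
  for (m in 0:7) {
    idx <- ((j2 - m + 4L) %% n) + 1L
    contrib <- db4_dec_lo[m + 1L] * a + db4_dec_hi[m + 1L] * d
    x[idx] <- x[idx] + contrib
  }
  x
}

# decomposition depth: limited by the number of factors of 2 in n and by the
# filter support (no level with fewer samples than taps)
dwt_max_level <- function(n) {
  lev <- 0L
  while (n %% 2 == 0 && n >= length(db4_dec_lo)) {
    lev <- lev + 1L
    n <- n %/% 2L
  }
  lev
}

#' Full periodized db4 wavelet decomposition
#'
#' @param x numeric vector whose length supports at least one level
#' @param level decomposition depth; default is the maximum supported
#' @return list with `coeffs` (single vector, ordered `a_L, d_L, ..., d_1`),
#'   `lengths` (per-piece lengths), `level`, `n`
#' @export
dwt_db4 <- function(x, level = NULL) {
  n <- length(x)
  maxlev <- dwt_max_level(n)
  level <- level %||% maxlev
  if (level < 1 || level > maxlev) {
    stop("level must be between 1 and ", maxlev, " for length ", n, call. = FALSE)
  }
  details <- vector("list", level)
  a <- x
  for (l in seq_len(level)) {
    st <- dwt_step(a)
    a <- st$a
    details[[l]] <- st$d
  }
  pieces <- c(list(a), rev(details))
  list(coeffs = unlist(pieces), lengths = lengths(pieces),
       level = level, n = n)
}

#' Inverse of [dwt_db4()]
#'
#' @param dec decomposition as returned by [dwt_db4()] (the `coeffs` vector
#'   may have been modified, e.g. thresholded)
#' @return reconstructed signal of the original length
#' @export
idwt_db4 <- function(dec) {
  splits <- split(dec$coeffs, rep(seq_along(dec$lengths), dec$lengths))
  a <- splits[[1]]
  for (l in 2:length(splits)) {
    a <- idwt_step(a, splits[[l]])
  }
  a
}

# cached orthonormal transform matrices W (coeffs = W %*% x) per length, so
# that many rows / many blocks can be transformed by matrix products
wavelet_matrix_cache <- new.env(parent = emptyenv())

wavelet_matrix <- function(n) {
  key <- as.character(n)
  if (!is.null(wavelet_matrix_cache[[key]])) return(wavelet_matrix_cache[[key]])
  if (dwt_max_level(n) < 1) {
    W <- diag(n)                        # block too short: identity transform
  } else {
    W <- vapply(seq_len(n), function(i) {
      e <- numeric(n); e[i] <- 1
      dwt_db4(e)$coeffs
    }, numeric(n))
  }
  wavelet_matrix_cache[[key]] <- W
  W
}
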