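# Independent oracles used across the suite. These deliberately use
# different algorithms / code paths than the implementation they check.

# Mean power (uV^2 per sample) of the [f_low, f_high] band of a signal,
# summed directly over discrete-Fourier bins (Parseval route).
fft_band_power_oracle <- function(x, fs, f_low, f_high) {
  n <- length(x)
  X <- fft(x)
  f <- (seq_len(n) - 1) * fs / n
  f_sym <- pmin(f, fs - f)               # |frequency| of each bin
  keep <- f_sym >= f_low & f_sym <= f_high
  sum(Mod(X[keep])^2) / n^2
}

# Exact soft-margin SVM dual solution by exhaustive active-set enumeration:
# every variable is free, at 0, or at C; each consistent KKT system is a
# small linear solve. Intended for n <= 8.
brute_force_svm_qp <- function(K, y, C, tol = 1e-8) {
  n <- length(y)
  Q <- K * outer(y, y)
  best <- NULL; best_obj <- -Inf
  states <- expand.grid(rep(list(0:2), n))  # 0: at 0, 1: free, 2: at C
  for (r in seq_len(nrow(states))) {
    st <- as.integer(states[r, ])
    alpha <- ifelse(st == 2, C, 0)
    free <- which(st == 1)
    fixed_contrib <- if (any(st == 2)) rowSums(Q[, st == 2, drop = FALSE]) * C else numeric(n)
    if (length(free) > 0) {
      A <- rbind(cbind(Q[free, free, drop = FALSE], y[free]),
                 c(y[free], 0))
      rhs <- c(1 - fixed_contrib[free], -sum(alpha[st == 2] * y[st == 2]))
      sol <- tryCatch(solve(A, rhs), error = function(e) NULL)
      if (is.null(sol)) next
      af <- sol[seq_along(free)]; b <- sol[length(sol)]
      if (any(af < -tol) || any(af > C + tol)) next
      alpha[free] <- pmin(pmax(af, 0), C)
    } else {
      if (abs(sum(alpha * y)) > tol) next
      # b from any margin condition is unconstrained; pick the feasible range
      g <- as.numeric(Q %*% alpha)
      lo <- -Inf; hi <- Inf
      for (i in seq_len(n)) {
        # y_i (sum_j alpha_j y_j K_ij + b) >= 1 (at 0) or <= 1 (at C)
        bound <- (1 - g[i]) * y[i]     # y_i*b compared to (1 - g_i)
        if (st[i] == 0) { if (y[i] > 0) lo <- max(lo, bound) else hi <- min(hi, bound) }
        else { if (y[i] > 0) hi <- min(hi, bound) else lo <- max(lo, bound) }
      }
      if (lo > hi + tol) next
      b <- if (is.finite(lo)) lo else if (is.finite(hi)) hi else 0
    }
    # verify full KKT
    fx <- as.numeric(Q %*% alpha) + y * b
    ok <- TRUE
    for (i in seq_len(n)) {
      yf <- fx[i]                      # y_i f(x_i) in margin units
      if (alpha[i] < tol) { if (yf < 1 - 1e-6) { ok <- FALSE; break } }
      else if (alpha[i] > C - tol) { if (yf > 1 + 1e-6) { ok <- FALSE; break } }
      else if (abs(yf - 1) > 1e-6) { ok <- FALSE; break }
    }
    if (!ok || abs(sum(alpha * y)) > 1e-6) next
    obj <- sum(alpha) - 0.5 * as.numeric(t(alpha) %*% Q %*% alpha)
    if (obj > best_obj + 1e-12) {
      best_obj <- obj
      best <- list(alpha = alpha, b = b, objective = obj)
    }
  }
  best
}

# Naive stepwise selection implemented directly with lm()/summary():
# the slow reference for swlda_select.
naive_stepwise <- function(X, y, alpha_in = 0.10, alpha_out = 0.15,
                           max_features = nrow(X)) {
  selected <- integer(0)
  n <- nrow(X)
  repeat {
    changed <- FALSE
    if (length(selected) < max_features && n - length(selected) - 2 >= 1) {
      cand <- setdiff(seq_len(ncol(X)), selected)
      ps <- vapply(cand, function(j) {
        dat <- data.frame(y = y, X[, c(selected, j), drop = FALSE])
        fit <- lm(y ~ ., data = dat)
        cf <- summary(fit)$coefficients
        if (nrow(cf) < length(selected) + 2) return(1)
        cf[nrow(cf), 4]
      }, numeric(1))
      if (min(ps) < alpha_in) {
        selected <- c(selected, cand[which.min(ps)])
        changed <- TRUE
      }
    }
    while (length(selected) > 1) {
      dat <- data.frame(y = y, X[, selected, drop = FALSE])
      cf <- summary(lm(y ~ ., data = dat))$coefficients
      if (nrow(cf) < length(selected) + 1) break
      ps <- cf[-1, 4]
      if (max(ps) > alpha_out) {
        selected <- selected[-which.max(ps)]
        changed <- TRUE
      } else break
    }
    if (!changed || length(selected) >= max_features) break
  }
  selected
}

# small standard fixtures ----------------------------------------------------

two_blobs <- function(n_per = 10, sep = 4, d = 2, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per * d, -sep / 2), n_per, d),
             matrix(rnorm(n_per * d, sep / 2), n_per, d))
  list(X = X, y = rep(c(-1, 1), each = n_per))
}

# a tiny feature set with labels and optional class signal in "theta" columns
toy_feature_set <- function(n_pos = 8, n_neg = 6, n_windows = 4,
                            channels = c("C3", "C4"), effect = 0, seed = 1) {
  set.seed(seed)
  bands <- eeg_bands()$name
  prov <- data.frame(
    channel = rep(channels, each = length(bands) * n_windows),
    band = rep(rep(bands, each = n_windows), times = length(channels)),
    window = rep(seq_len(n_windows), times = length(channels) * length(bands)),
    stringsAsFactors = FALSE
  )
  n <- n_pos + n_neg
  X <- matrix(rnorm(n * nrow(prov)), n)
  lab <- c(rep("TMS+", n_pos), rep("TMS-", n_neg))
  X[lab == "TMS+", prov$band == "theta"] <-
    X[lab == "TMS+", prov$band == "theta"] + effect
  subjects <- data.frame(subject_id = sprintf("S%02d", 1:n), label = lab,
                         stringsAsFactors = FALSE)
  feature_set(X, prov, subjects, window_length_s = 2)
}
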