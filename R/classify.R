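# Soft-margin SVM behind the pipeline's classifier interface. The dual
# problem
#   max  sum(alpha) - 1/2 alpha' (yy' * K) alpha,  0 <= alpha <= C,
#        sum(alpha * y) = 0
# is solved by a compact SMO (sequential minimal optimization) with
# maximal-violating-pair working-set selection, operating on a precomputed
# kernel matrix. On the cohort sizes this pipeline sees (n <= 14) a fit is
# well under a millisecond, which the Monte-Carlo engine's tens of
# thousands of fits require; the solver is checked in the test suite
# against an independent libsvm implementation and against an exhaustive
# active-set QP enumeration. The trained model stores support vectors,
# dual coefficients and bias so the decision function
#   f(x) = sum_m alpha_m y_m K(x, x_m) + b
# is evaluated explicitly by this package's own predict method.

#' SVM hyperparameters
#'
#' The RBF kernel uses the Gaussian-width convention
#' `K(x, x') = exp(-||x - x'||^2 / (2 sigma^2))`.
#'
#' @param C soft-margin cost, > 0 (default 1)
#' @param sigma RBF width, > 0; `NULL` (default) resolves to `sqrt(d / 2)`
#'   for d standardized features (the 1/d inverse-scale convention)
#' @param kernel `"rbf"` or `"linear"`
#' @return object of class `svm_params`
#' @export
svm_params <- function(C = 1, sigma = NULL, kernel = c("rbf", "linear")) {
  kernel <- match.arg(kernel)
  stopifnot(C > 0, is.null(sigma) || sigma > 0)
  structure(list(C = C, sigma = sigma, kernel = kernel), class = "svm_params")
}

svm_kernel_matrix <- function(X, Y, params) {
  if (params$kernel == "linear") return(tcrossprod(X, Y))
  sx <- rowSums(X^2); sy <- rowSums(Y^2)
  d2 <- outer(sx, sy, "+") - 2 * tcrossprod(X, Y)
  d2[d2 < 0] <- 0
  exp(-d2 / (2 * params$sigma^2))
}

# SMO solver for the C-SVC dual on a precomputed kernel. Keerthi-style
# maximal-violating-pair selection; stops when the duality gap measure
# m - M drops below tol. Returns alpha (unsigned) and the bias b of
# f(x) = sum alpha_i y_i K(x, x_i) + b.
svm_dual_solve <- function(K, y, C, tol = 1e-6, max_iter = 100000L) {
  n <- length(y)
  alpha <- numeric(n)
  Fv <- numeric(n)                       # F_i = sum_j alpha_j y_j K_ij
  for (iter in seq_len(max_iter)) {
    crit <- y - Fv                       # -y_i * gradient_i
    up <- (y > 0 & alpha < C - 1e-12) | (y < 0 & alpha > 1e-12)
    lo <- (y < 0 & alpha < C - 1e-12) | (y > 0 & alpha > 1e-12)
    if (!any(up) || !any(lo)) break
    i <- which(up)[which.max(crit[up])]
    j <- which(lo)[which.min(crit[lo])]
    m <- crit[i]; M <- crit[j]
    if (m - M < tol) break
    a2 <- K[i, i] + K[j, j] - 2 * K[i, j]
    if (a2 <= 1e-12) a2 <- 1e-12
    lam <- (m - M) / a2
    # step direction: alpha_i += y_i*lam, alpha_j -= y_j*lam (keeps the
    # equality constraint); clip to the box
    lim_i <- if (y[i] > 0) C - alpha[i] else alpha[i]
    lim_j <- if (y[j] > 0) alpha[j] else C - alpha[j]
    lam <- min(lam, lim_i, lim_j)
    if (lam <= 0) break
    alpha[i] <- alpha[i] + y[i] * lam
    alpha[j] <- alpha[j] - y[j] * lam
    Fv <- Fv + lam * (K[, i] - K[, j])
  }
  crit <- y - Fv
  up <- (y > 0 & alpha < C - 1e-12) | (y < 0 & alpha > 1e-12)
  lo <- (y < 0 & alpha < C - 1e-12) | (y > 0 & alpha > 1e-12)
  m <- if (any(up)) max(crit[up]) else max(crit)
  M <- if (any(lo)) min(crit[lo]) else min(crit)
  list(alpha = alpha, b = (m + M) / 2)
}

#' Train a soft-margin SVM
#'
#' Features are expected to be standardized with training statistics before
#' the call (the validation engine does this); pass the fitted standardizer
#' in `scaling` to have [predict.svm_model()] apply it to new raw rows.
#'
#' @param X numeric training matrix (rows = samples)
#' @param y labels: +/-1 or a two-class factor/character vector; `"TMS+"`
#'   maps to +1
#' @param params an [svm_params()]
#' @param scaling optional `standardizer` stored for prediction
#' @return object of class `svm_model` with fields `sv` (support vectors),
#'   `coef` (alpha_m y_m), `alpha`, `b`, `params`, `n_sv`, `levels`,
#'   `train_majority`, `scaling`
#' @export
train_svm <- function(X, y, params = svm_params(), scaling = NULL) {
  X <- as.matrix(X)
  yy <- encode_pm1(y)
  yv <- yy$y
  if (length(unique(yv)) < 2) {
    stop("training data contains a single class", call. = FALSE)
  }
  params$sigma <- params$sigma %||% sqrt(ncol(X) / 2)
  K <- svm_kernel_matrix(X, X, params)
  sol <- svm_dual_solve(K, yv, params$C)
  ai <- which(sol$alpha > 1e-8)
  co <- sol$alpha[ai] * yv[ai]
  b <- sol$b
  maj <- if (sum(yv > 0) >= sum(yv < 0)) 1 else -1
  structure(
    list(sv = X[ai, , drop = FALSE], sv_index = ai, coef = co,
         alpha = abs(co), sv_labels = sign(co), b = b, params = params,
         n_sv = length(ai), n_features = ncol(X), levels = yy$levels,
         train_majority = maj, scaling = scaling),
    class = "svm_model"
  )
}

#' Evaluate the SVM decision function
#'
#' Computes `f(x) = sum_m alpha_m y_m K(x, x_m) + b` over the stored support
#' vectors. Labels are `sign(f)`; exact ties (`f == 0`) go to the majority
#' training class.
#'
#' @param object an `svm_model`
#' @param newdata feature matrix with the training column count
#' @param type `"class"` for labels, `"decision"` for f(x)
#' @param ... unused
#' @export
predict.svm_model <- function(object, newdata, type = c("class", "decision"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_features) {
    stop(sprintf("newdata has %d columns; model was trained on %d",
                 ncol(newdata), object$n_features), call. = FALSE)
  }
  if (!is.null(object$scaling)) newdata <- apply_standardizer(object$scaling, newdata)
  K <- svm_kernel_matrix(newdata, object$sv, object$params)
  f <- as.numeric(K %*% object$coef + object$b)
  if (type == "decision") return(f)
  lab <- ifelse(f > 0, 1, ifelse(f < 0, -1, object$train_majority))
  decode_pm1(lab, object$levels)
}

#' Train the SWLDA linear classifier
#'
#' The stepwise selection's fitted least-squares discriminant used directly
#' as a classifier; see [swlda_select()].
#'
#' @inheritParams swlda_select
#' @return an `swlda_model`
#' @export
train_swlda_classifier <- function(X, y, alpha_in = 0.10, alpha_out = 0.15,
                                   max_features = NULL) {
  swlda_select(X, y, alpha_in = alpha_in, alpha_out = alpha_out,
               max_features = max_features)
}

#' Classification accuracy in percent
#'
#' @param y_true,y_pred equal-length label vectors
#' @return `100 * matches / total`
#' @export
accuracy <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 1)
  100 * mean(as.character(y_true) == as.character(y_pred))
}
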