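# Feature-selection / dimension-reduction routes compared by the pipeline:
# none, PCA, wavelet-coefficient selection, SWLDA, linear-SVM weight
# ranking, and restriction to a single frequency band. Every route is fit
# on training rows only and applied unchanged to validation/test rows.

#' Principal-component reduction fitted on training rows
#'
#' Components are the eigenvectors of the training covariance, ordered by
#' decreasing eigenvalue; the same centering and projection are applied to
#' any rows passed to [pca_transform()].
#'
#' @param X training feature matrix
#' @param k number of components, `k <= min(n_samples - 1, n_features)`
#' @return object of class `pca_reduction`: `projection` (d x k), `center`,
#'   `eigenvalues` (all), `transformed` (training scores, n x k)
#' @export
pca_reduce <- function(X, k = 20) {
  X <- as.matrix(X)
  kmax <- min(nrow(X) - 1L, ncol(X))
  if (k > kmax) {
    stop("k = ", k, " exceeds min(n_samples - 1, n_features) = ", kmax,
         call. = FALSE)
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  structure(
    list(projection = pc$rotation[, seq_len(k), drop = FALSE],
         center = pc$center,
         eigenvalues = pc$sdev^2,
         k = k,
         transformed = pc$x[, seq_len(k), drop = FALSE]),
    class = "pca_reduction"
  )
}

#' Apply a fitted PCA reduction to rows
#' @param obj a `pca_reduction`
#' @param X matrix with the training column count
#' @return n x k score matrix
#' @export
pca_transform <- function(obj, X) {
  stopifnot(inherits(obj, "pca_reduction"))
  sweep(as.matrix(X), 2, obj$center) %*% obj$projection
}

#' Wavelet-coefficient feature selection
#'
#' Each (channel, band) window series is transformed independently by the
#' periodized db4 wavelet decomposition (transforms never cross channel
#' boundaries). Coefficient positions are ranked by their mean absolute
#' value over the training rows and the global top `keep_fraction` retained;
#' the identical positions are extracted from any rows transformed later.
#'
#' @param X training feature matrix
#' @param provenance provenance data.frame aligned with the columns of `X`
#' @param keep_fraction fraction of coefficients kept, in (0, 1]
#' @return object of class `wavelet_selection`
#' @export
wavelet_select <- function(X, provenance, keep_fraction = 0.1) {
  stopifnot(keep_fraction > 0, keep_fraction <= 1)
  X <- as.matrix(X)
  blocks <- wavelet_blocks(provenance)
  C <- wavelet_transform_rows(X, blocks)
  importance <- colMeans(abs(C))
  n_keep <- max(1L, ceiling(keep_fraction * ncol(C)))
  positions <- sort(order(importance, decreasing = TRUE)[seq_len(n_keep)])
  structure(
    list(blocks = blocks, positions = positions,
         keep_fraction = keep_fraction,
         fit_stats = list(
           retained_energy_fraction = sum(C[, positions]^2) / max(sum(C^2), .Machine$double.eps),
           n_coefficients = ncol(C), n_kept = n_keep)),
    class = "wavelet_selection"
  )
}

#' Apply a fitted wavelet selection to rows
#' @param obj a `wavelet_selection`
#' @param X matrix with the training column count
#' @return matrix of the retained wavelet coefficients
#' @export
wavelet_transform <- function(obj, X) {
  stopifnot(inherits(obj, "wavelet_selection"))
  wavelet_transform_rows(as.matrix(X), obj$blocks)[, obj$positions, drop = FALSE]
}

# contiguous column runs sharing (channel, band)
wavelet_blocks <- function(provenance) {
  key <- paste(provenance$channel, provenance$band, sep = "\r")
  runs <- rle(key)$lengths
  ends <- cumsum(runs)
  starts <- ends - runs + 1L
  Map(function(s, e) s:e, starts, ends)
}

# transform every block of every row: coefficient matrix, same dim as X
wavelet_transform_rows <- function(X, blocks) {
  out <- matrix(0, nrow(X), ncol(X))
  for (blk in blocks) {
    W <- wavelet_matrix(length(blk))
    out[, blk] <- X[, blk, drop = FALSE] %*% t(W)
  }
  out
}

#' Rank features by linear-SVM weight magnitude
#'
#' For a linear-kernel model the primal weight vector is
#' `w = sum_m alpha_m y_m x_m`; `|w_j|` measures the importance of feature j
#' and band importances are the sums over member features.
#'
#' @param model an `svm_model` trained with the linear kernel on
#'   standardized features
#' @param provenance provenance data.frame aligned with the model's features
#' @return object of class `feature_weight_report`: `weights` data.frame
#'   (provenance + weight), `band_weights` (named, descending), `ranking`
#'   (permutation of feature indices by decreasing weight)
#' @export
svm_weight_ranking <- function(model, provenance) {
  stopifnot(inherits(model, "svm_model"))
  if (model$params$kernel != "linear") {
    stop("feature weights are defined for the linear kernel only; ",
         "refit with kernel = \"linear\" for ranking", call. = FALSE)
  }
  w <- abs(as.numeric(crossprod(model$sv, model$coef)))
  bw <- tapply(w, provenance$band, sum)
  bw <- sort(unlist(as.list(bw)), decreasing = TRUE)
  structure(
    list(weights = cbind(provenance, weight = w),
         band_weights = bw,
         ranking = order(w, decreasing = TRUE)),
    class = "feature_weight_report"
  )
}

#' Restrict a feature matrix to one frequency band
#'
#' @param X feature matrix
#' @param provenance provenance data.frame aligned with the columns of `X`
#' @param band band name present in the provenance
#' @return list with `X` (columns in original order) and `provenance`
#' @export
band_restrict <- function(X, provenance, band) {
  if (!band %in% provenance$band) {
    stop("unknown band: ", band, call. = FALSE)
  }
  idx <- which(provenance$band == band)
  list(X = as.matrix(X)[, idx, drop = FALSE],
       provenance = provenance[idx, , drop = FALSE],
       index = idx)
}

# ---- unified selector interface for the validation engine -----------------

#' Fit a feature selector on training rows
#'
#' @param method one of `"none"`, `"pca"`, `"wavelet"`, `"swlda"`,
#'   `"svm_weights"`, `"band_restrict"`
#' @param X standardized training matrix
#' @param y training labels
#' @param provenance provenance data.frame for the columns of `X`
#' @param params method parameters: `k` (pca: components, default 20;
#'   svm_weights: features kept, default `nrow(X)`), `keep_fraction`
#'   (wavelet, default 0.1), `band` (band_restrict), `alpha_in`/`alpha_out`
#'   (swlda), `C` (svm_weights companion fit, default 1)
#' @return object of class `selector`
#' @export
fit_selector <- function(method, X, y, provenance, params = list()) {
  method <- match.arg(method, c("none", "pca", "wavelet", "swlda",
                                "svm_weights", "band_restrict"))
  core <- switch(
    method,
    none = list(),
    # default 20 components, capped by what the training rows support
    pca = pca_reduce(X, k = min(params$k %||% 20, nrow(X) - 1L, ncol(X))),
    wavelet = wavelet_select(X, provenance,
                             keep_fraction = params$keep_fraction %||% 0.1),
    swlda = swlda_select(X, y, alpha_in = params$alpha_in %||% 0.10,
                         alpha_out = params$alpha_out %||% 0.15,
                         max_features = params$max_features),
    svm_weights = {
      m <- train_svm(X, y, svm_params(C = params$C %||% 1, kernel = "linear"))
      rep_ <- svm_weight_ranking(m, provenance)
      k <- min(params$k %||% nrow(X), ncol(X))
      list(report = rep_, keep = sort(rep_$ranking[seq_len(k)]))
    },
    band_restrict = {
      br <- band_restrict(X, provenance, params$band %||% "theta")
      list(index = br$index)
    }
  )
  structure(list(method = method, core = core, n_features_in = ncol(X)),
            class = "selector")
}

#' Apply a fitted selector to rows
#' @param sel a `selector` from [fit_selector()]
#' @param X matrix with the training column count
#' @return reduced matrix
#' @export
apply_selector <- function(sel, X) {
  stopifnot(inherits(sel, "selector"), ncol(X) == sel$n_features_in)
  X <- as.matrix(X)
  switch(
    sel$method,
    none = X,
    pca = pca_transform(sel$core, X),
    wavelet = wavelet_transform(sel$core, X),
    swlda = X[, sel$core$selected, drop = FALSE],
    svm_weights = X[, sel$core$keep, drop = FALSE],
    band_restrict = X[, sel$core$index, drop = FALSE]
  )
}
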