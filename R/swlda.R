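# Stepwise linear discriminant analysis: forward inclusion / backward
# elimination of features by ordinary-least-squares regression p-values
# against the +/-1 class code, yielding a linear discriminant over the
# selected features. The number of selected features is capped by the number
# of training samples (the least-squares system is otherwise rank-deficient).

#' Stepwise linear discriminant feature selection
#'
#' Forward steps add the candidate with the smallest regression p-value when
#' it is below `alpha_in`; backward steps remove any included feature whose
#' p-value rises above `alpha_out`; the loop runs to a fixed point or until
#' `max_features` (default: the number of training samples) are included.
#' If no feature passes `alpha_in` an empty selection is returned with a
#' warning status rather than an error; the resulting classifier predicts
#' the majority class.
#'
#' @param X numeric feature matrix (rows = samples)
#' @param y class labels: +/-1, logical, or a two-level factor/character
#' @param alpha_in forward-inclusion p-value threshold (default 0.10)
#' @param alpha_out backward-removal p-value threshold (default 0.15)
#' @param max_features inclusion cap; default `nrow(X)`
#' @return object of class `swlda_model`: `selected` (column indices in
#'   inclusion order), `coef` (intercept + coefficients of the final
#'   discriminant), `history`, `status` ("ok" or "empty"), `majority`
#' @export
swlda_select <- function(X, y, alpha_in = 0.10, alpha_out = 0.15,
                         max_features = NULL) {
  X <- as.matrix(X)
  yy <- encode_pm1(y)
  if (length(unique(yy$y)) < 2) stop("both classes must be present", call. = FALSE)
  n <- nrow(X); d <- ncol(X)
  max_features <- min(max_features %||% n, n)
  yv <- yy$y
  selected <- integer(0)
  history <- list()
  repeat {
    changed <- FALSE
    # ---- forward step -------------------------------------------------
    if (length(selected) < max_features) {
      df_new <- n - length(selected) - 2L   # residual df after adding one
      if (df_new >= 1) {
        cand <- setdiff(seq_len(d), selected)
        if (length(cand) > 0) {
          Q <- qr.Q(qr(cbind(1, X[, selected, drop = FALSE])))
          ry <- yv - Q %*% crossprod(Q, yv)
          RX <- X[, cand, drop = FALSE]
          RX <- RX - Q %*% crossprod(Q, RX)
          sxx <- colSums(RX^2)
          sxy <- as.numeric(crossprod(RX, ry))
          ok <- sxx > 1e-12 * max(1, max(sxx))
          beta <- ifelse(ok, sxy / sxx, 0)
          rss <- sum(ry^2) - beta^2 * sxx
          rss[rss < 0] <- 0
          tstat <- ifelse(ok & rss > 0,
                          beta * sqrt(sxx) * sqrt(df_new) / sqrt(rss),
                          ifelse(ok, Inf, 0))
          pvals <- 2 * pt(-abs(tstat), df_new)
          pvals[!ok] <- 1
          jbest <- which.min(pvals)
          if (pvals[jbest] < alpha_in) {
            selected <- c(selected, cand[jbest])
            history[[length(history) + 1]] <-
              data.frame(action = "add", feature = cand[jbest],
                         p = pvals[jbest])
            changed <- TRUE
          }
        }
      }
    }
    # ---- backward step ------------------------------------------------
    while (length(selected) > 1) {
      p_in <- ols_pvalues(X[, selected, drop = FALSE], yv)
      worst <- which.max(p_in)
      if (p_in[worst] > alpha_out) {
        history[[length(history) + 1]] <-
          data.frame(action = "drop", feature = selected[worst],
                     p = p_in[worst])
        selected <- selected[-worst]
        changed <- TRUE
      } else break
    }
    if (!changed || length(selected) >= max_features) break
  }
  maj <- if (sum(yv > 0) >= sum(yv < 0)) 1 else -1
  cf <- if (length(selected) > 0) {
    fit <- stats::lm.fit(cbind(1, X[, selected, drop = FALSE]), yv)
    unname(fit$coefficients)
  } else numeric(0)
  cf[is.na(cf)] <- 0
  structure(
    list(selected = selected, coef = cf,
         history = if (length(history)) do.call(rbind, history) else
           data.frame(action = character(0), feature = integer(0), p = numeric(0)),
         status = if (length(selected) > 0) "ok" else "empty",
         majority = maj, levels = yy$levels, n_train = n),
    class = "swlda_model"
  )
}

# p-values of the non-intercept coefficients of an OLS fit of y on X
ols_pvalues <- function(X, y) {
  n <- nrow(X); p <- ncol(X)
  df <- n - p - 1L
  if (df < 1) return(rep(0, p))       # saturated: keep everything
  fit <- stats::lm.fit(cbind(1, X), y)
  rss <- sum(fit$residuals^2)
  R <- qr.R(fit$qr)
  XtXinv_diag <- diag(chol2inv(R))
  se <- sqrt(pmax(rss / df * XtXinv_diag, 0))[-1]
  b <- fit$coefficients[-1]
  tt <- ifelse(se > 0, abs(b) / se, Inf)
  2 * pt(-tt, df)
}

# map labels to +/-1 and remember the original coding
encode_pm1 <- function(y) {
  if (is.numeric(y)) {
    stopifnot(all(y %in% c(-1, 1)))
    return(list(y = as.numeric(y), levels = c(`-1` = -1, `1` = 1)))
  }
  y <- as.character(y)
  lv <- sort(unique(y))
  if (length(lv) > 2) stop("more than two classes", call. = FALSE)
  # convention: "TMS+" (or the later sorted level) codes +1
  pos <- if ("TMS+" %in% lv) "TMS+" else lv[length(lv)]
  list(y = ifelse(y == pos, 1, -1), levels = c(neg = setdiff(lv, pos), pos = pos))
}

decode_pm1 <- function(v, levels) {
  if (identical(names(levels), c("-1", "1")) || is.numeric(levels)) return(v)
  ifelse(v > 0, levels[["pos"]], levels[["neg"]])
}

#' Predict with an SWLDA discriminant
#'
#' @param object an `swlda_model`
#' @param newdata feature matrix with the same columns as training
#' @param type `"class"` for labels, `"score"` for the discriminant score
#' @param ... unused
#' @export
predict.swlda_model <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (object$status == "empty") {
    score <- rep(0, nrow(newdata))
  } else {
    score <- as.numeric(cbind(1, newdata[, object$selected, drop = FALSE]) %*%
                          object$coef)
  }
  if (type == "score") return(score)
  lab <- ifelse(score > 0, 1, ifelse(score < 0, -1, object$majority))
  if (object$status == "empty") lab <- rep(object$majority, length(lab))
  decode_pm1(lab, object$levels)
}
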