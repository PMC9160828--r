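# Interval-shrinking ("evolutionary") hyperparameter search: evaluate a
# coarse grid over the current interval, re-center on the best point, shrink
# interval and step geometrically, stop when the best score stops improving.
# Cheaper than exhaustive grid search, which is kept as an optional mode and
# as the test oracle. Both parameters are searched on a log10 scale, the
# standard choice for SVM cost and kernel width.

#' Search space for the SVM hyperparameter search
#'
#' @param C_range,sigma_range parameter bounds (natural scale); a degenerate
#'   range (equal bounds) pins the parameter
#' @param n_grid grid points per axis and iteration
#' @param shrink interval shrink factor per iteration, in (0, 1)
#' @param max_iter maximum number of refinement iterations
#' @return object of class `search_space`
#' @export
search_space <- function(C_range = c(1e-2, 1e3), sigma_range = c(1e-2, 1e2),
                         n_grid = 5, shrink = 0.5, max_iter = 6) {
  stopifnot(length(C_range) == 2, length(sigma_range) == 2,
            C_range[1] <= C_range[2], sigma_range[1] <= sigma_range[2],
            all(c(C_range, sigma_range) > 0),
            n_grid >= 1, shrink > 0, shrink < 1, max_iter >= 1)
  structure(list(C = log10(C_range), sigma = log10(sigma_range),
                 n_grid = as.integer(n_grid), shrink = shrink,
                 max_iter = as.integer(max_iter)),
            class = "search_space")
}

axis_points <- function(bounds, n) {
  if (bounds[1] == bounds[2]) return(bounds[1])
  seq(bounds[1], bounds[2], length.out = n)
}

# deterministic tie-break: highest accuracy, then smaller C, then smaller sigma
pick_best <- function(evals) {
  evals[order(-evals$accuracy, evals$C, evals$sigma), ][1, ]
}

#' Interval-shrinking hyperparameter search
#'
#' @param objective function taking `list(C =, sigma =)` and returning a
#'   scalar score (validation accuracy); evaluation failures are skipped and
#'   logged
#' @param space a [search_space()]
#' @return list with `best` (C, sigma, accuracy), `trace` (one row per
#'   evaluation: iteration, C, sigma, accuracy, interval bounds) and
#'   `n_evaluations`
#' @export
evolutionary_search <- function(objective, space) {
  stopifnot(inherits(space, "search_space"))
  loC <- space$C; loS <- space$sigma
  curC <- loC; curS <- loS
  cache <- new.env(parent = emptyenv())
  trace <- list()
  best_acc <- -Inf
  for (it in seq_len(space$max_iter)) {
    grid <- expand.grid(lc = axis_points(curC, space$n_grid),
                        ls = axis_points(curS, space$n_grid))
    evals <- lapply(seq_len(nrow(grid)), function(g) {
      key <- sprintf("%.12g|%.12g", grid$lc[g], grid$ls[g])
      if (!is.null(cache[[key]])) return(NULL)   # already evaluated
      val <- tryCatch(
        objective(list(C = 10^grid$lc[g], sigma = 10^grid$ls[g])),
        error = function(e) NA_real_)
      row <- data.frame(iteration = it, C = 10^grid$lc[g],
                        sigma = 10^grid$ls[g], accuracy = val,
                        C_lo = 10^curC[1], C_hi = 10^curC[2],
                        sigma_lo = 10^curS[1], sigma_hi = 10^curS[2])
      cache[[key]] <- row
      row
    })
    trace <- c(trace, Filter(Negate(is.null), evals))
    all_evals <- do.call(rbind, trace)
    ok <- all_evals[!is.na(all_evals$accuracy), ]
    if (nrow(ok) == 0) {
      if (it == space$max_iter) stop("objective failed at every point", call. = FALSE)
      next
    }
    best <- pick_best(ok)
    improved <- best$accuracy > best_acc
    best_acc <- max(best_acc, best$accuracy)
    if (!improved && it > 1) break       # scores stopped improving
    # re-center on the best point, shrink interval, clip to original bounds
    recenter <- function(bounds0, cur, center_log) {
      half <- space$shrink * (cur[2] - cur[1]) / 2
      lo <- max(bounds0[1], center_log - half)
      hi <- min(bounds0[2], center_log + half)
      c(lo, hi)
    }
    curC <- recenter(loC, curC, log10(best$C))
    curS <- recenter(loS, curS, log10(best$sigma))
  }
  all_evals <- do.call(rbind, trace)
  ok <- all_evals[!is.na(all_evals$accuracy), ]
  if (nrow(ok) == 0) stop("objective failed at every point", call. = FALSE)
  best <- pick_best(ok)
  list(best = list(C = best$C, sigma = best$sigma, accuracy = best$accuracy),
       trace = all_evals, n_evaluations = nrow(all_evals))
}

#' Exhaustive grid search
#'
#' Evaluates the full log-spaced grid; the comparator and test oracle for
#' [evolutionary_search()], and an optional search mode in its own right.
#'
#' @param objective as in [evolutionary_search()]
#' @param space a [search_space()]
#' @param resolution points per axis
#' @return list with `best` and `evaluations`
#' @export
grid_search <- function(objective, space, resolution = 10) {
  stopifnot(inherits(space, "search_space"), resolution >= 1)
  grid <- expand.grid(lc = axis_points(space$C, resolution),
                      ls = axis_points(space$sigma, resolution))
  evals <- do.call(rbind, lapply(seq_len(nrow(grid)), function(g) {
    val <- tryCatch(objective(list(C = 10^grid$lc[g], sigma = 10^grid$ls[g])),
                    error = function(e) NA_real_)
    data.frame(C = 10^grid$lc[g], sigma = 10^grid$ls[g], accuracy = val)
  }))
  ok <- evals[!is.na(evals$accuracy), ]
  if (nrow(ok) == 0) stop("objective failed at every point", call. = FALSE)
  best <- pick_best(ok)
  list(best = list(C = best$C, sigma = best$sigma, accuracy = best$accuracy),
       evaluations = evals)
}
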