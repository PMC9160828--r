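# Labeling and the balanced Monte-Carlo leave-one-out evaluation engine.
#
# With 8 responders and 6 non-responders a plain leave-one-out split leaves
# an unbalanced training set, which both destabilizes model selection and
# makes raw accuracies misleading. The engine therefore holds out one
# subject, repeatedly draws a maximal class-balanced subset of the rest,
# partitions it into balanced training and validation sets, fits everything
# (standardization, selector, classifier, optional hyperparameter search)
# on the training rows only, and averages the test outcome over trials and
# folds. The number of trials per fold is the number of distinct maximal
# balanced subsets times the number of distinct train/validation partitions,
# capped (default 50).

#' Label subjects from their MMSE change
#'
#' A subject whose MMSE score did not decrease after treatment is a
#' responder: label TMS+ iff `mmse_post >= mmse_pre` (ties count as
#' benefit).
#'
#' @param table data.frame with columns `subject_id`, `mmse_pre`, `mmse_post`
#' @return the table with a `label` column added; class counts in
#'   `attr(, "class_counts")`
#' @export
label_subjects <- function(table) {
  req <- c("subject_id", "mmse_pre", "mmse_post")
  stopifnot(all(req %in% names(table)))
  for (col in c("mmse_pre", "mmse_post")) {
    bad <- which(is.na(table[[col]]))
    if (length(bad) > 0) {
      stop("missing ", col, " for subject ", table$subject_id[bad[1]],
           call. = FALSE)
    }
    if (any(table[[col]] < 0 | table[[col]] > 30)) {
      stop("MMSE scores must lie in [0, 30]", call. = FALSE)
    }
  }
  table$label <- ifelse(table$mmse_post >= table$mmse_pre, "TMS+", "TMS-")
  attr(table, "class_counts") <- table(table$label)
  table
}

#' Draw a maximal class-balanced subject subset
#'
#' Samples `min(n_pos, n_neg)` ids without replacement from each class using
#' the current RNG stream.
#'
#' @param ids_pos,ids_neg subject ids per class
#' @return character vector of `2 * min(n_pos, n_neg)` ids
#' @export
max_balanced_subset <- function(ids_pos, ids_neg) {
  if (length(ids_pos) == 0 || length(ids_neg) == 0) {
    stop("both classes must be non-empty", call. = FALSE)
  }
  m <- min(length(ids_pos), length(ids_neg))
  c(resample(ids_pos, m), resample(ids_neg, m))
}

# sample() without the scalar-x surprise
resample <- function(x, size) x[sample.int(length(x), size)]

#' Number of Monte-Carlo trials needed to cover the sampling space
#'
#' The count of distinct maximal balanced subsets is the number of ways to
#' drop the surplus majority-class members, `choose(max, max - min)`; each
#' subset admits `choose(m, t)^2 * choose(m - t, v)^2` distinct balanced
#' train/validation partitions (t training, v validation subjects per
#' class, m = min count). The returned trial count is the product, capped.
#'
#' @param n_pos,n_neg class counts available for trial sampling
#' @param cap upper bound on the trial count (default 50)
#' @param val_per_class validation subjects per class (default 1)
#' @param train_per_class training subjects per class; default `m - val_per_class`
#' @return integer trial count
#' @export
n_trials_required <- function(n_pos, n_neg, cap = 50, val_per_class = 1,
                              train_per_class = NULL) {
  stopifnot(n_pos >= 1, n_neg >= 1)
  m <- min(n_pos, n_neg)
  subsets <- choose(max(n_pos, n_neg), max(n_pos, n_neg) - m)
  tpc <- train_per_class %||% (m - val_per_class)
  partitions <- choose(m, tpc)^2 * choose(m - tpc, val_per_class)^2
  as.integer(min(subsets * partitions, cap))
}

#' Assemble a feature set from externally computed pieces
#'
#' Mostly useful for constructing small synthetic feature sets directly; the
#' usual entry point is [cohort_features()].
#'
#' @param X subjects x features matrix
#' @param provenance provenance data.frame, one row per column of `X`
#' @param subjects data.frame with at least `subject_id` and `label`
#' @param window_length_s feature window length (metadata)
#' @return object of class `feature_set`
#' @export
feature_set <- function(X, provenance, subjects, window_length_s = NA_real_) {
  X <- as.matrix(X)
  stopifnot(nrow(provenance) == ncol(X), nrow(subjects) == nrow(X),
            all(c("subject_id", "label") %in% names(subjects)))
  structure(list(X = X, provenance = provenance, subjects = subjects,
                 window_length_s = window_length_s),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> %d subjects x %d features (%s)\n",
              nrow(x$X), ncol(x$X),
              paste(names(table(x$subjects$label)),
                    table(x$subjects$label), collapse = " / ")))
  invisible(x)
}

# one Monte-Carlo trial: split -> standardize -> select -> fit -> predict
run_trial <- function(X, y, prov, train_idx, val_idx, test_idx,
                      selector, selector_params, classifier, params,
                      hyperopt_space) {
  std <- fit_standardizer(X[train_idx, , drop = FALSE])
  Xtr <- apply_standardizer(std, X[train_idx, , drop = FALSE])
  Xte <- apply_standardizer(std, X[test_idx, , drop = FALSE])
  ytr <- y[train_idx]
  sel <- fit_selector(selector, Xtr, ytr, prov, selector_params)
  Xtr2 <- apply_selector(sel, Xtr)
  Xte2 <- apply_selector(sel, Xte)
  if (ncol(Xtr2) == 0) {                 # empty selection: majority vote
    maj <- if (sum(ytr > 0) >= sum(ytr < 0)) 1 else -1
    return(list(pred = rep(maj, length(test_idx)), params_used = params,
                empty_selection = TRUE))
  }
  params_used <- params
  if (classifier == "svm" && !is.null(hyperopt_space) && length(val_idx) > 0) {
    Xval2 <- apply_selector(sel, apply_standardizer(std, X[val_idx, , drop = FALSE]))
    yval <- y[val_idx]
    obj <- function(p) {
      m <- train_svm(Xtr2, ytr, svm_params(C = p$C, sigma = p$sigma,
                                           kernel = params$kernel))
      accuracy(yval, predict(m, Xval2))
    }
    best <- evolutionary_search(obj, hyperopt_space)$best
    params_used <- svm_params(C = best$C, sigma = best$sigma,
                              kernel = params$kernel)
  }
  model <- if (classifier == "svm") {
    train_svm(Xtr2, ytr, params_used)
  } else {
    train_swlda_classifier(Xtr2, ytr)
  }
  list(pred = predict(model, Xte2), params_used = params_used,
       empty_selection = FALSE)
}

#' Balanced Monte-Carlo leave-one-out validation
#'
#' Every subject serves as the test case exactly once. Per fold,
#' [n_trials_required()] Monte-Carlo draws of a maximal balanced subset of
#' the remaining subjects are partitioned into balanced train / validation
#' sets; the standardizer, selector and classifier see training rows only.
#' The report aggregates per-subject and overall accuracies and the
#' across-trial standard deviation.
#'
#' @param features a `feature_set`
#' @param selector selector method name (see [fit_selector()])
#' @param selector_params selector parameters
#' @param classifier `"svm"` or `"swlda"`
#' @param params an [svm_params()] for the SVM route
#' @param hyperopt_space optional [search_space()]; when supplied, C and
#'   sigma are tuned per trial by maximizing balanced-validation accuracy
#' @param val_per_class validation subjects per class (default 1)
#' @param train_per_class training subjects per class; default uses all
#'   non-validation members of the balanced subset
#' @param trial_cap cap for [n_trials_required()] (default 50)
#' @param n_trials override the computed trial count
#' @param seed RNG seed; identical seeds give identical reports
#' @param audit if `TRUE`, record every trial's split composition
#' @return object of class `validation_report`
#' @export
mc_leave_one_out <- function(features,
                             selector = "band_restrict",
                             selector_params = list(band = "theta"),
                             classifier = c("svm", "swlda"),
                             params = svm_params(),
                             hyperopt_space = NULL,
                             val_per_class = 1,
                             train_per_class = NULL,
                             trial_cap = 50,
                             n_trials = NULL,
                             seed = 1,
                             audit = FALSE) {
  classifier <- match.arg(classifier)
  stopifnot(inherits(features, "feature_set"))
  subj <- features$subjects
  y <- encode_pm1(subj$label)$y
  if (min(table(y)) < 2) stop("need >= 2 subjects per class", call. = FALSE)
  n <- nrow(features$X)
  with_seed(seed, {
    per_subject <- data.frame(subject_id = subj$subject_id,
                              label = subj$label,
                              n_trials = 0L, accuracy = NA_real_,
                              stringsAsFactors = FALSE)
    trial_outcomes <- list()
    audit_log <- list()
    skipped <- character(0)
    for (i in seq_len(n)) {
      rest <- setdiff(seq_len(n), i)
      pos <- rest[y[rest] > 0]; neg <- rest[y[rest] < 0]
      m <- min(length(pos), length(neg))
      tpc <- train_per_class %||% (m - val_per_class)
      if (m < 1 || tpc < 1 || tpc + val_per_class > m) {
        skipped <- c(skipped, sprintf(
          "%s: infeasible balance (%d/%d remaining, train %s + val %d per class)",
          subj$subject_id[i], length(pos), length(neg),
          as.character(tpc), val_per_class))
        next
      }
      nt <- n_trials %||% n_trials_required(length(pos), length(neg),
                                            cap = trial_cap,
                                            val_per_class = val_per_class,
                                            train_per_class = train_per_class)
      correct <- numeric(nt)
      for (t in seq_len(nt)) {
        sp <- resample(pos, m); sn <- resample(neg, m)
        tr <- c(sp[seq_len(tpc)], sn[seq_len(tpc)])
        va <- if (val_per_class > 0) {
          c(sp[tpc + seq_len(val_per_class)], sn[tpc + seq_len(val_per_class)])
        } else integer(0)
        stopifnot(length(intersect(tr, va)) == 0, !(i %in% tr), !(i %in% va),
                  sum(y[tr] > 0) == sum(y[tr] < 0))
        if (val_per_class > 0) stopifnot(sum(y[va] > 0) == sum(y[va] < 0))
        res <- run_trial(features$X, y, features$provenance, tr, va, i,
                         selector, selector_params, classifier, params,
                         hyperopt_space)
        correct[t] <- 100 * (sign_of(res$pred) == y[i])
        if (audit) {
          audit_log[[length(audit_log) + 1]] <- list(
            test_id = subj$subject_id[i],
            train_ids = subj$subject_id[tr],
            val_ids = subj$subject_id[va],
            params = unclass(res$params_used))
        }
      }
      per_subject$n_trials[i] <- nt
      per_subject$accuracy[i] <- mean(correct)
      trial_outcomes[[i]] <- correct
    }
    outcomes <- unlist(trial_outcomes)
    if (length(outcomes) == 0) stop("every fold was infeasible", call. = FALSE)
    structure(
      list(per_subject = per_subject,
           overall = mean(outcomes),
           sd_trials = sd(outcomes),
           n_trials_total = length(outcomes),
           skipped_folds = skipped,
           config = list(mode = "mc_leave_one_out", selector = selector,
                         selector_params = selector_params,
                         classifier = classifier, params = unclass(params),
                         val_per_class = val_per_class,
                         train_per_class = train_per_class,
                         trial_cap = trial_cap, seed = seed,
                         hyperopt = !is.null(hyperopt_space)),
           audit = if (audit) audit_log else NULL),
      class = "validation_report"
    )
  })
}

sign_of <- function(pred) {
  if (is.numeric(pred)) sign(pred[1]) else if (pred[1] == "TMS+") 1 else -1
}

#' Direct classification with random stratified splits
#'
#' The simpler protocol without a validation set: `n_random_trials`
#' stratified train/test splits at `train_fraction`; the test set is
#' balanced by subsampling the held-out remainder to equal class counts.
#'
#' @inheritParams mc_leave_one_out
#' @param train_fraction fraction of subjects used for training (default
#'   9/14)
#' @param n_random_trials number of random splits (default 50)
#' @return a `validation_report`
#' @export
direct_classification <- function(features,
                                  train_fraction = 9 / 14,
                                  n_random_trials = 50,
                                  selector = "band_restrict",
                                  selector_params = list(band = "theta"),
                                  classifier = c("svm", "swlda"),
                                  params = svm_params(),
                                  seed = 1,
                                  audit = FALSE) {
  classifier <- match.arg(classifier)
  stopifnot(inherits(features, "feature_set"))
  subj <- features$subjects
  y <- encode_pm1(subj$label)$y
  n <- nrow(features$X)
  pos <- which(y > 0); neg <- which(y < 0)
  ntr_pos <- round(train_fraction * length(pos))
  ntr_neg <- round(train_fraction * length(neg))
  if (ntr_pos < 1 || ntr_neg < 1 ||
      ntr_pos >= length(pos) || ntr_neg >= length(neg)) {
    stop("train_fraction leaves a class empty in train or test", call. = FALSE)
  }
  with_seed(seed, {
    acc <- numeric(n_random_trials)
    hits <- integer(n); appearances <- integer(n)
    audit_log <- list()
    for (t in seq_len(n_random_trials)) {
      trp <- resample(pos, ntr_pos); trn <- resample(neg, ntr_neg)
      tr <- c(trp, trn)
      remp <- setdiff(pos, trp); remn <- setdiff(neg, trn)
      mte <- min(length(remp), length(remn))
      te <- c(resample(remp, mte), resample(remn, mte))
      res <- run_trial(features$X, y, features$provenance, tr, integer(0), te,
                       selector, selector_params, classifier, params, NULL)
      ok <- vapply(seq_along(te), function(j) {
        s <- if (is.numeric(res$pred)) sign(res$pred[j]) else
          if (res$pred[j] == "TMS+") 1 else -1
        s == y[te[j]]
      }, logical(1))
      acc[t] <- 100 * mean(ok)
      hits[te] <- hits[te] + ok
      appearances[te] <- appearances[te] + 1L
      if (audit) {
        audit_log[[t]] <- list(train_ids = subj$subject_id[tr],
                               test_ids = subj$subject_id[te])
      }
    }
    structure(
      list(per_subject = data.frame(
             subject_id = subj$subject_id, label = subj$label,
             n_trials = appearances,
             accuracy = ifelse(appearances > 0, 100 * hits / appearances, NA),
             stringsAsFactors = FALSE),
           overall = mean(acc),
           sd_trials = sd(acc),
           n_trials_total = n_random_trials,
           skipped_folds = character(0),
           config = list(mode = "direct_classification",
                         train_fraction = train_fraction,
                         n_random_trials = n_random_trials,
                         selector = selector,
                         selector_params = selector_params,
                         classifier = classifier, params = unclass(params),
                         seed = seed),
           audit = if (audit) audit_log else NULL),
      class = "validation_report"
    )
  })
}

#' Accuracy as a function of training or validation set size
#'
#' Repeats [mc_leave_one_out()] over the feasible grid of balanced set
#' sizes and tabulates mean accuracy per size.
#'
#' @inheritParams mc_leave_one_out
#' @param mode `"train"`: vary training subjects per class with the
#'   validation set fixed at `val_per_class`; `"val"`: vary validation
#'   subjects per class with `train_per_class` fixed
#' @param sizes per-class sizes to evaluate; default is the feasible grid
#' @param ... passed to [mc_leave_one_out()]
#' @return data.frame (size per class, total size, mean accuracy, sd)
#' @export
size_sweep <- function(features, mode = c("train", "val"), sizes = NULL,
                       val_per_class = 1, train_per_class = NULL,
                       seed = 1, ...) {
  mode <- match.arg(mode)
  y <- encode_pm1(features$subjects$label)$y
  m_after <- min(sum(y > 0), sum(y < 0)) - 1  # worst-case after removing test
  if (mode == "train") {
    sizes <- sizes %||% seq_len(max(1, m_after - val_per_class))
    rows <- lapply(sizes, function(s) {
      rep <- mc_leave_one_out(features, val_per_class = val_per_class,
                              train_per_class = s, seed = seed, ...)
      data.frame(size_per_class = s, total_size = 2 * s,
                 mean_accuracy = rep$overall, sd = rep$sd_trials)
    })
  } else {
    tpc <- train_per_class %||% 1
    sizes <- sizes %||% seq_len(max(1, m_after - tpc))
    rows <- lapply(sizes, function(s) {
      rep <- mc_leave_one_out(features, val_per_class = s,
                              train_per_class = tpc, seed = seed, ...)
      data.frame(size_per_class = s, total_size = 2 * s,
                 mean_accuracy = rep$overall, sd = rep$sd_trials)
    })
  }
  out <- do.call(rbind, rows)
  attr(out, "mode") <- mode
  out
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %s: overall %.1f%% (sd %.1f over %d trials)\n",
              x$config$mode, x$overall, x$sd_trials, x$n_trials_total))
  if (length(x$skipped_folds) > 0) {
    cat("  skipped folds:", length(x$skipped_folds), "\n")
  }
  invisible(x)
}
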