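# End-to-end orchestration: cohort -> preprocessing -> windowed band-power
# features -> selector -> balanced Monte-Carlo validation, plus the
# comparison tables the analysis scripts tabulate (selector comparison,
# window-length sweep).

#' Compute the cohort feature matrix
#'
#' Runs the full per-subject pipeline (band-pass + notch filter, 1-s
#' epoching, amplitude-threshold rejection, windowed band-power extraction)
#' and assembles the subjects x features matrix. Because rejection can drop
#' different numbers of epochs per subject, every subject is truncated to
#' the cohort-minimum window count so columns align.
#'
#' @param cohort a `synthetic_cohort`, or a `synthetic_config` (recordings
#'   are then generated one at a time and discarded after feature
#'   extraction, keeping memory flat)
#' @param window_length_s feature window length in seconds (default 2)
#' @param bands band table
#' @param band_subset optional band-name restriction at extraction time
#' @param low_hz,high_hz,notch_hz filter settings (see [bandpass_notch()])
#' @param epoch_length_s cleaning epoch length (default 1 s)
#' @param amp_threshold_uv artifact rejection threshold (default 100)
#' @param preprocess set `FALSE` to skip filtering/rejection (features on
#'   the raw signal; mainly for controlled experiments)
#' @return a `feature_set`
#' @export
cohort_features <- function(cohort, window_length_s = 2, bands = eeg_bands(),
                            band_subset = NULL, low_hz = 0.1, high_hz = 60,
                            notch_hz = 50, epoch_length_s = 1,
                            amp_threshold_uv = 100, preprocess = TRUE) {
  if (inherits(cohort, "synthetic_config")) {
    config <- cohort
    n <- config$n_pos + config$n_neg
    labels <- c(rep("TMS+", config$n_pos), rep("TMS-", config$n_neg))
    ids <- sprintf("S%02d", seq_len(n))
    subjects <- generate_cohort_subjects(config, labels, ids)
    get_rec <- function(i) generate_recording(config, labels[i],
                                              derive_seed(config$seed, i),
                                              subject_id = ids[i])
  } else if (inherits(cohort, "synthetic_cohort")) {
    subjects <- cohort$subjects
    n <- nrow(subjects)
    get_rec <- function(i) cohort$recordings[[i]]
  } else {
    stop("cohort must be a synthetic_cohort or synthetic_config", call. = FALSE)
  }
  series <- vector("list", n)
  for (i in seq_len(n)) {
    rec <- get_rec(i)
    if (preprocess) rec <- bandpass_notch(rec, low_hz, high_hz, notch_hz)
    ep <- segment_epochs(rec, epoch_length_s)
    if (preprocess) ep <- reject_artifacts(ep, amp_threshold_uv)
    series[[i]] <- extract_features(ep, bands = bands,
                                    window_length_s = window_length_s,
                                    band_subset = band_subset)
    rm(rec, ep)
  }
  nw_common <- min(vapply(series, function(s) s$n_windows, numeric(1)))
  keep <- series[[1]]$provenance$window <= nw_common
  prov <- series[[1]]$provenance[keep, , drop = FALSE]
  X <- t(vapply(series, function(s) {
    s$features[s$provenance$window <= nw_common]
  }, numeric(sum(keep))))
  rownames(prov) <- NULL
  feature_set(X, prov, subjects, window_length_s = window_length_s)
}

# subject table for a config without generating any signal
generate_cohort_subjects <- function(config, labels, ids) {
  cohort_meta <- with_seed(derive_seed(config$seed, 0L), {
    rule <- config$mmse_rule
    n_tie <- round((rule$pos$tie_fraction %||% 0) * config$n_pos)
    tie_idx <- if (n_tie > 0) sample(seq_len(config$n_pos), n_tie) else integer(0)
    n <- length(labels)
    pre <- integer(n); post <- integer(n)
    for (i in seq_len(n)) {
      if (labels[i] == "TMS+") {
        pre[i] <- sample(rule$pos$pre_range[1]:rule$pos$pre_range[2], 1)
        delta <- if (i %in% tie_idx) 0L else
          sample(rule$pos$delta_range[1]:rule$pos$delta_range[2], 1)
      } else {
        pre[i] <- sample(rule$neg$pre_range[1]:rule$neg$pre_range[2], 1)
        delta <- sample(rule$neg$delta_range[1]:rule$neg$delta_range[2], 1)
      }
      post[i] <- pre[i] + delta
    }
    data.frame(subject_id = ids, mmse_pre = pre, mmse_post = post,
               condition = "eyes-closed", label = labels,
               stringsAsFactors = FALSE)
  })
  cohort_meta
}

#' Run one end-to-end experiment
#'
#' @param cohort a `synthetic_cohort`, `synthetic_config`, or a precomputed
#'   `feature_set` (feature options are then ignored)
#' @param selector,selector_params selector route (see [fit_selector()])
#' @param classifier `"svm"` or `"swlda"`
#' @param params an [svm_params()]
#' @param validation `"loo"` for [mc_leave_one_out()] or `"direct"` for
#'   [direct_classification()]
#' @param hyperopt_space optional [search_space()] (loo mode)
#' @param window_length_s feature window length
#' @param seed RNG seed for the validation engine
#' @param out_dir if given, the report (with config fingerprint and seed)
#'   is written there as JSON
#' @param ... further arguments to the validation engine
#' @return a `validation_report`
#' @export
run_experiment <- function(cohort, selector = "none",
                           selector_params = list(),
                           classifier = "svm", params = svm_params(),
                           validation = c("loo", "direct"),
                           hyperopt_space = NULL,
                           window_length_s = 2, seed = 1,
                           out_dir = NULL, ...) {
  validation <- match.arg(validation)
  features <- if (inherits(cohort, "feature_set")) cohort else
    cohort_features(cohort, window_length_s = window_length_s)
  report <- if (validation == "loo") {
    mc_leave_one_out(features, selector = selector,
                     selector_params = selector_params,
                     classifier = classifier, params = params,
                     hyperopt_space = hyperopt_space, seed = seed, ...)
  } else {
    direct_classification(features, selector = selector,
                          selector_params = selector_params,
                          classifier = classifier, params = params,
                          seed = seed, ...)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_validation_report(report, file.path(out_dir, sprintf(
      "report_%s_%s_seed%d.json", validation, selector, seed)))
  }
  report
}

#' Compare feature-selection routes on one feature set
#'
#' @param features a `feature_set`
#' @param selectors named list: route name -> list(selector =,
#'   selector_params =); default covers the five standard routes
#' @param seed seed shared by every route (paired comparison)
#' @param ... passed to [mc_leave_one_out()]
#' @return data.frame (method, mean_accuracy, sd, n_trials)
#' @export
compare_selectors <- function(features, selectors = default_selector_routes(),
                              seed = 1, ...) {
  rows <- lapply(names(selectors), function(nm) {
    s <- selectors[[nm]]
    rep <- mc_leave_one_out(features, selector = s$selector,
                            selector_params = s$selector_params %||% list(),
                            seed = seed, ...)
    data.frame(method = nm, mean_accuracy = rep$overall,
               sd = rep$sd_trials, n_trials = rep$n_trials_total,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' The five standard selector routes
#' @return named list usable with [compare_selectors()]
#' @export
default_selector_routes <- function() {
  list(
    none = list(selector = "none"),
    pca = list(selector = "pca", selector_params = list(k = 20)),
    wavelet = list(selector = "wavelet",
                   selector_params = list(keep_fraction = 0.1)),
    swlda = list(selector = "swlda"),
    theta = list(selector = "band_restrict",
                 selector_params = list(band = "theta"))
  )
}

#' Accuracy as a function of the feature window length
#'
#' @param cohort cohort or config accepted by [cohort_features()]
#' @param windows window lengths in seconds (default 1, 2, 4)
#' @param ... passed to [mc_leave_one_out()]
#' @param seed validation seed
#' @return data.frame (window_length_s, mean_accuracy, sd, n_features)
#' @export
window_sweep <- function(cohort, windows = c(1, 2, 4), seed = 1, ...) {
  rows <- lapply(windows, function(w) {
    fs <- cohort_features(cohort, window_length_s = w)
    rep <- mc_leave_one_out(fs, seed = seed, ...)
    data.frame(window_length_s = w, mean_accuracy = rep$overall,
               sd = rep$sd_trials, n_features = ncol(fs$X))
  })
  do.call(rbind, rows)
}
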