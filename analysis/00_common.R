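# Shared setup for the analysis scripts: the study-condition generator
# configuration (14 subjects, 8 responders / 6 non-responders, 30 channels,
# 4-min eyes-closed recordings at 500 Hz, theta amplitude gain ratio 1.5)
# and a feature cache under scratch/ so the scripts can be run in any order
# without regenerating the cohort each time.

suppressMessages(library(rtmseeg))

ANALYSIS_SEED <- 20260401L

results_dir <- "results"
scratch_dir <- "scratch"
dir.create(results_dir, showWarnings = FALSE)
dir.create(scratch_dir, showWarnings = FALSE)

study_config <- function(seed = ANALYSIS_SEED, ...) {
  synthetic_config(seed = seed, ...)
}

null_config <- function(seed = ANALYSIS_SEED) {
  gains <- c(delta = 8, theta = 8, alpha = 8, beta = 8, gamma = 8)
  synthetic_config(band_gains_pos = gains, band_gains_neg = gains, seed = seed)
}

# cached cohort features (window 2 s, full preprocessing)
study_features <- function(config = study_config(), tag = "study") {
  cache <- file.path(scratch_dir, sprintf("features_%s_seed%d.rds", tag,
                                          config$seed))
  if (file.exists(cache)) return(readRDS(cache))
  fs <- cohort_features(config)
  saveRDS(fs, cache)
  fs
}
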