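#!/usr/bin/env Rscript
# Compare the feature-selection routes under balanced Monte-Carlo
# leave-one-out validation with the RBF SVM, on the positive-control cohort
# and on the matched null cohort. The theta-band restriction should lead on
# the positive control (the implanted effect lives there); every route
# should fall to chance on the null cohort.

source("analysis/00_common.R")

fs <- study_features()

cat("positive-control cohort:\n")
tab <- compare_selectors(fs, seed = ANALYSIS_SEED)
# the scalar-power baseline (one mean power per channel-band) for contrast
scalar_rep <- mc_leave_one_out(scalar_band_power(fs), selector = "none",
                               seed = ANALYSIS_SEED)
tab <- rbind(tab, data.frame(method = "scalar_power",
                             mean_accuracy = scalar_rep$overall,
                             sd = scalar_rep$sd_trials,
                             n_trials = scalar_rep$n_trials_total))
# SWLDA as a classifier in its own right (not only as a selector)
swlda_rep <- mc_leave_one_out(fs, selector = "band_restrict",
                              selector_params = list(band = "theta"),
                              classifier = "swlda", seed = ANALYSIS_SEED)
tab <- rbind(tab, data.frame(method = "swlda_classifier_theta",
                             mean_accuracy = swlda_rep$overall,
                             sd = swlda_rep$sd_trials,
                             n_trials = swlda_rep$n_trials_total))
print(tab, digits = 3)
write.csv(tab, file.path(results_dir, "selector_comparison.csv"),
          row.names = FALSE)

cat("\nnull cohort (no class difference):\n")
fs0 <- study_features(null_config(), tag = "null")
tab0 <- compare_selectors(
  fs0, selectors = list(none = list(selector = "none"),
                        theta = list(selector = "band_restrict",
                                     selector_params = list(band = "theta"))),
  seed = ANALYSIS_SEED)
print(tab0, digits = 3)
write.csv(tab0, file.path(results_dir, "selector_comparison_null.csv"),
          row.names = FALSE)
cat("chance for a single 14-subject cohort is wide: subject-level structure\n",
    "makes per-subject outcomes all-or-nothing, so the exact null 95% band\n",
    "is roughly 29-71%; only the across-seed mean concentrates at 50%\n")
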