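#!/usr/bin/env Rscript
# Which band carries the decision? Cumulative per-band weights of a
# linear-kernel SVM fit on the standardized cohort features, and the bands
# of the features SWLDA selects. On the positive-control cohort both should
# concentrate on theta.

source("analysis/00_common.R")

fs <- study_features()
std <- fit_standardizer(fs$X)
Xs <- apply_standardizer(std, fs$X)

lin <- train_svm(Xs, fs$subjects$label, svm_params(kernel = "linear"))
rep_ <- svm_weight_ranking(lin, fs$provenance)
svm_tab <- data.frame(band = names(rep_$band_weights),
                      cumulative_weight = as.numeric(rep_$band_weights),
                      share = as.numeric(rep_$band_weights) /
                        sum(rep_$band_weights))
cat("linear-SVM cumulative band weights:\n")
print(svm_tab, digits = 3)

sw <- swlda_select(Xs, fs$subjects$label)
sw_bands <- table(factor(fs$provenance$band[sw$selected],
                         levels = eeg_bands()$name))
cat("\nbands of SWLDA-selected features:\n")
print(sw_bands)

out <- merge(svm_tab,
             data.frame(band = names(sw_bands),
                        swlda_selected = as.integer(sw_bands)),
             by = "band", all = TRUE)
write.csv(out[order(-out$cumulative_weight), ],
          file.path(results_dir, "band_weights.csv"), row.names = FALSE)
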