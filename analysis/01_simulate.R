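#!/usr/bin/env Rscript
# Generate the synthetic study cohort, export the subject table and a
# BrainVision sample, and compute the windowed band-power feature matrix.
#
# What this produced on the default seed: a 14-subject cohort (8 TMS+ /
# 6 TMS-) whose MMSE table reproduces the labels under the tie-goes-to-
# responder rule, and a 14 x ~13k feature matrix (30 channels x 5 bands x
# ~90-120 two-second windows surviving artifact rejection).

source("analysis/00_common.R")

cfg <- study_config()
cohort <- generate_cohort(cfg)
cat(sprintf("cohort: %d subjects (%d TMS+ / %d TMS-)\n",
            nrow(cohort$subjects), sum(cohort$subjects$label == "TMS+"),
            sum(cohort$subjects$label == "TMS-")))

write_subject_table(cohort$subjects, file.path(results_dir, "subjects.csv"))
relabeled <- label_subjects(read_subject_table(file.path(results_dir, "subjects.csv")))
stopifnot(identical(relabeled$label, cohort$subjects$label))
cat("subject table written; labels re-derive exactly from MMSE scores\n")

# one truncated recording as a BrainVision sample (10 s keeps it small)
demo <- cohort$recordings[[1]]
demo$data <- demo$data[, seq_len(10 * cfg$fs)]
write_brainvision(demo, "sample_subject01_10s", scratch_dir)
back <- read_brainvision(file.path(scratch_dir, "sample_subject01_10s.vhdr"))
stopifnot(max(abs(back$data - demo$data)) < 1e-3)
cat("BrainVision round trip verified on the 10 s sample\n")

fs <- study_features(cfg)
cat(sprintf("feature matrix: %d x %d (%d windows per channel-band)\n",
            nrow(fs$X), ncol(fs$X), max(fs$provenance$window)))

# per-band scalar power summary by class (sanity view of the implanted effect)
sc <- scalar_band_power(fs)
bands <- unique(sc$provenance$band)
summ <- do.call(rbind, lapply(bands, function(b) {
  cols <- sc$provenance$band == b
  data.frame(band = b,
             mean_power_tms_pos = mean(sc$X[sc$subjects$label == "TMS+", cols]),
             mean_power_tms_neg = mean(sc$X[sc$subjects$label == "TMS-", cols]))
}))
summ$ratio <- summ$mean_power_tms_pos / summ$mean_power_tms_neg
write.csv(summ, file.path(results_dir, "band_power_by_class.csv"),
          row.names = FALSE)
print(summ, digits = 3)
cat("theta ratio tracks the squared amplitude gain (1.5^2 = 2.25), pulled\n",
    "toward 1 by in-band pink background and per-subject gain variability\n")
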