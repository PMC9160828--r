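#!/usr/bin/env Rscript
# Effect of the feature-extraction window length (1, 2, 4 s) on
# leave-one-out accuracy with theta-band features. The window length trades
# temporal resolution of the power series against per-window estimation
# noise.

source("analysis/00_common.R")

cfg <- study_config()
tab <- window_sweep(cfg, windows = c(1, 2, 4),
                    selector = "band_restrict",
                    selector_params = list(band = "theta"),
                    seed = ANALYSIS_SEED)
print(tab, digits = 3)
write.csv(tab, file.path(results_dir, "window_sweep.csv"), row.names = FALSE)
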