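#!/usr/bin/env Rscript
# Stage 2: the standard cleaning chain on the simulated walk -- 1-200 Hz
# zero-phase FIR (order 7500), 50 Hz notch (order 3302), common-average
# reference, Infomax ICA with EOG-guided component rejection.

library(gaitsource)

rec <- read_eeg("scratch/analysis/walk.edf")
rec$montage <- montage_1020()
rec$eog <- readRDS("scratch/analysis/eog.rds")

rec <- bandpass_fir(rec, lo_hz = 1, hi_hz = 200, order = 7500)
rec <- notch_fir(rec, mains_hz = 50, order = 3302)
rec <- common_average(rec)

# fit ICA on 4x-decimated data (ample for component topographies), then
# reject and reconstruct at the full rate
dec <- seq(1, ncol(rec$data), by = 4)
rec_fit <- eeg_recording(rec$data[, dec], rec$rate / 4, rec$channel_names,
                         montage = rec$montage,
                         reference = "common_average", eog = rec$eog[dec])
ica <- infomax_ica(rec_fit, n_components = 15, seed = 2)
rec <- reject_components(ica, rec,
                         thresholds = list(eog_corr = 0.5, lf_ratio = 3))
info <- attr(rec, "ica")

saveRDS(rec, "scratch/analysis/clean.rds")
write.table(info$component_scores, "results/ica_component_scores.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)
message(sprintf("ICA: %d/%d components rejected (%s)",
                length(info$rejected), nrow(info$component_scores),
                paste(info$rejected, collapse = ", ")))
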