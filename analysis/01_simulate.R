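#!/usr/bin/env Rscript
# Stage 1: generate the synthetic walking-EEG study used by the rest of the
# workflow: a combined cortex+cerebellum head model, 500 strides of 19-channel
# EEG at 512 Hz with a cerebellar source active in the 25-75% gait phase,
# mains noise and eye blinks, plus heel-strike events and ground truth.
#
# Bulky binaries go to scratch/analysis/; small text summaries to results/.

library(gaitsource)

dir.create("scratch/analysis", recursive = TRUE, showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)

space <- build_source_space(n_cortex = 500, n_cerebellum = 100, seed = 1)
fwd <- leadfield_sphere(space, montage_1020())
saveRDS(fwd, "scratch/analysis/forward.rds")

cb <- which(space$surface == "cerebellum")
truth <- list(vertex_id = cb[10], region = space$region[cb[10]],
              active_quartiles = c("Q2", "Q3"), freq_hz = 10)
src <- do.call(planted_source, c(truth[c("vertex_id", "active_quartiles",
                                         "freq_hz")],
                                 list(waveform = "sinusoid")))

scenario <- sim_scenario(n_epochs = 500, stride_s = 1.1,
                         stride_jitter_frac = 0.05, rate = 512,
                         sources = list(src), snr = 0.5,
                         line_hz = 50, line_amp_uv = 20,
                         blink_rate_hz = 0.25, blink_amp_uv = 120, seed = 101)
events <- simulate_gait_events(scenario)
rec <- simulate_eeg(scenario, fwd, events)

write_eeg(rec, "scratch/analysis/walk.edf")
write_events(events, "scratch/analysis/events.tsv")
saveRDS(rec$eog, "scratch/analysis/eog.rds")
jsonlite::write_json(truth, "results/ground_truth.json", auto_unbox = TRUE)

message(sprintf("simulated %d strides, %.1f min of EEG at %g Hz; planted %s source at vertex %d",
                scenario$n_epochs, ncol(rec$data) / rec$rate / 60, rec$rate,
                truth$region, truth$vertex_id))
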