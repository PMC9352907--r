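#!/usr/bin/env Rscript
# Generate the synthetic photon streams used by the downstream stages:
# a full three-state reduced-WT acquisition and a two-state O1<->O2 stream
# for the filtered-FCS analysis. Streams are written in the plain-text
# photon container under results/ (large; regenerated on demand).

library(fretdyn)
dir.create("results", showWarnings = FALSE)

seed <- 1

# three-state reduced WT, ~10000 transits over 200 s
sch <- pdi_scheme("reduced")
mod <- molecule_model(sch)
acq <- acquisition_config(duration_s = 200)
stream3 <- simulate_experiment(mod, acq, n_bursts = 10000, seed = seed)
write_photon_stream(stream3, "results/stream_reduced_wt.csv")
cat("three-state stream:", nrow(stream3), "photons\n")

# two-state O1<->O2 exchange at the reduced WT rates, 60 s
k2 <- matrix(c(0, 8.49, 6.28, 0), 2, 2, byrow = TRUE)
sch2 <- kinetic_scheme(k2, c(80, 55), c(2.75, 0.91), c("O1", "O2"))
mod2 <- molecule_model(sch2, contaminant_fractions = c(0.05, 0.03))
acq2 <- acquisition_config(duration_s = 60)
stream2 <- simulate_experiment(mod2, acq2, n_bursts = 6000, seed = seed)
write_photon_stream(stream2, "results/stream_two_state.csv")
cat("two-state stream:", nrow(stream2), "photons\n")
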