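#!/usr/bin/env Rscript

# Stage 1 — simulate the drought-phenotyping screen.
#
# Generates a 151-accession experiment under the stop-watering protocol
# (watering to field capacity ~0.60, decay to below 0.20, one rewatering,
# measurements on 18/25/29/33/36/39/43/46 DAS, five plants per arm) and
# writes the plant/accession/climate/truth tables plus the configuration.

suppressMessages(library(droughtphen))

cfg <- simulation_config(n_accessions = 151, seed = 20240927)
sim <- simulate_experiment(cfg)

dir.create("results/data", showWarnings = FALSE, recursive = TRUE)
write_experiment(sim, "results/data", config = cfg)

viol <- validate_tables(sim$plants, sim$accessions, sim$climate)
cat(sprintf("simulated %d accessions: %d plant records, %d with climate data\n",
            cfg$n_accessions, nrow(sim$plants), nrow(sim$climate)))
cat(sprintf("validation violations: %d (expect 0)\n", nrow(viol)))
cat(sprintf("reflectance clipping events: %d\n", sum(sim$clipping$n_clipped)))

drt <- sim$plants[sim$plants$treatment == "drought" & sim$plants$rewatered, ]
cat("rewatering day distribution (final measurement):\n")
print(table(drt$das))
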