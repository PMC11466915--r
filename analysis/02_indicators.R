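#!/usr/bin/env Rscript

# Stage 2 — derive the five drought-resistance indicators per accession:
# biomass penalty, soil moisture at wilting (monotone WUE curve), at leaf
# desiccation (1528/1417 nm plateau junction), at chlorosis (NDVI plateau
# junction), and the pre-drought root/shoot ratio. Also checks recovery
# against the generator's ground truth.

suppressMessages(library(droughtphen))

plants <- read_plant_table("results/data/plants.csv")
accessions <- tibble::as_tibble(read.csv("results/data/accessions.csv"))
truth <- tibble::as_tibble(read.csv("results/data/truth.csv"))

ind <- build_indicator_table(plants, accessions)
write.csv(ind, "results/indicator_table.csv", row.names = FALSE)

desc <- descriptive_stats(ind)
write.csv(desc, "results/descriptive_stats.csv", row.names = FALSE)
cat("descriptive statistics (cf. a real screen's indicator table):\n")
print(as.data.frame(desc), digits = 3)

sp <- spearman_matrix(ind)
write.csv(cbind(indicator = rownames(sp$rho), as.data.frame(round(sp$rho, 3))),
          "results/spearman_rho.csv", row.names = FALSE)
cat("\nSpearman correlations (Bonferroni k = 10):\n")
print(sp)

tr <- truth[match(ind$accession_id, truth$accession_id), ]
rec <- function(est, tru, qc) {
  use <- !is.na(est) & !nzchar(qc)
  sprintf("n=%3d  median|err|=%.4f  bias=%+.4f", sum(use),
          median(abs(est[use] - tru[use])), mean(est[use] - tru[use]))
}
cat("\nground-truth recovery:\n")
cat(" wilting    ", rec(ind$wue_wilting_moisture, tr$theta_w, ind$qc_wue), "\n")
cat(" desiccation", rec(ind$rwc_desiccation_moisture, tr$theta_rwc, ind$qc_rwc), "\n")
cat(" chlorosis  ", rec(ind$ndvi_chlorosis_moisture, tr$theta_ndvi, ind$qc_ndvi), "\n")
cat(" penalty    ", rec(ind$biomass_penalty, tr$true_penalty, ind$qc_penalty), "\n")
cat(" root/shoot ", rec(ind$root_shoot_ratio, tr$true_root_shoot, ind$qc_root_shoot), "\n")

n_flag <- sum(nzchar(ind$qc_rwc) | nzchar(ind$qc_ndvi) | nzchar(ind$qc_wue))
cat(sprintf("\naccessions with at least one QC flag: %d of %d\n", n_flag, nrow(ind)))
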