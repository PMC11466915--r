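#!/usr/bin/env Rscript

# Stage 4 — group accessions by drought-response profile (Ward clustering on
# Manhattan distances, tree cut at five clusters chosen from the WSS scree),
# visualise the indicator space (covariance PCA, no rescaling), and relate
# drought resistance to site-of-origin climate (RDA, 999 permutations, plus
# the pairwise Pearson correlation table).

suppressMessages({
  library(droughtphen)
  library(ggplot2)
})

ind <- tibble::as_tibble(read.csv("results/indicator_table.csv"))
clim <- tibble::as_tibble(read.csv("results/data/climate.csv"))
dir.create("results/figures", showWarnings = FALSE, recursive = TRUE)

dmat <- manhattan_distances(ind)
tree <- ward_cluster(dmat)
cl <- cut_tree(tree, 5)
write.csv(data.frame(accession_id = names(cl), cluster = as.integer(cl)),
          "results/clusters.csv", row.names = FALSE)
cat("cluster sizes at k = 5:\n")
print(table(cl))

scree <- wss_scree(ind, 1:10)
write.csv(scree, "results/wss_scree.csv", row.names = FALSE)
ggsave("results/figures/wss_scree.png", width = 5, height = 3.5, dpi = 150,
       plot = ggplot(scree, aes(k, wss)) + geom_line() + geom_point() +
         geom_vline(xintercept = 5, linetype = 2) +
         labs(y = "within-cluster sum of squares") + theme_minimal())
png("results/figures/dendrogram.png", width = 1400, height = 600)
plot(tree, labels = FALSE, hang = -1, main = "Ward / Manhattan clustering")
rect.hclust(tree, k = 5)
dev.off()

pca <- pca_indicators(ind)
cat(sprintf("\nPCA: PC1 %.1f%%, PC2 %.1f%% of variance; Kaiser retains %d axes\n",
            100 * pca$variance_fraction[1], 100 * pca$variance_fraction[2],
            pca$kaiser_retained))
sc <- data.frame(pca$scores[, 1:2],
                 cluster = factor(cl[rownames(pca$scores)]))
ggsave("results/figures/pca_clusters.png", width = 6, height = 4.5, dpi = 150,
       plot = ggplot(sc, aes(PC1, PC2, colour = cluster)) + geom_point() +
         theme_minimal() + labs(title = "Accessions in indicator space"))

res <- rda_climate(ind, clim, n_perm = 999, seed = 20240928)
cat(sprintf("\nRDA on %d accessions with climate data:\n", res$n))
print(res)
write.csv(data.frame(axis = seq_along(res$eigenvalues),
                     eigenvalue = res$eigenvalues, p_axis = res$p_axes,
                     r2 = res$r2, adj_r2 = res$adj_r2, p_model = res$p_model),
          "results/rda_summary.csv", row.names = FALSE)

ct <- indicator_climate_correlations(ind, clim)
cat("\nindicator x climate Pearson correlations:\n")
print(ct)
write.csv(cbind(indicator = rownames(ct$r), as.data.frame(round(ct$r, 3))),
          "results/climate_correlations.csv", row.names = FALSE)

sig <- which(ct$p[, "annual_precipitation"] < 0.05)
cat(sprintf("\nindicators significantly related to annual precipitation: %s\n",
            paste(rownames(ct$r)[sig], collapse = ", ")))
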