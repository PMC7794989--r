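#!/usr/bin/env Rscript

# Step 2 — normalize and cluster the pooled steady states into phenotypes.
#
# Each replicate's solutions are normalized gene-wise (z of log2 levels
# against the replicate's own pool), partitioned by k-means on the four core
# nodes (miR-200, ZEB, LIN28, let-7), and labeled e / he / hm / m by
# ascending cluster-median ZEB. Cluster-count quality metrics and the PCA
# summary are written alongside. Outputs, under results/:
#   base_solutions_labeled.csv  z-scored solutions with phenotype labels
#   base_cluster_quality.csv    silhouette/CH/DB/inertia per k per replicate
#   base_pca.csv                PC variance fractions per replicate
#   base_phase_frequencies.csv  phase composition by multistability class

library(empstem)

sol <- read.csv("results/base_solutions.csv")
nodes <- c("miR200", "ZEB", "SNAIL", "LIN28", "let7", "NFkB")

labeled <- list(); quality <- list(); pca <- list(); phases <- list()
for (r in sort(unique(sol$replicate))) {
  raw <- sol[sol$replicate == r, ]
  z <- normalize_solutions(raw, normalization_stats(raw, nodes))
  asg <- kmeans_phenotypes(z, k = 4, restarts = 10, seed = 1 + 7919 * r)
  z$label <- asg$labels
  labeled[[r]] <- z
  q <- cluster_quality_sweep(z, k_range = 2:8, restarts = 10, seed = 1 + r)
  quality[[r]] <- cbind(replicate = r, q)
  p <- pca_summary(z)
  pca[[r]] <- data.frame(replicate = r, component = names(p$variance_fraction),
                         variance_fraction = unname(p$variance_fraction))
  ph <- label_phases(z$label, z$model_id, z$n_states)
  phases[[r]] <- cbind(replicate = r, ph$frequencies)
}

write.csv(do.call(rbind, labeled), "results/base_solutions_labeled.csv",
          row.names = FALSE)
write.csv(do.call(rbind, quality), "results/base_cluster_quality.csv",
          row.names = FALSE)
write.csv(do.call(rbind, pca), "results/base_pca.csv", row.names = FALSE)
write.csv(do.call(rbind, phases), "results/base_phase_frequencies.csv",
          row.names = FALSE)

q <- do.call(rbind, quality)
sil <- tapply(q$silhouette, q$k, mean)
cat("Average silhouette width by k (mean across replicates):\n")
print(round(sil, 3))
cat("Peak at k =", names(which.max(sil)), "\n")
pcv <- do.call(rbind, pca)
cat("PC1/PC2 variance (%, mean):",
    round(100 * mean(pcv$variance_fraction[pcv$component == "PC1"]), 1), "/",
    round(100 * mean(pcv$variance_fraction[pcv$component == "PC2"]), 1), "\n")
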