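#!/usr/bin/env Rscript
# Stage 6: accession-level cohort analysis.
#
# Assembles the 16-variable trait matrix (accession means, z-scored),
# clusters it by k-means over 10,000 random centre sets (k = 3 as the
# configured input; a silhouette diagnostic is emitted but never selects),
# projects onto the first two principal components with a loadings table
# ordered by |PC1|, and runs per-level ANOVA with Benjamini-Hochberg
# correction plus trait-trait correlations.

suppressPackageStartupMessages(library(vpdresponse))

ss <- utils::read.csv("results/steady_state.csv", stringsAsFactors = FALSE)
pe <- utils::read.csv("results/phi_e_leaf.csv", stringsAsFactors = FALSE)
al <- utils::read.csv("results/a_limitation.csv", stringsAsFactors = FALSE)
st <- utils::read.csv("results/stomatal_reduction.csv", stringsAsFactors = FALSE)
pw <- utils::read.csv("results/phi_e_whole_plant.csv", stringsAsFactors = FALSE)
fits <- utils::read.csv("results/segmented_fits.csv", stringsAsFactors = FALSE)
seg_leaf <- fits[fits$measurement_level == "leaf", ]
seg_wp <- fits[fits$measurement_level == "whole_plant", ]

tm <- build_trait_matrix(al, pe, pw, seg_leaf, seg_wp, st)
write_output_table(data.frame(accession = rownames(tm), tm,
                              check.names = FALSE),
                   "results/trait_matrix.csv")

km <- kmeans_cluster(tm, k = 3, n_restarts = 10000, seed = 20230821)
sil <- silhouette_by_k(tm, ks = 2:5, n_restarts = 200, seed = 20230821)
pc <- pca_project(tm)
write_output_table(pc$loadings_table, "results/pca_loadings.csv")
write_output_table(sil, "results/silhouette_by_k.csv")
jsonlite::write_json(
  list(k = km$k, n_restarts = km$n_restarts,
       tot_withinss = km$tot_withinss,
       assignments = as.list(km$cluster),
       var_explained_pc12 = pc$var_explained[1:2]),
  "results/clusters.json", auto_unbox = TRUE, digits = NA, pretty = TRUE
)

cat("cluster assignments:\n"); print(km$cluster)
cat(sprintf("within-SS %.3f over %d restarts (%d discarded)\n",
            km$tot_withinss, km$n_restarts, km$n_discarded))
cat(sprintf("PC1/PC2 explain %.0f%% / %.0f%% of trait variance\n",
            100 * pc$var_explained[1], 100 * pc$var_explained[2]))
cat("top PC1 loadings:\n")
print(head(within(pc$loadings_table,
                  { PC1 <- round(PC1, 2); PC2 <- round(PC2, 2) }), 6),
      row.names = FALSE)
cat("silhouette diagnostic (k never auto-selected):\n")
print(sil, row.names = FALSE)

# per-level accession ANOVA on steady-state gs and E, BH within family
gs_aov <- anova_bh(data.frame(accession = ss$accession, level = ss$level,
                              value = ss$gs))
e_aov <- anova_bh(data.frame(accession = ss$accession, level = ss$level,
                             value = ss$E))
gs_aov$response <- "gs"; e_aov$response <- "E"
write_output_table(rbind(gs_aov, e_aov), "results/anova_bh.csv")
cat(sprintf("ANOVA: accession differences significant (BH p < 0.05) at %d/%d gs levels, %d/%d E levels\n",
            sum(gs_aov$p_adjusted < 0.05), nrow(gs_aov),
            sum(e_aov$p_adjusted < 0.05), nrow(e_aov)))

# trait-trait correlations over accessions
pe_top <- tapply(pe$phi_e[pe$level == max(pe$level)],
                 pe$accession[pe$level == max(pe$level)], mean)
al_top <- al$limitation[al$level == max(al$level)][
  match(names(pe_top), al$accession[al$level == max(al$level)])]
psi_leaf <- seg_leaf$psi[match(names(pe_top), seg_leaf$accession)]
pairs <- list(
  c("phi_e_leaf_top", "a_limitation_top"),
  c("phi_e_leaf_top", "breakpoint_leaf"),
  c("a_limitation_top", "breakpoint_leaf")
)
vals <- list(phi_e_leaf_top = as.numeric(pe_top),
             a_limitation_top = as.numeric(al_top),
             breakpoint_leaf = psi_leaf)
cors <- do.call(rbind, lapply(pairs, function(p) {
  r <- correlation_r2(vals[[p[1]]], vals[[p[2]]])
  data.frame(x = p[1], y = p[2], r_squared = r$r_squared, p_value = r$p_value,
             n = r$n)
}))
write_output_table(cors, "results/correlations.csv")
cat("trait-trait R2 across accessions:\n")
print(within(cors, { r_squared <- round(r_squared, 2)
                     p_value <- signif(p_value, 2) }), row.names = FALSE)

# figures: clusters on PC1/PC2, breakpoint vs slopes
dir.create("results/figures", showWarnings = FALSE, recursive = TRUE)
grDevices::pdf("results/figures/clusters_pca.pdf", width = 6, height = 5)
plot(pc$scores[, 1], pc$scores[, 2], pch = 19, col = km$cluster + 1,
     xlab = sprintf("PC1 (%.0f%%)", 100 * pc$var_explained[1]),
     ylab = sprintf("PC2 (%.0f%%)", 100 * pc$var_explained[2]),
     main = "Phenotypic groups on the first two principal components")
text(pc$scores[, 1], pc$scores[, 2], rownames(tm), pos = 3, cex = 0.7)
grDevices::dev.off()
grDevices::pdf("results/figures/breakpoints_slopes.pdf", width = 9, height = 4.5)
op <- par(mfrow = c(1, 2))
for (sl in c("slope_before", "slope_after")) {
  plot(fits$psi[fits$measurement_level == "leaf"],
       fits[[sl]][fits$measurement_level == "leaf"],
       pch = 19, col = km$cluster + 1,
       xlab = "breakpoint (kPa)", ylab = gsub("_", " ", sl),
       main = sprintf("Leaf: %s vs breakpoint", gsub("_", " ", sl)))
}
par(op); grDevices::dev.off()
cat("wrote results/trait_matrix.csv, clusters.json, pca_loadings.csv, anova_bh.csv, correlations.csv, figures/\n")
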