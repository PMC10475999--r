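#!/usr/bin/env Rscript
# Stage 7: validate the pipeline against the generative ground truth.
#
# Because the cohort is synthetic, every estimate can be compared with the
# parameter that generated it: breakpoints and slopes at both measurement
# levels, the stomatal reduction, and the cluster partition (compared label
# invariantly through the adjusted Rand index).

suppressPackageStartupMessages(library(vpdresponse))

truth <- jsonlite::read_json("scratch/cohort/truth.json", simplifyVector = TRUE)
fits <- utils::read.csv("results/segmented_fits.csv", stringsAsFactors = FALSE)
st <- utils::read.csv("results/stomatal_reduction.csv", stringsAsFactors = FALSE)
cl <- jsonlite::read_json("results/clusters.json", simplifyVector = TRUE)

clusters <- structure(list(cluster = unlist(cl$assignments)),
                      class = "kmeans_restarts")
report <- ground_truth_check(
  truth,
  seg_leaf = fits[fits$measurement_level == "leaf", ],
  seg_wp = fits[fits$measurement_level == "whole_plant", ],
  stom = st, clusters = clusters,
  tol = list(psi = 0.15, slope = 0.3, phi_stom = 0.05)
)
write_output_table(report, "results/ground_truth_report.csv")

cat(sprintf("ground-truth checks: %d/%d pass\n", sum(report$pass), nrow(report)))
if (!all(report$pass)) print(report[!report$pass, ], row.names = FALSE)
ari <- report$estimate[report$check == "cluster_ari"]
cat(sprintf("cluster recovery (adjusted Rand index): %.3f\n", ari))
cat("wrote results/ground_truth_report.csv\n")
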