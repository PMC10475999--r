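#!/usr/bin/env Rscript
# Stage 3: leaf-level response statistics.
#
# From the steady-state table: transpiration reduction phi_E (two-point
# baseline through the lowest two leaf-VPD levels extrapolated to the three
# highest), photosynthetic limitation per accession and level, and the
# stomatal reduction phi_stom (absolute slope of gs on log leaf VPD) per
# plant, with its relation to the maximum observed gs.

suppressPackageStartupMessages(library(vpdresponse))

ss <- utils::read.csv("results/steady_state.csv", stringsAsFactors = FALSE)

pe <- phi_e(ss)
al <- limitation_of_a(ss)
st <- stomatal_reduction(ss)
write_output_table(pe, "results/phi_e_leaf.csv")
write_output_table(al, "results/a_limitation.csv")
write_output_table(st, "results/stomatal_reduction.csv")

top <- accession_means(pe[pe$level == max(pe$level), ], "phi_e")
cat("phi_E at the highest leaf VPD level (accession mean +/- se):\n")
print(within(top, { mean <- round(mean, 3); se <- round(se, 3) }),
      row.names = FALSE)
lim_top <- al[al$level == max(al$level), ]
cat(sprintf("limitation of A at the top level: %.1f-%.1f%%\n",
            100 * min(lim_top$limitation), 100 * max(lim_top$limitation)))

mg <- max_gs_table(ss)
r2 <- correlation_r2(tapply(st$phi_stom, st$accession, mean),
                     tapply(mg$max_gs, mg$accession, mean))
cat(sprintf("phi_stom vs max gs across accessions: R2 = %.2f (p = %.3g)\n",
            r2$r_squared, r2$p_value))
cat("wrote results/phi_e_leaf.csv, results/a_limitation.csv, results/stomatal_reduction.csv\n")
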