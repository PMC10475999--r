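#!/usr/bin/env Rscript
# Stage 4: gravimetric whole-plant transpiration.
#
# Differentiates 5-min average balance mass between the start and end of
# each chamber-VPD step, normalizes by leaf area, converts to molar units,
# and computes the whole-plant transpiration reduction at the highest step.

suppressPackageStartupMessages(library(vpdresponse))

raw <- "scratch/cohort"
areas <- utils::read.csv(file.path(raw, "leaf_areas.csv"),
                         stringsAsFactors = FALSE)
bal <- read_balance(file.path(raw, "balance.csv"), areas)
design_chamber <- read_step_design(file.path(raw, "design_chamber.csv"))

wp <- whole_plant_rate_table(bal, design_chamber)
pw <- phi_e_whole_plant(wp)
write_output_table(wp, "results/whole_plant_rates.csv")
write_output_table(pw, "results/phi_e_whole_plant.csv")

ok <- !wp$missing
lo <- wp$level == 1; hi <- wp$level == max(wp$level)
incr <- tapply(wp$e_rate[ok & hi], wp$accession[ok & hi], mean) /
  tapply(wp$e_rate[ok & lo], wp$accession[ok & lo], mean) - 1
cat(sprintf("whole-plant E increase from first to last VPD step: %.0f-%.0f%%\n",
            100 * min(incr), 100 * max(incr)))
cat("whole-plant phi_E at the top step (accession mean +/- se):\n")
pm <- accession_means(pw, "phi_e")
print(within(pm, { mean <- round(mean, 3); se <- round(se, 3) }),
      row.names = FALSE)
cat("wrote results/whole_plant_rates.csv, results/phi_e_whole_plant.csv\n")
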