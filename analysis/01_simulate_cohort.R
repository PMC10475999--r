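#!/usr/bin/env Rscript
# Stage 1: simulate the study cohort.
#
# Generates a synthetic cohort emulating the step-change VPD experiment:
# 9 accessions in three response archetypes (1 conservative early limiter,
# 2 high-flux shutdown types, 6 risk takers), 5 plants each, leaf
# gas-exchange records every 60 s over six leaf-VPD levels and balance
# records every 10 s over five chamber-VPD levels. Raw traces are large and
# go under scratch/; everything downstream reads them back through the
# ingest layer exactly as instrument exports would be read.

suppressPackageStartupMessages(library(vpdresponse))

out_dir <- "scratch/cohort"
cfg <- cohort_config(seed = 20230821)
cohort <- generate_cohort(cfg)
write_cohort(cohort, out_dir)

cat(sprintf("simulated %d accessions / %d plants\n",
            nrow(cohort$truth$accessions), nrow(cohort$truth$plants)))
cat(sprintf("gas-exchange records: %d; balance records: %d\n",
            nrow(cohort$gas_exchange), nrow(cohort$balance)))
cat(sprintf("leaf VPD levels (kPa): %s\n",
            paste(cfg$leaf_levels, collapse = ", ")))
cat(sprintf("chamber VPD levels (kPa): %s\n",
            paste(cfg$chamber_levels, collapse = ", ")))
cat("wrote", out_dir, "\n")
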