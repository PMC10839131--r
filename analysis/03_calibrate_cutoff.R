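#!/usr/bin/env Rscript
# Stage 3: calibrate the MSLC-vs-IPM decision cutoff.
#
# Positive (clonally related) pairs are built by drawing 40%, 60% and 80%
# of each reference sample's mutations twice with replacement; negative
# (unrelated) pairs are whole mutation sets of two distinct samples. One
# repetition scores all 1515 + 1515 pairs with the clonality index and
# takes the accuracy-optimal cutoff; 100 repetitions give the median cutoff
# and its 95% percentile interval.

suppressPackageStartupMessages(library(clonalCI))

seed <- 20240901L
reference <- read_maf("results/data/reference.maf")
catalog <- read_catalog("results/catalog.tsv")
sets <- mutation_sets(reference)

cal <- calibrate(sets, catalog, proportions = c(0.4, 0.6, 0.8),
                 reps = 100L, seed = seed)
write_calibration(cal, "results/calibration.json")
print(cal)

message(sprintf(
  "cutoff spread across repetitions: min %.2f / median %.2f / max %.2f",
  min(cal$per_rep$cutoff), cal$median_cutoff, max(cal$per_rep$cutoff)))
message("wrote results/calibration.json")
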