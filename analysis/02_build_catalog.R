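#!/usr/bin/env Rscript
# Stage 2: estimate the cohort prevalence catalog.
#
# Every mutation key observed in the reference cohort gets a prevalence
# p = carriers / N (sample-fraction estimator); unseen keys will later be
# served the smoothing floor 1/(N+1). The catalog is the null model behind
# the clonality index: a shared mutation contributes -log10 C(2,2) p^2.

suppressPackageStartupMessages(library(clonalCI))

reference <- read_maf("results/data/reference.maf")
catalog <- build_catalog(reference)
write_catalog(catalog, "results/catalog.tsv")
print(catalog)

counts <- sort(catalog$counts, decreasing = TRUE)
message("most prevalent keys (these are the coincidental-sharing risks):")
top <- utils::head(counts, 8)
for (i in seq_along(top)) {
  message(sprintf("  %-24s %3d / %d  (p = %.3f, single-share CI = %.2f)",
                  names(top)[i], top[i], catalog$cohort_size,
                  top[i] / catalog$cohort_size,
                  -2 * log10(top[i] / catalog$cohort_size)))
}
message("singleton keys: ", sum(counts == 1L), " of ", length(counts),
        " (single-share CI = ",
        sprintf("%.2f", -2 * log10(1 / catalog$cohort_size)), ")")
message("wrote results/catalog.tsv")
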