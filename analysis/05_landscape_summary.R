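#!/usr/bin/env Rscript
# Stage 5: mutational-landscape summary of the study cohort.
#
# Tumor-level gene recurrence, named driver-allele breakdown (L858R,
# exon 19 deletions, G12x, ...), driver co-occurrence, and per-sample
# mutation burden over the panel footprint.

suppressPackageStartupMessages(library(clonalCI))

lesion_rec <- read_maf("results/data/lesions.maf")
ls <- summarize_landscape(lesion_rec, panel_mb = 2.2)
paths <- write_landscape(ls, "results/landscape")
print(ls)

message("driver allele breakdown:")
ab <- ls$allele_breakdown
for (i in seq_len(nrow(ab))) {
  message(sprintf("  %-6s %-10s %d tumors", ab$gene[i], ab$allele_class[i],
                  ab$n_tumors[i]))
}
viol <- check_driver_exclusivity(ls, lesion_rec)
message("tumors violating EGFR/KRAS/BRAF/ERBB2/MET exclusivity: ",
        if (length(viol)) paste(viol, collapse = ", ") else "none")
message(sprintf("TMB: median %.2f /Mb (range %.2f-%.2f)",
                median(ls$tmb), min(ls$tmb), max(ls$tmb)))
message("wrote ", paste(paths, collapse = ", "))
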