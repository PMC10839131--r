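#!/usr/bin/env Rscript
# Stage 1: generate the study inputs.
#
# No patient-level data are redistributable for this analysis, so the whole
# workflow runs on a seeded synthetic stand-in: a 505-sample reference
# cohort with a hotspot-skewed prevalence spectrum (the catalog/calibration
# cohort) and a 200-patient paired-lesion study cohort with known MSLC/IPM
# ground truth. Everything downstream reads only the files written here.

suppressPackageStartupMessages(library(clonalCI))

out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 20240901L

tm <- reference_spec(n_samples = 505L, seed = seed)
ref <- generate_reference(tm)
write_maf(ref$records, file.path(out, "reference.maf"))
write.table(ref$truth_prevalence, file.path(out, "reference_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

coh <- generate_paired_cohort(
  paired_cohort_spec(n_patients = 200L, seed = seed + 1L),
  tumor_model = tm)
write_maf(coh$records, file.path(out, "lesions.maf"))
write.table(coh$manifest, file.path(out, "manifest.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(coh$truth, file.path(out, "truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

message("reference: ", length(unique(ref$records$sample_id)), " samples, ",
        nrow(ref$records), " mutation rows")
message("hotspot prevalences (target -> realized):")
for (i in seq_len(nrow(ref$truth_prevalence))) {
  message(sprintf("  %-24s %.3f -> %.3f", ref$truth_prevalence$key[i],
                  ref$truth_prevalence$target_prevalence[i],
                  ref$truth_prevalence$realized_prevalence[i]))
}
message("study cohort: ", nrow(coh$manifest), " patients (",
        sum(coh$truth$true_class == "IPM"), " IPM / ",
        sum(coh$truth$true_class == "MSLC"), " MSLC by truth)")
message("wrote ", out, "/{reference.maf,lesions.maf,manifest.tsv,truth.tsv}")
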