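# In-code fixtures shared across the suite. All files are written to
# tempdir() at test time.

toy_maf_lines <- function() {
  c(paste("Tumor_Sample_Barcode", "Hugo_Symbol", "Chromosome",
          "Start_Position", "Reference_Allele", "Tumor_Seq_Allele2",
          "HGVSp_Short", "Variant_Classification", sep = "\t"),
    "S1\tEGFR\tchr7\t55259515\tT\tG\tp.L858R\tMissense_Mutation",
    "S1\tTP53\tchr17\t7578406\tC\tT\tp.R175H\tMissense_Mutation",
    "S2\tKRAS\tchr12\t25398285\tC\tA\tp.G12C\tMissense_Mutation")
}

write_toy_maf <- function(lines = toy_maf_lines()) {
  path <- tempfile(fileext = ".maf")
  writeLines(lines, path)
  path
}

toy_vcf_lines <- function() {
  c("##fileformat=VCFv4.2",
    "##contig=<ID=chr7>",
    "##contig=<ID=chr12>",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr7\t55259515\t.\tT\tG\t60\tPASS\t.",
    "chr12\t25398285\t.\tC\tA\t60\tPASS\t.",
    "chr7\t140453136\t.\tA\tT\t10\tq10\t.",
    "chr17\t7578406\t.\tC\tT,G\t50\tPASS\t.")
}

write_toy_vcf <- function(lines = toy_vcf_lines()) {
  path <- tempfile(fileext = ".vcf")
  writeLines(lines, path)
  path
}

# Catalog with known prevalences: key -> count among n samples, plus floor.
fixed_catalog <- function(counts, n_samples,
                          mode = "sample_fraction", floor = NULL) {
  recs <- do.call(rbind, lapply(names(counts), function(key) {
    parts <- strsplit(key, ":", fixed = TRUE)[[1]]
    mutation_records(sample_id = paste0("S", seq_len(counts[[key]])),
                     chrom = parts[1], pos = as.integer(parts[2]),
                     ref_allele = parts[3], alt_allele = parts[4],
                     variant_class = "missense")
  }))
  # pad cohort to n_samples with unique filler mutations
  have <- max(c(0L, counts))
  if (n_samples > have) {
    extra <- mutation_records(
      sample_id = paste0("S", seq_len(n_samples)),
      chrom = "chrF", pos = 1000L + seq_len(n_samples),
      ref_allele = "A", alt_allele = "C", variant_class = "missense")
    recs <- rbind(recs, extra)
  }
  build_catalog(recs, prevalence_mode = mode, smoothing_floor = floor)
}

# Brute-force oracle for the accuracy-optimal threshold: evaluate accuracy
# at every candidate cutoff (midpoints + sentinels) with naive counting.
brute_force_cutoff <- function(pos, neg) {
  u <- sort(unique(c(pos, neg)))
  cand <- c(u[1] - 1, if (length(u) > 1) (u[-length(u)] + u[-1]) / 2,
            u[length(u)] + 1)
  acc <- vapply(cand, function(c) {
    (sum(pos > c) + sum(neg <= c)) / (length(pos) + length(neg))
  }, numeric(1))
  best <- max(which(acc == max(acc)))
  list(cutoff = cand[best], accuracy = acc[best],
       sensitivity = sum(pos > cand[best]) / length(pos),
       specificity = sum(neg <= cand[best]) / length(neg))
}

# Small reference cohort as per-sample key sets with controllable sizes.
random_key_sets <- function(n_samples, mean_keys, seed, universe = 5000L) {
  set.seed(seed)
  stats::setNames(lapply(seq_len(n_samples), function(i) {
    n <- max(1L, stats::rpois(1L, mean_keys))
    paste0("chrS:", unique(sample.int(universe, n, replace = TRUE)), ":A:G")
  }), paste0("S", seq_len(n_samples)))
}
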