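test_that("read_maf reads complete rows and reports dropped ones", {
  path <- write_toy_maf()
  rec <- read_maf(path)
  expect_equal(nrow(rec), 3L)
  expect_equal(attr(rec, "load_report")$n_dropped, 0L)
  expect_equal(rec$gene, c("EGFR", "TP53", "KRAS"))
  expect_equal(rec$variant_class, rep("missense", 3))

  # a row with neither coordinates nor gene+protein identity is dropped
  lines <- c(toy_maf_lines(), "S3\t\t\t\t\t\t\tMissense_Mutation")
  rec2 <- read_maf(write_toy_maf(lines))
  expect_equal(nrow(rec2), 3L)
  expect_equal(attr(rec2, "load_report")$n_dropped, 1L)
})

test_that("read_maf errors name missing required columns, warns on empty", {
  lines <- toy_maf_lines()
  lines[1] <- sub("Reference_Allele", "RefX", lines[1])
  expect_error(read_maf(write_toy_maf(lines)), "Reference_Allele")
  expect_warning(rec <- read_maf(write_toy_maf(toy_maf_lines()[1])), "empty")
  expect_equal(nrow(rec), 0L)
})

test_that("duplicated MAF rows survive reading but collapse in the key set", {
  lines <- c(toy_maf_lines(),
             "S1\tEGFR\tchr7\t55259515\tT\tG\tp.L858R\tMissense_Mutation")
  rec <- read_maf(write_toy_maf(lines))
  expect_equal(sum(rec$sample_id == "S1"), 3L)
  expect_equal(length(mutation_set(rec, "S1")), 2L)
})

test_that("MAF round-trip preserves the multiset of (sample, key) pairs", {
  ref <- generate_reference(reference_spec(n_samples = 8, seed = 11))
  path <- tempfile(fileext = ".maf")
  write_maf(ref$records, path)
  back <- read_maf(path)
  orig <- sort(paste(ref$records$sample_id, mutation_keys(ref$records)))
  rt <- sort(paste(back$sample_id, mutation_keys(back)))
  expect_identical(rt, orig)
})

test_that("VCF ingestion keeps PASS records and expands multi-allelic sites", {
  rec <- read_vcf_as_records(write_toy_vcf(), sample_id = "L1")
  # 2 PASS SNVs + 1 biallelic split into 2 records; q10 record skipped
  expect_equal(nrow(rec), 4L)
  expect_true(all(rec$sample_id == "L1"))
  expect_equal(sum(rec$chrom == "chr17"), 2L)
  expect_setequal(rec$alt_allele[rec$chrom == "chr17"], c("T", "G"))
  expect_false(any(rec$pos == 140453136))
})

test_that("MAF- and VCF-style spellings of one indel share a genomic key", {
  # deletion: VCF anchors with the preceding base, MAF drops it
  vcf_style <- mutation_records("a", chrom = "chr7", pos = 55242464,
                                ref_allele = "AGGAATT", alt_allele = "A")
  maf_style <- mutation_records("b", chrom = "chr7", pos = 55242465,
                                ref_allele = "GGAATT", alt_allele = "-")
  expect_identical(mutation_keys(vcf_style), mutation_keys(maf_style))
  # case-insensitive alleles
  expect_identical(
    mutation_keys(mutation_records("a", chrom = "1", pos = 5,
                                   ref_allele = "a", alt_allele = "g")),
    mutation_keys(mutation_records("b", chrom = "1", pos = 5,
                                   ref_allele = "A", alt_allele = "G")))
})

test_that("keying is idempotent and falls back between modes", {
  rec <- mutation_records("s", gene = "EGFR", chrom = "chr7", pos = 55259515,
                          ref_allele = "T", alt_allele = "G",
                          protein_change = "p.L858R",
                          variant_class = "missense")
  expect_equal(mutation_keys(rec, "genomic"), "chr7:55259515:T:G")
  expect_equal(mutation_keys(rec, "protein"), "EGFR:p.L858R")
  # same record keyed twice gives the same key
  expect_identical(mutation_keys(rec), mutation_keys(rec))
  # no coordinates -> genomic mode falls back to the protein key
  rec2 <- mutation_records("s", gene = "EGFR", protein_change = "p.L858R",
                           variant_class = "missense")
  expect_equal(mutation_keys(rec2, "genomic"), "EGFR:p.L858R")
  # fusions/amplifications key as gene:event_class in both modes
  fus <- mutation_records("s", gene = "ALK", variant_class = "fusion")
  expect_equal(mutation_keys(fus, "genomic"), "ALK:fusion")
  expect_equal(mutation_keys(fus, "protein"), "ALK:fusion")
})

test_that("mutation_set applies set semantics and the synonymous policy", {
  rec <- rbind(
    mutation_records("s", chrom = "1", pos = 1, ref_allele = "A",
                     alt_allele = "G", variant_class = "missense"),
    mutation_records("s", chrom = "1", pos = 1, ref_allele = "A",
                     alt_allele = "G", variant_class = "missense"),
    mutation_records("s", chrom = "1", pos = 9, ref_allele = "C",
                     alt_allele = "T", variant_class = "synonymous"))
  expect_equal(length(mutation_set(rec, "s", include_synonymous = FALSE)), 1L)
  expect_equal(length(mutation_set(rec, "s", include_synonymous = TRUE)), 2L)
  expect_lte(length(mutation_set(rec, "s")), nrow(rec))
})

test_that("manifest reader enforces the two-lesion contract", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("patient_id\tlesion1_sample\tlesion2_sample",
               "P1\tP1_L1\tP1_L2", "P2\tP2_L1\tP2_L2"), path)
  m <- read_manifest(path)
  expect_equal(nrow(m), 2L)
  writeLines(c("patient_id\tlesion1_sample\tlesion2_sample",
               "P1\tP1_L1\tP1_L1"), path)
  expect_error(read_manifest(path), "same sample")
  writeLines(c("patient_id\tlesion1_sample", "P1\tP1_L1"), path)
  expect_error(read_manifest(path), "lesion2_sample")
})
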