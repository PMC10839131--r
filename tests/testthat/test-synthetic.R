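test_that("identical specs generate byte-identical cohorts", {
  spec <- reference_spec(n_samples = 20, seed = 41)
  r1 <- generate_reference(spec)
  r2 <- generate_reference(spec)
  expect_identical(r1$records, r2$records)
  expect_identical(r1$truth_prevalence, r2$truth_prevalence)

  cspec <- paired_cohort_spec(n_patients = 15, seed = 42)
  c1 <- generate_paired_cohort(cspec, tumor_model = spec)
  c2 <- generate_paired_cohort(cspec, tumor_model = spec)
  expect_identical(c1$records, c2$records)
  expect_identical(c1$truth, c2$truth)
})

test_that("realized hotspot carrier counts sit in the binomial 99% band", {
  n <- 400L
  hs <- data.frame(gene = "EGFR", chrom = "chr7", pos = 55259515L,
                   ref_allele = "T", alt_allele = "G",
                   protein_change = "p.L858R", variant_class = "missense",
                   prevalence = 0.3, stringsAsFactors = FALSE)
  ref <- generate_reference(reference_spec(n_samples = n, hotspots = hs,
                                           seed = 7))
  carriers <- ref$truth_prevalence$realized_prevalence * n
  band <- stats::qbinom(c(0.005, 0.995), n, 0.3)
  expect_gte(carriers, band[1])
  expect_lte(carriers, band[2])
})

test_that("a huge passenger universe makes cross-sample collisions rare", {
  # 2 samples, ~20 passengers each from a 1e6 universe: the expected number
  # of shared passenger keys is ~ 20*20/1e6 = 4e-4, so over 30 seeded
  # replicates we should see essentially none.
  shared <- vapply(1:30, function(s) {
    ref <- generate_reference(reference_spec(
      n_samples = 2, passenger_universe_size = 1000000L, seed = 100 + s))
    sets <- mutation_sets(ref$records)
    syn_a <- grep("^chr7:55|^chr12:25|^chr17:7|^chr7:140", sets[[1]],
                  invert = TRUE, value = TRUE)
    syn_b <- grep("^chr7:55|^chr12:25|^chr17:7|^chr7:140", sets[[2]],
                  invert = TRUE, value = TRUE)
    length(intersect(syn_a, syn_b))
  }, integer(1))
  expect_lte(sum(shared), 1L)
})

test_that("every reference sample is non-empty and MAF-readable", {
  ref <- generate_reference(reference_spec(n_samples = 25, seed = 3))
  sets <- mutation_sets(ref$records)
  expect_length(sets, 25L)
  expect_true(all(lengths(sets) >= 1L))
  path <- tempfile(fileext = ".maf")
  write_maf(ref$records, path)
  back <- read_maf(path)
  expect_equal(attr(back, "load_report")$n_dropped, 0L)
  expect_equal(nrow(back), nrow(ref$records))
})

test_that("ipm_fraction = 0 yields an all-MSLC truth table", {
  coh <- generate_paired_cohort(paired_cohort_spec(n_patients = 12,
                                                   ipm_fraction = 0,
                                                   seed = 5),
                                tumor_model = reference_spec(n_samples = 10,
                                                             seed = 5))
  expect_true(all(coh$truth$true_class == "MSLC"))
  expect_equal(nrow(coh$manifest), 12L)
  # manifest + records + truth are mutually consistent
  expect_setequal(unique(coh$records$sample_id),
                  c(coh$manifest$lesion1_sample, coh$manifest$lesion2_sample))
  expect_identical(coh$truth$patient_id, coh$manifest$patient_id)
})

test_that("no forced sharing and a huge universe put ~all MSLC in group 3", {
  tm <- reference_spec(n_samples = 10, passenger_universe_size = 1000000L,
                       hotspots = data.frame(
                         gene = "EGFR", chrom = "chr7", pos = 55259515L,
                         ref_allele = "T", alt_allele = "G",
                         protein_change = "p.L858R",
                         variant_class = "missense", prevalence = 0.005,
                         stringsAsFactors = FALSE),
                       seed = 11)
  coh <- generate_paired_cohort(paired_cohort_spec(n_patients = 40,
                                                   ipm_fraction = 0,
                                                   driver_sharing_prob = 0,
                                                   seed = 11),
                                tumor_model = tm)
  sets <- mutation_sets(coh$records,
                        sample_ids = c(coh$manifest$lesion1_sample,
                                       coh$manifest$lesion2_sample))
  groups <- vapply(seq_len(nrow(coh$manifest)), function(i) {
    assign_group(sets[[coh$manifest$lesion1_sample[i]]],
                 sets[[coh$manifest$lesion2_sample[i]]])
  }, integer(1))
  # hotspot prevalence 0.005 makes coincidental sharing ~ (0.005)^2; allow
  # at most one such pair in 40
  expect_gte(sum(groups == 3L), 39L)
})

test_that("IPM lesions subsample one parent at the requested overlap", {
  tm <- reference_spec(n_samples = 10, seed = 19)
  coh <- generate_paired_cohort(paired_cohort_spec(n_patients = 10,
                                                   ipm_fraction = 1,
                                                   clonal_overlap_range =
                                                     c(0.6, 0.6),
                                                   seed = 19),
                                tumor_model = tm)
  expect_true(all(coh$truth$true_class == "IPM"))
  expect_true(all(abs(coh$truth$overlap - 0.6) < 1e-12))
  sets <- mutation_sets(coh$records,
                        sample_ids = c(coh$manifest$lesion1_sample,
                                       coh$manifest$lesion2_sample))
  for (i in seq_len(nrow(coh$manifest))) {
    a <- sets[[coh$manifest$lesion1_sample[i]]]
    b <- sets[[coh$manifest$lesion2_sample[i]]]
    # both lesions subsample the same parent, so they overlap
    expect_gte(length(intersect(a, b)), 0L)
    expect_true(length(a) >= 1L && length(b) >= 1L)
  }
})
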