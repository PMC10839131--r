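make_calibration <- function(cutoff = 7.77, hi = 7.97) {
  structure(list(median_cutoff = cutoff,
                 cutoff_ci95 = c(low = cutoff - 0.14, high = hi),
                 median_accuracy = 0.96),
            class = "calibration_result")
}

test_that("patients are grouped by lesion emptiness and sharing", {
  kg <- c("EGFR:p.L858R" = "EGFR", "EGFR:p.E746_A750del" = "EGFR",
          "KRAS:p.G12D" = "KRAS", "SYN:1:A:G" = "SYNGENE1")
  drv <- driver_config()
  expect_equal(assign_group(character(0), "EGFR:p.L858R", drv, kg), 1L)
  expect_equal(assign_group("EGFR:p.L858R", character(0), drv, kg), 1L)
  expect_equal(assign_group(c("EGFR:p.L858R", "SYN:1:A:G"),
                            "EGFR:p.L858R", drv, kg), 2L)
  # shared passenger without any driver is still group 2
  expect_equal(assign_group("SYN:1:A:G", "SYN:1:A:G", drv, kg), 2L)
  # distinct drivers, nothing shared -> group 3
  expect_equal(assign_group("EGFR:p.E746_A750del", "KRAS:p.G12D", drv, kg),
               3L)
})

test_that("the CI rule maps group-2 pairs to MSLC / IPM / ambiguous", {
  cal <- make_calibration()
  drv <- driver_config()
  cat_ <- fixed_catalog(c("chr7:55259515:T:G" = 20), n_samples = 505,
                        floor = 1e-9)
  kg <- c("chr7:55259515:T:G" = "EGFR", "chr1:1:A:G" = "SYNGENE1",
          "chr1:2:A:G" = "SYNGENE2")

  # high CI with shared passengers -> IPM
  pair_ipm <- clonality_index(c("chr1:1:A:G", "chr1:2:A:G"),
                              c("chr1:1:A:G", "chr1:2:A:G"), cat_,
                              patient_id = "P_ipm")
  expect_gt(pair_ipm$ci, cal$cutoff_ci95[["high"]])
  call_ipm <- classify_pair(pair_ipm, cal, drv, kg)
  expect_equal(call_ipm$final_class, "IPM")
  expect_equal(call_ipm$group, 2L)

  # CI exactly at the cutoff -> MSLC (boundary belongs to MSLC)
  pair_at <- clonality_index("chr7:55259515:T:G", "chr7:55259515:T:G", cat_,
                             patient_id = "P_at")
  pair_at$ci <- cal$median_cutoff
  expect_equal(classify_pair(pair_at, cal, drv, kg)$final_class, "MSLC")

  # CI below the cutoff -> MSLC regardless of what is shared
  pair_low <- clonality_index("chr7:55259515:T:G", "chr7:55259515:T:G", cat_,
                              patient_id = "P_low")
  pair_low$ci <- 6.69
  expect_equal(classify_pair(pair_low, cal, drv, kg)$final_class, "MSLC")

  # above the cutoff but sharing only a driver hotspot -> ambiguous
  pair_hot <- clonality_index("chr7:55259515:T:G", "chr7:55259515:T:G", cat_,
                              patient_id = "P_hot")
  pair_hot$ci <- 9.5
  call_hot <- classify_pair(pair_hot, cal, drv, kg)
  expect_equal(call_hot$final_class, "ambiguous")
  expect_equal(call_hot$rule_branch, "hotspot_only_sharing_above_cutoff")

  # inside the cutoff uncertainty band with passengers -> ambiguous
  pair_band <- clonality_index("chr1:1:A:G", "chr1:1:A:G", cat_,
                               patient_id = "P_band")
  pair_band$ci <- 7.9
  expect_equal(classify_pair(pair_band, cal, drv, kg)$final_class,
               "ambiguous")

  expect_error(classify_pair(pair_band, NULL, drv, kg), "calibration")
})

test_that("raising CI never moves a call from IPM toward MSLC", {
  cal <- make_calibration()
  drv <- driver_config()
  cat_ <- fixed_catalog(c("chr1:1:A:G" = 1), n_samples = 100)
  kg <- c("chr1:1:A:G" = "SYNGENE1")
  pair <- clonality_index("chr1:1:A:G", "chr1:1:A:G", cat_,
                          patient_id = "P")
  rank <- c(MSLC = 1L, ambiguous = 2L, IPM = 3L)
  cis <- c(0.5, 7.77, 7.9, 8.5, 20, 40)
  calls <- vapply(cis, function(ci) {
    pair$ci <- ci
    classify_pair(pair, cal, drv, kg)$final_class
  }, character(1))
  expect_true(all(diff(rank[calls]) >= 0))
})

test_that("cohort_calls tallies groups and errors on missing samples", {
  cal <- make_calibration(cutoff = 5, hi = 6)
  cat_ <- fixed_catalog(c("chr1:1:A:G" = 1), n_samples = 100)
  kg <- c("chr1:1:A:G" = "SYNGENE1", "chr2:2:C:T" = "SYNGENE2",
          "chr3:3:G:A" = "SYNGENE3")
  manifest <- data.frame(patient_id = c("P1", "P2", "P3"),
                         lesion1_sample = c("P1_L1", "P2_L1", "P3_L1"),
                         lesion2_sample = c("P1_L2", "P2_L2", "P3_L2"))
  sets <- list(
    P1_L1 = character(0), P1_L2 = "chr2:2:C:T",              # group 1
    P2_L1 = c("chr1:1:A:G", "chr1:1:A:G"), P2_L2 = "chr1:1:A:G",  # group 2
    P3_L1 = "chr2:2:C:T", P3_L2 = "chr3:3:G:A")              # group 3
  res <- cohort_calls(manifest, sets, cat_, cal, driver_config(), kg)
  expect_equal(unname(res$group_counts), c(1L, 1L, 1L))
  expect_equal(res$calls$final_class[c(1, 3)], c("MSLC", "MSLC"))
  expect_equal(sum(res$class_counts), 3L)
  expect_error(cohort_calls(manifest, sets[-1], cat_, cal, driver_config(),
                            kg), "P1_L1")
})

test_that("synthetic cohort group counts match generator truth", {
  tm <- reference_spec(n_samples = 50, seed = 17)
  ref <- generate_reference(tm)
  cat_ <- build_catalog(ref$records)
  cal <- calibrate(mutation_sets(ref$records), cat_, reps = 3, seed = 17)
  coh <- generate_paired_cohort(paired_cohort_spec(n_patients = 40,
                                                   seed = 23),
                                tumor_model = tm)
  sets <- mutation_sets(coh$records,
                        sample_ids = unique(c(coh$manifest$lesion1_sample,
                                              coh$manifest$lesion2_sample)))
  kg <- key_gene_map(coh$records)
  res <- cohort_calls(coh$manifest, sets, cat_, cal, driver_config(), kg)
  # recompute the expected grouping directly from the generated sets
  want <- vapply(seq_len(nrow(coh$manifest)), function(i) {
    a <- sets[[coh$manifest$lesion1_sample[i]]]
    b <- sets[[coh$manifest$lesion2_sample[i]]]
    if (!length(a) || !length(b)) 1L
    else if (length(intersect(a, b))) 2L else 3L
  }, integer(1))
  expect_equal(res$calls$group, want)
  # every patient gets exactly one group and one class; groups 1/3 are MSLC
  expect_equal(sum(res$group_counts), nrow(coh$manifest))
  expect_equal(sum(res$class_counts), nrow(coh$manifest))
  expect_true(all(res$calls$final_class[res$calls$group != 2L] == "MSLC"))
})

test_that("driver config round-trips through TSV and ships a default", {
  shipped <- system.file("extdata", "drivers.tsv", package = "clonalCI")
  drv <- read_driver_config(shipped)
  expect_true(all(c("EGFR", "KRAS", "BRAF", "ERBB2", "MET") %in%
                    drv$driver_genes))
  expect_error(driver_config(character(0)), "non-empty")
})
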