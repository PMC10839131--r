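#' Validated end-to-end run configuration
#'
#' Collects every knob the analysis exposes — the under-specified choices
#' (prevalence mode, binomial n/k, keying mode, synonymous policy) are
#' always explicit here and are stamped into every artifact's provenance.
#'
#' @param reference_maf path to the reference-cohort MAF.
#' @param lesion_maf path to the study cohort's per-lesion MAF (all lesions
#'   in one table, keyed by sample).
#' @param manifest path to the patient/lesion manifest TSV.
#' @param keying_mode,include_synonymous key policy, see [mutation_keys()].
#' @param prevalence_mode,smoothing_floor catalog policy,
#'   see [build_catalog()].
#' @param n,k binomial model parameters.
#' @param proportions,reps calibration policy, see [calibrate()].
#' @param seed master seed.
#' @param drivers a [driver_config()].
#' @param panel_mb sequenced footprint in Mb for the landscape TMB.
#' @return validated `run_config` list.
#' @export
run_config <- function(reference_maf, lesion_maf, manifest,
                       keying_mode = "genomic", include_synonymous = TRUE,
                       prevalence_mode = "sample_fraction",
                       smoothing_floor = NULL,
                       n = 2L, k = 2L,
                       proportions = c(0.4, 0.6, 0.8), reps = 100L,
                       seed = 1L, drivers = driver_config(), panel_mb = 2.2) {
  stopifnot(keying_mode %in% c("genomic", "protein"),
            prevalence_mode %in% c("sample_fraction", "mutation_fraction"),
            is.logical(include_synonymous),
            n >= 1L, k >= 0L, k <= n,
            all(proportions > 0), all(proportions <= 1),
            panel_mb > 0)
  if (reps < 1L) stop("reps must be >= 1")
  if (!is.null(smoothing_floor)) {
    stopifnot(smoothing_floor > 0, smoothing_floor < 1)
  }
  structure(list(reference_maf = reference_maf, lesion_maf = lesion_maf,
                 manifest = manifest, keying_mode = keying_mode,
                 include_synonymous = include_synonymous,
                 prevalence_mode = prevalence_mode,
                 smoothing_floor = smoothing_floor,
                 n = as.integer(n), k = as.integer(k),
                 proportions = proportions, reps = as.integer(reps),
                 seed = as.integer(seed), drivers = drivers,
                 panel_mb = panel_mb),
            class = "run_config")
}

.log_line <- function(con, stage, ...) {
  entry <- c(list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                  stage = stage), list(...))
  writeLines(jsonlite::toJSON(entry, auto_unbox = TRUE, digits = NA), con)
}

#' Run the whole clonality analysis
#'
#' Executes the stages in order — prevalence catalog, cutoff calibration,
#' per-pair clonality indices, patient classification, landscape summary —
#' each stage reading only the previous stages' declared artifacts. Writes
#' under `out_dir`: `config.json`, `catalog.tsv`, `calibration.json`,
#' `pairs_ci.tsv`, `calls.tsv`, `landscape_*.tsv/json`, `run_log.jsonl`.
#' Everything is seeded from `config$seed`: the same config reproduces every
#' artifact.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return list with the in-memory stage results (`catalog`, `calibration`,
#'   `pairs`, `calls`, `landscape`) and `paths` of the written artifacts.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  for (p in c(config$reference_maf, config$lesion_maf, config$manifest)) {
    if (!file.exists(p)) stop("input not readable: ", p)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_path <- file.path(out_dir, "config.json")
  cfg_plain <- unclass(config)
  cfg_plain$drivers <- unclass(cfg_plain$drivers)
  jsonlite::write_json(cfg_plain, cfg_path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  cfg_hash <- unname(tools::md5sum(cfg_path))
  log_con <- file(file.path(out_dir, "run_log.jsonl"), "w")
  on.exit(close(log_con))
  stage <- "load"
  result <- tryCatch({
    reference <- read_maf(config$reference_maf, config$keying_mode)
    lesion_rec <- read_maf(config$lesion_maf, config$keying_mode)
    manifest <- read_manifest(config$manifest)
    .log_line(log_con, stage, config_hash = cfg_hash,
              n_reference_rows = nrow(reference),
              n_lesion_rows = nrow(lesion_rec),
              n_patients = nrow(manifest))

    stage <- "catalog"
    catalog <- build_catalog(reference, config$prevalence_mode,
                             config$smoothing_floor,
                             config$include_synonymous, config$keying_mode)
    catalog_path <- file.path(out_dir, "catalog.tsv")
    write_catalog(catalog, catalog_path)
    .log_line(log_con, stage, n_reference_samples = catalog$cohort_size,
              prevalence_mode = catalog$prevalence_mode,
              smoothing_floor = catalog$smoothing_floor,
              binomial_n = config$n, binomial_k = config$k)

    stage <- "calibration"
    ref_sets <- mutation_sets(reference,
                              include_synonymous = config$include_synonymous,
                              keying_mode = config$keying_mode)
    calibration <- calibrate(ref_sets, catalog, config$proportions,
                             config$reps, seed = config$seed,
                             n = config$n, k = config$k)
    calib_path <- file.path(out_dir, "calibration.json")
    write_calibration(calibration, calib_path)
    .log_line(log_con, stage, median_cutoff = calibration$median_cutoff,
              median_accuracy = calibration$median_accuracy)

    stage <- "clonality"
    lesions <- unique(c(manifest$lesion1_sample, manifest$lesion2_sample))
    # a MAF carries one row per mutation, so a lesion with no detected
    # mutations has no rows: manifest samples absent from the table are
    # treated as empty mutation sets (the group-1 situation) but flagged,
    # since a typo'd sample id would look the same
    absent <- setdiff(lesions, unique(lesion_rec$sample_id))
    if (length(absent)) {
      warning("manifest sample(s) with no rows in the lesion MAF ",
              "(treated as mutation-free): ",
              paste(absent, collapse = ", "))
    }
    sets <- mutation_sets(lesion_rec, sample_ids = lesions,
                          include_synonymous = config$include_synonymous,
                          keying_mode = config$keying_mode)
    pairs <- lapply(seq_len(nrow(manifest)), function(i) {
      clonality_index(sets[[manifest$lesion1_sample[i]]],
                      sets[[manifest$lesion2_sample[i]]],
                      catalog, config$n, config$k,
                      patient_id = manifest$patient_id[i])
    })
    pairs_path <- file.path(out_dir, "pairs_ci.tsv")
    utils::write.table(pair_report(pairs), pairs_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    .log_line(log_con, stage, n_pairs = length(pairs))

    stage <- "classification"
    key_genes <- key_gene_map(lesion_rec, config$keying_mode)
    calls <- cohort_calls(manifest, sets, catalog, calibration,
                          config$drivers, key_genes, config$n, config$k)
    calls_path <- file.path(out_dir, "calls.tsv")
    utils::write.table(calls$calls, calls_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    .log_line(log_con, stage,
              group_counts = as.list(calls$group_counts),
              class_counts = as.list(calls$class_counts))

    stage <- "landscape"
    landscape <- summarize_landscape(lesion_rec, config$drivers,
                                     config$panel_mb)
    landscape_paths <- write_landscape(landscape,
                                       file.path(out_dir, "landscape"))
    .log_line(log_con, stage, n_tumors = landscape$n_tumors)

    list(catalog = catalog, calibration = calibration, pairs = pairs,
         calls = calls, landscape = landscape,
         paths = c(config = cfg_path, catalog = catalog_path,
                   calibration = calib_path, pairs = pairs_path,
                   calls = calls_path, landscape_paths))
  }, error = function(e) {
    .log_line(log_con, stage, error = conditionMessage(e))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  result
}
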