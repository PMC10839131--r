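#' Driver-gene configuration
#'
#' Genes whose recurrent hotspot alterations are weak clonality evidence
#' (two independent primaries can share EGFR L858R by chance), versus
#' passenger mutations whose sharing is strong evidence. The default gene
#' set covers the actionable lung adenocarcinoma drivers plus TP53;
#' `hotspot_keys` optionally flags specific keys as hotspots in addition to
#' the gene-level rule.
#'
#' @param driver_genes character vector of HUGO symbols.
#' @param hotspot_keys optional character vector of mutation keys.
#' @return object of class `driver_config`.
#' @export
driver_config <- function(driver_genes = c("EGFR", "KRAS", "BRAF", "ERBB2",
                                           "MET", "ALK", "RET", "ROS1",
                                           "TP53"),
                          hotspot_keys = character(0)) {
  if (!length(driver_genes)) stop("driver_genes must be non-empty")
  structure(list(driver_genes = unique(driver_genes),
                 hotspot_keys = unique(hotspot_keys)),
            class = "driver_config")
}

#' Read a driver configuration from TSV
#'
#' Two-column TSV (`type`, `value`) with `type` in `gene` / `hotspot_key`;
#' shipped default at `system.file("extdata", "drivers.tsv",
#' package = "clonalCI")`.
#'
#' @param path TSV path.
#' @return a `driver_config`.
#' @export
read_driver_config <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("type", "value") %in% names(tab))) {
    stop("driver config needs columns: type, value")
  }
  driver_config(driver_genes = tab$value[tab$type == "gene"],
                hotspot_keys = tab$value[tab$type == "hotspot_key"])
}

.is_driver_key <- function(keys, drivers, key_genes) {
  genes <- unname(key_genes[keys])
  keys %in% drivers$hotspot_keys |
    (!is.na(genes) & genes %in% drivers$driver_genes)
}

#' Assign a patient to the mutation-sharing groups
#'
#' Partition used before any clonality-index arithmetic:
#' \describe{
#'   \item{group 1}{at least one lesion has no detected mutations — nothing
#'     to compare, called MSLC.}
#'   \item{group 2}{the lesions share at least one mutation key (a shared
#'     driver, or shared non-driver mutations) — relatedness is undecided
#'     and the CI rule applies.}
#'   \item{group 3}{both lesions carry mutations but share none (e.g.
#'     distinct drivers) — independent origin, called MSLC.}
#' }
#'
#' @param set_a,set_b mutation key sets of the two lesions.
#' @param drivers a [driver_config()] (kept for interface symmetry; the
#'   grouping itself depends only on sharing).
#' @param key_genes named vector `key -> gene` from [key_gene_map()].
#' @return integer 1, 2 or 3.
#' @export
assign_group <- function(set_a, set_b, drivers = driver_config(),
                         key_genes = character(0)) {
  if (length(set_a) == 0L || length(set_b) == 0L) return(1L)
  if (length(intersect(set_a, set_b)) > 0L) return(2L)
  3L
}

#' Classify a lesion pair as MSLC, IPM or ambiguous
#'
#' Applies the decision flow to one patient. Groups 1 and 3 are MSLC
#' directly. For group 2 the calibrated cutoff decides, with the nature of
#' the shared mutations as corroborating evidence:
#' \itemize{
#'   \item `ci <= median_cutoff` — MSLC (a CI exactly at the cutoff is MSLC);
#'   \item `ci` above the upper 95% calibration bound \emph{and} at least one
#'     shared passenger (non-driver, non-hotspot) mutation — IPM;
#'   \item otherwise (`ci` above the cutoff but the sharing limited to driver
#'     hotspots, or inside the cutoff's uncertainty band) — ambiguous,
#'     flagged for clinical review.
#' }
#' Every call records the rule branch and the cutoffs used so alternative
#' rules can be audited.
#'
#' @param pair a [clonality_index()] result.
#' @param calibration a [calibrate()] result.
#' @param drivers a [driver_config()].
#' @param key_genes named vector `key -> gene`.
#' @param group optional precomputed group (1/2/3); recomputed if `NULL`.
#' @return one-row data.frame: `patient_id`, `group`, `ci`, `final_class`,
#'   `rule_branch`, `shared_keys`, `evidence`.
#' @export
classify_pair <- function(pair, calibration, drivers = driver_config(),
                          key_genes = character(0), group = NULL) {
  if (is.null(calibration)) stop("calibration result is required")
  if (is.null(group)) {
    group <- assign_group(pair$set_a, pair$set_b, drivers, key_genes)
  }
  cutoff <- calibration$median_cutoff
  hi <- calibration$cutoff_ci95[["high"]]
  shared <- pair$shared
  if (group == 1L) {
    cls <- "MSLC"; branch <- "group1_empty_lesion"; ci <- 0
  } else if (group == 3L) {
    cls <- "MSLC"; branch <- "group3_no_shared"; ci <- 0
  } else {
    ci <- pair$ci
    has_passenger <- any(!.is_driver_key(shared, drivers, key_genes))
    if (ci <= cutoff) {
      cls <- "MSLC"; branch <- "ci_at_or_below_cutoff"
    } else if (ci > hi && has_passenger) {
      cls <- "IPM"; branch <- "ci_above_band_with_shared_passengers"
    } else if (has_passenger) {
      cls <- "ambiguous"; branch <- "ci_within_uncertainty_band"
    } else {
      cls <- "ambiguous"; branch <- "hotspot_only_sharing_above_cutoff"
    }
  }
  data.frame(
    patient_id = pair$patient_id, group = group, ci = ci, final_class = cls,
    rule_branch = branch,
    shared_keys = paste(shared, collapse = ";"),
    evidence = sprintf("cutoff=%.4g;ci95_high=%.4g;n_shared=%d",
                       cutoff, hi, length(shared)),
    stringsAsFactors = FALSE)
}

#' Classify a whole paired-lesion cohort
#'
#' Runs grouping and classification for every manifest patient and tallies
#' groups and final classes.
#'
#' @param manifest data.frame from [read_manifest()].
#' @param sets named list `sample_id -> mutation key vector`; must cover
#'   every manifest lesion (empty sets allowed).
#' @param catalog prevalence catalog.
#' @param calibration a [calibrate()] result.
#' @param drivers a [driver_config()].
#' @param key_genes named vector `key -> gene`.
#' @param n,k binomial model parameters.
#' @return list: `calls` data frame (one row per patient), `group_counts`,
#'   `class_counts`.
#' @export
cohort_calls <- function(manifest, sets, catalog, calibration,
                         drivers = driver_config(), key_genes = character(0),
                         n = 2L, k = 2L) {
  lesions <- c(manifest$lesion1_sample, manifest$lesion2_sample)
  missing <- setdiff(lesions, names(sets))
  if (length(missing)) {
    stop("manifest sample(s) missing from variant input: ",
         paste(missing, collapse = ", "))
  }
  calls <- do.call(rbind, lapply(seq_len(nrow(manifest)), function(i) {
    pair <- clonality_index(sets[[manifest$lesion1_sample[i]]],
                            sets[[manifest$lesion2_sample[i]]],
                            catalog, n, k,
                            patient_id = manifest$patient_id[i])
    classify_pair(pair, calibration, drivers, key_genes)
  }))
  group_counts <- stats::setNames(
    vapply(1:3, function(g) sum(calls$group == g), integer(1)),
    c("group1", "group2", "group3"))
  class_counts <- stats::setNames(
    vapply(c("MSLC", "IPM", "ambiguous"),
           function(cl) sum(calls$final_class == cl), integer(1)),
    c("MSLC", "IPM", "ambiguous"))
  list(calls = calls, group_counts = group_counts,
       class_counts = class_counts)
}
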