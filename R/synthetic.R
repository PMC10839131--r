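# Driver hotspot table used by the generator: classical lung adenocarcinoma
# alleles with cohort carrier prevalences in the range reported for Western
# adenocarcinoma cohorts (hg19 coordinates; coordinates only need to be
# plausible and internally consistent, the analysis never touches sequence).
.HOTSPOT_TABLE <- data.frame(
  gene = c("KRAS", "KRAS", "KRAS", "EGFR", "EGFR", "EGFR",
           "BRAF", "TP53", "ERBB2"),
  chrom = c("chr12", "chr12", "chr12", "chr7", "chr7", "chr7",
            "chr7", "chr17", "chr17"),
  pos = c(25398285L, 25398284L, 25398281L, 55259515L, 55242465L, 55249010L,
          140453136L, 7578406L, 37880979L),
  ref_allele = c("C", "C", "C", "T", "GGAATTAAGAGAAGCA", "G",
                 "A", "C", "A"),
  alt_allele = c("A", "T", "T", "G", "G", "GTCC",
                 "T", "T", "AATACGTGATGGC"),
  protein_change = c("p.G12C", "p.G12D", "p.G13D", "p.L858R",
                     "p.E746_A750del", "p.V769_D770insASV",
                     "p.V600E", "p.R175H", "p.Y772_A775dup"),
  variant_class = c("missense", "missense", "missense", "missense",
                    "inframe_indel", "inframe_indel",
                    "missense", "missense", "inframe_indel"),
  prevalence = c(0.12, 0.08, 0.02, 0.04, 0.03, 0.008,
                 0.015, 0.02, 0.005),
  stringsAsFactors = FALSE)

#' Specification for a synthetic reference cohort
#'
#' Describes a cohort emulating a lung adenocarcinoma reference set as seen
#' through a broad targeted panel: a handful of recurrent driver hotspots at
#' realistic carrier prevalences over a large universe of essentially
#' non-recurrent passenger mutations. Defaults model a ~509-gene (~2.2 Mb)
#' panel on an adenocarcinoma cohort: Poisson mean 20 mutations per sample
#' (TMB around 9 per Mb) and hotspot prevalences between 0.005 and 0.12.
#'
#' @param n_samples number of reference samples.
#' @param hotspots data.frame with at least `gene`, `chrom`, `pos`,
#'   `ref_allele`, `alt_allele`, `protein_change`, `variant_class`,
#'   `prevalence` (target carrier fraction in (0,1)).
#' @param passenger_universe_size distinct passenger loci available.
#' @param mutations_per_sample_mean Poisson mean of passenger count.
#' @param synonymous_fraction fraction of passengers emitted as synonymous.
#' @param seed integer seed; all generator randomness derives from it.
#' @return object of class `reference_spec`.
#' @export
reference_spec <- function(n_samples = 505L,
                           hotspots = .HOTSPOT_TABLE,
                           passenger_universe_size = 200000L,
                           mutations_per_sample_mean = 20,
                           synonymous_fraction = 0.07,
                           seed = 1L) {
  stopifnot(n_samples >= 2L,
            all(hotspots$prevalence > 0), all(hotspots$prevalence < 1),
            passenger_universe_size > mutations_per_sample_mean,
            mutations_per_sample_mean > 0,
            synonymous_fraction >= 0, synonymous_fraction < 1)
  structure(list(n_samples = as.integer(n_samples), hotspots = hotspots,
                 passenger_universe_size = as.integer(passenger_universe_size),
                 mutations_per_sample_mean = mutations_per_sample_mean,
                 synonymous_fraction = synonymous_fraction,
                 seed = as.integer(seed)),
            class = "reference_spec")
}

# Deterministic MAF-shaped fields for passenger locus ids, so synthetic
# cohorts exercise the real MAF reader and genomic keying. Variant class is
# a deterministic function of the id (every 1/synonymous_fraction-th locus
# is synonymous), keeping records reproducible given the id alone.
.passenger_records <- function(sample_id, ids, synonymous_fraction) {
  bases <- c("A", "C", "G", "T")
  ref <- bases[(ids %% 4L) + 1L]
  alt <- bases[((ids + 1L) %% 4L) + 1L]
  period <- if (synonymous_fraction > 0) ceiling(1 / synonymous_fraction) else 0L
  syn <- period > 0L & ids %% period == 0L
  mutation_records(
    sample_id = sample_id,
    gene = paste0("SYNGENE", ids %% 600L),
    chrom = paste0("chr", (ids %% 22L) + 1L),
    pos = 1000000L + ids,
    ref_allele = ref, alt_allele = alt,
    protein_change = paste0("p.X", ids, "Y"),
    variant_class = ifelse(syn, "synonymous", "missense"))
}

# One reference-like sample: independent Bernoulli carriage of each hotspot
# plus a Poisson number of passenger loci drawn uniformly (with replacement,
# then deduplicated) from the universe. A sample that would come out empty
# is given one passenger so every reference sample is usable in pair
# simulation.
.draw_sample_records <- function(sample_id, spec) {
  hs <- spec$hotspots[stats::runif(nrow(spec$hotspots)) <
                        spec$hotspots$prevalence, , drop = FALSE]
  n_pass <- stats::rpois(1L, spec$mutations_per_sample_mean)
  if (n_pass == 0L && nrow(hs) == 0L) n_pass <- 1L
  ids <- unique(sample.int(spec$passenger_universe_size, n_pass,
                           replace = TRUE))
  rec <- .passenger_records(sample_id, ids, spec$synonymous_fraction)
  if (nrow(hs)) {
    hs_rec <- mutation_records(sample_id = sample_id, gene = hs$gene,
                               chrom = hs$chrom, pos = hs$pos,
                               ref_allele = hs$ref_allele,
                               alt_allele = hs$alt_allele,
                               protein_change = hs$protein_change,
                               variant_class = hs$variant_class)
    rec <- rbind(hs_rec, rec)
  }
  rec
}

#' Generate a synthetic reference cohort
#'
#' Draws `n_samples` reference samples under the spec and returns MAF-shaped
#' records plus a truth table of target versus realized hotspot prevalences.
#' Identical specs (including seed) give identical cohorts.
#'
#' @param spec a [reference_spec()].
#' @return list: `records` (mutation-record data frame), `truth_prevalence`
#'   (data.frame key/gene/target_prevalence/realized_prevalence), `spec`.
#' @export
generate_reference <- function(spec = reference_spec()) {
  stopifnot(inherits(spec, "reference_spec"))
  set.seed(spec$seed)
  ids <- sprintf("REF%04d", seq_len(spec$n_samples))
  records <- do.call(rbind, lapply(ids, .draw_sample_records, spec = spec))
  hs_keys <- mutation_keys(mutation_records(
    sample_id = "x", gene = spec$hotspots$gene, chrom = spec$hotspots$chrom,
    pos = spec$hotspots$pos, ref_allele = spec$hotspots$ref_allele,
    alt_allele = spec$hotspots$alt_allele,
    protein_change = spec$hotspots$protein_change,
    variant_class = spec$hotspots$variant_class))
  all_keys <- mutation_keys(records)
  carriers <- vapply(hs_keys, function(k) {
    length(unique(records$sample_id[all_keys == k]))
  }, integer(1))
  truth <- data.frame(key = hs_keys, gene = spec$hotspots$gene,
                      target_prevalence = spec$hotspots$prevalence,
                      realized_prevalence = carriers / spec$n_samples,
                      stringsAsFactors = FALSE)
  list(records = records, truth_prevalence = truth, spec = spec)
}

#' Specification for a synthetic paired-lesion cohort
#'
#' Describes a study cohort of patients with two lung lesions each and known
#' ground truth. IPM patients get two lesions subsampled from one parent
#' tumor (clonal); MSLC patients get two independent reference-like tumors,
#' a fraction of which are forced to share one driver hotspot to model
#' coincidental hotspot sharing — the confound the clonality index must not
#' mistake for clonality.
#'
#' @param n_patients number of patients (two lesions each).
#' @param ipm_fraction fraction of patients whose truth is IPM.
#' @param clonal_overlap_range range of the per-lesion subsampling fraction
#'   for IPM pairs.
#' @param driver_sharing_prob probability an MSLC pair is forced to share a
#'   driver hotspot (drawn by prevalence weight).
#' @param seed integer seed.
#' @return object of class `paired_cohort_spec`.
#' @export
paired_cohort_spec <- function(n_patients = 200L, ipm_fraction = 0.15,
                               clonal_overlap_range = c(0.4, 0.8),
                               driver_sharing_prob = 0.12, seed = 1L) {
  stopifnot(n_patients >= 1L, ipm_fraction >= 0, ipm_fraction <= 1,
            length(clonal_overlap_range) == 2L,
            clonal_overlap_range[1] <= clonal_overlap_range[2],
            all(clonal_overlap_range > 0), all(clonal_overlap_range <= 1),
            driver_sharing_prob >= 0, driver_sharing_prob <= 1)
  structure(list(n_patients = as.integer(n_patients),
                 ipm_fraction = ipm_fraction,
                 clonal_overlap_range = clonal_overlap_range,
                 driver_sharing_prob = driver_sharing_prob,
                 seed = as.integer(seed)),
            class = "paired_cohort_spec")
}

# Subsample a parent tumor's records at fraction q (draw with replacement,
# deduplicate) — mirrors the positive-pair construction used in calibration.
.subsample_records <- function(records, q, sample_id) {
  m <- .draw_size(q, nrow(records))
  rec <- records[unique(sample.int(nrow(records), m, replace = TRUE)), ,
                 drop = FALSE]
  rec$sample_id <- sample_id
  rownames(rec) <- NULL
  rec
}

#' Generate a synthetic paired-lesion study cohort
#'
#' @param spec a [paired_cohort_spec()].
#' @param tumor_model a [reference_spec()] describing the tumor model the
#'   lesions are drawn from (only its mutation model is used, not its
#'   samples).
#' @return list: `records` (all lesions), `manifest` (patient_id,
#'   lesion1_sample, lesion2_sample), `truth` (patient_id, true_class,
#'   overlap, forced_shared_driver), `spec`.
#' @export
generate_paired_cohort <- function(spec = paired_cohort_spec(),
                                   tumor_model = reference_spec()) {
  stopifnot(inherits(spec, "paired_cohort_spec"))
  set.seed(spec$seed)
  hs <- tumor_model$hotspots
  n_ipm <- round(spec$n_patients * spec$ipm_fraction)
  is_ipm <- c(rep(TRUE, n_ipm), rep(FALSE, spec$n_patients - n_ipm))

  records <- vector("list", spec$n_patients)
  truth <- vector("list", spec$n_patients)
  manifest <- vector("list", spec$n_patients)
  for (i in seq_len(spec$n_patients)) {
    pid <- sprintf("PT%03d", i)
    les <- paste0(pid, c("_L1", "_L2"))
    if (is_ipm[i]) {
      parent <- .draw_sample_records(pid, tumor_model)
      q <- stats::runif(1, spec$clonal_overlap_range[1],
                        spec$clonal_overlap_range[2])
      rec <- rbind(.subsample_records(parent, q, les[1]),
                   .subsample_records(parent, q, les[2]))
      truth[[i]] <- data.frame(patient_id = pid, true_class = "IPM",
                               overlap = q, forced_shared_driver = NA,
                               stringsAsFactors = FALSE)
    } else {
      a <- .draw_sample_records(les[1], tumor_model)
      b <- .draw_sample_records(les[2], tumor_model)
      forced <- NA_character_
      if (stats::runif(1) < spec$driver_sharing_prob) {
        j <- sample.int(nrow(hs), 1L, prob = hs$prevalence)
        forced <- hs$protein_change[j]
        for (rec_i in c("a", "b")) {
          r <- get(rec_i)
          hr <- mutation_records(sample_id = r$sample_id[1], gene = hs$gene[j],
                                 chrom = hs$chrom[j], pos = hs$pos[j],
                                 ref_allele = hs$ref_allele[j],
                                 alt_allele = hs$alt_allele[j],
                                 protein_change = hs$protein_change[j],
                                 variant_class = hs$variant_class[j])
          assign(rec_i, unique(rbind(r, hr)))
        }
      }
      rec <- rbind(a, b)
      truth[[i]] <- data.frame(patient_id = pid, true_class = "MSLC",
                               overlap = NA_real_,
                               forced_shared_driver = forced,
                               stringsAsFactors = FALSE)
    }
    records[[i]] <- rec
    manifest[[i]] <- data.frame(patient_id = pid, lesion1_sample = les[1],
                                lesion2_sample = les[2],
                                stringsAsFactors = FALSE)
  }
  list(records = do.call(rbind, records),
       manifest = do.call(rbind, manifest),
       truth = do.call(rbind, truth),
       spec = spec)
}
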