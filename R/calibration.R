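# Subsample size: round-half-up of q * set size, at least 1 pick.
.draw_size <- function(q, n) max(1L, as.integer(floor(q * n + 0.5)))

#' Simulate clonally related (positive) lesion pairs
#'
#' Emulates intratumor heterogeneity between clonally related lesions: for
#' each reference sample and each subsampling proportion `q`, two
#' independent draws of `round(q * |set|)` mutations are taken with
#' replacement from the sample's mutation set and each draw is collapsed to a
#' set. The two draws form one positive pair; their intersection is the
#' sharing a clonal pair would show at that heterogeneity level. With the
#' default proportions `c(0.4, 0.6, 0.8)` a reference of N samples yields
#' `3 N` positive pairs.
#'
#' @param sets named list `sample_id -> mutation key vector`; every sample
#'   must have at least one mutation.
#' @param proportions subsampling fractions in (0, 1].
#' @param seed integer RNG seed.
#' @return list of `list(set_a, set_b, source_sample, proportion)`.
#' @export
simulate_positive_pairs <- function(sets, proportions = c(0.4, 0.6, 0.8),
                                    seed = 1L) {
  if (any(proportions <= 0 | proportions > 1)) {
    stop("proportions must lie in (0, 1]")
  }
  if (any(lengths(sets) == 0L)) {
    stop("every reference sample needs at least one mutation")
  }
  set.seed(seed)
  out <- vector("list", length(sets) * length(proportions))
  i <- 0L
  for (q in proportions) {
    for (s in names(sets)) {
      keys <- sets[[s]]
      m <- .draw_size(q, length(keys))
      i <- i + 1L
      out[[i]] <- list(set_a = unique(sample(keys, m, replace = TRUE)),
                       set_b = unique(sample(keys, m, replace = TRUE)),
                       source_sample = s, proportion = q)
    }
  }
  out
}

#' Simulate unrelated (negative) lesion pairs
#'
#' Draws `count` pairs of two distinct reference samples uniformly at random;
#' each sample's whole mutation set is used. These pairs share mutations only
#' by chance recurrence, the null the clonality index tests against.
#'
#' @param sets named list `sample_id -> mutation key vector` (>= 2 samples).
#' @param count number of pairs.
#' @param seed integer RNG seed.
#' @return list of `list(set_a, set_b, sample_a, sample_b)`.
#' @export
simulate_negative_pairs <- function(sets, count, seed = 1L) {
  if (length(sets) < 2L) stop("need at least 2 reference samples")
  set.seed(seed)
  ids <- names(sets)
  lapply(seq_len(count), function(i) {
    pick <- sample(ids, 2L, replace = FALSE)
    list(set_a = sets[[pick[1]]], set_b = sets[[pick[2]]],
         sample_a = pick[1], sample_b = pick[2])
  })
}

#' Accuracy-optimal CI cutoff
#'
#' Exhaustive threshold search: candidate cutoffs are the midpoints between
#' adjacent distinct observed CI values plus sentinels below the minimum and
#' above the maximum; a pair is called clonal (positive) when `ci > cutoff`.
#' The returned cutoff maximizes accuracy `(TP + TN) / (P + N)`; accuracy
#' ties are broken toward the highest cutoff, favoring specificity.
#'
#' @param positive_cis,negative_cis CI values of the simulated clonal and
#'   unrelated pairs.
#' @return list `cutoff`, `accuracy`, `sensitivity`, `specificity`.
#' @export
optimal_accuracy_cutoff <- function(positive_cis, negative_cis) {
  if (!length(positive_cis) || !length(negative_cis)) {
    stop("both score lists must be non-empty")
  }
  u <- sort(unique(c(positive_cis, negative_cis)))
  cand <- c(u[1] - 1, if (length(u) > 1) (u[-length(u)] + u[-1]) / 2,
            u[length(u)] + 1)
  P <- length(positive_cis)
  N <- length(negative_cis)
  sp <- sort(positive_cis)
  sn <- sort(negative_cis)
  # TP(c) = #positives > c ; TN(c) = #negatives <= c
  tp <- P - findInterval(cand, sp)
  tn <- findInterval(cand, sn)
  acc <- (tp + tn) / (P + N)
  best <- max(which(acc == max(acc)))  # tie -> highest cutoff
  list(cutoff = cand[best], accuracy = acc[best],
       sensitivity = tp[best] / P, specificity = tn[best] / N)
}

# Rank-statistic AUROC, reported as a diagnostic alongside the operative
# accuracy-optimal cutoff.
.auroc <- function(positive_cis, negative_cis) {
  roc <- pROC::roc(response = c(rep(1L, length(positive_cis)),
                                rep(0L, length(negative_cis))),
                   predictor = c(positive_cis, negative_cis),
                   direction = "<", quiet = TRUE)
  as.numeric(pROC::auc(roc))
}

#' Calibrate the MSLC/IPM clonality-index cutoff
#'
#' One repetition simulates a fresh positive set ([simulate_positive_pairs()],
#' one pair per sample per proportion) and an equally sized negative set
#' ([simulate_negative_pairs()]), scores every pair with the clonality index
#' against `catalog`, and takes the accuracy-optimal cutoff. Repetitions are
#' summarized by the median and the 2.5/97.5 percentile interval (linear
#' interpolation between order statistics). Rerunning with the same seed
#' reproduces `per_rep` exactly.
#'
#' @param sets named list `sample_id -> mutation key vector` for the
#'   reference cohort.
#' @param catalog prevalence catalog (normally built from the same cohort).
#' @param proportions subsampling fractions for the positives.
#' @param reps number of repetitions (>= 1).
#' @param seed integer master seed; repetition r uses substream `seed + r`.
#' @param n,k binomial model parameters.
#' @return object of class `calibration_result`: `per_rep` data frame
#'   (cutoff, accuracy, sensitivity, specificity, auroc), `median_cutoff`,
#'   `cutoff_ci95`, `median_accuracy`, `median_sensitivity`,
#'   `median_specificity`, `median_auroc`, plus the run parameters.
#' @export
calibrate <- function(sets, catalog, proportions = c(0.4, 0.6, 0.8),
                      reps = 100L, seed = 1L, n = 2L, k = 2L) {
  if (reps < 1L) stop("reps must be >= 1")
  per_rep <- vector("list", reps)
  n_pos <- length(sets) * length(proportions)
  for (r in seq_len(reps)) {
    sub_seed <- seed + r
    pos <- simulate_positive_pairs(sets, proportions, seed = sub_seed)
    neg <- simulate_negative_pairs(sets, count = n_pos, seed = sub_seed + reps)
    pos_ci <- vapply(pos, function(p) ci_value(p$set_a, p$set_b, catalog,
                                               n, k), numeric(1))
    neg_ci <- vapply(neg, function(p) ci_value(p$set_a, p$set_b, catalog,
                                               n, k), numeric(1))
    opt <- optimal_accuracy_cutoff(pos_ci, neg_ci)
    opt$auroc <- .auroc(pos_ci, neg_ci)
    per_rep[[r]] <- as.data.frame(opt)
  }
  per_rep <- do.call(rbind, per_rep)
  qs <- stats::quantile(per_rep$cutoff, c(0.025, 0.975), names = FALSE,
                        type = 7)
  structure(list(
    per_rep = per_rep,
    median_cutoff = stats::median(per_rep$cutoff),
    cutoff_ci95 = c(low = qs[1], high = qs[2]),
    median_accuracy = stats::median(per_rep$accuracy),
    median_sensitivity = stats::median(per_rep$sensitivity),
    median_specificity = stats::median(per_rep$specificity),
    median_auroc = stats::median(per_rep$auroc),
    reps = reps, proportions = proportions, seed = seed,
    n = n, k = k, n_reference = length(sets),
    n_positive = n_pos, n_negative = n_pos,
    prevalence_mode = catalog$prevalence_mode),
    class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(paste0(
    "calibration_result: %d reps on %d reference samples ",
    "(%d pos / %d neg pairs per rep, mode = %s)\n"),
    x$reps, x$n_reference, x$n_positive, x$n_negative, x$prevalence_mode))
  cat(sprintf("  median cutoff %.4g (95%% CI %.4g-%.4g)\n",
              x$median_cutoff, x$cutoff_ci95["low"], x$cutoff_ci95["high"]))
  cat(sprintf(
    "  median accuracy %.2f%% | sensitivity %.2f%% | specificity %.2f%% | AUROC %.4f\n",
    100 * x$median_accuracy, 100 * x$median_sensitivity,
    100 * x$median_specificity, x$median_auroc))
  invisible(x)
}

#' Write / read a calibration result as JSON
#'
#' @param calibration a `calibration_result`.
#' @param path JSON path.
#' @return `path` invisibly (write); a `calibration_result` (read).
#' @export
write_calibration <- function(calibration, path) {
  stopifnot(inherits(calibration, "calibration_result"))
  out <- unclass(calibration)
  out$cutoff_ci95 <- as.list(out$cutoff_ci95)  # keep low/high names in JSON
  jsonlite::write_json(out, path, auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$per_rep <- as.data.frame(x$per_rep)
  ci <- unlist(x$cutoff_ci95)
  x$cutoff_ci95 <- c(low = unname(ci[["low"]]), high = unname(ci[["high"]]))
  structure(x, class = "calibration_result")
}
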