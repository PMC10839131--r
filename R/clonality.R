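#' Binomial probability of observing a shared mutation
#'
#' For a mutation with population prevalence `p`, the chance of observing it
#' `k` times in `n` sampled tumors is `C(n,k) p^k (1-p)^(n-k)`. For a pair of
#' lesions both carrying the mutation the defaults are `n = k = 2`, giving
#' `p^2`.
#'
#' @param p prevalence in (0, 1].
#' @param n,k binomial trials and successes, `0 <= k <= n`.
#' @return probability vector, recycled over `p`.
#' @export
binomial_point_probability <- function(p, n = 2L, k = 2L) {
  if (any(p <= 0) || any(p > 1)) stop("prevalence p must be in (0, 1]")
  if (k < 0 || k > n) stop("require 0 <= k <= n")
  stats::dbinom(k, size = n, prob = p)
}

# -log10 point probability, computed in log space to avoid underflow when a
# pair shares many rare mutations (products can be far below .Machine range).
.neg_log10_point <- function(p, n, k) {
  -stats::dbinom(k, size = n, prob = p, log = TRUE) / log(10)
}

#' Clonality index of a lesion pair
#'
#' Scores how unlikely the two lesions' shared mutations are to co-occur by
#' chance. Each shared key contributes `-log10 P(X)` with
#' `P(X) = C(n,k) p^k (1-p)^(n-k)` at that key's catalog prevalence `p`; the
#' clonality index (CI) is the sum over shared keys, i.e. `-log10` of the
#' product of per-mutation probabilities, accumulated in log space. An empty
#' intersection gives CI = 0 (empty product). High CI means the sharing is
#' implausible under independent origin, i.e. evidence of clonal relatedness.
#'
#' @param set_a,set_b character vectors of mutation keys for the two lesions.
#' @param catalog a [build_catalog()] result.
#' @param n,k binomial model parameters, fixed per run (default 2, 2:
#'   observed in both lesions of a pair).
#' @param patient_id optional label carried into the result.
#' @return object of class `lesion_pair`: `patient_id`, `set_a`, `set_b`,
#'   `shared`, `evidence` (per-key prevalence and -log10 P, sorted by
#'   descending contribution), `ci`.
#' @export
clonality_index <- function(set_a, set_b, catalog, n = 2L, k = 2L,
                            patient_id = NA_character_) {
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  shared <- intersect(set_a, set_b)
  if (length(shared)) {
    p <- prevalence(catalog, shared)
    nl <- .neg_log10_point(p, n, k)
    ord <- order(nl, decreasing = TRUE)
    evidence <- data.frame(key = shared[ord], prevalence = p[ord],
                           point_probability = 10^(-nl[ord]),
                           neg_log10 = nl[ord], stringsAsFactors = FALSE)
    ci <- sum(nl)
  } else {
    evidence <- data.frame(key = character(0), prevalence = numeric(0),
                           point_probability = numeric(0),
                           neg_log10 = numeric(0), stringsAsFactors = FALSE)
    ci <- 0
  }
  structure(list(patient_id = patient_id, set_a = set_a, set_b = set_b,
                 shared = evidence$key, evidence = evidence, ci = ci),
            class = "lesion_pair")
}

#' @export
print.lesion_pair <- function(x, ...) {
  cat(sprintf("lesion_pair %s: |A| = %d, |B| = %d, shared = %d, CI = %.4g\n",
              ifelse(is.na(x$patient_id), "<unnamed>", x$patient_id),
              length(x$set_a), length(x$set_b), length(x$shared), x$ci))
  invisible(x)
}

# Fast path used by the calibration simulations: CI value only, no evidence
# table. Must agree with clonality_index()$ci exactly.
ci_value <- function(set_a, set_b, catalog, n = 2L, k = 2L) {
  shared <- intersect(set_a, set_b)
  if (!length(shared)) return(0)
  sum(.neg_log10_point(prevalence(catalog, shared), n, k))
}

#' Per-pair clonality report table
#'
#' Flattens a list of [clonality_index()] results into the tabular per-pair
#' report: set sizes, CI, and the shared keys with their prevalences and
#' contributions.
#'
#' @param pairs list of `lesion_pair` objects.
#' @return data.frame, one row per pair.
#' @export
pair_report <- function(pairs) {
  do.call(rbind, lapply(pairs, function(p) {
    data.frame(
      patient_id = p$patient_id,
      n_a = length(p$set_a), n_b = length(p$set_b),
      n_shared = length(p$shared),
      ci = p$ci,
      shared_keys = paste(sprintf("%s(p=%.3g,-log10P=%.3g)",
                                  p$evidence$key, p$evidence$prevalence,
                                  p$evidence$neg_log10), collapse = ";"),
      stringsAsFactors = FALSE)
  }))
}
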