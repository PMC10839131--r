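#' Allele-class pattern table
#'
#' Editable rules mapping protein-change strings to clinically named allele
#' classes. A record matches a row when its gene equals `gene`, its
#' protein change matches `match_regex`, and (if non-empty) also matches
#' `require_regex`. First matching row wins; unmatched driver alleles fall
#' into `<gene>:other`. Residue windows encode the EGFR exon 19 deletion
#' (residues 729-761) and exon 20 insertion/duplication (residues 762-823)
#' classes.
#'
#' @return data.frame with columns `gene`, `allele_class`, `match_regex`,
#'   `require_regex`.
#' @export
default_allele_patterns <- function() {
  data.frame(
    gene = c("EGFR", "EGFR", "EGFR", "EGFR", "EGFR", "EGFR",
             "KRAS", "KRAS", "BRAF"),
    allele_class = c("L858R", "T790M", "G719X", "L861Q",
                     "exon19del", "exon20ins",
                     "G12X", "Q61X", "V600E"),
    match_regex = c("L858R", "T790M", "G719[A-Z]", "L861Q",
                    "(72[9]|7[3-5][0-9]|76[01])",
                    "(76[2-9]|7[7-9][0-9]|8[01][0-9]|82[0-3])",
                    "G12[A-Z]|Gly12", "Q61[A-Z]|Gln61", "V600E"),
    require_regex = c("", "", "", "", "del", "ins|dup", "", "", ""),
    stringsAsFactors = FALSE)
}

.allele_class <- function(gene, protein_change, patterns) {
  out <- rep(NA_character_, length(gene))
  for (i in seq_len(nrow(patterns))) {
    hit <- is.na(out) & !is.na(gene) & gene == patterns$gene[i] &
      !is.na(protein_change) &
      grepl(patterns$match_regex[i], protein_change)
    if (nzchar(patterns$require_regex[i])) {
      hit <- hit & grepl(patterns$require_regex[i], protein_change)
    }
    out[hit] <- patterns$allele_class[i]
  }
  out
}

#' Summarize the cohort's mutational landscape
#'
#' Tumor-level recurrence counts (a gene counted once per tumor), named
#' allele-class breakdown for the classical driver alleles, a symmetric
#' driver co-occurrence matrix, and per-sample mutation burden. TMB is the
#' non-synonymous mutation count divided by the sequenced panel footprint in
#' megabases; raw per-tumor counts are reported separately since the two are
#' routinely conflated.
#'
#' @param records mutation-record data frame for all lesions.
#' @param drivers a [driver_config()].
#' @param panel_mb sequenced footprint in Mb (> 0); required, panel-specific.
#' @param patterns allele-class rules, see [default_allele_patterns()].
#' @return object of class `landscape_summary`: `per_gene_tumor_counts`,
#'   `allele_breakdown` (data.frame gene/allele_class/n_tumors),
#'   `co_driver_matrix`, `tmb` (per sample), `raw_mutation_counts`,
#'   `n_tumors`, `panel_mb`.
#' @export
summarize_landscape <- function(records, drivers = driver_config(), panel_mb,
                                patterns = default_allele_patterns()) {
  if (missing(panel_mb) || !is.numeric(panel_mb) || panel_mb <= 0) {
    stop("panel_mb must be a positive number")
  }
  tumors <- unique(records$sample_id)
  has_gene <- !is.na(records$gene) & records$gene != ""
  gr <- records[has_gene, , drop = FALSE]

  per_gene <- if (nrow(gr)) {
    pairs <- unique(data.frame(gene = gr$gene, sample = gr$sample_id,
                               stringsAsFactors = FALSE))
    sort(table(pairs$gene), decreasing = TRUE)
  } else table(character(0))
  per_gene <- stats::setNames(as.integer(per_gene), names(per_gene))

  cls <- .allele_class(gr$gene, gr$protein_change, patterns)
  ab <- if (any(!is.na(cls))) {
    u <- unique(data.frame(gene = gr$gene[!is.na(cls)],
                           allele_class = cls[!is.na(cls)],
                           sample = gr$sample_id[!is.na(cls)],
                           stringsAsFactors = FALSE))
    agg <- stats::aggregate(list(n_tumors = u$sample),
                            by = list(gene = u$gene,
                                      allele_class = u$allele_class),
                            FUN = length)
    agg[order(agg$gene, -agg$n_tumors), ]
  } else {
    data.frame(gene = character(0), allele_class = character(0),
               n_tumors = integer(0))
  }

  dg <- drivers$driver_genes
  co <- matrix(0L, length(dg), length(dg), dimnames = list(dg, dg))
  if (nrow(gr)) {
    by_tumor <- split(gr$gene, gr$sample_id)
    for (genes in by_tumor) {
      present <- intersect(unique(genes), dg)
      if (length(present) >= 2L) {
        for (a in present) for (b in present) {
          if (a != b) co[a, b] <- co[a, b] + 1L
        }
      }
    }
  }

  nonsyn <- records[!is.na(records$variant_class) &
                      records$variant_class != "synonymous", , drop = FALSE]
  raw_counts <- stats::setNames(
    vapply(tumors, function(s) sum(nonsyn$sample_id == s), integer(1)),
    tumors)
  structure(list(per_gene_tumor_counts = per_gene,
                 allele_breakdown = ab,
                 co_driver_matrix = co,
                 tmb = raw_counts / panel_mb,
                 raw_mutation_counts = raw_counts,
                 n_tumors = length(tumors),
                 panel_mb = panel_mb),
            class = "landscape_summary")
}

#' @export
print.landscape_summary <- function(x, ...) {
  cat("landscape_summary:", x$n_tumors, "tumors, panel", x$panel_mb, "Mb\n")
  top <- utils::head(x$per_gene_tumor_counts, 8)
  cat("  top genes:", paste(names(top), top, sep = "=", collapse = ", "), "\n")
  cat(sprintf("  median TMB %.3g /Mb | mean raw mutations per tumor %.3g\n",
              stats::median(x$tmb), mean(x$raw_mutation_counts)))
  invisible(x)
}

#' Check mutual exclusivity of a driver-gene set
#'
#' Lists tumors altered in two or more genes of `genes`. An empty result
#' asserts the expected mutual exclusivity of the major lung adenocarcinoma
#' drivers.
#'
#' @param summary a [summarize_landscape()] result.
#' @param genes driver genes to check (must be in the summary's co-driver
#'   matrix); defaults to the classical mutually exclusive receptor/RAS/RAF
#'   set.
#' @param records the record frame the summary was built from (needed to name
#'   the violating tumors).
#' @return character vector of violating tumor sample ids (possibly empty).
#' @export
check_driver_exclusivity <- function(summary, records,
                                     genes = c("EGFR", "KRAS", "BRAF",
                                               "ERBB2", "MET")) {
  stopifnot(inherits(summary, "landscape_summary"))
  has_gene <- !is.na(records$gene) & records$gene %in% genes
  by_tumor <- split(records$gene[has_gene], records$sample_id[has_gene])
  viol <- names(by_tumor)[vapply(by_tumor,
                                 function(g) length(unique(g)) >= 2L,
                                 logical(1))]
  sort(viol)
}

#' Write the landscape summary as TSV + JSON
#'
#' `<stem>_genes.tsv` (gene, n_tumors), `<stem>_alleles.tsv`,
#' `<stem>_tmb.tsv`, and `<stem>.json` with the full structure; the TSVs are
#' long-format and suitable for oncoprint-style plotting by external tools.
#'
#' @param summary a `landscape_summary`.
#' @param stem output path prefix.
#' @return character vector of the files written, invisibly.
#' @export
write_landscape <- function(summary, stem) {
  g <- data.frame(gene = names(summary$per_gene_tumor_counts),
                  n_tumors = unname(summary$per_gene_tumor_counts))
  t1 <- paste0(stem, "_genes.tsv")
  utils::write.table(g, t1, sep = "\t", quote = FALSE, row.names = FALSE)
  t2 <- paste0(stem, "_alleles.tsv")
  utils::write.table(summary$allele_breakdown, t2, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  tmb <- data.frame(sample_id = names(summary$tmb),
                    tmb = unname(summary$tmb),
                    raw_mutations = unname(summary$raw_mutation_counts))
  t3 <- paste0(stem, "_tmb.tsv")
  utils::write.table(tmb, t3, sep = "\t", quote = FALSE, row.names = FALSE)
  t4 <- paste0(stem, ".json")
  jsonlite::write_json(list(
    per_gene_tumor_counts = as.list(summary$per_gene_tumor_counts),
    allele_breakdown = summary$allele_breakdown,
    co_driver_matrix = summary$co_driver_matrix,
    tmb = as.list(summary$tmb),
    n_tumors = summary$n_tumors, panel_mb = summary$panel_mb),
    t4, auto_unbox = TRUE, digits = NA)
  invisible(c(t1, t2, t3, t4))
}
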