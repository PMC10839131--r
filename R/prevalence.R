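#' Build a mutation prevalence catalog from a reference cohort
#'
#' Estimates the population prevalence `p` of every mutation key observed in
#' a reference cohort. Two estimators:
#' \describe{
#'   \item{sample_fraction}{`p = `(number of distinct cohort samples carrying
#'     the key)` / N`. Duplicate rows of a key within one sample count once.
#'     The default reading of "population prevalence".}
#'   \item{mutation_fraction}{`p = `(occurrences of the key)` / `(total
#'     mutation rows in the cohort). Much smaller for common hotspots; offered
#'     because per-mutation frequency is the alternative reading and yields
#'     larger clonality indices for shared drivers.}
#' }
#' Keys never seen in the cohort are served the smoothing floor (default
#' `1/(N+1)`), so lookups are always in (0, 1] and the clonality index is
#' finite.
#'
#' @param reference mutation-record data frame for the reference cohort.
#' @param prevalence_mode `"sample_fraction"` or `"mutation_fraction"`.
#' @param smoothing_floor probability in (0,1) served for unseen keys;
#'   `NULL` means `1/(N+1)`.
#' @param include_synonymous,keying_mode key-construction policy; must match
#'   the policy used for the lesion sets scored against this catalog.
#' @return object of class `prevalence_catalog`.
#' @export
build_catalog <- function(reference,
                          prevalence_mode = c("sample_fraction",
                                              "mutation_fraction"),
                          smoothing_floor = NULL,
                          include_synonymous = TRUE,
                          keying_mode = c("genomic", "protein")) {
  prevalence_mode <- match.arg(prevalence_mode)
  keying_mode <- match.arg(keying_mode)
  if (is.null(reference) || nrow(reference) == 0L) {
    stop("reference cohort is empty")
  }
  if (!include_synonymous) {
    reference <- reference[is.na(reference$variant_class) |
                             reference$variant_class != "synonymous", ,
                           drop = FALSE]
  }
  n_samples <- length(unique(reference$sample_id))
  keys <- mutation_keys(reference, keying_mode)
  ok <- !is.na(keys)
  keys <- keys[ok]
  samples <- reference$sample_id[ok]
  total_records <- length(keys)
  counts <- if (prevalence_mode == "sample_fraction") {
    pair <- !duplicated(paste(samples, keys, sep = "\r"))
    table(keys[pair])
  } else {
    table(keys)
  }
  counts <- stats::setNames(as.integer(counts), names(counts))
  if (is.null(smoothing_floor)) smoothing_floor <- 1 / (n_samples + 1)
  stopifnot(smoothing_floor > 0, smoothing_floor < 1)
  structure(list(counts = counts,
                 cohort_size = n_samples,
                 prevalence_mode = prevalence_mode,
                 smoothing_floor = smoothing_floor,
                 total_mutation_records = total_records,
                 keying_mode = keying_mode,
                 include_synonymous = include_synonymous),
            class = "prevalence_catalog")
}

#' Look up smoothed mutation prevalences
#'
#' Pure, deterministic lookup: seen keys return their estimated prevalence,
#' unseen keys the smoothing floor; results are clamped to (0, 1].
#'
#' @param catalog a `prevalence_catalog`.
#' @param keys character vector of mutation keys.
#' @return numeric vector of probabilities, same length as `keys`.
#' @export
prevalence <- function(catalog, keys) {
  stopifnot(inherits(catalog, "prevalence_catalog"))
  denom <- if (catalog$prevalence_mode == "sample_fraction") {
    catalog$cohort_size
  } else {
    catalog$total_mutation_records
  }
  p <- unname(catalog$counts[keys]) / denom
  p[is.na(p)] <- catalog$smoothing_floor  # floor only backs unseen keys
  pmin(p, 1)
}

#' @export
print.prevalence_catalog <- function(x, ...) {
  cat("prevalence_catalog:", length(x$counts), "keys |",
      "N =", x$cohort_size, "samples |",
      x$total_mutation_records, "mutation records\n")
  cat("  mode =", x$prevalence_mode,
      "| floor =", signif(x$smoothing_floor, 4),
      "| keying =", x$keying_mode,
      "| synonymous =", x$include_synonymous, "\n")
  invisible(x)
}

#' Write / read a prevalence catalog as TSV
#'
#' Plain-text serialization: `#`-prefixed header lines carry `cohort_size`,
#' `mode`, `floor`, `total_records`, `keying_mode`, `include_synonymous`;
#' then columns `key`, `count`, `prevalence`. The round trip preserves all
#' lookups exactly.
#'
#' @param catalog a `prevalence_catalog`.
#' @param path TSV path.
#' @return `path` invisibly (write); a `prevalence_catalog` (read).
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "prevalence_catalog"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("#cohort_size=", catalog$cohort_size),
    paste0("#mode=", catalog$prevalence_mode),
    paste0("#floor=", format(catalog$smoothing_floor, digits = 17)),
    paste0("#total_records=", catalog$total_mutation_records),
    paste0("#keying_mode=", catalog$keying_mode),
    paste0("#include_synonymous=", catalog$include_synonymous),
    "key\tcount\tprevalence"), con)
  p <- prevalence(catalog, names(catalog$counts))
  writeLines(paste(names(catalog$counts), unname(catalog$counts),
                   format(p, digits = 17, scientific = FALSE, trim = TRUE),
                   sep = "\t"), con)
  invisible(path)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(name) {
    hit <- grep(paste0("^#", name, "="), hdr, value = TRUE)
    if (length(hit) != 1L) stop("catalog file missing header #", name, "=")
    sub(paste0("^#", name, "="), "", hit)
  }
  body <- lines[!grepl("^#", lines)]
  if (length(body) == 0L || body[1] != "key\tcount\tprevalence") {
    stop("catalog file missing column header line")
  }
  mode <- get("mode")
  if (!mode %in% c("sample_fraction", "mutation_fraction")) {
    stop("unknown catalog mode: ", mode)
  }
  tab <- utils::read.delim(text = body, stringsAsFactors = FALSE,
                           colClasses = c("character", "integer", "numeric"))
  structure(list(counts = stats::setNames(tab$count, tab$key),
                 cohort_size = as.integer(get("cohort_size")),
                 prevalence_mode = mode,
                 smoothing_floor = as.numeric(get("floor")),
                 total_mutation_records = as.integer(get("total_records")),
                 keying_mode = get("keying_mode"),
                 include_synonymous = as.logical(get("include_synonymous"))),
            class = "prevalence_catalog")
}
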