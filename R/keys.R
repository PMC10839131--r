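# Canonical record columns used throughout the package. `pos` is 1-based
# (MAF convention; VCF is also 1-based so positions are used as-is).
RECORD_COLUMNS <- c("sample_id", "gene", "chrom", "pos", "ref_allele",
                    "alt_allele", "protein_change", "variant_class", "vaf")

VARIANT_CLASSES <- c("missense", "nonsense", "frameshift", "inframe_indel",
                     "splice", "synonymous", "fusion", "amplification", "other")

#' Construct a mutation-record table
#'
#' Builds the canonical per-mutation data frame used by every other function:
#' one row per somatic alteration per sample. Missing optional fields may be
#' `NA`. Every record must carry either genomic coordinates (`chrom`, `pos`,
#' `ref_allele`, `alt_allele`) or a protein-level identity
#' (`gene`, `protein_change`); rows with neither are rejected.
#'
#' @param sample_id,gene,chrom,pos,ref_allele,alt_allele,protein_change
#'   vectors recycled to a common length.
#' @param variant_class one of `r paste(VARIANT_CLASSES, collapse=", ")`.
#' @param vaf optional variant allele fraction in \[0, 1\].
#' @return data.frame with the canonical record columns.
#' @export
mutation_records <- function(sample_id, gene = NA_character_,
                             chrom = NA_character_, pos = NA_integer_,
                             ref_allele = NA_character_,
                             alt_allele = NA_character_,
                             protein_change = NA_character_,
                             variant_class = "other", vaf = NA_real_) {
  if (length(sample_id) == 0L) {
    return(data.frame(sample_id = character(0), gene = character(0),
                      chrom = character(0), pos = integer(0),
                      ref_allele = character(0), alt_allele = character(0),
                      protein_change = character(0),
                      variant_class = character(0), vaf = numeric(0),
                      stringsAsFactors = FALSE))
  }
  df <- data.frame(sample_id = as.character(sample_id),
                   gene = as.character(gene),
                   chrom = as.character(chrom),
                   pos = as.integer(pos),
                   ref_allele = toupper(as.character(ref_allele)),
                   alt_allele = toupper(as.character(alt_allele)),
                   protein_change = as.character(protein_change),
                   variant_class = as.character(variant_class),
                   vaf = as.numeric(vaf),
                   stringsAsFactors = FALSE)
  bad_class <- !is.na(df$variant_class) & !df$variant_class %in% VARIANT_CLASSES
  if (any(bad_class)) {
    stop("unknown variant_class: ",
         paste(unique(df$variant_class[bad_class]), collapse = ", "))
  }
  df
}

# Empty allele spellings used by MAF dialects for insertions/deletions.
.blank_allele <- function(x) is.na(x) | x == "" | x == "-" | x == "."

#' Normalize a variant's coordinate representation
#'
#' Reference-free normalization so that MAF- and VCF-style spellings of the
#' same substitution or indel produce the same key: alleles are upper-cased,
#' the shared suffix then the shared prefix of ref/alt are trimmed, and `pos`
#' is advanced by the trimmed prefix length. An allele emptied by trimming is
#' written `-`.
#'
#' @param chrom,pos,ref,alt parallel vectors describing variants.
#' @return data.frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @export
normalize_variant <- function(chrom, pos, ref, alt) {
  ref <- toupper(ifelse(.blank_allele(ref), "", as.character(ref)))
  alt <- toupper(ifelse(.blank_allele(alt), "", as.character(alt)))
  pos <- as.integer(pos)
  n <- length(ref)
  for (i in seq_len(n)) {
    r <- ref[i]; a <- alt[i]
    # trim shared suffix
    while (nchar(r) > 0L && nchar(a) > 0L &&
           substr(r, nchar(r), nchar(r)) == substr(a, nchar(a), nchar(a)) &&
           !(nchar(r) == 1L && nchar(a) == 1L)) {
      r <- substr(r, 1L, nchar(r) - 1L)
      a <- substr(a, 1L, nchar(a) - 1L)
    }
    # trim shared prefix, advancing pos
    while (nchar(r) > 0L && nchar(a) > 0L &&
           substr(r, 1L, 1L) == substr(a, 1L, 1L) &&
           !(nchar(r) == 1L && nchar(a) == 1L)) {
      r <- substr(r, 2L, nchar(r))
      a <- substr(a, 2L, nchar(a))
      pos[i] <- pos[i] + 1L
    }
    ref[i] <- if (nchar(r) == 0L) "-" else r
    alt[i] <- if (nchar(a) == 0L) "-" else a
  }
  data.frame(chrom = as.character(chrom), pos = pos, ref = ref, alt = alt,
             stringsAsFactors = FALSE)
}

#' Canonical identity keys for mutation records
#'
#' Maps each record to a deterministic identity string used for cross-sample
#' matching ("identical mutation" semantics). Two modes:
#' \describe{
#'   \item{genomic}{`chrom:pos:ref:alt` after [normalize_variant()]; records
#'     without coordinates fall back to `gene:protein_change`. Strictest
#'     matching; the default.}
#'   \item{protein}{`gene:protein_change`; records without a protein change
#'     fall back to the genomic key. Enables driver-level matching when only
#'     protein annotations are comparable across call sets.}
#' }
#' Fusions and amplifications are keyed `gene:event_class` in both modes.
#'
#' @param records mutation-record data frame.
#' @param keying_mode `"genomic"` or `"protein"`.
#' @return character vector of keys, `NA` where no identity is derivable.
#' @export
mutation_keys <- function(records, keying_mode = c("genomic", "protein")) {
  keying_mode <- match.arg(keying_mode)
  n <- nrow(records)
  if (n == 0L) return(character(0))
  event <- !is.na(records$variant_class) &
    records$variant_class %in% c("fusion", "amplification")

  has_coord <- !is.na(records$chrom) & !is.na(records$pos) &
    !(.blank_allele(records$ref_allele) & .blank_allele(records$alt_allele))
  has_prot <- !is.na(records$gene) & records$gene != "" &
    !is.na(records$protein_change) & records$protein_change != ""

  genomic <- rep(NA_character_, n)
  if (any(has_coord)) {
    nv <- normalize_variant(records$chrom[has_coord], records$pos[has_coord],
                            records$ref_allele[has_coord],
                            records$alt_allele[has_coord])
    genomic[has_coord] <- paste(nv$chrom, nv$pos, nv$ref, nv$alt, sep = ":")
  }
  protein <- rep(NA_character_, n)
  protein[has_prot] <- paste(records$gene[has_prot],
                             records$protein_change[has_prot], sep = ":")

  keys <- if (keying_mode == "genomic") {
    ifelse(is.na(genomic), protein, genomic)
  } else {
    ifelse(is.na(protein), genomic, protein)
  }
  keys[event] <- paste(records$gene[event], records$variant_class[event],
                       sep = ":")
  keys
}

#' Map mutation keys to gene symbols
#'
#' Driver/passenger rules need the gene behind each key. Returns a named
#' character vector `key -> gene` derived from the records that produced the
#' keys; keys whose records carry no gene annotation map to `NA`.
#'
#' @inheritParams mutation_keys
#' @return named character vector.
#' @export
key_gene_map <- function(records, keying_mode = c("genomic", "protein")) {
  keys <- mutation_keys(records, keying_mode)
  keep <- !is.na(keys) & !duplicated(keys)
  stats::setNames(as.character(records$gene[keep]), keys[keep])
}
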