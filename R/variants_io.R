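# MAF column names accepted for each canonical field (first match wins).
.MAF_COLUMN_MAP <- list(
  sample_id      = c("Tumor_Sample_Barcode", "sample_id", "sample"),
  gene           = c("Hugo_Symbol", "gene"),
  chrom          = c("Chromosome", "chrom"),
  pos            = c("Start_Position", "Start_position", "pos"),
  ref_allele     = c("Reference_Allele", "ref"),
  alt_allele     = c("Tumor_Seq_Allele2", "alt"),
  protein_change = c("HGVSp_Short", "Protein_Change", "protein_change"),
  variant_class  = c("Variant_Classification", "variant_class"),
  vaf            = c("vaf", "t_vaf", "tumor_vaf")
)

# MAF Variant_Classification vocabulary -> internal classes.
.MAF_CLASS_MAP <- c(
  Missense_Mutation = "missense", Nonsense_Mutation = "nonsense",
  Frame_Shift_Del = "frameshift", Frame_Shift_Ins = "frameshift",
  In_Frame_Del = "inframe_indel", In_Frame_Ins = "inframe_indel",
  Splice_Site = "splice", Splice_Region = "splice",
  Silent = "synonymous", Fusion = "fusion", Amplification = "amplification"
)

.map_maf_class <- function(x) {
  out <- unname(.MAF_CLASS_MAP[as.character(x)])
  out[is.na(out) & !is.na(x)] <- ifelse(
    tolower(x[is.na(out) & !is.na(x)]) %in% VARIANT_CLASSES,
    tolower(x[is.na(out) & !is.na(x)]), "other")
  out[is.na(x)] <- "other"
  out
}

.pick_column <- function(header, aliases) {
  hit <- aliases[aliases %in% header]
  if (length(hit) == 0L) NA_character_ else hit[[1L]]
}

#' Read a MAF-style mutation table
#'
#' Reads a tab-delimited mutation table (one somatic mutation per sample per
#' row) into the canonical record frame. Standard MAF headers
#' (`Tumor_Sample_Barcode`, `Hugo_Symbol`, `Chromosome`, `Start_Position`,
#' `Reference_Allele`, `Tumor_Seq_Allele2`, `HGVSp_Short`,
#' `Variant_Classification`) and their lowercase internal aliases are
#' accepted. Rows whose identity cannot be keyed (no coordinates and no
#' gene + protein change) are dropped and counted in the attached load
#' report, `attr(x, "load_report")`.
#'
#' @param path path to a tab-delimited file. Lines starting `#` are skipped.
#' @param keying_mode passed through to the report only; keys themselves are
#'   computed lazily by [mutation_keys()].
#' @return mutation-record data frame with a `load_report` attribute
#'   (`n_rows`, `n_kept`, `n_dropped`).
#' @export
read_maf <- function(path, keying_mode = c("genomic", "protein")) {
  keying_mode <- match.arg(keying_mode)
  if (!file.exists(path)) stop("MAF file not found: ", path)
  raw <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                           check.names = FALSE,
                           colClasses = "character", na.strings = c("NA", ""))
  required <- c("sample_id", "gene", "chrom", "pos", "ref_allele",
                "alt_allele")
  cols <- vapply(.MAF_COLUMN_MAP, .pick_column, character(1),
                 header = names(raw))
  missing_req <- required[is.na(cols[required])]
  if (length(missing_req)) {
    stop("MAF is missing required column(s): ",
         paste(vapply(missing_req,
                      function(f) .MAF_COLUMN_MAP[[f]][1], character(1)),
               collapse = ", "))
  }
  if (nrow(raw) == 0L) {
    warning("empty MAF: ", path)
    rec <- mutation_records(character(0))
    attr(rec, "load_report") <- list(n_rows = 0L, n_kept = 0L, n_dropped = 0L,
                                     keying_mode = keying_mode)
    return(rec)
  }
  field <- function(f) if (is.na(cols[[f]])) NULL else raw[[cols[[f]]]]
  rec <- mutation_records(
    sample_id = raw[[cols[["sample_id"]]]],
    gene = field("gene") %||% NA_character_,
    chrom = field("chrom") %||% NA_character_,
    pos = suppressWarnings(as.integer(field("pos") %||% NA_character_)),
    ref_allele = field("ref_allele") %||% NA_character_,
    alt_allele = field("alt_allele") %||% NA_character_,
    protein_change = field("protein_change") %||% NA_character_,
    variant_class = .map_maf_class(field("variant_class") %||% NA_character_),
    vaf = suppressWarnings(as.numeric(field("vaf") %||% NA_character_)))

  keyable <- !is.na(mutation_keys(rec, keying_mode))
  out <- rec[keyable, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "load_report") <- list(n_rows = nrow(rec), n_kept = sum(keyable),
                                   n_dropped = sum(!keyable),
                                   keying_mode = keying_mode)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write mutation records as a MAF-style table
#'
#' Inverse of [read_maf()]: writes the canonical columns under standard MAF
#' headers so the output round-trips through `read_maf`.
#'
#' @param records mutation-record data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_maf <- function(records, path) {
  class_back <- stats::setNames(names(.MAF_CLASS_MAP), unname(.MAF_CLASS_MAP))
  out <- data.frame(
    Tumor_Sample_Barcode = records$sample_id,
    Hugo_Symbol = records$gene,
    Chromosome = records$chrom,
    Start_Position = records$pos,
    Reference_Allele = records$ref_allele,
    Tumor_Seq_Allele2 = records$alt_allele,
    HGVSp_Short = records$protein_change,
    Variant_Classification = ifelse(
      records$variant_class %in% names(class_back),
      class_back[records$variant_class], records$variant_class),
    vaf = records$vaf,
    stringsAsFactors = FALSE, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read per-lesion variant calls from a VCF
#'
#' Ingests a VCF 4.x file as mutation records for one lesion. Only records
#' with `FILTER` equal to `PASS` or `.` are kept; multi-allelic sites are
#' expanded to one record per ALT allele. Gene and protein annotations are
#' not parsed from INFO (annotation is out of scope), so VCF-derived records
#' key genomically.
#'
#' @param path VCF file path (plain or bgzipped).
#' @param sample_id sample identifier to stamp on every record.
#' @return mutation-record data frame.
#' @export
read_vcf_as_records <- function(path, sample_id) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) return(mutation_records(character(0)))
  pass <- is.na(fix$FILTER) | fix$FILTER %in% c("PASS", ".")
  fix <- fix[pass, , drop = FALSE]
  if (nrow(fix) == 0L) return(mutation_records(character(0)))
  alts <- strsplit(fix$ALT, ",", fixed = TRUE)
  idx <- rep(seq_len(nrow(fix)), lengths(alts))
  mutation_records(
    sample_id = sample_id,
    chrom = fix$CHROM[idx],
    pos = as.integer(fix$POS[idx]),
    ref_allele = fix$REF[idx],
    alt_allele = unlist(alts),
    variant_class = "other")
}

#' Read a patient-to-lesion manifest
#'
#' Tab-delimited manifest with columns `patient_id`, `lesion1_sample`,
#' `lesion2_sample` (exactly two lesions per patient). Extra columns are
#' carried through as metadata.
#'
#' @param path TSV path.
#' @return data.frame, one row per patient.
#' @export
read_manifest <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "lesion1_sample", "lesion2_sample")
  miss <- setdiff(need, names(m))
  if (length(miss)) stop("manifest missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(m$patient_id)) stop("duplicate patient_id in manifest")
  if (any(m$lesion1_sample == m$lesion2_sample)) {
    stop("manifest lists the same sample twice for a patient")
  }
  m
}

#' Collapse one sample's records to a set of mutation keys
#'
#' Duplicate keys collapse (set semantics). Synonymous variants are excluded
#' unless `include_synonymous` is `TRUE`; the clonality analysis follows the
#' convention of counting all somatic alterations, synonymous included, so
#' the pipeline default is `TRUE`.
#'
#' @param records mutation-record data frame.
#' @param sample_id which sample to extract; `NULL` uses all records.
#' @param include_synonymous keep synonymous variants?
#' @param keying_mode see [mutation_keys()].
#' @return character vector of unique keys.
#' @export
mutation_set <- function(records, sample_id = NULL, include_synonymous = TRUE,
                         keying_mode = c("genomic", "protein")) {
  keying_mode <- match.arg(keying_mode)
  if (!is.null(sample_id)) {
    records <- records[records$sample_id == sample_id, , drop = FALSE]
  }
  if (!include_synonymous) {
    records <- records[is.na(records$variant_class) |
                         records$variant_class != "synonymous", , drop = FALSE]
  }
  keys <- mutation_keys(records, keying_mode)
  unique(keys[!is.na(keys)])
}

#' Per-sample mutation sets for a whole cohort
#'
#' @inheritParams mutation_set
#' @param sample_ids samples to include; defaults to all present. Samples
#'   with no records yield empty sets (a lesion may have no detected
#'   mutations).
#' @return named list `sample_id -> character vector of keys`.
#' @export
mutation_sets <- function(records, sample_ids = NULL,
                          include_synonymous = TRUE,
                          keying_mode = c("genomic", "protein")) {
  keying_mode <- match.arg(keying_mode)
  if (is.null(sample_ids)) sample_ids <- unique(records$sample_id)
  stats::setNames(lapply(sample_ids, function(s) {
    mutation_set(records, s, include_synonymous, keying_mode)
  }), sample_ids)
}
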