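#' @importFrom rlang .data %||%
#' @importFrom tibble tibble as_tibble
NULL

TAIL_CLASSES <- c("none", "monoA", "oligoA", "monoU", "oligoU", "U_then_A", "other")
CALL_STATUSES <- c("called", "no_adapter", "unmatched", "ambiguous_ref")
REF_CLASSES <- c("miRNA", "snRNA")
ARM_ROLES <- c("guide", "passenger", "none")

#' Normalize a nucleotide string to the RNA alphabet
#'
#' Uppercases and converts T to U. References typically come from DNA
#' genome assemblies while the molecules analysed are RNA, so both
#' alphabets are accepted on input and everything is stored as ACGU.
#'
#' @param x Character vector of sequences.
#' @return Character vector over ACGU.
#' @export
normalize_rna <- function(x) {
  chartr("t", "u", chartr("T", "U", toupper(x)))
}

assert_rna_alphabet <- function(x, what, ids = NULL) {
  bad <- which(!grepl("^[ACGU]*$", x))
  if (length(bad)) {
    label <- if (is.null(ids)) bad[1] else ids[bad[1]]
    stop(sprintf("%s for record '%s' contains characters outside ACGU(T)", what, label),
         call. = FALSE)
  }
  invisible(x)
}

#' Build a validated reference set from in-memory vectors
#'
#' A reference set is a tibble with one row per small RNA: its mature
#' sequence (5'->3'), the genomic bases immediately 3' of the canonical
#' end (`downstream_seq`, used to decide whether a 3'-terminal base is
#' templated or added), an optional Lsm-boundary offset for snRNAs
#' (the end offset whose position is labelled "+1U"), and optional
#' guide/passenger pairing.
#'
#' End offsets throughout the package are relative to the canonical 3'
#' end: offset 0 is the last base of `mature_seq`, offset +k is the k-th
#' base of `downstream_seq`, negative offsets are trimmed ends.
#'
#' @param ref_id Character vector of unique identifiers.
#' @param ref_class "miRNA" or "snRNA", recycled.
#' @param mature_seq Mature sequences (ACGU or ACGT; at least 15 nt).
#' @param downstream_seq Genomic context 3' of the canonical end
#'   (>= 8 nt recommended).
#' @param boundary_offset Integer or NA; for snRNA, the end offset of the
#'   "+1U" position adjacent to the Lsm2-8 site.
#' @param partner_id Identifier of the paired arm, or NA.
#' @param arm_role "guide", "passenger" or "none".
#' @return A tibble with class `rnatails_refs`.
#' @export
#' @examples
#' reference_set("mirX", "miRNA", "ACGUACGUACGUACGUACG", "AAGG")
reference_set <- function(ref_id, ref_class, mature_seq, downstream_seq,
                          boundary_offset = NA_integer_, partner_id = NA_character_,
                          arm_role = "none") {
  refs <- tibble(
    ref_id = as.character(ref_id),
    ref_class = as.character(ref_class),
    mature_seq = normalize_rna(mature_seq),
    downstream_seq = normalize_rna(downstream_seq),
    boundary_offset = as.integer(boundary_offset),
    partner_id = as.character(partner_id),
    arm_role = as.character(arm_role)
  )
  validate_reference_set(refs)
}

validate_reference_set <- function(refs) {
  if (anyDuplicated(refs$ref_id)) {
    stop("duplicate ref_id: ", refs$ref_id[duplicated(refs$ref_id)][1], call. = FALSE)
  }
  if (!all(refs$ref_class %in% REF_CLASSES)) {
    stop("ref_class must be one of: ", paste(REF_CLASSES, collapse = ", "), call. = FALSE)
  }
  if (!all(refs$arm_role %in% ARM_ROLES)) {
    stop("arm_role must be one of: ", paste(ARM_ROLES, collapse = ", "), call. = FALSE)
  }
  assert_rna_alphabet(refs$mature_seq, "mature_seq", refs$ref_id)
  assert_rna_alphabet(refs$downstream_seq, "downstream_seq", refs$ref_id)
  short <- nchar(refs$mature_seq) < 15
  if (any(short)) {
    stop("mature_seq shorter than 15 nt for record '", refs$ref_id[short][1], "'",
         call. = FALSE)
  }
  has_partner <- !is.na(refs$partner_id)
  if (any(has_partner)) {
    missing <- !(refs$partner_id[has_partner] %in% refs$ref_id)
    if (any(missing)) {
      stop("partner_id '", refs$partner_id[has_partner][missing][1],
           "' does not refer to an existing record", call. = FALSE)
    }
    idx <- match(refs$partner_id[has_partner], refs$ref_id)
    back <- refs$partner_id[idx]
    sym <- !is.na(back) & back == refs$ref_id[has_partner]
    if (!all(sym)) {
      stop("partner pairing is not symmetric for record '",
           refs$ref_id[has_partner][!sym][1], "'", call. = FALSE)
    }
  }
  class(refs) <- unique(c("rnatails_refs", class(refs)))
  refs
}

#' Load a reference set from FASTA plus annotation TSV
#'
#' The FASTA holds the mature sequences; the annotation TSV carries one
#' row per FASTA record with columns `ref_id`, `ref_class`,
#' `downstream_seq`, `boundary_offset` (empty allowed), `partner_id`
#' (empty allowed) and `arm_role`. T is accepted on input and stored
#' as U.
#'
#' @param fasta_path Path to the mature-sequence FASTA.
#' @param annotation_path Path to the annotation TSV.
#' @return A validated reference tibble (see [reference_set()]).
#' @export
load_reference_set <- function(fasta_path, annotation_path) {
  seqs <- Biostrings::readBStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  ann <- readr::read_tsv(
    annotation_path,
    col_types = readr::cols(
      ref_id = readr::col_character(),
      ref_class = readr::col_character(),
      downstream_seq = readr::col_character(),
      boundary_offset = readr::col_integer(),
      partner_id = readr::col_character(),
      arm_role = readr::col_character()
    ),
    progress = FALSE
  )
  absent <- setdiff(ids, ann$ref_id)
  if (length(absent)) {
    stop("no annotation row for FASTA record '", absent[1], "'", call. = FALSE)
  }
  ann <- ann[match(ids, ann$ref_id), ]
  reference_set(
    ref_id = ids,
    ref_class = ann$ref_class,
    mature_seq = unname(as.character(seqs)),
    downstream_seq = ann$downstream_seq,
    boundary_offset = ann$boundary_offset,
    partner_id = ann$partner_id,
    arm_role = ann$arm_role
  )
}

#' Write a reference set to FASTA plus annotation TSV
#'
#' @param refs Reference tibble from [reference_set()].
#' @param fasta_path,annotation_path Output paths.
#' @return Invisibly, `refs`.
#' @export
write_reference_set <- function(refs, fasta_path, annotation_path) {
  seqs <- Biostrings::BStringSet(stats::setNames(refs$mature_seq, refs$ref_id))
  Biostrings::writeXStringSet(seqs, fasta_path)
  readr::write_tsv(
    refs[, c("ref_id", "ref_class", "downstream_seq", "boundary_offset",
             "partner_id", "arm_role")],
    annotation_path, progress = FALSE
  )
  invisible(refs)
}

#' Load small-RNA reads from FASTQ
#'
#' Returns one row per read with the sequence normalized to the RNA
#' alphabet; qualities are carried through unused by the caller.
#'
#' @param fastq_path Path to a FASTQ file (4-line records).
#' @return Tibble with columns `read_id`, `seq`, `qual`.
#' @export
load_reads <- function(fastq_path) {
  seqs <- Biostrings::readBStringSet(fastq_path, format = "fastq", with.qualities = TRUE)
  quals <- S4Vectors::mcols(seqs)$qualities
  tibble(
    read_id = sub("\\s.*$", "", names(seqs)),
    seq = unname(normalize_rna(as.character(seqs))),
    qual = if (is.null(quals)) NA_character_ else unname(as.character(quals))
  )
}

#' Write reads to FASTQ
#'
#' @param reads Tibble with `read_id`, `seq` and optionally `qual`
#'   (defaults to uniform "I" when absent).
#' @param fastq_path Output path.
#' @return Invisibly, `fastq_path`.
#' @export
write_reads <- function(reads, fastq_path) {
  qual <- if ("qual" %in% names(reads) && !anyNA(reads$qual)) {
    reads$qual
  } else {
    strrep("I", nchar(reads$seq))
  }
  seqs <- Biostrings::BStringSet(stats::setNames(reads$seq, reads$read_id))
  Biostrings::writeXStringSet(
    seqs, fastq_path, format = "fastq",
    qualities = Biostrings::BStringSet(qual)
  )
  invisible(fastq_path)
}

#' Read and write tail-call tables
#'
#' Tail calls round-trip through TSV with a fixed column order:
#' `read_id`, `ref_id`, `end_offset`, `tail_seq`, `tail_class`,
#' `n_mismatch`, `status`. Integer fields are exact; the empty tail is
#' written as an empty cell and restored as `""`.
#'
#' @param calls Tibble of tail calls (see [call_sample()]).
#' @param path TSV path.
#' @return `write_tail_calls()` returns `calls` invisibly;
#'   `read_tail_calls()` returns the tibble.
#' @export
write_tail_calls <- function(calls, path) {
  cols <- c("read_id", "ref_id", "end_offset", "tail_seq", "tail_class",
            "n_mismatch", "status")
  readr::write_tsv(calls[, cols], path, na = "", progress = FALSE)
  invisible(calls)
}

#' @rdname write_tail_calls
#' @export
read_tail_calls <- function(path) {
  out <- readr::read_tsv(
    path,
    col_types = readr::cols(
      read_id = readr::col_character(),
      ref_id = readr::col_character(),
      end_offset = readr::col_integer(),
      tail_seq = readr::col_character(),
      tail_class = readr::col_character(),
      n_mismatch = readr::col_integer(),
      status = readr::col_character()
    ),
    na = "", progress = FALSE
  )
  # empty tail and missing tail are both written as an empty cell; a tail
  # that was never called is the empty string by convention
  out$tail_seq[is.na(out$tail_seq)] <- ""
  out
}

#' Read and write 3'-end profile tables
#'
#' Profiles round-trip through TSV with columns `ref_id`, `sample_id`,
#' `end_offset`, `tail_class`, `tail_len`, `count`, `fraction`;
#' fractions are written with six decimal places.
#'
#' @param profile Profile tibble from [build_profile()].
#' @param path TSV path.
#' @return `write_profile()` returns `profile` invisibly;
#'   `read_profile()` the tibble.
#' @export
write_profile <- function(profile, path) {
  out <- profile[, c("ref_id", "sample_id", "end_offset", "tail_class",
                     "tail_len", "count", "fraction")]
  out$fraction <- sprintf("%.6f", out$fraction)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(profile)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  readr::read_tsv(
    path,
    col_types = readr::cols(
      ref_id = readr::col_character(),
      sample_id = readr::col_character(),
      end_offset = readr::col_integer(),
      tail_class = readr::col_character(),
      tail_len = readr::col_integer(),
      count = readr::col_integer(),
      fraction = readr::col_double()
    ),
    progress = FALSE
  )
}

#' Read and write count tables
#'
#' Count tables are wide: a `ref_id` column plus one nonnegative integer
#' column per sample, with unique row and column labels.
#'
#' @param counts Wide tibble (`ref_id` + sample columns).
#' @param path TSV path.
#' @return `write_count_table()` returns `counts` invisibly;
#'   `read_count_table()` the validated tibble.
#' @export
write_count_table <- function(counts, path) {
  readr::write_tsv(counts, path, progress = FALSE)
  invisible(counts)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path) {
  counts <- readr::read_tsv(path, col_types = readr::cols(
    ref_id = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  validate_count_table(counts)
}

validate_count_table <- function(counts) {
  if (anyDuplicated(counts$ref_id)) {
    stop("duplicate ref_id in count table", call. = FALSE)
  }
  num <- counts[setdiff(names(counts), "ref_id")]
  if (anyDuplicated(names(num))) stop("duplicate sample columns", call. = FALSE)
  if (any(vapply(num, function(x) any(x < 0, na.rm = TRUE), logical(1)))) {
    stop("count table contains negative cells", call. = FALSE)
  }
  counts
}
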