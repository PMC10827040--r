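#' Default 3' adapter sequence
#'
#' The standard small-RNA 3' ligation adapter (TruSeq small RNA layout),
#' in the RNA alphabet.
#'
#' @return A single string.
#' @export
default_adapter <- function() "UGGAAUUCUCGGGUGCCAAGG"

# character matrix with one row per sequence, NA beyond each sequence end
seq_char_matrix <- function(x, width = max(nchar(x), 1L)) {
  m <- matrix(NA_character_, length(x), width)
  for (j in seq_len(width)) {
    cj <- substr(x, j, j)
    cj[cj == ""] <- NA_character_
    m[, j] <- cj
  }
  m
}

#' Classify a non-templated tail sequence
#'
#' Every tail string maps to exactly one class: `none` (empty), `monoA`
#' ("A"), `oligoA` (two or more A), `monoU`, `oligoU`, `U_then_A`
#' (one or more U followed by one or more A, the oUA substrate layout),
#' and `other` for any remaining nonempty tail.
#'
#' @param tails Character vector of tail sequences (ACGU).
#' @return Character vector of tail classes.
#' @export
#' @examples
#' classify_tails(c("", "A", "AAA", "UUA", "GA"))
classify_tails <- function(tails) {
  out <- rep("other", length(tails))
  out[tails == ""] <- "none"
  out[tails == "A"] <- "monoA"
  out[tails == "U"] <- "monoU"
  out[grepl("^A{2,}$", tails)] <- "oligoA"
  out[grepl("^U{2,}$", tails)] <- "oligoU"
  out[grepl("^U+A+$", tails)] <- "U_then_A"
  out
}

#' Trim the 3' adapter from reads
#'
#' Scans each read 5'->3' for the earliest occurrence of an adapter
#' prefix of at least `min_overlap` bases with at most `max_mismatch`
#' substitutions, considering match start positions at or after read
#' position 15 (so at least 14 insert bases are kept). When the read
#' ends before any adapter-like suffix is found, the full read is
#' returned with status `no_adapter`; such reads remain eligible for
#' tail calling but stay flagged.
#'
#' @param reads Character vector of read sequences (RNA or DNA alphabet).
#' @param adapter_seq Adapter sequence; see [default_adapter()].
#' @param min_overlap Minimum adapter prefix length to accept a match.
#' @param max_mismatch Maximum substitutions tolerated in the match.
#' @return Tibble with columns `insert`, `status` (`called`/`no_adapter`)
#'   and `trim_at` (1-based adapter start, NA when not found).
#' @export
trim_adapter <- function(reads, adapter_seq = default_adapter(),
                         min_overlap = 6, max_mismatch = 1) {
  adapter_seq <- normalize_rna(adapter_seq)
  alen <- nchar(adapter_seq)
  if (alen < min_overlap) {
    stop("adapter_seq must be at least min_overlap bases long", call. = FALSE)
  }
  seqs <- normalize_rna(reads)
  n <- length(seqs)
  lens <- nchar(seqs)
  lmax <- max(lens, 1L)
  cm <- seq_char_matrix(seqs, lmax)
  avec <- strsplit(adapter_seq, "")[[1]]
  trim_at <- rep(NA_integer_, n)
  first_p <- 15L
  if (lmax >= first_p) {
    for (p in first_p:lmax) {
      pending <- is.na(trim_at)
      if (!any(pending)) break
      jmax <- min(alen, lmax - p + 1L)
      block <- cm[, p:(p + jmax - 1L), drop = FALSE]
      ref_block <- matrix(avec[seq_len(jmax)], n, jmax, byrow = TRUE)
      mism <- rowSums(block != ref_block, na.rm = TRUE)
      overlap <- rowSums(!is.na(block))
      hit <- pending & overlap >= min_overlap & mism <= max_mismatch
      trim_at[hit] <- p
    }
  }
  tibble(
    insert = ifelse(is.na(trim_at), seqs, substr(seqs, 1L, trim_at - 1L)),
    status = ifelse(is.na(trim_at), "no_adapter", "called"),
    trim_at = trim_at
  )
}

# Maximal templated decomposition of inserts against mature + downstream.
#
# Returns, per insert, the matched templated length expressed as an end
# offset (matched length - mature length), the remaining suffix as the
# tail, mismatches used, and whether the match reaches at least 3 bases
# short of the canonical end. Mismatches are permitted only in the
# mature body (never in the templated extension), never within the
# final 4 matched bases, and at most `max_mismatch` in total: boundary
# determination must be exact or calls are untrustworthy.
decompose_inserts <- function(inserts, mature_seq, downstream_seq, max_mismatch = 1) {
  template <- paste0(mature_seq, downstream_seq)
  mlen <- nchar(mature_seq)
  tlen <- nchar(template)
  tvec <- strsplit(template, "")[[1]]
  n <- length(inserts)
  lens <- nchar(inserts)
  w <- min(max(lens, 1L), tlen)
  cm <- seq_char_matrix(inserts, w)
  mism <- cm != matrix(tvec[seq_len(w)], n, w, byrow = TRUE)
  maxm <- pmin(lens, tlen)
  end_offset <- integer(n)
  nm <- integer(n)
  matched <- logical(n)
  for (i in seq_len(n)) {
    mi <- maxm[i]
    mm <- which(mism[i, seq_len(mi)])
    m <- mi
    repeat {
      used <- mm[mm <= m]
      if (length(used) > max_mismatch) {
        m <- used[max_mismatch + 1L] - 1L
        next
      }
      bad <- used[used > mlen | used > m - 4L]
      if (length(bad)) {
        m <- min(bad) - 1L
        next
      }
      break
    }
    end_offset[i] <- m - mlen
    nm[i] <- sum(mm <= m)
    matched[i] <- m >= mlen - 3L
  }
  tibble(
    end_offset = end_offset,
    tail_seq = substring(inserts, mlen + end_offset + 1L),
    n_mismatch = nm,
    matched = matched
  )
}

#' Call the non-templated tail of adapter-trimmed inserts
#'
#' Decomposes each insert into a templated body and a non-templated 3'
#' tail against one reference. The templated body is the maximal prefix
#' matching `mature_seq` then `downstream_seq`: a 3'-terminal base that
#' could be either genomic or added is always counted genomic, so a read
#' ending one templated base past the canonical end (the GUG vs GUGA
#' situation, where the genome encodes an A after the mature end) is
#' reported as a templated extension (`end_offset` +1, no tail), and
#' only additional bases beyond the templated context become the tail.
#' Trimmed species up to 3 bases short of the canonical end are called
#' with negative `end_offset`; anything shorter is `unmatched`.
#'
#' @param insert Character vector of adapter-trimmed insert sequences.
#' @param ref One-row reference tibble (see [reference_set()]).
#' @param max_mismatch Substitutions tolerated in the mature body; none
#'   are ever allowed in the templated extension or the final 4 matched
#'   bases.
#' @return Tibble with `ref_id`, `end_offset`, `tail_seq`, `tail_class`,
#'   `n_mismatch`, `status`.
#' @export
#' @examples
#' ref <- reference_set("mir", "miRNA", "UCCCUGAGACCCUUUAACCUGUG", "AUUUCGCC")
#' call_tail(c(
#'   "UCCCUGAGACCCUUUAACCUGUG",     # canonical end
#'   "UCCCUGAGACCCUUUAACCUGUGA",    # templated A: genomic, offset +1
#'   "UCCCUGAGACCCUUUAACCUGUGAAA"   # first A templated, then an AA tail
#' ), ref)
call_tail <- function(insert, ref, max_mismatch = 1) {
  stopifnot(nrow(ref) == 1)
  insert <- normalize_rna(insert)
  d <- decompose_inserts(insert, ref$mature_seq, ref$downstream_seq, max_mismatch)
  ok <- d$matched & nchar(insert) >= 15L
  tibble(
    ref_id = ifelse(ok, ref$ref_id, NA_character_),
    end_offset = ifelse(ok, d$end_offset, NA_integer_),
    tail_seq = ifelse(ok, d$tail_seq, ""),
    tail_class = ifelse(ok, classify_tails(d$tail_seq), NA_character_),
    n_mismatch = ifelse(ok, d$n_mismatch, NA_integer_),
    status = ifelse(ok, "called", "unmatched")
  )
}

# longest exact 5'-anchored match of each insert against each reference
assign_references <- function(inserts, refs, min_anchor = 10) {
  n <- length(inserts)
  nref <- nrow(refs)
  w <- max(nchar(inserts), 1L)
  cm <- seq_char_matrix(inserts, w)
  lcp <- matrix(0L, n, nref)
  for (r in seq_len(nref)) {
    mvec <- strsplit(refs$mature_seq[r], "")[[1]]
    jmax <- min(length(mvec), w)
    alive <- rep(TRUE, n)
    cur <- integer(n)
    for (j in seq_len(jmax)) {
      alive <- alive & !is.na(cm[, j]) & cm[, j] == mvec[j]
      if (!any(alive)) break
      cur[alive] <- j
    }
    lcp[, r] <- cur
  }
  best <- max.col(lcp, ties.method = "first")
  best_len <- lcp[cbind(seq_len(n), best)]
  n_best <- rowSums(lcp == matrix(best_len, n, nref))
  tibble(
    ref_idx = best,
    anchor_len = best_len,
    ambiguous = n_best > 1L & best_len >= min_anchor,
    unmatched = best_len < min_anchor
  )
}

#' Call tails for a whole sample
#'
#' Runs the full per-sample pipeline: adapter trimming, assignment of
#' each insert to the reference with the longest exact 5'-anchored
#' match, and maximal-templated tail decomposition. Reads tying between
#' references get status `ambiguous_ref` and are excluded from
#' downstream profiles; reads matching no reference 5' end are
#' `unmatched`; reads without a recognizable adapter are still called
#' but keep status `no_adapter`.
#'
#' @param reads Tibble with `read_id` and `seq` (see [load_reads()]), or
#'   a character vector of read sequences.
#' @param refs Reference tibble from [reference_set()].
#' @param adapter_seq 3' adapter to trim; see [default_adapter()].
#' @param max_mismatch Substitutions tolerated in the mature body.
#' @param min_anchor Minimum exact 5' match length for assignment.
#' @return Tibble of tail calls (`read_id`, `ref_id`, `end_offset`,
#'   `tail_seq`, `tail_class`, `n_mismatch`, `status`), with a
#'   `status_counts` attribute; see [status_summary()].
#' @export
call_sample <- function(reads, refs, adapter_seq = default_adapter(),
                        max_mismatch = 1, min_anchor = 10) {
  if (nrow(refs) == 0) stop("empty reference set", call. = FALSE)
  if (is.character(reads)) {
    reads <- tibble(read_id = paste0("read", seq_along(reads)), seq = reads)
  }
  n <- nrow(reads)
  seqs <- normalize_rna(reads$seq)
  tr <- trim_adapter(seqs, adapter_seq)
  asg <- assign_references(tr$insert, refs, min_anchor = min_anchor)

  ref_id <- rep(NA_character_, n)
  end_offset <- rep(NA_integer_, n)
  tail_seq <- rep("", n)
  tail_class <- rep(NA_character_, n)
  n_mismatch <- rep(NA_integer_, n)
  status <- tr$status
  status[asg$unmatched | nchar(tr$insert) < 15L] <- "unmatched"
  status[asg$ambiguous] <- "ambiguous_ref"

  callable <- status %in% c("called", "no_adapter")
  for (r in unique(asg$ref_idx[callable])) {
    idx <- which(callable & asg$ref_idx == r)
    d <- decompose_inserts(tr$insert[idx], refs$mature_seq[r],
                           refs$downstream_seq[r], max_mismatch)
    good <- d$matched & nchar(tr$insert[idx]) >= 15L
    hit <- idx[good]
    ref_id[hit] <- refs$ref_id[r]
    end_offset[hit] <- d$end_offset[good]
    tail_seq[hit] <- d$tail_seq[good]
    n_mismatch[hit] <- d$n_mismatch[good]
    status[idx[!good]] <- "unmatched"
  }
  tail_class[!is.na(ref_id)] <- classify_tails(tail_seq[!is.na(ref_id)])

  calls <- tibble(
    read_id = reads$read_id,
    ref_id = ref_id,
    end_offset = end_offset,
    tail_seq = tail_seq,
    tail_class = tail_class,
    n_mismatch = n_mismatch,
    status = status
  )
  attr(calls, "status_counts") <- status_summary(calls)
  calls
}

#' Summarize call statuses
#'
#' @param calls Tail-call tibble from [call_sample()].
#' @return Tibble with one row per status and its read count.
#' @export
status_summary <- function(calls) {
  out <- dplyr::count(calls, .data$status, name = "n_reads")
  missing <- setdiff(CALL_STATUSES, out$status)
  if (length(missing)) {
    out <- dplyr::bind_rows(out, tibble(status = missing, n_reads = 0L))
  }
  dplyr::arrange(out, match(.data$status, CALL_STATUSES))
}
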