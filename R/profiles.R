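#' Aggregate tail calls into a per-reference 3'-end profile
#'
#' Builds the joint distribution over (end offset, tail class, tail
#' length) from called reads, the histogram behind per-reference 3'-end
#' bar plots. Only calls with status `called` contribute; counts are
#' conserved exactly and fractions are computed within each reference.
#'
#' @param calls Tail-call tibble (see [call_sample()]).
#' @param sample_id Label stored in the profile.
#' @return Profile tibble with columns `ref_id`, `sample_id`,
#'   `end_offset`, `tail_class`, `tail_len`, `count`, `fraction`. An
#'   empty input yields a zero-row profile (no division is attempted).
#' @export
build_profile <- function(calls, sample_id = "sample") {
  called <- dplyr::filter(calls, .data$status == "called")
  if (nrow(called) == 0) {
    return(tibble(
      ref_id = character(), sample_id = character(),
      end_offset = integer(), tail_class = character(),
      tail_len = integer(), count = integer(), fraction = double()
    ))
  }
  called |>
    dplyr::mutate(tail_len = nchar(.data$tail_seq)) |>
    dplyr::count(.data$ref_id, .data$end_offset, .data$tail_class,
                 .data$tail_len, name = "count") |>
    dplyr::group_by(.data$ref_id) |>
    dplyr::mutate(fraction = .data$count / sum(.data$count)) |>
    dplyr::ungroup() |>
    dplyr::mutate(sample_id = sample_id, .after = "ref_id") |>
    dplyr::arrange(.data$ref_id, .data$end_offset, .data$tail_class)
}

#' Default tail categories for profile summaries
#'
#' Maps profile rows to the categories used in 3'-end figures:
#' `genomic` (no tail), `monoA`, `oligoA`, `U_containing` (any tail
#' with a U: monoU, oligoU, U-then-A) and `other`.
#'
#' @param profile Profile tibble (or any tibble with a `tail_class`
#'   column).
#' @return Character vector of categories, one per row.
#' @export
tail_category <- function(profile) {
  dplyr::case_match(
    profile$tail_class,
    "none" ~ "genomic",
    "monoA" ~ "monoA",
    "oligoA" ~ "oligoA",
    c("monoU", "oligoU", "U_then_A") ~ "U_containing",
    .default = "other"
  )
}

#' Binary adenylation categories
#'
#' Marks rows whose tail contains at least one non-templated A
#' (mono-A, oligo-A or U-then-A) as `adenylated`.
#'
#' @inheritParams tail_category
#' @return Character vector of categories, one per row.
#' @export
adenylated_category <- function(profile) {
  ifelse(profile$tail_class %in% c("monoA", "oligoA", "U_then_A"),
         "adenylated", "not_adenylated")
}

#' Summarize a 3'-end profile
#'
#' Three views of one reference's profile:
#' * `"tail"`: fractions per tail category (see [tail_category()]).
#' * `"endpos"`: the distribution over templated end offsets; for an
#'   snRNA with a known Lsm-boundary offset the positions are labelled
#'   `+1U`, `+2U`, ... so the base adjacent to the Lsm site is `+1U`.
#' * `"adenylated_inclusive"`: counts the templated single-A extension
#'   (end offset +1 where the templated base is an A, no tail) together
#'   with non-templated A tails as one `A_ended` category - the view in
#'   which a genomically encoded terminal A is treated as functionally
#'   adenylated.
#'
#' @param profile Profile tibble restricted to one reference.
#' @param mode One of `"tail"`, `"endpos"`, `"adenylated_inclusive"`.
#' @param ref Optional one-row reference tibble; required for
#'   `adenylated_inclusive` (supplies the downstream base) and used for
#'   `+nU` labels in `endpos` mode.
#' @return Tibble of categories with `count` and `fraction`.
#' @export
summarize_profile <- function(profile, mode = c("tail", "endpos",
                                                "adenylated_inclusive"),
                              ref = NULL) {
  mode <- match.arg(mode)
  if (nrow(profile) == 0) stop("empty profile", call. = FALSE)
  if (dplyr::n_distinct(profile$ref_id) > 1) {
    stop("summarize_profile expects a single-reference profile", call. = FALSE)
  }
  total <- sum(profile$count)
  if (mode == "tail") {
    out <- profile |>
      dplyr::mutate(category = tail_category(profile)) |>
      dplyr::count(.data$category, wt = .data$count, name = "count")
  } else if (mode == "endpos") {
    out <- profile |>
      dplyr::count(.data$end_offset, wt = .data$count, name = "count") |>
      dplyr::arrange(.data$end_offset)
    b <- if (!is.null(ref)) ref$boundary_offset[1] else NA_integer_
    out$label <- if (!is.na(b)) {
      ifelse(out$end_offset - b + 1L >= 1L,
             sprintf("+%dU", out$end_offset - b + 1L),
             sprintf("%+d", out$end_offset))
    } else {
      sprintf("%+d", out$end_offset)
    }
    out <- out[, c("end_offset", "label", "count")]
  } else {
    if (is.null(ref)) {
      stop("adenylated_inclusive mode needs the reference record", call. = FALSE)
    }
    templated_a <- profile$tail_class == "none" & profile$end_offset == 1L &
      substr(ref$downstream_seq[1], 1, 1) == "A"
    category <- dplyr::case_when(
      templated_a ~ "A_ended",
      profile$tail_class %in% c("monoA", "oligoA", "U_then_A") ~ "A_ended",
      profile$tail_class == "none" ~ "genomic",
      profile$tail_class %in% c("monoU", "oligoU") ~ "U_containing",
      .default = "other"
    )
    out <- profile |>
      dplyr::mutate(category = category) |>
      dplyr::count(.data$category, wt = .data$count, name = "count")
  }
  out$fraction <- out$count / total
  out
}

#' A-tail length histogram
#'
#' Length distribution of pure A tails (mono-A and oligo-A) in a
#' profile; the A-run length of mixed U-then-A tails is not recoverable
#' from the (class, length) cells and those tails are excluded. Lengths
#' beyond `cap` are pooled into a `"cap+"` bin.
#'
#' @param profile Profile tibble.
#' @param cap Longest length reported individually.
#' @return Tibble with `a_len` (character label), `count` and
#'   `fraction` of A-tailed reads.
#' @export
tail_length_histogram <- function(profile, cap = 10) {
  a <- dplyr::filter(profile, .data$tail_class %in% c("monoA", "oligoA"))
  if (nrow(a) == 0) {
    return(tibble(a_len = character(), count = integer(), fraction = double()))
  }
  out <- a |>
    dplyr::mutate(a_len = ifelse(.data$tail_len >= cap, paste0(cap, "+"),
                                 as.character(.data$tail_len))) |>
    dplyr::count(.data$a_len, wt = .data$count, name = "count") |>
    dplyr::arrange(suppressWarnings(as.numeric(sub("\\+$", "", .data$a_len))))
  out$fraction <- out$count / sum(out$count)
  out
}

welch_p <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) return(NA_real_)
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (isTRUE(all.equal(mean(x), mean(y)))) {
      warning("zero variance in both conditions with equal means; p = 1",
              call. = FALSE)
      return(1)
    }
    warning("zero variance in both conditions with unequal means; p unavailable",
            call. = FALSE)
    return(NA_real_)
  }
  stats::t.test(x, y)$p.value
}

#' Compare per-category 3'-end fractions between two conditions
#'
#' Computes per-replicate category fractions (replicates are the
#' distinct `sample_id` values within each profile tibble), then per
#' category the replicate mean and SD in each condition, the difference
#' of means, and a Welch two-sided t-test on the replicate fractions.
#' The experimental design this mirrors reports category fractions as
#' mean +/- SD over biological replicates; the Welch test is this
#' package's choice of formal comparison.
#'
#' @param profiles_a,profiles_b Profile tibbles for the two conditions,
#'   each holding one reference and >= 1 replicate (`sample_id`).
#' @param categories Function mapping profile rows to category labels;
#'   see [tail_category()] and [adenylated_category()].
#' @param adjust Apply Benjamini-Hochberg correction across categories
#'   (off by default).
#' @return Tibble with `category`, `mean_a`, `sd_a`, `mean_b`, `sd_b`,
#'   `diff` (B - A) and `p_value`. With a single replicate per
#'   condition, SD and p are NA.
#' @export
compare_conditions <- function(profiles_a, profiles_b,
                               categories = tail_category, adjust = FALSE) {
  frac_by_rep <- function(profiles) {
    profiles |>
      dplyr::mutate(category = categories(profiles)) |>
      dplyr::group_by(.data$sample_id, .data$category) |>
      dplyr::summarise(count = sum(.data$count), .groups = "drop_last") |>
      dplyr::mutate(fraction = .data$count / sum(.data$count)) |>
      dplyr::ungroup()
  }
  fa <- frac_by_rep(profiles_a)
  fb <- frac_by_rep(profiles_b)
  cats <- sort(unique(c(fa$category, fb$category)))
  fill <- function(f) {
    tidyr::complete(f, sample_id = unique(f$sample_id), category = cats,
                    fill = list(count = 0L, fraction = 0))
  }
  fa <- fill(fa)
  fb <- fill(fb)
  single <- dplyr::n_distinct(fa$sample_id) < 2 || dplyr::n_distinct(fb$sample_id) < 2
  if (single) {
    warning("single replicate in a condition: SD and p-value unavailable",
            call. = FALSE)
  }
  out <- purrr::map_dfr(cats, function(ct) {
    x <- fa$fraction[fa$category == ct]
    y <- fb$fraction[fb$category == ct]
    tibble(
      category = ct,
      mean_a = mean(x),
      sd_a = if (length(x) > 1) stats::sd(x) else NA_real_,
      mean_b = mean(y),
      sd_b = if (length(y) > 1) stats::sd(y) else NA_real_,
      diff = mean(y) - mean(x),
      p_value = welch_p(x, y)
    )
  })
  if (adjust) out$p_value <- stats::p.adjust(out$p_value, method = "BH")
  out
}

#' Counts-per-million normalization
#'
#' @param counts Wide count tibble (`ref_id` plus sample columns) with
#'   positive column totals.
#' @return Tibble of the same shape with each sample column scaled to
#'   sum to 1e6.
#' @export
cpm_normalize <- function(counts) {
  counts <- validate_count_table(counts)
  samp <- setdiff(names(counts), "ref_id")
  totals <- vapply(counts[samp], sum, numeric(1))
  if (any(totals <= 0)) stop("column totals must be > 0", call. = FALSE)
  counts[samp] <- purrr::map2(counts[samp], totals, function(x, tot) x / tot * 1e6)
  counts
}

#' Per-reference log2 fold change between two conditions
#'
#' Fold changes are computed on the CPM scale with a pseudocount to
#' avoid log of zero for dropout references:
#' `log2((mean_b + pc) / (mean_a + pc))`.
#'
#' @param norm_table CPM-normalized table from [cpm_normalize()].
#' @param cond_a_cols,cond_b_cols Column names of the two conditions.
#' @param pseudocount Added to both means before the ratio.
#' @return Tibble with `ref_id`, `mean_a`, `mean_b`, `log2fc`.
#' @export
log2fc <- function(norm_table, cond_a_cols, cond_b_cols, pseudocount = 0.5) {
  mean_a <- rowMeans(norm_table[cond_a_cols])
  mean_b <- rowMeans(norm_table[cond_b_cols])
  tibble(
    ref_id = norm_table$ref_id,
    mean_a = mean_a,
    mean_b = mean_b,
    log2fc = log2((mean_b + pseudocount) / (mean_a + pseudocount))
  )
}

#' Guide/passenger strand asymmetry of expression change
#'
#' For each miRNA duplex, computes the guide and passenger log2 fold
#' changes between two conditions and their difference
#' `delta = guide_log2fc - passenger_log2fc`; across duplexes, a
#' two-sided Wilcoxon signed-rank test asks whether deltas differ from
#' zero, i.e. whether the change is guide-specific.
#'
#' @param norm_table CPM-normalized table containing both arms of every
#'   pair.
#' @param pairs Pair table from [make_pairs()] or [strand_pairs()].
#' @param cond_a_cols,cond_b_cols Column names of the two conditions.
#' @param pseudocount Passed to [log2fc()].
#' @return An object of class `strand_asymmetry`: the per-pair tibble
#'   (`pair_id`, `guide_log2fc`, `passenger_log2fc`, `delta`) with the
#'   test available through [glance()].
#' @export
strand_asymmetry <- function(norm_table, pairs, cond_a_cols, cond_b_cols,
                             pseudocount = 0.5) {
  missing <- setdiff(c(pairs$guide_id, pairs$passenger_id), norm_table$ref_id)
  if (length(missing)) {
    stop("pair arm '", missing[1], "' absent from the count table", call. = FALSE)
  }
  fc <- log2fc(norm_table, cond_a_cols, cond_b_cols, pseudocount)
  lf <- stats::setNames(fc$log2fc, fc$ref_id)
  out <- tibble(
    pair_id = pairs$pair_id,
    guide_log2fc = unname(lf[pairs$guide_id]),
    passenger_log2fc = unname(lf[pairs$passenger_id])
  )
  out$delta <- out$guide_log2fc - out$passenger_log2fc
  if (all(out$delta == 0)) {
    warning("all deltas are zero; Wilcoxon p set to 1", call. = FALSE)
    test <- list(p_value = 1, statistic = NA_real_,
                 method = "Wilcoxon signed rank (degenerate: all deltas 0)")
  } else {
    wt <- suppressWarnings(stats::wilcox.test(out$delta, mu = 0))
    test <- list(p_value = wt$p.value, statistic = unname(wt$statistic),
                 method = wt$method)
  }
  structure(out, class = c("strand_asymmetry", class(out)), test = test)
}

#' @method tidy strand_asymmetry
#' @export
tidy.strand_asymmetry <- function(x, ...) {
  out <- x
  attr(out, "test") <- NULL
  class(out) <- setdiff(class(out), "strand_asymmetry")
  out
}

#' @method glance strand_asymmetry
#' @export
glance.strand_asymmetry <- function(x, ...) {
  test <- attr(x, "test")
  tibble(
    n_pairs = nrow(x),
    median_delta = stats::median(x$delta),
    statistic = test$statistic,
    p_value = test$p_value,
    method = test$method
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
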