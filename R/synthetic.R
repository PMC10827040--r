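RNA_BASES <- c("A", "C", "G", "U")

# truncated geometric over min..max, success probability p
trunc_geom_probs <- function(p, min_len, max_len) {
  stopifnot(p > 0, p <= 1, max_len >= min_len)
  pr <- p * (1 - p)^(seq(min_len, max_len) - min_len)
  pr / sum(pr)
}

#' Describe the 3'-end structure of one reference in a synthetic sample
#'
#' A tail model is a categorical distribution over templated end offsets
#' joined with a categorical distribution over tail classes; oligo tail
#' lengths follow truncated geometric distributions (the simplest
#' monotone family for tail-length histograms).
#'
#' @param end_offset_probs Named numeric: probability per templated end
#'   offset (names are integer offsets relative to the canonical end).
#' @param tail_class_probs Named numeric over a subset of
#'   `none, monoA, oligoA, monoU, oligoU, U_then_A, other`; must sum
#'   to 1.
#' @param p_a,max_a Truncated-geometric parameter and cap for oligo(A)
#'   lengths (lengths 2..`max_a`).
#' @param p_u,max_u Same for oligo(U) lengths (2..`max_u`). U-then-A
#'   tails draw their U run from the oligo(U) distribution and their A
#'   run from the oligo(A) distribution.
#' @param other_pool Tail strings drawn uniformly for class `other`.
#' @return An object of class `tail_model`.
#' @export
tail_model <- function(end_offset_probs = c(`0` = 1),
                       tail_class_probs = c(none = 0.5, monoA = 0.5),
                       p_a = 0.5, max_a = 8, p_u = 0.5, max_u = 10,
                       other_pool = c("AGC", "UCA", "AUCG")) {
  if (abs(sum(end_offset_probs) - 1) > 1e-9) {
    stop("end_offset_probs must sum to 1", call. = FALSE)
  }
  if (abs(sum(tail_class_probs) - 1) > 1e-9) {
    stop("tail_class_probs must sum to 1", call. = FALSE)
  }
  if (!all(names(tail_class_probs) %in% TAIL_CLASSES)) {
    stop("unknown tail class in tail_class_probs", call. = FALSE)
  }
  if (is.null(names(end_offset_probs))) {
    stop("end_offset_probs must be named by integer offset", call. = FALSE)
  }
  structure(
    list(
      end_offset_probs = end_offset_probs,
      tail_class_probs = tail_class_probs,
      p_a = p_a, max_a = max_a, p_u = p_u, max_u = max_u,
      other_pool = other_pool
    ),
    class = "tail_model"
  )
}

#' Configure one synthetic sequencing sample
#'
#' @param tail_models Named list of [tail_model()] objects, one per
#'   `ref_id` to simulate (a single unnamed model is recycled over all
#'   references at simulation time).
#' @param n_reads Number of reads to emit.
#' @param seed Integer seed; identical (config, seed) gives
#'   byte-identical output.
#' @param weights Named per-reference abundance weights (uniform over
#'   simulated references when NULL).
#' @param seq_error_rate Per-base substitution probability applied to
#'   the insert (templated body + tail), never to the adapter.
#' @param adapter_seq 3' adapter appended to every read.
#' @return An object of class `sample_config`.
#' @export
sample_config <- function(tail_models, n_reads = 10000, seed = 1,
                          weights = NULL, seq_error_rate = 0,
                          adapter_seq = default_adapter()) {
  if (inherits(tail_models, "tail_model")) tail_models <- list(tail_models)
  stopifnot(n_reads >= 0)
  if (seq_error_rate < 0 || seq_error_rate >= 0.25) {
    stop("seq_error_rate must be in [0, 0.25)", call. = FALSE)
  }
  structure(
    list(
      tail_models = tail_models,
      n_reads = as.integer(n_reads),
      seed = as.integer(seed),
      weights = weights,
      seq_error_rate = seq_error_rate,
      adapter_seq = normalize_rna(adapter_seq)
    ),
    class = "sample_config"
  )
}

draw_lengths <- function(n, p, min_len, max_len) {
  if (n == 0) return(integer(0))
  sample(min_len:max_len, n, replace = TRUE,
         prob = trunc_geom_probs(p, min_len, max_len))
}

draw_tails <- function(classes, model) {
  tails <- character(length(classes))
  tails[classes == "monoA"] <- "A"
  tails[classes == "monoU"] <- "U"
  i <- classes == "oligoA"
  tails[i] <- strrep("A", draw_lengths(sum(i), model$p_a, 2, model$max_a))
  i <- classes == "oligoU"
  tails[i] <- strrep("U", draw_lengths(sum(i), model$p_u, 2, model$max_u))
  i <- classes == "U_then_A"
  tails[i] <- paste0(
    strrep("U", draw_lengths(sum(i), model$p_u, 2, model$max_u)),
    strrep("A", draw_lengths(sum(i), model$p_a, 2, model$max_a))
  )
  i <- classes == "other"
  tails[i] <- sample(model$other_pool, sum(i), replace = TRUE)
  tails
}

apply_substitutions <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  lens <- nchar(seqs)
  nerr <- stats::rbinom(length(seqs), lens, rate)
  for (i in which(nerr > 0)) {
    pos <- sample.int(lens[i], nerr[i])
    ch <- strsplit(seqs[i], "")[[1]]
    for (p in pos) ch[p] <- sample(setdiff(RNA_BASES, ch[p]), 1)
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

# shift the decomposition boundary templated-ward while the first tail
# base equals the next templated base: (offset, tail) is otherwise not
# identifiable from the read, so ground truth is recorded in canonical
# (maximal-templated) form
canonicalize_truth <- function(offsets, tails, templates, mlen) {
  repeat {
    nxt <- substr(templates, mlen + offsets + 1L, mlen + offsets + 1L)
    first <- substr(tails, 1L, 1L)
    shift <- first != "" & nxt != "" & first == nxt
    if (!any(shift)) break
    offsets[shift] <- offsets[shift] + 1L
    tails[shift] <- substring(tails[shift], 2L)
  }
  list(offsets = offsets, tails = tails)
}

#' Simulate one 3'-end sequencing sample with ground truth
#'
#' Each read is composed as `mature_seq` up to the drawn templated end
#' offset, plus a drawn non-templated tail, plus the adapter; iid
#' substitution errors at `seq_error_rate` are applied to the insert
#' only. The truth table records the pre-error structure of every read,
#' canonicalized to the maximal-templated decomposition (a tail base
#' identical to the next templated base is recorded as templated, since
#' the two are indistinguishable on the read).
#'
#' @param refs Reference tibble from [reference_set()].
#' @param config A [sample_config()].
#' @param sample_id Prefix used for read identifiers.
#' @return List with `reads` (tibble `read_id`, `seq`, `qual`) and
#'   `truth` (tibble `read_id`, `ref_id`, `true_end_offset`,
#'   `true_tail_seq`, `true_tail_class`).
#' @export
simulate_sample <- function(refs, config, sample_id = "sim") {
  stopifnot(inherits(config, "sample_config"))
  models <- config$tail_models
  if (is.null(names(models)) || any(names(models) == "")) {
    if (length(models) != 1) {
      stop("tail_models must be named by ref_id (or be a single model)",
           call. = FALSE)
    }
    models <- stats::setNames(rep(models, nrow(refs)), refs$ref_id)
  }
  sim_refs <- refs[match(names(models), refs$ref_id), ]
  if (anyNA(sim_refs$ref_id)) {
    stop("tail_models name references absent from refs", call. = FALSE)
  }
  for (j in seq_len(nrow(sim_refs))) {
    offs <- as.integer(names(models[[j]]$end_offset_probs))
    if (any(offs > nchar(sim_refs$downstream_seq[j]))) {
      stop("end offset beyond downstream context for '", sim_refs$ref_id[j],
           "'", call. = FALSE)
    }
    if (any(offs < 15L - nchar(sim_refs$mature_seq[j]))) {
      stop("end offset trims '", sim_refs$ref_id[j], "' below 15 nt",
           call. = FALSE)
    }
  }
  weights <- config$weights %||% stats::setNames(rep(1, nrow(sim_refs)), sim_refs$ref_id)
  weights <- weights[sim_refs$ref_id]
  n <- config$n_reads
  templates <- paste0(sim_refs$mature_seq, sim_refs$downstream_seq)
  mlens <- nchar(sim_refs$mature_seq)

  withr::with_seed(config$seed, {
    ridx <- sample.int(nrow(sim_refs), n, replace = TRUE, prob = weights)
    offsets <- integer(n)
    classes <- character(n)
    tails <- character(n)
    for (j in unique(ridx)) {
      i <- which(ridx == j)
      model <- models[[sim_refs$ref_id[j]]]
      off_support <- as.integer(names(model$end_offset_probs))
      offsets[i] <- off_support[
        sample.int(length(off_support), length(i), replace = TRUE,
                   prob = model$end_offset_probs)]
      cls_support <- names(model$tail_class_probs)
      classes[i] <- cls_support[
        sample.int(length(cls_support), length(i), replace = TRUE,
                   prob = model$tail_class_probs)]
      tails[i] <- draw_tails(classes[i], model)
    }
    insert <- paste0(
      substr(templates[ridx], 1L, mlens[ridx] + offsets),
      tails
    )
    insert <- apply_substitutions(insert, config$seq_error_rate)
    canon <- canonicalize_truth(offsets, tails, templates[ridx], mlens[ridx])
  })

  read_id <- sprintf("%s_r%06d", sample_id, seq_len(n))
  seqs <- paste0(insert, config$adapter_seq)
  list(
    reads = tibble(read_id = read_id, seq = seqs, qual = strrep("I", nchar(seqs))),
    truth = tibble(
      read_id = read_id,
      ref_id = sim_refs$ref_id[ridx],
      true_end_offset = canon$offsets,
      true_tail_seq = canon$tails,
      true_tail_class = classify_tails(canon$tails)
    )
  )
}

#' Illustrative wild-type-like and mutant-like sample presets
#'
#' Returns two editable [sample_config()] objects emulating the two
#' cellular states studied with 3'-end sequencing of U6-type snRNAs and
#' miRNAs: a wild-type-like state whose snRNA ends concentrate at the
#' +1U Lsm-boundary position with tails mostly absent or mono-A, and an
#' exonuclease-deficient ("mutant-like") state whose snRNA ends shift
#' to +3U/+4U with predominantly oligo-A tails, and whose miRNAs carry
#' more oligo-A. The exact fractions are illustrative package defaults,
#' not estimates fitted to any dataset.
#'
#' @param refs Reference tibble containing at least one snRNA and one
#'   miRNA record.
#' @param n_reads,seq_error_rate,adapter_seq Passed to [sample_config()].
#' @param seed_wt,seed_mut Seeds for the two configs.
#' @return Named list with elements `wt` and `mut`.
#' @export
wt_mut_presets <- function(refs, n_reads = 10000, seq_error_rate = 0.001,
                           adapter_seq = default_adapter(),
                           seed_wt = 101, seed_mut = 202) {
  if (!any(refs$ref_class == "snRNA") || !any(refs$ref_class == "miRNA")) {
    stop("refs must include at least one snRNA and one miRNA record",
         call. = FALSE)
  }
  sn_wt <- tail_model(
    end_offset_probs = c(`-1` = 0.15, `0` = 0.40, `1` = 0.25, `2` = 0.15, `3` = 0.05),
    tail_class_probs = c(none = 0.35, monoA = 0.55, oligoA = 0.05,
                         monoU = 0.02, oligoU = 0.02, U_then_A = 0.01)
  )
  sn_mut <- tail_model(
    end_offset_probs = c(`0` = 0.05, `1` = 0.15, `2` = 0.38, `3` = 0.42),
    tail_class_probs = c(none = 0.15, monoA = 0.08, oligoA = 0.60,
                         monoU = 0.02, oligoU = 0.05, U_then_A = 0.10)
  )
  mi_wt <- tail_model(
    end_offset_probs = c(`0` = 0.9, `1` = 0.1),
    tail_class_probs = c(none = 0.55, monoA = 0.35, oligoA = 0.05,
                         monoU = 0.02, oligoU = 0.01, U_then_A = 0.02)
  )
  mi_mut <- tail_model(
    end_offset_probs = c(`0` = 0.9, `1` = 0.1),
    tail_class_probs = c(none = 0.30, monoA = 0.20, oligoA = 0.40,
                         monoU = 0.02, oligoU = 0.02, U_then_A = 0.06)
  )
  models_for <- function(wt) {
    stats::setNames(lapply(seq_len(nrow(refs)), function(j) {
      if (refs$ref_class[j] == "snRNA") {
        if (wt) sn_wt else sn_mut
      } else {
        if (wt) mi_wt else mi_mut
      }
    }), refs$ref_id)
  }
  list(
    wt = sample_config(models_for(TRUE), n_reads = n_reads, seed = seed_wt,
                       seq_error_rate = seq_error_rate, adapter_seq = adapter_seq),
    mut = sample_config(models_for(FALSE), n_reads = n_reads, seed = seed_mut,
                        seq_error_rate = seq_error_rate, adapter_seq = adapter_seq)
  )
}

#' Derive replicate configs from one sample config
#'
#' @param config A [sample_config()].
#' @param n_replicates Number of replicates.
#' @param seed_base First replicate's seed; replicate i uses
#'   `seed_base + i - 1`.
#' @return List of configs.
#' @export
replicate_configs <- function(config, n_replicates, seed_base = config$seed) {
  lapply(seq_len(n_replicates), function(i) {
    cfg <- config
    cfg$seed <- as.integer(seed_base + i - 1L)
    cfg
  })
}

#' Bundled synthetic reference set
#'
#' A small hard-coded reference set used in examples and tests: one
#' U6-type snRNA whose canonical end is the +1U adjacent to the Lsm
#' site (with a templated U tract downstream, so extended ends read
#' +2U..+4U), and two guide/passenger miRNA duplexes. The first guide
#' carries a genomically encoded A immediately 3' of its canonical end,
#' reproducing the templated-extension ambiguity at adenylated miRNA
#' ends. All records are synthetic, miRBase-flavoured sequences.
#'
#' @return A reference tibble (see [reference_set()]).
#' @export
example_references <- function() {
  reference_set(
    ref_id = c("U6sim", "mir125sim-5p", "mir125sim-3p",
               "mir223sim-3p", "mir223sim-5p"),
    ref_class = c("snRNA", "miRNA", "miRNA", "miRNA", "miRNA"),
    mature_seq = c(
      "GCUCGCUUCGGCAGCACAUAUACU",
      "UCCCUGAGACCCUUUAACCUGUG",
      "ACAGGUGAGGUUCUUGGGAGCC",
      "UGUCAGUUUGUCAAAUACCCCA",
      "CGUGUAUUUGACAAGCUGAGUU"
    ),
    downstream_seq = c(
      "UUUGCGCCGC",
      "AGGUCGCC",
      "CUGGCGCC",
      "GCGGCCUC",
      "GGCCGCAU"
    ),
    boundary_offset = c(0L, NA, NA, NA, NA),
    partner_id = c(NA, "mir125sim-3p", "mir125sim-5p",
                   "mir223sim-5p", "mir223sim-3p"),
    arm_role = c("none", "guide", "passenger", "guide", "passenger")
  )
}

#' Simulate transcription-shutoff decay time courses
#'
#' Expected counts follow first-order decay, `n0 * exp(-k * t)`,
#' multiplied by lognormal noise with the given coefficient of
#' variation and rounded to integers.
#'
#' @param k Named nonnegative decay rates per hour (names are ref ids;
#'   an unnamed scalar simulates a single "ref1").
#' @param timepoints Hours after shutoff; must include 0.
#' @param n0 Expected abundance at t = 0 (scalar or per-ref).
#' @param noise_cv Coefficient of variation of the multiplicative
#'   lognormal noise (0 for noiseless).
#' @param n_replicates Replicates per reference.
#' @param seed Integer seed.
#' @return List with `counts` (tibble `ref_id`, `replicate`, `time`,
#'   `abundance`) and `truth` (tibble `ref_id`, `k`, `half_life`).
#' @export
simulate_decay <- function(k, timepoints = c(0, 4, 8), n0 = 1000,
                           noise_cv = 0.1, n_replicates = 3, seed = 1) {
  if (is.null(names(k))) names(k) <- paste0("ref", seq_along(k))
  stopifnot(all(k >= 0))
  if (!0 %in% timepoints) stop("timepoints must include 0", call. = FALSE)
  if (any(n0 < 0)) stop("negative n0", call. = FALSE)
  n0 <- stats::setNames(rep_len(n0, length(k)), names(k))
  grid <- tidyr::expand_grid(
    ref_id = names(k),
    replicate = seq_len(n_replicates),
    time = sort(unique(timepoints))
  )
  expected <- unname(n0[grid$ref_id] * exp(-k[grid$ref_id] * grid$time))
  withr::with_seed(seed, {
    noise <- if (noise_cv > 0) {
      sdlog <- sqrt(log(1 + noise_cv^2))
      stats::rlnorm(nrow(grid), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else {
      rep(1, nrow(grid))
    }
  })
  grid$abundance <- round(expected * noise)
  list(
    counts = grid,
    truth = tibble(ref_id = names(k), k = unname(k),
                   half_life = ifelse(k > 0, log(2) / unname(k), Inf))
  )
}

#' Abstract guide/passenger pair table
#'
#' @param n_pairs Number of duplexes.
#' @return Tibble with `pair_id`, `guide_id`, `passenger_id`.
#' @export
make_pairs <- function(n_pairs) {
  tibble(
    pair_id = sprintf("pair%02d", seq_len(n_pairs)),
    guide_id = sprintf("mir%02d-5p", seq_len(n_pairs)),
    passenger_id = sprintf("mir%02d-3p", seq_len(n_pairs))
  )
}

#' Extract guide/passenger pairs from a reference set
#'
#' @param refs Reference tibble with symmetric `partner_id` pairing.
#' @return Tibble with `pair_id`, `guide_id`, `passenger_id`.
#' @export
strand_pairs <- function(refs) {
  g <- refs[refs$arm_role == "guide" & !is.na(refs$partner_id), ]
  if (nrow(g) == 0) stop("no paired guide records in refs", call. = FALSE)
  tibble(pair_id = g$ref_id, guide_id = g$ref_id, passenger_id = g$partner_id)
}

#' Simulate a two-condition count table for guide/passenger pairs
#'
#' Condition A uses the baseline expected counts; condition B scales
#' each arm's expectation by `2^logfc` for its role, emulating
#' guide-specific destabilization with unchanged passenger levels.
#' Counts are Poisson-sampled unless `poisson = FALSE`.
#'
#' @param pairs Pair table from [make_pairs()] or [strand_pairs()].
#' @param guide_logfc,passenger_logfc Log2 fold changes applied to
#'   condition B expectations per arm role.
#' @param base_guide,base_passenger Baseline expected counts (scalar or
#'   per pair).
#' @param n_replicates Replicates per condition.
#' @param seed Integer seed.
#' @param poisson Poisson-sample counts (TRUE) or return exact
#'   expectations (FALSE).
#' @return Wide count tibble: `ref_id` plus columns
#'   `condA_rep1..n`, `condB_rep1..n`.
#' @export
simulate_strand_pairs <- function(pairs, guide_logfc = -1, passenger_logfc = 0,
                                  base_guide = 2000, base_passenger = 400,
                                  n_replicates = 3, seed = 1, poisson = TRUE) {
  if (anyNA(pairs$guide_id) || anyNA(pairs$passenger_id)) {
    stop("unpaired reference passed", call. = FALSE)
  }
  n <- nrow(pairs)
  base_guide <- rep_len(base_guide, n)
  base_passenger <- rep_len(base_passenger, n)
  ref_id <- c(pairs$guide_id, pairs$passenger_id)
  mu_a <- c(base_guide, base_passenger)
  mu_b <- c(base_guide * 2^guide_logfc, base_passenger * 2^passenger_logfc)
  draw <- function(mu) {
    if (poisson) stats::rpois(length(mu), mu) else round(mu)
  }
  withr::with_seed(seed, {
    out <- tibble(ref_id = ref_id)
    for (r in seq_len(n_replicates)) out[[paste0("condA_rep", r)]] <- draw(mu_a)
    for (r in seq_len(n_replicates)) out[[paste0("condB_rep", r)]] <- draw(mu_b)
  })
  out
}
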