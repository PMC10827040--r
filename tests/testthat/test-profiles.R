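mk_calls <- function(tail_seqs, ref_id = "tA", end_offset = 0L,
                     status = "called") {
  tibble::tibble(
    read_id = paste0("r", seq_along(tail_seqs)),
    ref_id = ref_id,
    end_offset = as.integer(end_offset),
    tail_seq = tail_seqs,
    tail_class = classify_tails(tail_seqs),
    n_mismatch = 0L,
    status = status
  )
}

test_that("profiles aggregate counts exactly and conserve them", {
  calls <- mk_calls(c(rep("", 4), rep("A", 6)))
  prof <- build_profile(calls, "s1")
  expect_equal(sum(prof$count), 10)
  expect_equal(prof$fraction[prof$tail_class == "none"], 0.4)
  expect_equal(prof$fraction[prof$tail_class == "monoA"], 0.6)
  expect_equal(sum(prof$fraction), 1)

  expect_equal(nrow(build_profile(mk_calls(character(0)))), 0)

  # hand enumeration on a mixed fixture
  tails <- c("", "", "A", "AA", "AA", "U", "UUA", "GA", "", "A")
  prof2 <- build_profile(mk_calls(tails), "s2")
  expect_equal(prof2$count[prof2$tail_class == "none"], 3)
  expect_equal(prof2$count[prof2$tail_class == "oligoA" & prof2$tail_len == 2], 2)
  expect_equal(prof2$fraction[prof2$tail_class == "other"], 1 / 10)
})

test_that("non-called reads never enter a profile", {
  calls <- dplyr::bind_rows(
    mk_calls(c("", "A")),
    mk_calls("AA", status = "no_adapter"),
    mk_calls("", status = "unmatched")
  )
  prof <- build_profile(calls)
  expect_equal(sum(prof$count), 2)
})

test_that("tail summaries report mono/oligo splits and A-length histograms", {
  tails <- c(rep("A", 9), "AAA")
  prof <- build_profile(mk_calls(tails), "s")
  sm <- summarize_profile(prof, "tail")
  expect_equal(sm$fraction[sm$category == "monoA"], 0.9)
  hist <- tail_length_histogram(prof)
  expect_equal(hist$count[hist$a_len == "1"], 9)
  expect_equal(hist$count[hist$a_len == "3"], 1)
})

test_that("end-position summaries label snRNA offsets relative to the Lsm boundary", {
  refs <- example_references()
  u6 <- refs[refs$ref_id == "U6sim", ]
  prof <- build_profile(mk_calls(rep("", 5), ref_id = "U6sim",
                                 end_offset = 0L), "s")
  sm <- summarize_profile(prof, "endpos", ref = u6)
  expect_equal(sm$label, "+1U")
  expect_equal(sm$fraction, 1)

  mixed <- build_profile(
    mk_calls(rep("", 4), ref_id = "U6sim", end_offset = c(-1L, 0L, 2L, 3L)), "s"
  )
  sm2 <- summarize_profile(mixed, "endpos", ref = u6)
  expect_equal(sm2$label, c("-1", "+1U", "+3U", "+4U"))
})

test_that("the adenylated-inclusive view counts the templated A end", {
  # downstream of mir125sim-5p starts with a genomically encoded A
  refs <- example_references()
  mir <- refs[refs$ref_id == "mir125sim-5p", ]
  calls <- mk_calls(c("", "", "", "A", "AA", "UUA", "U", ""),
                    ref_id = mir$ref_id,
                    end_offset = c(0L, 1L, 1L, 0L, 0L, 0L, 0L, 0L))
  prof <- build_profile(calls, "s")
  sm <- summarize_profile(prof, "adenylated_inclusive", ref = mir)
  # A-ended: two templated +1 ends, monoA, oligoA, U-then-A = 5 of 8
  expect_equal(sm$fraction[sm$category == "A_ended"], 5 / 8)
  expect_equal(sm$fraction[sm$category == "genomic"], 2 / 8)
  expect_error(summarize_profile(prof, "adenylated_inclusive"), "reference")
  expect_error(summarize_profile(prof[0, ], "tail"), "empty")
})

test_that("condition comparison summarizes replicates and tests fractions", {
  mk_prof <- function(frac_a, sample_id) {
    n_a <- round(frac_a * 100)
    build_profile(mk_calls(c(rep("A", n_a), rep("", 100 - n_a))), sample_id)
  }
  pa <- dplyr::bind_rows(mk_prof(0.4, "a1"), mk_prof(0.4, "a2"))
  pb <- dplyr::bind_rows(mk_prof(0.8, "b1"), mk_prof(0.8, "b2"))
  cc <- suppressWarnings(compare_conditions(pa, pb))
  row <- cc[cc$category == "monoA", ]
  expect_equal(row$diff, 0.4)
  expect_equal(row$sd_a, 0)

  same <- suppressWarnings(compare_conditions(pa, pa))
  expect_equal(same$diff, rep(0, nrow(same)))
  expect_equal(same$p_value, rep(1, nrow(same)))

  # single-category degenerate case warns exactly once and returns p = 1
  mono <- dplyr::bind_rows(
    build_profile(mk_calls(rep("A", 50)), "a1"),
    build_profile(mk_calls(rep("A", 50)), "a2")
  )
  expect_warning(deg <- compare_conditions(mono, mono), "p = 1")
  expect_equal(deg$p_value, 1)

  pa2 <- dplyr::bind_rows(mk_prof(0.38, "a1"), mk_prof(0.44, "a2"))
  pb2 <- dplyr::bind_rows(mk_prof(0.78, "b1"), mk_prof(0.84, "b2"))
  cc2 <- compare_conditions(pa2, pb2, categories = adenylated_category)
  expect_true(all(c("adenylated", "not_adenylated") %in% cc2$category))
  expect_equal(cc2$diff[cc2$category == "adenylated"], 0.4)
  expect_lt(cc2$p_value[cc2$category == "adenylated"], 0.05)

  expect_warning(
    single <- compare_conditions(mk_prof(0.4, "a1"), mk_prof(0.8, "b1")),
    "single replicate"
  )
  expect_true(all(is.na(single$p_value)))
})

test_that("CPM columns each sum to one million", {
  counts <- tibble::tibble(ref_id = c("a", "b"), s1 = c(50, 50), s2 = c(10, 90))
  cpm <- cpm_normalize(counts)
  expect_equal(cpm$s1, c(5e5, 5e5))
  expect_equal(unname(colSums(cpm[c("s1", "s2")])), c(1e6, 1e6),
               tolerance = 1e-6)
  zero <- tibble::tibble(ref_id = "a", s1 = 0)
  expect_error(cpm_normalize(zero), "> 0")
})

test_that("log2 fold changes use pseudocounted CPM means", {
  norm <- tibble::tibble(
    ref_id = c("x", "y"),
    a1 = c(100, 200), a2 = c(100, 200),
    b1 = c(50, 200), b2 = c(50, 200)
  )
  fc <- log2fc(norm, c("a1", "a2"), c("b1", "b2"))
  expect_equal(fc$log2fc[fc$ref_id == "y"], 0)
  expect_equal(fc$log2fc[fc$ref_id == "x"], log2(50.5 / 100.5))
})

test_that("strand asymmetry reports per-pair deltas and a signed-rank test", {
  pairs <- make_pairs(4)
  tab <- simulate_strand_pairs(pairs, guide_logfc = -1, passenger_logfc = 0,
                               n_replicates = 2, poisson = FALSE)
  # equalize library sizes across conditions is not needed for exact case:
  # guide halved and passenger unchanged in raw counts; normalize first
  sa <- strand_asymmetry(tab, pairs, c("condA_rep1", "condA_rep2"),
                         c("condB_rep1", "condB_rep2"), pseudocount = 0)
  expect_s3_class(sa, "strand_asymmetry")
  expect_equal(nrow(tidy(sa)), 4)
  expect_equal(sa$delta, rep(-1, 4))
  expect_equal(glance(sa)$median_delta, -1)

  # identical fold changes on both arms: all deltas zero, p = 1
  tab0 <- simulate_strand_pairs(pairs, guide_logfc = 0, passenger_logfc = 0,
                                n_replicates = 2, poisson = FALSE)
  expect_warning(sa0 <- strand_asymmetry(tab0, pairs, c("condA_rep1", "condA_rep2"),
                                         c("condB_rep1", "condB_rep2")),
                 "deltas")
  expect_equal(sa0$delta, rep(0, 4))
  expect_equal(glance(sa0)$p_value, 1)

  expect_error(
    strand_asymmetry(tab[-1, ], pairs, "condA_rep1", "condB_rep1"),
    "absent"
  )
})
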