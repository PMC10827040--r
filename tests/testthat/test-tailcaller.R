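test_that("adapter trimming finds clean and singly-substituted adapters", {
  ref <- toy_refs()[1, ]
  insert <- ref$mature_seq
  adapter <- default_adapter()

  tr <- trim_adapter(paste0(insert, adapter), adapter)
  expect_equal(tr$insert, insert)
  expect_equal(tr$status, "called")

  # no adapter-like suffix: full read back, flagged
  tr2 <- trim_adapter(paste0(insert, "CCCC"), adapter)
  expect_equal(tr2$insert, paste0(insert, "CCCC"))
  expect_equal(tr2$status, "no_adapter")

  # every 1-substitution variant of the first 6 adapter bases still
  # trims at the same point
  for (pos in 1:6) {
    for (b in setdiff(c("A", "C", "G", "U"), substr(adapter, pos, pos))) {
      mut <- adapter
      substr(mut, pos, pos) <- b
      tr3 <- trim_adapter(paste0(insert, mut), adapter)
      expect_equal(tr3$insert, insert)
      expect_equal(tr3$status, "called")
    }
  }
})

test_that("partial adapter at the read end is trimmed from min_overlap up", {
  ref <- toy_refs()[1, ]
  adapter <- default_adapter()
  for (o in 6:10) {
    tr <- trim_adapter(paste0(ref$mature_seq, substr(adapter, 1, o)), adapter)
    expect_equal(tr$insert, ref$mature_seq)
  }
  # five bases of adapter are below min_overlap
  tr <- trim_adapter(paste0(ref$mature_seq, substr(adapter, 1, 5)), adapter)
  expect_equal(tr$status, "no_adapter")
})

test_that("call_tail resolves the templated/tail boundary templated-maximally", {
  # mature ends ...CCUGUG with a genomically encoded A immediately 3'
  ref <- reference_set("mir", "miRNA", "UCCCUGAGACCCUUUAACCUGUG", "AUUUCGCC")
  m <- ref$mature_seq

  # the single extra A is genomic, not a tail
  one_a <- call_tail(paste0(m, "A"), ref)
  expect_equal(one_a$end_offset, 1L)
  expect_equal(one_a$tail_seq, "")
  expect_equal(one_a$tail_class, "none")

  ident <- call_tail(m, ref)
  expect_equal(ident$end_offset, 0L)
  expect_equal(ident$tail_class, "none")

  # first A templated, the remaining two are the tail
  three_a <- call_tail(paste0(m, "AAA"), ref)
  expect_equal(three_a$end_offset, 1L)
  expect_equal(three_a$tail_seq, "AA")
  expect_equal(three_a$tail_class, "oligoA")

  # UUA cannot extend into the downstream A, so it is all tail
  uua <- call_tail(paste0(m, "UUA"), ref)
  expect_equal(uua$end_offset, 0L)
  expect_equal(uua$tail_seq, "UUA")
  expect_equal(uua$tail_class, "U_then_A")
})

test_that("trimmed species call with negative offsets down to -3", {
  ref <- toy_refs()[1, ]
  m <- ref$mature_seq
  for (k in 1:3) {
    tc <- call_tail(substr(m, 1, nchar(m) - k), ref)
    expect_equal(tc$end_offset, -k)
    expect_equal(tc$status, "called")
  }
  tc4 <- call_tail(substr(m, 1, nchar(m) - 4), ref)
  expect_equal(tc4$status, "unmatched")
})

test_that("a single mature-body substitution is tolerated and counted", {
  ref <- toy_refs()[1, ]
  m <- ref$mature_seq
  x <- m
  substr(x, 5, 5) <- setdiff(c("A", "C", "G", "U"), substr(m, 5, 5))[1]
  tc <- call_tail(paste0(x, "AA"), ref, max_mismatch = 1)
  expect_equal(tc$status, "called")
  expect_equal(tc$n_mismatch, 1L)
  expect_equal(tc$tail_seq, "AA")
  expect_equal(call_tail(x, ref, max_mismatch = 0)$status, "unmatched")
})

test_that("maximality: at zero mismatches no tail starts with the next templated base", {
  refs <- oracle_refs()
  withr::with_seed(11, {
    for (r in seq_len(nrow(refs))) {
      ref <- refs[r, ]
      template <- paste0(ref$mature_seq, ref$downstream_seq)
      inserts <- random_inserts(200, ref$mature_seq, ref$downstream_seq)
      tc <- call_tail(inserts, ref, max_mismatch = 0)
      called <- tc$status == "called" & tc$tail_seq != ""
      nxt <- substring(template, nchar(ref$mature_seq) + tc$end_offset + 1,
                       nchar(ref$mature_seq) + tc$end_offset + 1)
      expect_true(all(substr(tc$tail_seq[called], 1, 1) != nxt[called]))
    }
  })
})

test_that("every tail string maps to exactly one class", {
  expect_equal(
    classify_tails(c("", "A", "AA", "AAAAA", "U", "UU", "UA", "UUAA", "GA",
                     "AU", "C", "AAU")),
    c("none", "monoA", "oligoA", "oligoA", "monoU", "oligoU", "U_then_A",
      "U_then_A", "other", "other", "other", "other")
  )
  withr::with_seed(3, {
    tails <- replicate(300, paste(
      sample(c("A", "C", "G", "U"), sample(0:6, 1), replace = TRUE),
      collapse = ""
    ))
  })
  cls <- classify_tails(tails)
  expect_true(all(cls %in% c("none", "monoA", "oligoA", "monoU", "oligoU",
                             "U_then_A", "other")))
  expect_equal(cls == "none", tails == "")
})

test_that("call_sample assigns reads, flags collisions, counts statuses", {
  refs <- toy_refs()
  adapter <- default_adapter()
  reads <- c(
    paste0(refs$mature_seq[1], "AA", adapter),
    paste0(refs$mature_seq[2], adapter),
    paste0(strrep("C", 30), adapter)   # matches neither 5' end
  )
  calls <- call_sample(reads, refs)
  expect_equal(calls$ref_id[1:2], refs$ref_id)
  expect_equal(calls$tail_class[1], "oligoA")
  expect_equal(calls$status[3], "unmatched")
  sc <- status_summary(calls)
  expect_equal(sc$n_reads[sc$status == "called"], 2L)

  # two references sharing their first 17 bases: a read stopping inside
  # the shared prefix ties and is flagged ambiguous
  shared <- "ACGUACGUACGUACGUA"
  twins <- reference_set(
    c("twin1", "twin2"), "miRNA",
    paste0(shared, c("GGCCG", "CCGGC")), c("CGCG", "GCGC")
  )
  amb <- call_sample(paste0(shared, adapter), twins)
  expect_equal(amb$status, "ambiguous_ref")
  expect_true(is.na(amb$ref_id))
})

test_that("reads without adapter stay flagged but still decompose", {
  refs <- toy_refs()
  calls <- call_sample(paste0(refs$mature_seq[1], "AAA"), refs)
  expect_equal(calls$status, "no_adapter")
  expect_equal(calls$ref_id, "tA")
  expect_equal(calls$tail_seq, "AAA")
  expect_error(call_sample("ACGU", refs[0, ]), "empty reference")
})

test_that("call_tail agrees with the brute-force oracle on fuzzed inserts", {
  refs <- oracle_refs()
  withr::with_seed(29, {
    for (r in seq_len(nrow(refs))) {
      ref <- refs[r, ]
      inserts <- random_inserts(400, ref$mature_seq, ref$downstream_seq)
      tc <- call_tail(inserts, ref, max_mismatch = 0)
      for (i in seq_along(inserts)) {
        oc <- oracle_call(inserts[i], ref$mature_seq, ref$downstream_seq)
        expect_equal(tc$status[i] == "called", oc$matched)
        if (oc$matched) {
          expect_equal(tc$end_offset[i], oc$end_offset)
          expect_equal(tc$tail_seq[i], oc$tail_seq)
        }
      }
    }
  })
})
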