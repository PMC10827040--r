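# Two references whose downstream contexts never start with A or U at
# any simulated end offset, so every drawn (offset, tail) decomposition
# is identifiable on the read (no templated/tail collisions).
toy_refs <- function() {
  reference_set(
    ref_id = c("tA", "tB"),
    ref_class = "miRNA",
    mature_seq = c("ACGUACGUACGUACGUACGG", "GGAUCCGAUUACGGAUCCGA"),
    downstream_seq = c("CGCGCGCG", "GCGGCGGC")
  )
}

# tail model covering all seven classes, collision-free over toy_refs()
# offsets 0..2 (next templated bases are C/G; tails start with A or U)
cf_model <- function() {
  tail_model(
    end_offset_probs = c(`0` = 0.5, `1` = 0.3, `2` = 0.2),
    tail_class_probs = c(none = 0.30, monoA = 0.20, oligoA = 0.20,
                         monoU = 0.10, oligoU = 0.10, U_then_A = 0.05,
                         other = 0.05),
    other_pool = c("AGC", "UCA")
  )
}

# five references with varied downstream contexts (including templated
# A and U starts) for oracle-equivalence fuzzing
oracle_refs <- function() {
  reference_set(
    ref_id = paste0("o", 1:5),
    ref_class = "miRNA",
    mature_seq = c(
      "ACGUACGUACGUACGUACGG",
      "GGAUCCGAUUACGGAUCCGA",
      "UCCCUGAGACCCUUUAACCUGUG",
      "CAGUGGUUUUACCCUAUGGUAG",
      "AGCUACAUUGUCUGCUGGGUUU"
    ),
    downstream_seq = c(
      "CGCGCGCG",
      "AUUUGCGC",
      "AGGUCGCC",
      "UUUUAGCC",
      "GAUACGCC"
    )
  )
}
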