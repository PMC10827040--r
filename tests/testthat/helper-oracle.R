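# Brute-force maximal-templated decomposition: enumerate every split of
# the insert into (templated prefix along mature + downstream, suffix)
# and keep the longest exactly matching templated prefix. Deliberately
# written with plain string comparisons, independent of the package's
# matching code.
oracle_call <- function(insert, mature, downstream) {
  template <- paste0(mature, downstream)
  mlen <- nchar(mature)
  best <- 0L
  for (m in seq_len(min(nchar(insert), nchar(template)))) {
    if (substr(insert, 1, m) == substr(template, 1, m)) best <- m
  }
  list(
    end_offset = best - mlen,
    tail_seq = substring(insert, best + 1),
    matched = best >= mlen - 3L && nchar(insert) >= 15L
  )
}

# random inserts exercising the decomposition: pure noise, clean
# template prefixes with tails, and singly corrupted variants
random_inserts <- function(n, mature, downstream) {
  template <- paste0(mature, downstream)
  bases <- c("A", "C", "G", "U")
  vapply(seq_len(n), function(i) {
    kind <- sample(3, 1)
    if (kind == 1) {
      paste(sample(bases, sample(15:40, 1), replace = TRUE), collapse = "")
    } else {
      m <- sample(12:nchar(template), 1)
      tail <- paste(sample(bases, sample(0:8, 1), replace = TRUE), collapse = "")
      x <- paste0(substr(template, 1, m), tail)
      if (kind == 3 && nchar(x) > 0) {
        p <- sample(nchar(x), 1)
        substr(x, p, p) <- sample(setdiff(bases, substr(x, p, p)), 1)
      }
      substr(x, 1, 40)
    }
  }, character(1))
}
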