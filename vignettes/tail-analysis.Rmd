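---
title: "Calling and profiling non-templated 3' tails on small RNAs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling and profiling non-templated 3' tails on small RNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnatails)
library(dplyr)
```

## The problem

Small RNAs — miRNAs and the spliceosomal U6/U6atac snRNAs — are regulated at
their 3' ends by a push and pull between tailing enzymes and trimming
exonucleases. Non-canonical poly(A) polymerases (PAPD5/PAPD7) add short
destabilizing oligo(A) tails; terminal uridylyl transferases add U residues;
exonucleases such as USB1 and PARN remove them. In Poikiloderma with
Neutropenia, loss of USB1 activity leaves miRNAs oligoadenylated and
destabilized, and leaves U6 snRNA with extended uridylated, oligoadenylated
ends past its Lsm2--8 binding site.

Measuring this from 3'-end sequencing data requires one central operation:
deciding, for every read, where the genomically templated part of the
molecule ends and where the post-transcriptionally added tail begins. That
split is what `rnatails` implements, along with the downstream summaries a
study of this biology needs: per-reference 3'-end profiles, condition
comparisons, guide/passenger strand asymmetry, and decay-rate estimation
after transcription shutoff.

## The decomposition model

Each reference carries a mature sequence and its downstream genomic context
(`downstream_seq`), the bases the genome encodes 3' of the canonical end.
End positions are expressed as offsets relative to the canonical end:
offset 0 is the last mature base, offset +k the k-th downstream base,
negative offsets are trimmed ends. For snRNAs an annotated boundary offset
maps offsets onto the `+1U, +2U, ...` labelling used for positions adjacent
to the Lsm site.

`call_tail()` finds, for an adapter-trimmed insert, the *maximal templated
prefix* along mature + downstream sequence; the remaining suffix is the
tail. The convention is templated-maximal: a 3'-terminal base that could be
either genomic or added is always counted genomic. For a miRNA such as
miR-125a-5p, which the genome extends with an A immediately after its
canonical `...GUG` end, a read ending `...GUGA` is therefore reported as a
templated extension (offset +1, no tail), and `...GUGAAA` as offset +1 with
an `AA` tail. No information is lost: the end-offset histogram retains the
templated +1 A ends, and `summarize_profile(mode = "adenylated_inclusive")`
reports the alternative view in which the templated single-A end is pooled
with non-templated A tails into one "A-ended" category. Both conventions
are exposed because both are scientifically defensible and the choice
matters when a genomic A shadows enzymatic monoadenylation.

Tails are classified into `none`, `monoA`, `oligoA` (>= 2 A), `monoU`,
`oligoU`, `U_then_A` (>= 1 U then >= 1 A, the oUA layout produced when an
oligouridylated end is subsequently adenylated) and `other`. Every possible
tail string maps to exactly one class.

### Mismatch policy

Sequencing errors near the 3' end would masquerade as tails, so boundary
determination must be exact. The caller tolerates at most one substitution
(`max_mismatch = 1`) inside the mature body, but none within the final four
matched bases and none in the templated extension. Reads whose templated
match stops more than three bases short of the canonical end are
`unmatched`; the −3 window admits plausible exonucleolytic trimming
intermediates without accepting spurious short matches. 5' heterogeneity is
not modelled: reads must begin at mature base 1, which matches the anchored
assignment strategy (`call_sample()` assigns each insert to the reference
with the longest exact 5' match, flagging ties as `ambiguous_ref`).

### Adapter trimming

`trim_adapter()` scans 5'→3' for the earliest occurrence of an adapter
prefix (>= 6 bases, <= 1 substitution) starting at or after read position
15. Reads with no adapter-like suffix are kept and flagged `no_adapter`;
they are still decomposed but excluded from profiles, since their 3' ends
are not guaranteed to be complete.

## The synthetic-data generator

The study design this package targets — two genotypes, two or three
biological replicates, 3'-end libraries of a handful of references, decay
time courses at 0/4/8 h — is emulated by `simulate_sample()`,
`simulate_decay()` and `simulate_strand_pairs()`, each returning per-read
or per-measurement ground truth.

A `tail_model()` draws a templated end offset and a tail class
independently per read; oligo tail lengths follow truncated geometric
distributions (lengths 2--8 for A, 2--10 for U), the simplest monotone
family consistent with observed tail-length histograms. Reads are composed
as templated prefix + tail + adapter, with iid substitutions applied to the
insert only. Ground truth is recorded in canonical (maximal-templated) form:
when a drawn tail begins with the base the genome encodes next, the
decomposition is not identifiable from the read, and the truth table shifts
such bases into the templated body before recording. This is a property of
the molecules, not of the caller — on U6, where the genomic U tract
continues past the canonical end, a mono-U addition at the boundary is
physically indistinguishable from a templated U.

`wt_mut_presets()` encodes two illustrative states: a wild-type-like sample
whose snRNA ends concentrate at the +1U position (modal mass 0.40) with
mostly absent or mono-A tails, and a mutant-like sample whose snRNA ends
shift to +3U/+4U with predominantly oligo-A tails and more oligoadenylated
miRNAs. The fractions are package defaults chosen to be qualitatively
realistic; they are deliberately *not* fitted to any published dataset, so
that pipeline validation against the generator is not circular. Drawing
class and offset independently is a simplification — in the real biology
extended snRNA ends are preferentially oligoadenylated — which is
acceptable because nothing downstream assumes independence.

What the generator does **not** emulate: ligation and PCR biases, UMIs,
indel sequencing errors (substitution-only keeps the truth decomposition
well-defined), 5'-end heterogeneity, and multi-locus mapping ambiguity.
Passing the round-trip tests therefore demonstrates correctness of the
decomposition and aggregation logic under the stated error model, not
robustness to every artefact of real libraries.

## Statistics

* **Condition comparisons** (`compare_conditions()`): per-replicate
  category fractions are summarized as mean ± SD per condition — the form
  in which such experiments are usually reported — and compared with a
  Welch two-sided t-test on replicate fractions. The test choice is this
  package's; zero-variance degenerate cases return p = 1 (equal means) with
  a warning instead of erroring. Benjamini–Hochberg correction across
  categories is available but off by default, since these panels are
  typically few-category and hypothesis-driven.
* **Strand asymmetry** (`strand_asymmetry()`): per-duplex
  `delta = guide_log2fc − passenger_log2fc` on pseudocounted CPM
  (pseudocount 0.5 avoids log of zero for dropouts), with a two-sided
  Wilcoxon signed-rank test of deltas against zero. All-zero deltas return
  p = 1 by convention.
* **Decay kinetics** (`fit_decay()`): abundances are normalized to t = 0
  within replicate, so the log-linear least-squares fit is constrained
  through the origin; `k = −slope`, clipped at zero, pooled as the
  replicate mean with `se_k = SD/√n`, and `half_life = ln 2 / k`. A free
  intercept is available behind a flag for series where the t = 0 point is
  unreliable. Zeros are floored at `1e-6` of the t = 0 abundance before
  the log, with a warning; upward drift produces a warning and a clipped
  rate of 0. Genotype comparison (`compare_decay()`) reports the rate
  ratio and a Welch t-test on replicate-level rates.

## Numerical and validation choices

Validation in `tests/testthat/` runs at fixed, documented problem sizes
chosen to make binomial and simulation error bounds tight while keeping the
default test run fast: decomposition is checked against a brute-force
oracle that enumerates every (templated prefix, suffix) split on 10,000
fuzzed inserts across 5 references; generator → caller → profiler round
trips use 10,000 reads (3·binomial-SE bounds on every configured class
probability, per-read concordance 100% at error 0, >= 97% at 0.5%
substitution error); preset discrimination uses 100 seeded runs of
3 replicates × 10,000 reads per condition; decay power uses 100 seeded
3-replicate comparisons of a true 2× rate difference. Determinism is
guaranteed per (config, seed) pair; tests always compare pipeline output to
stored truth tables from the same run, never to re-generated random
streams.

## Known limitations

* Reads are assigned by exact anchored prefix match, not genome-wide
  alignment; paralogous references with long shared 5' sequence are
  reported `ambiguous_ref` rather than resolved.
* The A-tail length histogram excludes U-then-A tails, whose A-run length
  is not recoverable from (class, total length) profile cells.
* Quality scores are carried but unused; there is no quality-aware error
  model.
* Single-exponential decay only; no multi-phase fitting.
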