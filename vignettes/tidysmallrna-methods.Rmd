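---
title: "Methods: tiered small RNA annotation, isomiR profiling and size classes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tiered small RNA annotation, isomiR profiling and size classes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tidysmallrna)
library(dplyr)
```

## The analysis

`tidysmallrna` implements a homology-based annotation and profiling
pipeline for deep-sequenced small RNA libraries of the kind produced for
multi-tissue teleost surveys (e.g. *Takifugu rubripes*): fixed-length raw
reads carrying a 3′ sequencing adapter, annotated against a mature miRNA
reference (miRBase-style), profiled per tissue, and characterized down to
the repeat-derived putative piRNA population of the gonads. No genome,
hairpin or live database is needed: the reference sets are user-supplied
FASTA files, and a seeded simulator generates complete synthetic
experiments with per-read ground truth.

## Preprocessing

Low-quality reads are removed by mean Phred score. The upstream study
eliminated low-quality reads without stating its criterion, so the rule
here — mean Phred ≥ 20 — is an explicit, configurable assumption, not a
reconstruction.

Adapter trimming truncates each read at the leftmost position where the
read matches a prefix of the adapter over at least `min_overlap = 4`
nucleotides (either a full internal adapter occurrence or an adapter
prefix reaching the read's 3′ end). Matching is exact: the original
trimming script is unspecified, and exact matching is what makes the
following property provable rather than empirical. Terminal adapter
fragments of 1–3 nt cannot be distinguished from genuine small RNA
sequence; they are deliberately retained. On fixed 35-nt raw reads this
creates a structural hole in the trimmed length distribution: a read
trimmed at all has at least 4 adapter nucleotides, so its insert is at
most 31 nt, and an untrimmed read stays at 35 nt. **Lengths 32–34 nt
cannot occur.** The test suite asserts this on every simulated library.
When several positions match, the leftmost wins — the conservative
(shortest-insert) choice for adapter dimers. Exact trimming is idempotent.

## The four-tier classifier

Reads of 18–25 nt (the length range that covers essentially all known
mature miRNAs) are classified against the reference by a cascade that is
exhaustive and mutually exclusive; every read receives exactly one label.

1. **Tier 1 — offset-tolerant exact match.** An ungapped placement of the
   read against a reference exists in which every overlapping position is
   identical, with the read's 5′ end within ±2 nt and its 3′ end within
   ±4 nt of the reference ends. Offsets are read-minus-reference, so
   negative 5′ offsets mean the read extends 5′ of the reference. Read
   nucleotides that extend past a reference end are unconstrained: without
   precursor context there is nothing to validate them against, and this
   is documented in the output rather than silently assumed templated.
   Among qualifying placements the one minimizing |5′ offset| then
   |3′ offset| is reported.
2. **Tier 2 — long contiguous match.** The read's first 10 nt are
   identical to a reference's first 10 nt, and the 5′-anchored
   position-wise comparison contains a contiguous identical block of
   ≥ 16 nt.
3. **Tier 3 — Smith–Waterman rescue.** Prefix identity holds, the best
   block is < 16 nt, and the Smith–Waterman local alignment score under
   match +5 / mismatch −4 is ≥ 70.
4. **Putative miRNA.** Prefix identity holds but none of the above.
5. **Unannotated** otherwise.

Because 16 matches alone score 80, a tier-2 read can never fail the
tier-3 score — the cascade ordering is internally consistent, and the
suite checks the implication `run ≥ 16 ⟹ score ≥ 80` on whole simulated
libraries.

### Numerical choices

* **Gap penalties.** The published scoring scheme fixes only match and
  mismatch. Gaps default to a stiff affine penalty (a gap of length *k*
  scores −12 − 4*k*, the `gapOpening`/`gapExtension` convention). On
  18–25-nt reads a single-nucleotide gap costs more than two mismatches,
  so gapped and gap-free scoring almost never disagree at the 70
  threshold; the suite measures this directly (`use_gaps = FALSE`
  disables gaps entirely). Both penalties are configurable through
  `alignment_params()`.
* **Tie-breaking across references** is deterministic: highest tier,
  then highest score (longest block for tier 2), then smallest
  |5′ offset| + |3′ offset|, then lexicographically smallest reference
  id. Reference sets are sorted by id on load.
* **Tier 2/3 offsets.** These tiers are 5′-anchored, so the recorded
  offsets are 0 at the 5′ end and `length(read) − length(reference)` at
  the 3′ end — the reference-relative proxy used downstream by the
  isomiR taxonomy.
* **Naming.** A read matched to any species' mature entry is reported
  under the fugu-prefixed family name of that entry (`dre-miR-1-3p` →
  `fru-miR-1-3p`), the conventional treatment of conserved miRNAs.
* The Smith–Waterman kernel is implemented in C++ (Gotoh recurrences,
  score of the empty alignment 0, symmetric in its arguments) and is
  checked in the tests against an independent recursive enumerator and
  against `Biostrings::pairwiseAlignment()`.

## Expression and size profiles

Expression is reads per million (RPM):
`raw_count / total(18–25-nt reads in the tissue) × 10⁶`, no pseudocounts.
Size distributions use a *different* denominator — the 1–35-nt total —
so that the per-length values of a tissue sum to 10⁶. Both denominators
are attached to the result objects to prevent silent mixing. Only tiers
1–3 count toward a family's expression; putative miRNAs are tabulated in
a separate table, never merged. Category proportions report the five
cascade fractions per tissue (summing to 1), optionally stratified by
read length; the length-weighted average of the stratified fractions
reproduces the unstratified ones.

## IsomiRs and seed shifts

All tier 1–3 reads of one family in one tissue form an isomiR group. The
**major isomiR** is the variant with the highest count (ties: longer
sequence, then lexicographic — fully deterministic). Election is
**per tissue**, since the cross-tissue reports compare per-tissue majors;
this is a deliberate choice where either reading was possible. Terminal
variation is classified from reference-relative end offsets, not raw
sequence comparison: 5′ shifts reflect sliding of the Drosha cleavage
site relative to the precursor, and offsets against the mature reference
are the available proxy. A variant differing from its major only in the
3′ offset is `3p_only`, only 5′ is `5p_only`, both is `both`, neither is
`identical`; internal substitutions with unchanged termini stay
`identical` in this strictly terminal taxonomy and are flagged
separately. The seed is nucleotides 2–8 from the 5′ terminus, so any 5′
shift changes it; `seed_shift_report()` lists every family whose
per-tissue majors carry at least two distinct seeds, with the major
sequence, seed and RPM per tissue.

## Differential expression

Between two tissues the statistic is the plain RPM ratio, with the
published filters: fold > 1.5 and RPM > 1000 **in the higher tissue
only** — the published tables contain rows like 2310 vs 30 RPM, which
rules out a both-tissue reading. Rounding is to the nearest integer,
halves away from zero. Zero-denominator records are flagged infinite and
listed separately rather than ranked. No replicate statistics are
computed: single-library ratios are putative by construction and the
output says so in a `putative` flag instead of fabricating a p-value.

## Size classes and putative piRNAs

The non-miRNA population is classified against a user-supplied
repeat-element FASTA by exact substring matching (read or reverse
complement shares ≥ 20 nt with a repeat). This replaces the original
live-database homology search, whose cutoffs were never stated: the
substring criterion is an explicit stand-in chosen for reproducibility,
not a reconstruction, and `min_exact` is configurable. At 20 nt a chance
hit has probability ~4⁻²⁰ per position, so false positives are
negligible. A read is a **putative piRNA** if it is 26–31 nt *and*
repeat-derived — the length class and origin characteristic of
PIWI-interacting RNAs, which dominate gonadal libraries. Category
precedence over the 1–35-nt population is total (miRNA > putative miRNA
> repeat-derived > unidentified), so fractions sum to 1. Because piRNA
validation would additionally require positional nucleotide-bias and
protein-association evidence, the composition table reports the 1U
fraction of putative piRNAs as a diagnostic without applying any
threshold.

## The simulator and what passing tests mean

`simulation_config()` defines the emulated conditions:

* **Tissue structure.** Somatic profiles are miRNA-dominated (default
  70% miRNA-origin reads) and peak at ~22 nt; gonadal profiles are
  dominated by 26–31-nt repeat windows (default 70%, mode 27 nt) with a
  small miRNA component — the contrast observed between somatic and
  gonadal libraries in the motivating data. Residual reads are uniform
  random background standing in for the other ncRNA classes a real
  library contains (which this pipeline would also leave unidentified).
* **Mature lengths** are drawn from a miRBase-like distribution over
  19–25 nt with mode 22, not uniformly: real mature miRNAs cluster
  tightly around 22 nt, and reference length interacts with the 18–25-nt
  annotation window (a uniform-length reference would clip far more
  3′-shortened variants than real data do).
* **IsomiR offsets** follow `default_isomir_offsets()`: 50% canonical,
  49% 3′-only variation concentrated at ±1–2 nt, 1% involving the 5′ end
  — the strongly 3′-biased terminal variation reported for vertebrate
  libraries. 3′ extensions are drawn uniformly at random; templated
  extension is unknowable without hairpins, and this is the documented
  simplification.
* **Substitutions** occur at 1% per nucleotide, enough to populate tiers
  2–3 without overwhelming tier 1.
* **Planted structure.** Two miRNAs carry fixed between-tissue
  expression ratios (folds 8 and 4 at ~10% and ~8% expression share;
  at 10⁵-read libraries the binomial sampling error of the recovered
  ratio is then ~3–5%, comfortably inside the ±10% recovery check — a
  power calculation made before any test was run). One reference
  (`fru-miR-462-5p`) has its offset distribution re-centred on the +1
  5′-shifted variant in the second tissue, so its per-tissue majors
  carry two different seeds and the seed-shift report must find it.
* **Raw reads** are a fixed 35 nt: insert + adapter + random fill,
  truncated. Inserts of 32–34 nt therefore leave adapter fragments of
  1–3 nt and remain untrimmed — the generative counterpart of the
  trimming exclusion zone.
* **Ground truth** is written per read. Truth tiers are derived
  generatively — from the known substitution positions, prefix
  integrity, the gap structure of the mismatch set, and an ungapped
  max-subarray (Kadane) score — an independent code path from the
  classifier's alignment kernels, so recovery comparisons are not
  self-fulfilling.

A single integer seed determines every output byte.

What passing does **not** show: the simulator has no quality-error
model, no templated 3′ tailing, no multi-locus families sharing seeds,
no true novel miRNAs, and its "other ncRNA" background is random
sequence. Recovery results therefore validate the pipeline's logic and
calibration, not its behaviour on every pathology of real libraries.

## Problem sizes

Unit tests run on libraries of 10³–5×10³ reads with ~20 references; the
end-to-end recovery checks use the default three-tissue configuration at
10⁵ reads per tissue and ~100 references, the scale at which the
recovery tolerances above are meaningful while a full test run stays in
the order of a minute. `scripts/acceptance.R` re-runs the same
configuration from scratch at an arbitrary seed.

## Known limitations

* Tier 1 cannot validate read nucleotides beyond the reference ends
  (no precursor context); such reads still count as exact-tier matches.
* The repeat criterion is presence/absence of one exact substring; it
  does not score divergent repeat copies.
* Differential calls are single-library ratios with no uncertainty;
  they are labelled putative and should be treated as screening output.
* IsomiR classification depends on the annotated offsets; for tier-2/3
  reads these are the 5′-anchored proxy, so a genuine combined 5′+3′
  variant carrying a substitution may be recorded as 3′-only.
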