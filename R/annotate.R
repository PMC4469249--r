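
# Four-tier homology classifier for 18-25-nt reads against a mature miRNA
# reference:
#   tier 1  ungapped placement, every overlapping position identical,
#           |5' offset| <= 2 and |3' offset| <= 4;
#   tier 2  first 10 nt identical and a contiguous identical block >= 16 nt
#           in the 5'-anchored comparison;
#   tier 3  first 10 nt identical, block < 16 nt, Smith-Waterman score
#           (+5/-4) >= 70;
#   putative miRNA  first 10 nt identical but none of the above;
#   unannotated otherwise.
# The cascade is exhaustive and mutually exclusive.

TIER_LEVELS <- c("miRNA_tier1", "miRNA_tier2", "miRNA_tier3",
                 "putative_miRNA", "unannotated")
MIRNA_TIERS <- TIER_LEVELS[1:3]

# Reads matched to any species' mature entry are reported under the
# fugu-prefixed family name of that entry (conserved-miRNA naming).
fru_family <- function(family) {
  ifelse(is.na(family), NA_character_, paste0("fru-", family))
}

#' Smith-Waterman local alignment score
#'
#' Maximum local-alignment score under the classifier's scoring scheme
#' (match +5, mismatch -4 by default) with affine gaps: a gap of length k
#' scores `gap_open + k * gap_extend`. The empty alignment scores 0 and the
#' function is symmetric in its arguments. `use_gaps = FALSE` forbids gaps
#' entirely (ungapped local alignment).
#'
#' @param a,b Sequences (character vectors; recycled pairwise).
#' @param params An [alignment_params()] object.
#' @param use_gaps Allow gapped alignments?
#' @return Integer vector of scores.
#' @examples
#' sw_score(strrep("ACGT", 4), strrep("ACGT", 4)) # 16 matches -> 80
#' @export
sw_score <- function(a, b, params = alignment_params(), use_gaps = TRUE) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  go <- if (use_gaps) params$gap_open else -10000000L
  sw_batch_cpp(a, b, params$match_score, params$mismatch_score,
               go, params$gap_extend)
}

#' Longest contiguous identical block (5'-anchored)
#'
#' Length of the longest run of identical nucleotides in the position-wise
#' comparison of read and reference, both anchored at position 1 (ungapped).
#'
#' @param read,ref Sequences (character vectors; recycled pairwise).
#' @return Integer vector of run lengths.
#' @export
longest_run <- function(read, ref) {
  n <- max(length(read), length(ref))
  longest_run_cpp(rep_len(read, n), rep_len(ref, n))
}

#' Offset-tolerant exact-match test (tier 1)
#'
#' Tests whether an ungapped placement of the read against the reference
#' exists with |5' offset| <= `max_5p_offset`, |3' offset| <= `max_3p_offset`
#' and every overlapping position identical. Offsets are read start (end)
#' minus reference start (end); negative 5' offsets mean the read extends 5'
#' of the reference. Read nucleotides extending past either reference end
#' are unconstrained (no precursor context is available to check them).
#' Among qualifying placements the one minimizing |5' offset| then
#' |3' offset| is reported.
#'
#' @param read,ref Single sequences.
#' @param params An [alignment_params()] object.
#' @return A one-row tibble: `match`, `offset_5p`, `offset_3p`.
#' @export
tier1_match <- function(read, ref, params = alignment_params()) {
  hit <- tier1_pair_cpp(read, ref, params$max_5p_offset, params$max_3p_offset)
  tibble(match = hit[1] == 1L, offset_5p = hit[2], offset_3p = hit[3])
}

#' References sharing the read's first 10 nucleotides
#'
#' @param read A single read sequence (length >= `prefix_len` to match
#'   anything; shorter reads return an empty set).
#' @param reference A reference tibble from [read_mirna_reference()].
#' @param params An [alignment_params()] object.
#' @return The subset of `reference` whose first `prefix_len` nt equal the
#'   read's.
#' @export
prefix10_candidates <- function(read, reference, params = alignment_params()) {
  k <- params$prefix_len
  if (nchar(read) < k) {
    return(reference[0, , drop = FALSE])
  }
  reference[substr(reference$sequence, 1L, k) == substr(read, 1L, k), ,
            drop = FALSE]
}

# Vectorized cascade over unique sequences. Returns one row per sequence.
classify_sequences <- function(seqs, reference, params) {
  n <- length(seqs)
  res <- tibble(
    sequence = seqs,
    tier = factor(rep("unannotated", n), levels = TIER_LEVELS),
    matched_id = NA_character_,
    offset_5p = NA_integer_, offset_3p = NA_integer_,
    longest_run = NA_integer_, sw_score = NA_integer_
  )
  if (n == 0L || nrow(reference) == 0L) return(res)

  reference <- arrange(reference, .data$id) # deterministic tie-breaking
  refseq <- reference$sequence

  ## tier 1: scan all references, winner = smallest |o5| + |o3| then id
  t1 <- tier1_scan_cpp(seqs, refseq, params$max_5p_offset, params$max_3p_offset)
  hit1 <- t1[, 1] > 0L
  res$tier[hit1] <- "miRNA_tier1"
  res$matched_id[hit1] <- reference$id[t1[hit1, 1]]
  res$offset_5p[hit1] <- t1[hit1, 2]
  res$offset_3p[hit1] <- t1[hit1, 3]

  ## prefix-10 candidates for the remainder
  rest <- which(!hit1)
  if (!length(rest)) return(res)
  k <- params$prefix_len
  ref_by_prefix <- split(seq_len(nrow(reference)), substr(refseq, 1L, k))
  cand <- ref_by_prefix[substr(seqs[rest], 1L, k)]
  cand[lengths(cand) == 0L | is.na(names(cand))] <- list(integer())
  has_cand <- lengths(cand) > 0L
  if (!any(has_cand)) return(res)

  pairs <- tibble(
    si = rep(rest[has_cand], lengths(cand[has_cand])),
    ri = unlist(cand[has_cand], use.names = FALSE)
  )
  pairs$run <- longest_run_cpp(seqs[pairs$si], refseq[pairs$ri])

  ## tier 2: best run >= 16; winner = longest run then id order
  best2 <- pairs |>
    arrange(.data$si, desc(.data$run), .data$ri) |>
    group_by(.data$si) |>
    slice_head(n = 1L) |>
    ungroup()
  t2 <- best2[best2$run >= params$min_contiguous, , drop = FALSE]
  if (nrow(t2)) {
    res$tier[t2$si] <- "miRNA_tier2"
    res$matched_id[t2$si] <- reference$id[t2$ri]
    res$offset_5p[t2$si] <- 0L
    res$offset_3p[t2$si] <- nchar(seqs[t2$si]) - nchar(refseq[t2$ri])
    res$longest_run[t2$si] <- t2$run
  }

  ## tier 3 / putative: Smith-Waterman over remaining candidate pairs
  rem <- setdiff(best2$si, t2$si)
  if (!length(rem)) return(res)
  p3 <- pairs[pairs$si %in% rem, , drop = FALSE]
  p3$sw <- sw_batch_cpp(seqs[p3$si], refseq[p3$ri],
                        params$match_score, params$mismatch_score,
                        params$gap_open, params$gap_extend)
  best3 <- p3 |>
    arrange(.data$si, desc(.data$sw), .data$ri) |>
    group_by(.data$si) |>
    slice_head(n = 1L) |>
    ungroup()
  is3 <- best3$sw >= params$sw_threshold
  idx3 <- best3$si[is3]
  res$tier[idx3] <- "miRNA_tier3"
  res$offset_5p[idx3] <- 0L
  res$offset_3p[idx3] <- nchar(seqs[idx3]) - nchar(refseq[best3$ri[is3]])
  res$tier[best3$si[!is3]] <- "putative_miRNA"
  res$matched_id[best3$si] <- reference$id[best3$ri]
  res$longest_run[best3$si] <- best3$run
  res$sw_score[best3$si] <- best3$sw
  res
}

#' Classify one read through the annotation cascade
#'
#' Applies the full four-tier cascade to a single 18-25-nt read. See
#' [annotate_reads()] for the vectorized library version.
#'
#' @param read A single read sequence (18-25 nt).
#' @param reference A reference tibble from [read_mirna_reference()].
#' @param params An [alignment_params()] object.
#' @return A one-row annotation tibble (`sequence`, `tier`, `matched_id`,
#'   `matched_family`, `offset_5p`, `offset_3p`, `longest_run`, `sw_score`).
#' @export
classify_read <- function(read, reference, params = alignment_params()) {
  if (nchar(read) < 18L || nchar(read) > 25L) {
    abort("classify_read() is defined for reads of 18-25 nt.",
          class = "tidysmallrna_contract_error")
  }
  res <- classify_sequences(read, reference, params)
  res$matched_family <- fru_family(
    reference$family[match(res$matched_id, reference$id)])
  res
}

#' Annotate a collapsed small RNA library
#'
#' Runs the four-tier cascade over every distinct 18-25-nt sequence and
#' joins the result back onto the (count-weighted) reads. Reads outside
#' 18-25 nt are not candidates for miRNA annotation and are dropped here
#' (they re-enter the analysis in [composition_summary()]).
#'
#' @param reads A collapsed read tibble (`sequence`, `count`, `tissue`).
#' @param reference A reference tibble from [read_mirna_reference()].
#' @param params An [alignment_params()] object.
#' @return A tibble of class `srna_annotation` with one row per (sequence,
#'   tissue): `sequence`, `count`, `tissue`, `tier`, `matched_id`,
#'   `matched_family`, `offset_5p`, `offset_3p`, `longest_run`, `sw_score`.
#'   Deterministic given its inputs.
#' @export
annotate_reads <- function(reads, reference, params = alignment_params()) {
  if (nrow(reference) == 0L) {
    warn("Empty reference set: every read will be unannotated.")
  }
  reads <- select_length(reads, 18L, 25L)
  u <- unique(reads$sequence)
  cls <- classify_sequences(u, reference, params)
  cls$matched_family <- fru_family(
    reference$family[match(cls$matched_id, reference$id)])
  out <- reads |>
    left_join(cls, by = "sequence") |>
    select("sequence", "count", "tissue", "tier", "matched_id",
           "matched_family", "offset_5p", "offset_3p", "longest_run",
           "sw_score") |>
    arrange(.data$tissue, .data$sequence)
  if (nrow(out) == 0L) {
    out$tier <- factor(character(), levels = TIER_LEVELS)
  }
  class(out) <- c("srna_annotation", class(out))
  out
}

#' Per-tier read counts
#'
#' Collapse-weighted read counts per tissue and tier (every tier always
#' present, zero-filled); the per-tissue totals equal the 18-25-nt totals.
#'
#' @param annotations An `srna_annotation` tibble.
#' @return A tibble `tissue`, `tier`, `reads`.
#' @export
tier_counts <- function(annotations) {
  annotations |>
    as_tibble() |>
    group_by(.data$tissue, .data$tier) |>
    summarise(reads = sum(.data$count), .groups = "drop") |>
    tidyr::complete(tissue = unique(annotations$tissue),
                    tier = factor(TIER_LEVELS, levels = TIER_LEVELS),
                    fill = list(reads = 0L)) |>
    arrange(.data$tissue, .data$tier)
}

#' @export
tidy.srna_annotation <- function(x, ...) {
  tc <- tier_counts(x)
  tc |>
    group_by(.data$tissue) |>
    mutate(fraction = if (sum(.data$reads) > 0)
      .data$reads / sum(.data$reads) else rep(0, n())) |>
    ungroup()
}

#' @export
glance.srna_annotation <- function(x, ...) {
  tb <- as_tibble(x)
  tibble(
    n_sequences = nrow(tb),
    n_reads = sum(tb$count),
    n_tissues = length(unique(tb$tissue)),
    pct_mirna = if (sum(tb$count) > 0)
      100 * sum(tb$count[tb$tier %in% MIRNA_TIERS]) / sum(tb$count) else NA_real_
  )
}
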