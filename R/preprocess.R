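
#' Remove low-quality reads
#'
#' Drops reads whose mean Phred quality (Sanger encoding) is below
#' `min_mean_q`. The sequencing study this mirrors removed low-quality
#' reads without stating a criterion; mean Phred >= 20 is the configurable
#' default here. Input without a `quality` column (FASTA) is returned
#' unchanged with a warning.
#'
#' @param reads A read tibble from [read_smallrna()].
#' @param min_mean_q Minimum mean Phred quality.
#' @return The filtered tibble; the number removed is reported and attached
#'   as attribute `n_removed`.
#' @export
quality_filter <- function(reads, min_mean_q = 20) {
  if (!"quality" %in% names(reads)) {
    warn("No `quality` column (FASTA input?); quality filter is a no-op.")
    attr(reads, "n_removed") <- 0L
    return(reads)
  }
  mean_q <- vapply(reads$quality,
                   function(q) mean(utf8ToInt(q)) - 33,
                   numeric(1), USE.NAMES = FALSE)
  keep <- mean_q >= min_mean_q
  n_removed <- sum(!keep)
  if (n_removed > 0) {
    inform(sprintf("Quality filter removed %d of %d read(s) (mean Q < %g).",
                   n_removed, length(keep), min_mean_q))
  }
  out <- reads[keep, , drop = FALSE]
  attr(out, "n_removed") <- n_removed
  out
}

#' Trim the 3' sequencing adapter
#'
#' Finds the leftmost position at which the read suffix matches a prefix of
#' the adapter over at least `min_overlap` nucleotides (either a full
#' adapter occurrence inside the read, or an adapter prefix reaching the
#' read's 3' end) and truncates there. Adapter fragments of fewer than
#' `min_overlap` nucleotides cannot be distinguished from genuine small RNA
#' sequence and are deliberately retained, so on fixed 35-nt raw reads the
#' trimmed lengths fall in 0-31 or stay at 35 -- lengths 32-34 cannot occur.
#' Trimming is idempotent under exact matching.
#'
#' @param sequences Character vector of read sequences.
#' @param adapter The 3' adapter sequence (length >= `min_overlap`).
#' @param min_overlap Minimum adapter overlap (nt) required to trim.
#' @return A tibble with columns `sequence` (trimmed), `trimmed_length`,
#'   `adapter_found`.
#' @examples
#' trim_adapter(c("ACGTACGTTGGAATTCTC", "ACGTACGT"), adapter = "TGGAATTCTCGGGTGCCAAGG")
#' @export
trim_adapter <- function(sequences, adapter, min_overlap = 4L) {
  adapter <- normalize_seq(adapter)
  alen <- nchar(adapter)
  if (alen < min_overlap) {
    abort("`adapter` must be at least `min_overlap` nt long.",
          class = "tidysmallrna_param_error")
  }
  len <- nchar(sequences)
  cut_at <- rep(NA_integer_, length(sequences))
  max_len <- if (length(len)) max(len) else 0L
  for (p in seq_len(max_len)) {
    overlap <- pmin(alen, len - p + 1L)
    cand <- which(is.na(cut_at) & overlap >= min_overlap)
    if (!length(cand)) next
    hit <- substr(sequences[cand], p, p + overlap[cand] - 1L) ==
      substr(adapter, 1L, overlap[cand])
    cut_at[cand[hit]] <- p
  }
  found <- !is.na(cut_at)
  trimmed <- sequences
  trimmed[found] <- substr(sequences[found], 1L, cut_at[found] - 1L)
  tibble(sequence = trimmed,
         trimmed_length = nchar(trimmed),
         adapter_found = found)
}

#' @describeIn trim_adapter Trim a read tibble in place: replaces
#'   `sequence`, drops any `quality` column, and adds `trimmed_length` and
#'   `adapter_found`.
#' @param reads A read tibble.
#' @export
trim_reads <- function(reads, adapter, min_overlap = 4L) {
  tr <- trim_adapter(reads$sequence, adapter, min_overlap)
  out <- reads
  out$sequence <- tr$sequence
  out$quality <- NULL
  out$trimmed_length <- tr$trimmed_length
  out$adapter_found <- tr$adapter_found
  out
}

#' Collapse identical read sequences
#'
#' Merges identical sequences into one record with summed counts. All reads
#' must share one tissue label; total count is conserved.
#'
#' @param reads A read tibble with `sequence`, `count`, `tissue`.
#' @return A tibble with one row per distinct sequence.
#' @export
collapse_reads <- function(reads) {
  if (nrow(reads) == 0) {
    return(tibble(sequence = character(), count = integer(),
                  tissue = character()))
  }
  if (length(unique(reads$tissue)) > 1L) {
    abort("collapse_reads() requires a single tissue per call.",
          class = "tidysmallrna_contract_error")
  }
  reads |>
    group_by(.data$sequence, .data$tissue) |>
    summarise(count = sum(.data$count), .groups = "drop") |>
    select("sequence", "count", "tissue") |>
    arrange(.data$sequence)
}

#' Select reads by length
#'
#' @param reads A read tibble.
#' @param lo,hi Inclusive length bounds (nt).
#' @return The subset with `lo <= nchar(sequence) <= hi`.
#' @export
select_length <- function(reads, lo, hi) {
  stopifnot(lo <= hi)
  reads[nchar(reads$sequence) >= lo & nchar(reads$sequence) <= hi, ,
        drop = FALSE]
}
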