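
# Non-miRNA population: repeat-derived reads and putative piRNAs.
# The repeat call is an exact-substring criterion against a user-supplied
# repeat-element FASTA (>= min_exact nt shared with the read or its
# reverse complement); at the default 20 nt a chance hit against unrelated
# sequence has probability ~4^-20 per position, so false positives are
# negligible.

revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGTN", "TGCAN", x))
}

repeat_kmer_set <- function(repeats, k) {
  seqs <- c(repeats$sequence, revcomp(repeats$sequence))
  seqs <- seqs[nchar(seqs) >= k]
  unique(unlist(lapply(seqs, function(s) {
    substring(s, seq_len(nchar(s) - k + 1L), seq(k, nchar(s)))
  }), use.names = FALSE))
}

#' Does a read derive from a repeat element?
#'
#' TRUE iff the read or its reverse complement shares an exact substring of
#' at least `min_exact` nt with any repeat sequence.
#'
#' @param sequences Character vector of read sequences.
#' @param repeats A repeat tibble from [read_repeat_fasta()] (empty set:
#'   always FALSE, with a warning).
#' @param min_exact Minimum exact-match length (nt).
#' @return Logical vector.
#' @export
repeat_match <- function(sequences, repeats, min_exact = 20L) {
  if (is.null(repeats) || nrow(repeats) == 0L) {
    warn("Empty repeat set: repeat_match() is FALSE everywhere.")
    return(rep(FALSE, length(sequences)))
  }
  kmers <- repeat_kmer_set(repeats, min_exact)
  hit <- rep(FALSE, length(sequences))
  len <- nchar(sequences)
  max_start <- max(len) - min_exact + 1L
  for (p in seq_len(max(0L, max_start))) {
    cand <- which(!hit & len - p + 1L >= min_exact)
    if (!length(cand)) break
    hit[cand] <- substr(sequences[cand], p, p + min_exact - 1L) %in% kmers
  }
  hit
}

#' Flag putative piRNAs
#'
#' TRUE iff the (trimmed) read is 26-31 nt long and repeat-derived --
#' the length class and repeat origin characteristic of PIWI-interacting
#' RNAs, which dominate gonadal small RNA libraries.
#'
#' @inheritParams repeat_match
#' @return Logical vector.
#' @export
flag_putative_pirna <- function(sequences, repeats, min_exact = 20L) {
  len <- nchar(sequences)
  len >= 26L & len <= 31L & repeat_match(sequences, repeats, min_exact)
}

#' Composition of the full 1-35-nt small RNA population
#'
#' Assigns every read exactly one category with precedence
#' miRNA (tiers 1-3) > putative miRNA > repeat-derived > unidentified
#' (`other_annotated` is reserved for annotation sources outside this
#' pipeline and is always zero here), and reports per-tissue fractions,
#' the putative-piRNA fraction (26-31 nt AND repeat-derived), and the
#' fraction of putative-piRNA reads starting with U (T) -- the 1U bias is
#' a standard piRNA diagnostic, reported without applying a threshold.
#'
#' @param reads The full trimmed, collapsed 1-35-nt read tibble.
#' @param annotations The `srna_annotation` of the 18-25-nt subset.
#' @param repeats A repeat tibble (may be empty).
#' @param min_exact Minimum exact repeat match (nt).
#' @return A tibble of class `srna_composition` with one row per tissue
#'   and category plus per-tissue `putative_pirna_fraction` and
#'   `pirna_u1_fraction` columns.
#' @export
composition_summary <- function(reads, annotations, repeats,
                                min_exact = 20L) {
  reads <- select_length(reads, 1L, 35L)
  ann <- annotations |>
    as_tibble() |>
    select("sequence", "tissue", "tier")
  tb <- reads |>
    left_join(ann, by = c("sequence", "tissue")) |>
    mutate(
      is_repeat = repeat_match(.data$sequence, repeats, min_exact),
      length = nchar(.data$sequence),
      category = dplyr::case_when(
        .data$tier %in% MIRNA_TIERS ~ "miRNA",
        .data$tier == "putative_miRNA" ~ "putative_miRNA",
        .data$is_repeat ~ "repeat_derived",
        .default = "unidentified"
      ),
      is_pirna = .data$is_repeat & .data$length >= 26L & .data$length <= 31L,
      u1 = substr(.data$sequence, 1L, 1L) == "T"
    )
  cats <- c("miRNA", "putative_miRNA", "repeat_derived", "other_annotated",
            "unidentified")
  per_tissue <- tb |>
    group_by(.data$tissue) |>
    summarise(
      total = sum(.data$count),
      putative_pirna_fraction = sum(.data$count[.data$is_pirna]) / sum(.data$count),
      pirna_u1_fraction = if (sum(.data$count[.data$is_pirna]) > 0)
        sum(.data$count[.data$is_pirna & .data$u1]) /
          sum(.data$count[.data$is_pirna]) else NA_real_,
      .groups = "drop")
  out <- tb |>
    group_by(.data$tissue,
             category = factor(.data$category, levels = cats)) |>
    summarise(reads = sum(.data$count), .groups = "drop_last") |>
    tidyr::complete(category = factor(cats, levels = cats),
                    fill = list(reads = 0L)) |>
    mutate(fraction = .data$reads / sum(.data$reads)) |>
    ungroup() |>
    left_join(per_tissue, by = "tissue") |>
    arrange(.data$tissue, .data$category)
  class(out) <- c("srna_composition", class(out))
  out
}
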