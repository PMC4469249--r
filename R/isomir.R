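
# IsomiRs are terminal sequence variants of one mature miRNA. Variation is
# classified from reference-relative end offsets (5' shifts move the seed,
# reflecting variable Drosha/Dicer cleavage), never from raw sequence
# comparison: internal substitutions with unchanged termini are logged as
# internal variants but stay "identical" in the terminal taxonomy.

#' Group annotated reads into isomiR families
#'
#' Every confidently annotated read (tiers 1-3) joins the group of its
#' matched family in its tissue. Each group's major isomiR is elected by
#' [major_isomir()] and every variant is classified against it with
#' [classify_variant()].
#'
#' @param annotations An `srna_annotation` tibble.
#' @return A tibble of class `srna_isomir` with one row per variant:
#'   `family`, `tissue`, `sequence`, `count`, `offset_5p`, `offset_3p`,
#'   `is_major`, `major_sequence`, `variant_class`, `internal_variant`.
#'   The per-tissue 18-25-nt totals are attached as attribute
#'   `denominators`; the number of internal variants is reported.
#' @export
isomir_groups <- function(annotations) {
  totals <- total_18_25_by_tissue(annotations)
  v <- annotations |>
    as_tibble() |>
    filter(.data$tier %in% MIRNA_TIERS) |>
    select(family = "matched_family", "tissue", "sequence", "count",
           "offset_5p", "offset_3p")
  grouped <- v |>
    group_by(.data$family, .data$tissue) |>
    mutate(major_sequence = major_isomir(dplyr::pick("sequence", "count"))) |>
    mutate(is_major = .data$sequence == .data$major_sequence,
           major_offset_5p = .data$offset_5p[.data$is_major][1],
           major_offset_3p = .data$offset_3p[.data$is_major][1]) |>
    ungroup() |>
    mutate(variant_class = classify_variant(
      .data$offset_5p, .data$offset_3p,
      .data$major_offset_5p, .data$major_offset_3p),
      internal_variant = .data$variant_class == "identical" & !.data$is_major) |>
    select(-"major_offset_5p", -"major_offset_3p") |>
    arrange(.data$family, .data$tissue, desc(.data$count), .data$sequence)
  n_internal <- sum(grouped$internal_variant)
  if (n_internal > 0) {
    inform(sprintf(
      "%d variant(s) share their major's end offsets but differ internally (classified 'identical' at the termini).",
      n_internal))
  }
  attr(grouped, "denominators") <- totals
  class(grouped) <- c("srna_isomir", class(grouped))
  grouped
}

#' Elect the major isomiR of a group
#'
#' The variant with the highest count; ties are broken by longer sequence,
#' then lexicographically smallest sequence (deterministic).
#'
#' @param group A tibble with columns `sequence`, `count` (one isomiR
#'   group).
#' @return The major sequence (length-1 character).
#' @export
major_isomir <- function(group) {
  if (nrow(group) == 0L) {
    abort("major_isomir() on an empty group.",
          class = "tidysmallrna_contract_error")
  }
  o <- order(-group$count, -nchar(group$sequence), group$sequence)
  group$sequence[o[1]]
}

#' Classify terminal variation relative to the major isomiR
#'
#' Compares reference-relative end offsets: a variant differing from the
#' major only at the 3' offset is `3p_only`, only at the 5' offset
#' `5p_only`, at both `both`, at neither `identical`.
#'
#' @param offset_5p,offset_3p Variant offsets.
#' @param major_offset_5p,major_offset_3p Offsets of the group's major.
#' @return A factor with levels `identical`, `3p_only`, `5p_only`, `both`.
#' @export
classify_variant <- function(offset_5p, offset_3p,
                             major_offset_5p, major_offset_3p) {
  d5 <- offset_5p != major_offset_5p
  d3 <- offset_3p != major_offset_3p
  cls <- dplyr::case_when(
    d5 & d3 ~ "both",
    d5 ~ "5p_only",
    d3 ~ "3p_only",
    .default = "identical"
  )
  factor(cls, levels = c("identical", "3p_only", "5p_only", "both"))
}

#' Seed sequence (positions 2-8)
#'
#' The 7-nt seed, nucleotides 2-8 from the 5' terminus (1-based,
#' inclusive) -- the principal determinant of target recognition, so 5'
#' isomiR shifts change it.
#'
#' @param sequence Character vector of sequences, each of length >= 8 nt.
#' @return Character vector of 7-nt seeds.
#' @examples
#' seed_of("GTAACGGAACCCATAATGCAGCT") # "TAACGGA"
#' @export
seed_of <- function(sequence) {
  if (any(nchar(sequence) < 8L)) {
    abort("seed_of() requires sequences of at least 8 nt.",
          class = "tidysmallrna_contract_error")
  }
  substr(sequence, 2L, 8L)
}

#' Families whose major isomiR's seed shifts between tissues
#'
#' Reports, for every family whose per-tissue major isomiRs carry at least
#' two distinct seeds, the major sequence, its seed and its RPM in every
#' tissue. Families with a single common seed across tissues are excluded.
#'
#' @param groups An `srna_isomir` tibble from [isomir_groups()] spanning at
#'   least two tissues (fewer yield an empty report).
#' @return A tibble `family`, `tissue`, `major_sequence`, `seed`, `rpm`,
#'   ordered by family then tissue.
#' @export
seed_shift_report <- function(groups) {
  totals <- attr(groups, "denominators")
  majors <- groups |>
    as_tibble() |>
    filter(.data$is_major) |>
    group_by(.data$family, .data$tissue, .data$major_sequence) |>
    summarise(count = sum(.data$count), .groups = "drop") |>
    mutate(seed = seed_of(.data$major_sequence))
  if (length(unique(majors$tissue)) < 2L) {
    return(tibble(family = character(), tissue = character(),
                  major_sequence = character(), seed = character(),
                  rpm = double()))
  }
  shifted <- majors |>
    group_by(.data$family) |>
    filter(length(unique(.data$seed)) >= 2L) |>
    ungroup()
  shifted |>
    left_join(totals, by = "tissue") |>
    mutate(rpm = compute_rpm(.data$count, .data$total_18_25)) |>
    select("family", "tissue", "major_sequence", "seed", "rpm") |>
    arrange(.data$family, .data$tissue)
}
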