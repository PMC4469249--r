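
#' Reads per million (RPM)
#'
#' `raw_count / total_18_25 * 1e6`, with no pseudocounts. The denominator
#' for miRNA expression is the total number of 18-25-nt reads in the
#' tissue; size distributions (see [size_distribution()]) use the 1-35-nt
#' total instead -- the two denominators are never mixed.
#'
#' @param raw_count Read count(s) of the miRNA.
#' @param total_18_25 Total 18-25-nt read count of the tissue (>= 1).
#' @return RPM value(s); linear in `raw_count`.
#' @examples
#' compute_rpm(50, 1e6)
#' @export
compute_rpm <- function(raw_count, total_18_25) {
  if (any(total_18_25 < 1)) {
    abort("RPM denominator `total_18_25` must be >= 1.",
          class = "tidysmallrna_contract_error")
  }
  raw_count / total_18_25 * 1e6
}

total_18_25_by_tissue <- function(annotations) {
  annotations |>
    as_tibble() |>
    group_by(.data$tissue) |>
    summarise(total_18_25 = sum(.data$count), .groups = "drop")
}

#' miRNA expression matrix (long form)
#'
#' Collapse-weighted read counts and RPM per miRNA family and tissue. Only
#' the confident miRNA tiers (1-3) contribute; putative miRNAs are
#' tabulated separately by [putative_expression()]. Missing family/tissue
#' combinations are explicit zeros. Per-tissue denominators (total
#' 18-25-nt reads) are attached as attribute `denominators`.
#'
#' @param annotations An `srna_annotation` tibble.
#' @return A tibble of class `srna_expression`: `mirna_id` (fugu-prefixed
#'   family name), `tissue`, `raw_count`, `rpm`.
#' @export
expression_matrix <- function(annotations) {
  expression_table(annotations, tiers = MIRNA_TIERS, cls = "srna_expression")
}

#' Putative-miRNA expression table
#'
#' Same layout as [expression_matrix()] but restricted to reads whose only
#' evidence is 10-nt prefix identity (the putative tier).
#'
#' @inheritParams expression_matrix
#' @return A tibble `mirna_id`, `tissue`, `raw_count`, `rpm`.
#' @export
putative_expression <- function(annotations) {
  expression_table(annotations, tiers = "putative_miRNA",
                   cls = "srna_expression")
}

expression_table <- function(annotations, tiers, cls) {
  totals <- total_18_25_by_tissue(annotations)
  tb <- annotations |>
    as_tibble() |>
    filter(.data$tier %in% tiers, !is.na(.data$matched_family)) |>
    group_by(mirna_id = .data$matched_family, .data$tissue) |>
    summarise(raw_count = sum(.data$count), .groups = "drop")
  if (nrow(tb) > 0) {
    tb <- tidyr::complete(tb, .data$mirna_id, tissue = totals$tissue,
                          fill = list(raw_count = 0L))
  }
  out <- tb |>
    left_join(totals, by = "tissue") |>
    mutate(rpm = compute_rpm(.data$raw_count, .data$total_18_25)) |>
    select("mirna_id", "tissue", "raw_count", "rpm") |>
    arrange(.data$mirna_id, .data$tissue)
  attr(out, "denominators") <- totals
  class(out) <- c(cls, class(out))
  out
}

#' Read-length distribution per tissue
#'
#' Per-length read counts over 1-35 nt, normalized to reads per million
#' 1-35-nt reads (so the values for one tissue sum to 1e6).
#'
#' @param reads A trimmed (and typically collapsed) read tibble.
#' @return A tibble of class `srna_size_distribution`: `tissue`, `length`,
#'   `reads`, `rpm`.
#' @export
size_distribution <- function(reads) {
  reads <- select_length(reads, 1L, 35L)
  if (nrow(reads) == 0L) {
    abort("size_distribution() on an empty library.",
          class = "tidysmallrna_contract_error")
  }
  tissues <- unique(reads$tissue)
  out <- reads |>
    mutate(length = nchar(.data$sequence)) |>
    group_by(.data$tissue, .data$length) |>
    summarise(reads = sum(.data$count), .groups = "drop") |>
    tidyr::complete(tissue = tissues, length = 1:35,
                    fill = list(reads = 0L)) |>
    group_by(.data$tissue) |>
    mutate(rpm = .data$reads / sum(.data$reads) * 1e6) |>
    ungroup() |>
    arrange(.data$tissue, .data$length)
  class(out) <- c("srna_size_distribution", class(out))
  out
}

#' Annotation-category proportions of the 18-25-nt population
#'
#' Fractions of collapse-weighted 18-25-nt reads falling in each of the
#' five cascade categories, per tissue (optionally stratified by read
#' length). The five fractions sum to 1; stratified fractions, averaged
#' with length weights, reproduce the unstratified ones.
#'
#' @param annotations An `srna_annotation` tibble.
#' @param stratify_by_length Report fractions per read length 18-25?
#' @return A tibble of class `srna_category_proportions`: `tissue`,
#'   (`length`,) `tier`, `reads`, `fraction`.
#' @export
category_proportions <- function(annotations, stratify_by_length = FALSE) {
  tb <- as_tibble(annotations)
  grp <- if (stratify_by_length) {
    tb |>
      mutate(length = nchar(.data$sequence)) |>
      group_by(.data$tissue, .data$length, .data$tier)
  } else {
    group_by(tb, .data$tissue, .data$tier)
  }
  out <- grp |>
    summarise(reads = sum(.data$count), .groups = "drop_last") |>
    tidyr::complete(tier = factor(TIER_LEVELS, levels = TIER_LEVELS),
                    fill = list(reads = 0L)) |>
    mutate(fraction = if (sum(.data$reads) > 0)
      .data$reads / sum(.data$reads) else rep(0, n())) |>
    ungroup() |>
    arrange(across(all_of(setdiff(c("tissue", "length", "tier"),
                                  if (stratify_by_length) NULL else "length"))))
  class(out) <- c("srna_category_proportions", class(out))
  out
}
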