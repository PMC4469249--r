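
#' Fold change between two RPM values
#'
#' `fold = rpm_a / rpm_b`; `fold_rounded` is the nearest integer, halves
#' away from zero. A zero denominator yields an infinite-fold flag
#' (`fold = Inf`, `fold_rounded = NA`): such records are excluded from
#' ranking and listed separately by [differential_table()].
#'
#' @param rpm_a,rpm_b RPM values (numerator / denominator), recycled
#'   pairwise.
#' @return A tibble `fold`, `fold_rounded`, `infinite`.
#' @examples
#' fold_change(2310, 30)  # fold_rounded 77
#' fold_change(9054, 409) # fold_rounded 22
#' @export
fold_change <- function(rpm_a, rpm_b) {
  n <- max(length(rpm_a), length(rpm_b))
  rpm_a <- rep_len(rpm_a, n)
  rpm_b <- rep_len(rpm_b, n)
  inf <- rpm_b == 0
  fold <- ifelse(inf, Inf, rpm_a / rpm_b)
  fold_rounded <- rep(NA_integer_, n)
  fold_rounded[!inf] <- round_half_away(fold[!inf])
  tibble(fold = fold, fold_rounded = fold_rounded, infinite = inf)
}

# round half away from zero (round() rounds half to even)
round_half_away <- function(x) {
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

#' Ratio-based differential expression between two tissues
#'
#' For each direction (a over b, then b over a), keeps miRNAs with
#' `fold > min_fold` and RPM in the *higher* tissue above `min_rpm`, ranks
#' by descending fold (ties: higher `rpm_high`, then id) and truncates to
#' `top_n`. No replicate statistics are computed -- single-library ratios
#' are putative by construction, and the output carries a `putative` flag
#' rather than a significance column. Records with a zero-RPM denominator
#' are set aside in the `infinite` attribute.
#'
#' @param expr An `srna_expression` tibble from [expression_matrix()].
#' @param tissue_a,tissue_b Tissue labels present in `expr`.
#' @param min_fold Minimum fold (exclusive) to keep a record.
#' @param min_rpm Minimum RPM (exclusive) required of the higher tissue.
#' @param top_n Rows kept per direction.
#' @return A tibble of class `srna_differential`: `direction`, `mirna_id`,
#'   `tissue_high`, `tissue_low`, `rpm_high`, `rpm_low`, `fold`,
#'   `fold_rounded`, `putative`.
#' @export
differential_table <- function(expr, tissue_a, tissue_b,
                               min_fold = 1.5, min_rpm = 1000, top_n = 5L) {
  tissues <- unique(expr$tissue)
  if (!all(c(tissue_a, tissue_b) %in% tissues)) {
    abort(sprintf("Tissue(s) not in the expression matrix: %s",
                  paste(setdiff(c(tissue_a, tissue_b), tissues),
                        collapse = ", ")),
          class = "tidysmallrna_contract_error")
  }
  wide <- expr |>
    as_tibble() |>
    filter(.data$tissue %in% c(tissue_a, tissue_b)) |>
    select("mirna_id", "tissue", "rpm") |>
    tidyr::pivot_wider(names_from = "tissue", values_from = "rpm",
                       values_fill = 0)

  one_direction <- function(hi, lo, label) {
    fc <- fold_change(wide[[hi]], wide[[lo]])
    d <- tibble(direction = label, mirna_id = wide$mirna_id,
                tissue_high = hi, tissue_low = lo,
                rpm_high = wide[[hi]], rpm_low = wide[[lo]],
                fold = fc$fold, fold_rounded = fc$fold_rounded,
                infinite = fc$infinite)
    finite <- d |>
      filter(!.data$infinite, .data$fold > min_fold, .data$rpm_high > min_rpm) |>
      arrange(desc(.data$fold), desc(.data$rpm_high), .data$mirna_id) |>
      slice_head(n = top_n)
    list(kept = finite,
         infinite = filter(d, .data$infinite, .data$rpm_high > min_rpm))
  }
  ab <- one_direction(tissue_a, tissue_b, "a_gt_b")
  ba <- one_direction(tissue_b, tissue_a, "b_gt_a")
  out <- bind_rows(ab$kept, ba$kept) |>
    select(-"infinite") |>
    mutate(putative = TRUE)
  attr(out, "infinite") <- bind_rows(ab$infinite, ba$infinite)
  class(out) <- c("srna_differential", class(out))
  out
}

#' @export
tidy.srna_differential <- function(x, ...) {
  as_tibble(x)
}

#' @export
glance.srna_differential <- function(x, ...) {
  tb <- as_tibble(x)
  tibble(
    n_a_gt_b = sum(tb$direction == "a_gt_b"),
    n_b_gt_a = sum(tb$direction == "b_gt_a"),
    max_fold = if (nrow(tb)) max(tb$fold) else NA_real_,
    n_infinite = nrow(attr(x, "infinite") %||% tibble())
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
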