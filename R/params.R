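#' Alignment and classification parameters
#'
#' Bundles every constant of the four-tier miRNA classifier: the
#' Smith-Waterman match/mismatch scores (+5/-4) and acceptance threshold
#' (70), the minimum contiguous-match length (16 nt), the 5' prefix-identity
#' length (10 nt), and the offset tolerances of the exact-match tier
#' (1-2 nt at the 5' end, 1-4 nt at the 3' end). Gap penalties are not part
#' of the published scoring scheme and default to a stiff affine penalty
#' (a gap of length k scores `gap_open + k * gap_extend`); on 18-25-nt
#' reads they almost never change a threshold decision (see the methods
#' vignette), and `use_gaps = FALSE` in [sw_score()] disables them.
#'
#' @param match_score Integer score for a matching pair of nucleotides.
#' @param mismatch_score Integer score for a mismatching pair (negative).
#' @param gap_open Gap opening score (negative).
#' @param gap_extend Per-position gap extension score (negative).
#' @param sw_threshold Minimum Smith-Waterman score for a tier-3 call.
#' @param min_contiguous Minimum contiguous identical block (nt) for tier 2.
#' @param prefix_len 5' prefix length (nt) that must be identical for a read
#'   to enter tiers 2-3 / putative consideration.
#' @param max_5p_offset Maximum |5' offset| (nt) tolerated by tier 1.
#' @param max_3p_offset Maximum |3' offset| (nt) tolerated by tier 1.
#' @return An object of class `alignment_params` (a named list).
#' @examples
#' alignment_params()
#' @export
alignment_params <- function(match_score = 5L, mismatch_score = -4L,
                             gap_open = -12L, gap_extend = -4L,
                             sw_threshold = 70L, min_contiguous = 16L,
                             prefix_len = 10L, max_5p_offset = 2L,
                             max_3p_offset = 4L) {
  p <- list(
    match_score = as.integer(match_score),
    mismatch_score = as.integer(mismatch_score),
    gap_open = as.integer(gap_open),
    gap_extend = as.integer(gap_extend),
    sw_threshold = as.integer(sw_threshold),
    min_contiguous = as.integer(min_contiguous),
    prefix_len = as.integer(prefix_len),
    max_5p_offset = as.integer(max_5p_offset),
    max_3p_offset = as.integer(max_3p_offset)
  )
  if (p$match_score <= 0 || p$mismatch_score >= 0) {
    abort("`match_score` must be > 0 and `mismatch_score` < 0.",
          class = "tidysmallrna_param_error")
  }
  if (p$sw_threshold <= 0) {
    abort("`sw_threshold` must be positive.",
          class = "tidysmallrna_param_error")
  }
  if (p$gap_open > 0 || p$gap_extend > 0) {
    abort("gap penalties must be <= 0.", class = "tidysmallrna_param_error")
  }
  structure(p, class = "alignment_params")
}

#' @export
print.alignment_params <- function(x, ...) {
  cat("<alignment_params>\n")
  cat(sprintf("  match %+d / mismatch %+d, gaps %d/%d\n",
              x$match_score, x$mismatch_score, x$gap_open, x$gap_extend))
  cat(sprintf("  tier 1: |5' offset| <= %d, |3' offset| <= %d\n",
              x$max_5p_offset, x$max_3p_offset))
  cat(sprintf("  tier 2: prefix %d nt identical, run >= %d nt\n",
              x$prefix_len, x$min_contiguous))
  cat(sprintf("  tier 3: Smith-Waterman score >= %d\n", x$sw_threshold))
  invisible(x)
}
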