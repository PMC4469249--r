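# Independent reference implementations used only to check the package's
# alignment code. Both are deliberately naive; neither shares code with
# the implementation under test.

# Local affine alignment score by top-down recursion over end states
# (memoised). State 1: alignment ends with an aligned pair at (i, j);
# state 2: ends with a gap in b; state 3: ends with a gap in a.
local_align_oracle <- function(a, b, match = 5, mismatch = -4,
                               gap_open = -12, gap_extend = -4) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A)
  m <- length(B)
  if (n == 0 || m == 0) return(0)
  memo <- array(NA_real_, dim = c(n, m, 3))
  best_end <- function(i, j, s) {
    if (i < 1 || j < 1) return(-Inf)
    if (!is.na(memo[i, j, s])) return(memo[i, j, s])
    v <- if (s == 1) {
      prev <- max(0, best_end(i - 1, j - 1, 1), best_end(i - 1, j - 1, 2),
                  best_end(i - 1, j - 1, 3))
      prev + if (A[i] == B[j]) match else mismatch
    } else if (s == 2) {
      max(best_end(i - 1, j, 1) + gap_open + gap_extend,
          best_end(i - 1, j, 2) + gap_extend)
    } else {
      max(best_end(i, j - 1, 1) + gap_open + gap_extend,
          best_end(i, j - 1, 3) + gap_extend)
    }
    memo[i, j, s] <<- v
    v
  }
  best <- 0
  for (i in seq_len(n)) for (j in seq_len(m)) {
    best <- max(best, best_end(i, j, 1))
  }
  best
}

# Exhaustive enumeration of every ungapped placement of read against ref
# with |offset_5p| <= 2 and |offset_3p| <= 4 (the 5 x 9 offset grid; for
# given lengths offset_3p is determined by offset_5p). Returns the same
# (match, offset_5p, offset_3p) triple as tier1_match().
tier1_oracle <- function(read, ref, max5 = 2, max3 = 4) {
  L <- nchar(read)
  R <- nchar(ref)
  rd <- strsplit(read, "")[[1]]
  rf <- strsplit(ref, "")[[1]]
  hits <- list()
  for (o5 in seq(-max5, max5)) {
    o3 <- o5 + L - R
    if (abs(o3) > max3) next
    cs <- max(1, 1 + o5)
    ce <- min(R, L + o5)
    if (cs > ce) next
    if (all(rd[(cs:ce) - o5] == rf[cs:ce])) {
      hits[[length(hits) + 1]] <- c(o5, o3)
    }
  }
  if (!length(hits)) {
    return(list(match = FALSE, offset_5p = NA_integer_,
                offset_3p = NA_integer_))
  }
  ord <- order(vapply(hits, function(h) abs(h[1]), numeric(1)),
               vapply(hits, function(h) abs(h[2]), numeric(1)))
  h <- hits[[ord[1]]]
  list(match = TRUE, offset_5p = h[1], offset_3p = h[2])
}

# Longest identical run by rle() on the position-wise equality vector.
longest_run_oracle <- function(read, ref) {
  k <- min(nchar(read), nchar(ref))
  if (k == 0) return(0L)
  eq <- strsplit(read, "")[[1]][1:k] == strsplit(ref, "")[[1]][1:k]
  r <- rle(eq)
  runs <- r$lengths[r$values]
  if (length(runs)) max(runs) else 0L
}

# Plain re-statement of the annotation cascade built only on the oracles
# above plus Biostrings for the Smith-Waterman stage.
biostrings_sw <- function(a, b) {
  mat <- matrix(-4, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                          c("A", "C", "G", "T")))
  diag(mat) <- 5
  as.integer(Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "local",
    substitutionMatrix = mat, gapOpening = 12, gapExtension = 4,
    scoreOnly = TRUE))
}

cascade_oracle <- function(read, reference) {
  reference <- reference[order(reference$id), ]
  t1 <- lapply(reference$sequence, tier1_oracle, read = read)
  hit <- which(vapply(t1, `[[`, logical(1), "match"))
  if (length(hit)) {
    sums <- vapply(t1[hit], function(h) abs(h$offset_5p) + abs(h$offset_3p),
                   numeric(1))
    i <- hit[order(sums)[1]]
    return(list(tier = "miRNA_tier1", matched_id = reference$id[i]))
  }
  cand <- which(substr(reference$sequence, 1, 10) == substr(read, 1, 10))
  if (!length(cand)) return(list(tier = "unannotated", matched_id = NA))
  runs <- vapply(reference$sequence[cand], longest_run_oracle,
                 integer(1), read = read)
  if (max(runs) >= 16) {
    i <- cand[order(-runs, cand)[1]]
    return(list(tier = "miRNA_tier2", matched_id = reference$id[i]))
  }
  sws <- vapply(reference$sequence[cand], biostrings_sw, integer(1), a = read)
  i <- cand[order(-sws, cand)[1]]
  tier <- if (max(sws) >= 70) "miRNA_tier3" else "putative_miRNA"
  list(tier = tier, matched_id = reference$id[i])
}

rand_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}
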