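
# All sequence I/O normalizes to the DNA alphabet: sequencing output is DNA,
# so RNA references (U) are mapped to T on load and everything downstream
# works in {A,C,G,T}.

normalize_seq <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}

check_alphabet <- function(x, where) {
  bad <- stringr::str_detect(x, "[^ACGTN]")
  if (any(bad)) {
    abort(sprintf("%s: %d sequence(s) contain characters outside ACGTUN.",
                  where, sum(bad)),
          class = "tidysmallrna_parse_error")
  }
  invisible(x)
}

read_stringset <- function(path, format) {
  tryCatch({
    ss <- Biostrings::readBStringSet(path, format = format,
                                     with.qualities = identical(format,
                                                                "fastq"))
    out <- list(ids = names(ss), seqs = as.character(ss))
    if (identical(format, "fastq")) {
      out$quals <- as.character(S4Vectors::mcols(ss)$qualities)
      if (any(nchar(out$quals) != nchar(out$seqs))) {
        stop("sequence/quality length mismatch")
      }
    }
    out
  },
  error = function(e) {
    abort(sprintf("Malformed %s record in '%s': %s",
                  toupper(format), path, conditionMessage(e)),
          class = "tidysmallrna_parse_error")
  })
}

#' Read a small RNA library from FASTA or FASTQ
#'
#' Each input record becomes one read with `count = 1` (collapse afterwards
#' with [collapse_reads()]). U is converted to T; reads containing N are
#' dropped, and the number dropped is reported and attached as the
#' `n_dropped` attribute. FASTQ per-base qualities (Sanger encoding) are
#' kept in a `quality` column for [quality_filter()].
#'
#' @param path Path to the sequence file.
#' @param tissue Tissue label attached to every read.
#' @param format `"fasta"` or `"fastq"`.
#' @return A tibble with columns `sequence`, `count`, `tissue` and, for
#'   FASTQ, `quality`; input order is preserved.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">r1", "TGAGGUAGUAGGTTGTATAGTT", ">r2", "ACGTACGTACGTACGTAA"), fa)
#' read_smallrna(fa, tissue = "brain")
#' @export
read_smallrna <- function(path, tissue, format = c("fasta", "fastq")) {
  format <- rlang::arg_match(format)
  ss <- read_stringset(path, format)
  seqs <- normalize_seq(ss$seqs)
  check_alphabet(seqs, path)
  keep <- !stringr::str_detect(seqs, "N")
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    inform(sprintf("Dropped %d read(s) containing N from '%s'.",
                   n_dropped, path))
  }
  out <- tibble(sequence = unname(seqs[keep]), count = 1L, tissue = tissue)
  if (identical(format, "fastq")) {
    out$quality <- unname(ss$quals[keep])
  }
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Read a mature miRNA reference set (miRBase-style FASTA)
#'
#' The first whitespace-delimited token of each header is the id
#' (e.g. `dre-miR-1-3p`); the `family` column is the id with its species
#' prefix removed. RNA sequences are converted to DNA (U to T). Duplicate
#' ids are an error; duplicate sequences under different ids are retained.
#'
#' @param path Path to the reference FASTA.
#' @return A tibble with columns `id`, `family`, `sequence`, sorted by `id`.
#' @export
read_mirna_reference <- function(path) {
  ss <- read_stringset(path, "fasta")
  ids <- stringr::str_split_i(ss$ids, "\\s+", 1)
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    abort(sprintf("Duplicate reference id(s) in '%s': %s",
                  path, paste(dup, collapse = ", ")),
          class = "tidysmallrna_format_error")
  }
  seqs <- normalize_seq(ss$seqs)
  check_alphabet(seqs, path)
  len <- nchar(seqs)
  if (length(len) && any(len < 15 | len > 30)) {
    abort(sprintf("Reference '%s': mature sequences must be 15-30 nt.", path),
          class = "tidysmallrna_format_error")
  }
  tibble(id = ids,
         family = stringr::str_remove(ids, "^[A-Za-z0-9]+-"),
         sequence = unname(seqs)) |>
    arrange(.data$id)
}

#' Read a repeat-element reference FASTA
#'
#' @param path Path to the repeat FASTA.
#' @return A tibble with columns `id`, `sequence`.
#' @export
read_repeat_fasta <- function(path) {
  ss <- read_stringset(path, "fasta")
  seqs <- normalize_seq(ss$seqs)
  check_alphabet(seqs, path)
  tibble(id = stringr::str_split_i(ss$ids, "\\s+", 1),
         sequence = unname(seqs))
}

#' Read a tissue manifest
#'
#' Two-column tab-separated file mapping each sample file to its tissue
#' label, with header `sample_path<TAB>tissue`.
#'
#' @param path Path to the manifest TSV.
#' @return A tibble with columns `sample_path`, `tissue`.
#' @export
read_tissue_manifest <- function(path) {
  m <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  if (!all(c("sample_path", "tissue") %in% names(m))) {
    abort("Manifest must have columns 'sample_path' and 'tissue'.",
          class = "tidysmallrna_format_error")
  }
  m[, c("sample_path", "tissue")]
}

#' Write / read a result table (TSV)
#'
#' Tab-separated with a header row and stable column order; round-trips
#' through [read_result_table()]. Cells containing a tab are rejected
#' rather than quoted.
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `write_result_table()` returns `x` invisibly;
#'   `read_result_table()` returns a tibble.
#' @export
write_result_table <- function(x, path) {
  chr <- vapply(x, is.character, logical(1))
  if (any(vapply(x[chr], function(col) any(grepl("\t", col, fixed = TRUE)),
                 logical(1)))) {
    abort("Cells containing a tab character cannot be written to TSV.",
          class = "tidysmallrna_format_error")
  }
  readr::write_tsv(x, path)
  invisible(x)
}

#' @rdname write_result_table
#' @export
read_result_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Write sequences as FASTA or FASTQ
#'
#' Minimal deterministic writers used by the simulator (byte-identical
#' output for identical input).
#'
#' @param ids Record identifiers.
#' @param sequences Character vector of sequences.
#' @param path Output path.
#' @param qualities Quality strings (FASTQ only), same length as `sequences`.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(ids, sequences, path) {
  stopifnot(length(ids) == length(sequences))
  writeLines(paste0(">", ids, "\n", sequences), path, sep = "\n")
  invisible(path)
}

#' @rdname write_fasta
#' @export
write_fastq <- function(ids, sequences, qualities, path) {
  stopifnot(length(ids) == length(sequences),
            length(qualities) == length(sequences))
  writeLines(paste0("@", ids, "\n", sequences, "\n+\n", qualities),
             path, sep = "\n")
  invisible(path)
}
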