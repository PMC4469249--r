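
stage_try <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("Pipeline stage '%s' failed: %s", stage,
                  conditionMessage(e)),
          class = "tidysmallrna_stage_error", parent = e)
  })
}

#' Run the full small RNA analysis pipeline
#'
#' Stages, in order: quality filter and 3' adapter trimming per sample,
#' read collapsing, tiered miRNA annotation of the 18-25-nt population,
#' RPM expression and size/category profiling, isomiR grouping and
#' seed-shift detection, ratio-based differential expression for every
#' tissue pair, and 1-35-nt composition with putative-piRNA flagging.
#' A stage log records read counts entering and leaving every stage
#' (input = kept + dropped throughout). If `out_dir` is given every result
#' table is written as TSV as soon as it exists, so a failing stage
#' retains the partial outputs.
#'
#' @param manifest A tibble (`sample_path`, `tissue`) or the path of a
#'   manifest TSV; one sample file per tissue.
#' @param reference A reference tibble from [read_mirna_reference()] or
#'   the path of a miRBase-style FASTA.
#' @param repeats Optional repeat tibble / FASTA path (NULL: no repeat
#'   classification).
#' @param adapter 3' adapter sequence to trim.
#' @param format Sample file format, `"fastq"` or `"fasta"`.
#' @param params An [alignment_params()] object.
#' @param min_mean_q Quality-filter threshold (mean Phred).
#' @param min_overlap Minimum adapter overlap (nt).
#' @param min_fold,min_rpm,top_n Differential-expression filters, see
#'   [differential_table()].
#' @param min_exact Minimum exact repeat match (nt).
#' @param out_dir Optional output directory for TSVs.
#' @return A list with elements `reads` (trimmed, collapsed, all tissues),
#'   `annotations`, `expression`, `putative_expression`,
#'   `size_distribution`, `category_proportions`, `isomir`, `seed_shifts`,
#'   `differential`, `composition`, `log`.
#' @export
run_pipeline <- function(manifest, reference, repeats = NULL,
                         adapter = DEFAULT_ADAPTER,
                         format = c("fastq", "fasta"),
                         params = alignment_params(),
                         min_mean_q = 20, min_overlap = 4L,
                         min_fold = 1.5, min_rpm = 1000, top_n = 5L,
                         min_exact = 20L, out_dir = NULL) {
  format <- rlang::arg_match(format)
  if (is.character(manifest)) manifest <- read_tissue_manifest(manifest)
  missing_files <- manifest$sample_path[!file.exists(manifest$sample_path)]
  if (length(missing_files)) {
    abort(sprintf("Sample file(s) not found: %s",
                  paste(missing_files, collapse = ", ")),
          class = "tidysmallrna_config_error")
  }
  if (is.character(reference)) {
    if (!file.exists(reference)) {
      abort(sprintf("Reference FASTA not found: %s", reference),
            class = "tidysmallrna_config_error")
    }
    reference <- read_mirna_reference(reference)
  }
  if (is.character(repeats)) repeats <- read_repeat_fasta(repeats)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  }
  emit <- function(x, name) {
    if (!is.null(out_dir)) {
      write_result_table(as_tibble(x), file.path(out_dir,
                                                 paste0(name, ".tsv")))
    }
    x
  }

  log <- tibble(stage = character(), tissue = character(),
                reads_in = integer(), reads_kept = integer(),
                reads_dropped = integer())
  note <- function(stage, tissue, n_in, n_kept) {
    log <<- bind_rows(log, tibble(
      stage = stage, tissue = tissue, reads_in = as.integer(n_in),
      reads_kept = as.integer(n_kept),
      reads_dropped = as.integer(n_in - n_kept)))
  }

  collapsed <- stage_try("trim", {
    purrr::pmap(manifest, function(sample_path, tissue) {
      reads <- read_smallrna(sample_path, tissue = tissue, format = format)
      note("load", tissue, nrow(reads) + attr(reads, "n_dropped"),
           nrow(reads))
      filtered <- if (identical(format, "fastq")) {
        quality_filter(reads, min_mean_q)
      } else reads
      note("quality_filter", tissue, nrow(reads), nrow(filtered))
      trimmed <- trim_reads(filtered, adapter, min_overlap)
      note("trim", tissue, nrow(filtered), nrow(trimmed))
      collapse_reads(trimmed[, c("sequence", "count", "tissue")])
    }) |> bind_rows()
  })

  annotations <- stage_try("annotate", {
    emit(annotate_reads(select_length(collapsed, 18L, 25L),
                        reference, params),
         "annotations")
  })
  n1825 <- sum(select_length(collapsed, 18L, 25L)$count)
  note("annotate", "(all)", n1825, sum(annotations$count))

  expression <- stage_try("profile",
                          emit(expression_matrix(annotations),
                               "expression_rpm"))
  putative <- stage_try("profile",
                        emit(putative_expression(annotations),
                             "putative_expression"))
  sizes <- stage_try("profile",
                     emit(size_distribution(collapsed),
                          "size_distribution"))
  categories <- stage_try("profile",
                          emit(category_proportions(annotations),
                               "category_proportions"))

  isomir <- stage_try("isomir", emit(isomir_groups(annotations),
                                     "isomir_classes"))
  majors <- isomir |>
    as_tibble() |>
    filter(.data$is_major) |>
    select("family", "tissue", major_sequence = "sequence", "count")
  emit(majors, "major_isomirs")
  shifts <- stage_try("isomir", emit(seed_shift_report(isomir),
                                     "seed_shifts"))

  tissues <- unique(manifest$tissue)
  differential <- stage_try("diffexpr", {
    pairs <- if (length(tissues) >= 2L) {
      utils::combn(tissues, 2L, simplify = FALSE)
    } else list()
    purrr::map(pairs, function(p) {
      differential_table(expression, p[1], p[2], min_fold = min_fold,
                         min_rpm = min_rpm, top_n = top_n)
    }) |>
      bind_rows() |>
      emit("differential")
  })

  composition <- stage_try("classify-other", {
    emit(composition_summary(collapsed, annotations, repeats, min_exact),
         "composition")
  })

  emit(log, "run_log")
  list(reads = collapsed, annotations = annotations,
       expression = expression, putative_expression = putative,
       size_distribution = sizes, category_proportions = categories,
       isomir = isomir, seed_shifts = shifts, differential = differential,
       composition = composition, log = log)
}
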