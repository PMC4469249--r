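# Small simulated experiments shared across test files (built once).

small_config <- function(seed = 11L, lib = 4000L) {
  simulation_config(
    n_mirnas = 20L,
    tissues = list(
      fast_muscle = tissue_profile("somatic", library_size = lib),
      heart = tissue_profile("somatic", library_size = lib),
      ovary = tissue_profile("gonadal", library_size = lib)
    ),
    rng_seed = seed
  )
}

# Simulate -> quality filter -> trim -> collapse for one tissue.
process_tissue <- function(config, tissue, reference) {
  lib <- simulate_library(config, tissue, reference)
  reads <- tibble::tibble(sequence = lib$reads$sequence, count = 1L,
                          tissue = lib$reads$tissue,
                          quality = lib$reads$quality)
  filtered <- suppressMessages(quality_filter(reads))
  trimmed <- trim_reads(filtered, config$adapter)
  list(collapsed = collapse_reads(trimmed[, c("sequence", "count", "tissue")]),
       truth = lib$truth)
}

write_tmp_fasta <- function(lines) {
  path <- withr::local_tempfile(fileext = ".fa",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
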