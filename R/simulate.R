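
# Seeded generator for miRBase-style references, repeat elements, and raw
# 35-nt read libraries with per-read ground truth. The emulated structure:
# somatic libraries peak at 22 nt and are miRNA-dominated; gonadal
# libraries are dominated by 26-31-nt repeat-derived reads (mode 27 nt);
# isomiR variation is overwhelmingly 3'-terminal; raw reads are a fixed
# 35 nt (insert + 3' adapter + random fill), which reproduces the
# trimming artifact that no 32-34-nt product can exist.

DEFAULT_ADAPTER <- "TGGAATTCTCGGGTGCCAAGG"

PLANTED_REFERENCES <- tibble::tibble(
  id = c("fru-miR-462-5p", "fru-miR-101b-3p", "fru-miR-133-3p"),
  sequence = c("GTAACGGAACCCATAATGCAGCT",
               "GTACAGTACTATGATAACTGA",
               "TTGGTCCCCTTCAACCAGCC")
)

#' Default isomiR end-offset distribution
#'
#' Probability table over (5' offset, 3' offset) pairs: half the reads are
#' the canonical form, ~49% carry 3'-only variation (mostly +/-1-2 nt),
#' and any 5' involvement is rare (~1%, split between 5'-only and both
#' ends) -- the terminal-variation structure typical of vertebrate
#' small RNA libraries.
#'
#' @return A tibble `offset_5p`, `offset_3p`, `prob` (probabilities sum
#'   to 1).
#' @export
default_isomir_offsets <- function() {
  tibble(
    offset_5p = c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L,
                  1L, -1L, 1L, -1L, 1L, -1L),
    offset_3p = c(0L, 1L, -1L, 2L, -2L, 3L, -3L, 4L, -4L,
                  0L, 0L, 1L, -1L, -1L, 1L),
    prob = c(0.50, 0.15, 0.15, 0.075, 0.075, 0.015, 0.015, 0.005, 0.005,
             0.0025, 0.0025, 0.00125, 0.00125, 0.00125, 0.00125)
  )
}

#' Tissue profile for the simulator
#'
#' @param type `"somatic"` (22-nt-mode, miRNA-dominated) or `"gonadal"`
#'   (26-28-nt-mode, repeat-dominated).
#' @param library_size Number of raw reads to simulate.
#' @param mirna_fraction Fraction of reads of miRNA origin.
#' @param repeat_fraction Fraction of reads drawn as 26-31-nt repeat
#'   windows.
#' @return A named list.
#' @export
tissue_profile <- function(type = c("somatic", "gonadal"),
                           library_size = 1e5,
                           mirna_fraction = if (type == "somatic") 0.70 else 0.08,
                           repeat_fraction = if (type == "somatic") 0.05 else 0.70) {
  type <- rlang::arg_match(type)
  stopifnot(mirna_fraction + repeat_fraction <= 1)
  list(type = type, library_size = as.integer(library_size),
       mirna_fraction = mirna_fraction, repeat_fraction = repeat_fraction)
}

#' Simulation configuration
#'
#' Defines the study conditions the generator emulates. The defaults give
#' two somatic tissues and one gonadal tissue at 1e5 reads each, a
#' miRBase-like mature-length distribution (mode 22 nt over 19-25 nt),
#' the [default_isomir_offsets()] terminal-variation table, a 1% per-nt
#' substitution rate, two planted differentially expressed miRNAs (folds
#' 8 and 4 between the somatic tissues, at expression shares that keep
#' sampling error well below the recovery tolerance), and a planted 5'
#' seed shift: the fru-miR-462-5p major isomiR is the +1 5'-shifted
#' variant in the second tissue.
#'
#' @param n_mirnas Number of random mature references (the three fixed
#'   fugu parents used in worked examples are always added on top).
#' @param n_repeats Number of random repeat elements.
#' @param mature_length_probs Named numeric: P(mature length), names are
#'   lengths in nt.
#' @param tissues Named list of [tissue_profile()]s.
#' @param isomir_offsets Offset probability table
#'   (see [default_isomir_offsets()]).
#' @param substitution_rate Per-nucleotide substitution probability.
#' @param adapter 3' adapter sequence appended to every insert.
#' @param low_quality_fraction Fraction of reads emitted with uniformly
#'   low base quality (removed by [quality_filter()]).
#' @param planted_fold Tibble `id`, `tissue_high`, `tissue_low`, `fold`,
#'   `share_high` of planted between-tissue expression ratios (NULL for
#'   none).
#' @param planted_seed_shift List `id`, `tissue`, or NULL: in that tissue
#'   the named miRNA's offset distribution is re-centred on the +1
#'   5'-shifted variant, so its major isomiR's seed shifts.
#' @param rng_seed Integer seed; every output is a deterministic function
#'   of it.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(
    n_mirnas = 100L,
    n_repeats = 5L,
    mature_length_probs = c(`19` = 0.03, `20` = 0.09, `21` = 0.24,
                            `22` = 0.38, `23` = 0.19, `24` = 0.05,
                            `25` = 0.02),
    tissues = list(fast_muscle = tissue_profile("somatic"),
                   heart = tissue_profile("somatic"),
                   ovary = tissue_profile("gonadal")),
    isomir_offsets = default_isomir_offsets(),
    substitution_rate = 0.01,
    adapter = DEFAULT_ADAPTER,
    low_quality_fraction = 0.005,
    planted_fold = NULL,
    planted_seed_shift = NULL,
    rng_seed = 1L) {
  stopifnot(n_mirnas >= 1L, abs(sum(isomir_offsets$prob) - 1) < 1e-8,
            abs(sum(mature_length_probs) - 1) < 1e-8)
  tissue_names <- names(tissues)
  if (is.null(planted_fold) && n_mirnas >= 2L && length(tissue_names) >= 2L) {
    planted_fold <- tibble(
      id = c("syn-miR-1001-5p", "syn-miR-1002-5p"),
      tissue_high = tissue_names[c(1L, 2L)],
      tissue_low = tissue_names[c(2L, 1L)],
      fold = c(8, 4),
      share_high = c(0.10, 0.08))
  }
  if (is.null(planted_seed_shift) && length(tissue_names) >= 2L) {
    planted_seed_shift <- list(id = "fru-miR-462-5p",
                               tissue = tissue_names[2L])
  }
  structure(list(
    n_mirnas = as.integer(n_mirnas), n_repeats = as.integer(n_repeats),
    mature_length_probs = mature_length_probs, tissues = tissues,
    isomir_offsets = isomir_offsets, substitution_rate = substitution_rate,
    adapter = normalize_seq(adapter),
    low_quality_fraction = low_quality_fraction,
    planted_fold = planted_fold, planted_seed_shift = planted_seed_shift,
    rng_seed = as.integer(rng_seed)
  ), class = "simulation_config")
}

sim_seed <- function(config, offset) {
  as.integer((as.double(config$rng_seed) * 1000003 + offset) %% 2147483647)
}

rand_dna <- function(n_total) {
  paste(sample(c("A", "C", "G", "T"), n_total, replace = TRUE),
        collapse = "")
}

rand_dna_vec <- function(lens) {
  out <- character(length(lens))
  pos <- lens > 0
  if (any(pos)) {
    letters4 <- sample(c("A", "C", "G", "T"), sum(lens[pos]), replace = TRUE)
    grp <- rep(seq_len(sum(pos)), lens[pos])
    out[pos] <- vapply(split(letters4, grp), paste, character(1),
                       collapse = "")
  }
  out
}

#' Generate the reference sets
#'
#' Random mature miRNAs (lengths from the configured distribution,
#' pairwise-distinct 10-nt prefixes so prefix candidacy is unambiguous)
#' plus the three fixed fugu parents used in worked examples, and random
#' repeat elements. Byte-deterministic given the config seed.
#'
#' @param config A [simulation_config()].
#' @return A list: `mature` (tibble `id`, `family`, `sequence`) and
#'   `repeats` (tibble `id`, `sequence`).
#' @export
make_reference <- function(config) {
  withr::with_seed(sim_seed(config, 1L), {
    lens <- as.integer(names(config$mature_length_probs))
    n <- config$n_mirnas
    seqs <- character(0)
    prefixes <- substr(PLANTED_REFERENCES$sequence, 1, 10)
    while (length(seqs) < n) {
      len <- sample(lens, 1L, prob = config$mature_length_probs)
      s <- rand_dna(len)
      p <- substr(s, 1, 10)
      if (!p %in% prefixes) {
        seqs <- c(seqs, s)
        prefixes <- c(prefixes, p)
      }
    }
    mature <- bind_rows(
      PLANTED_REFERENCES,
      tibble(id = sprintf("syn-miR-%d-5p", 1000L + seq_len(n)),
             sequence = seqs)
    ) |>
      mutate(family = stringr::str_remove(.data$id, "^[A-Za-z0-9]+-")) |>
      select("id", "family", "sequence") |>
      arrange(.data$id)
    rep_lens <- sample(300:800, config$n_repeats, replace = TRUE)
    repeats <- tibble(
      id = sprintf("synrep-%02d", seq_len(config$n_repeats)),
      sequence = vapply(rep_lens, rand_dna, character(1)))
    list(mature = mature, repeats = repeats)
  })
}

# Per-tissue expression weights over the mature reference, with planted
# fixed shares (differential pairs + the three worked-example parents).
tissue_weights <- function(config, mature, tissue) {
  tissue_i <- match(tissue, names(config$tissues))
  n <- nrow(mature)
  w <- withr::with_seed(sim_seed(config, 2L), rlnorm(n, 0, 1)) *
    withr::with_seed(sim_seed(config, 100L + tissue_i), rlnorm(n, 0, 0.25))
  shares <- c(`fru-miR-462-5p` = 0.02, `fru-miR-101b-3p` = 0.01,
              `fru-miR-133-3p` = 0.01)
  pf <- config$planted_fold
  if (!is.null(pf)) {
    hi <- pf[pf$tissue_high == tissue & pf$id %in% mature$id, ]
    lo <- pf[pf$tissue_low == tissue & pf$id %in% mature$id, ]
    shares <- c(shares,
                setNames(hi$share_high, hi$id),
                setNames(lo$share_high / lo$fold, lo$id))
  }
  shares <- shares[names(shares) %in% mature$id]
  idx <- match(names(shares), mature$id)
  w[idx] <- 0
  w[idx] <- shares / (1 - sum(shares)) * sum(w)
  w / sum(w)
}

# Offset table for one parent in one tissue (seed-shift override).
offset_table_for <- function(config, id, tissue) {
  ps <- config$planted_seed_shift
  if (!is.null(ps) && identical(ps$id, id) && identical(ps$tissue, tissue)) {
    return(tibble(offset_5p = c(1L, 0L, 0L, 0L),
                  offset_3p = c(0L, 0L, 1L, -1L),
                  prob = c(0.60, 0.30, 0.05, 0.05)))
  }
  config$isomir_offsets
}

# Best ungapped local score by max-subarray (Kadane) over the +5/-4
# position values implied by the known mismatch set -- the generator-side
# truth path, independent of the classifier's alignment code.
kadane_score <- function(n_pos, mismatch_at, match = 5, mismatch = -4) {
  v <- rep(match, n_pos)
  v[mismatch_at] <- mismatch
  best <- 0; cur <- 0
  for (x in v) {
    cur <- max(0, cur + x)
    best <- max(best, cur)
  }
  best
}

# Truth tier from generative knowledge: overlap mismatch positions M
# (insert coordinates), offsets, insert/reference lengths.
truth_tier_one <- function(M, o5, o3, L, R) {
  if (length(M) == 0L) return("miRNA_tier1")
  if (o5 != 0L || min(M) <= 10L) return("unannotated")
  V <- min(L, R)
  M <- M[M <= V]
  if (length(M) == 0L) return("miRNA_tier1") # subs only in 3' overhang
  gaps <- diff(c(0L, sort(M), V + 1L)) - 1L
  if (max(gaps) >= 16L) return("miRNA_tier2")
  if (kadane_score(V, M) >= 70) return("miRNA_tier3")
  "putative_miRNA"
}

#' Simulate one tissue's raw read library
#'
#' Draws miRNA-derived inserts (parents by expression weight, terminal
#' offsets from the isomiR table, per-nt substitutions), 26-31-nt repeat
#' windows (either strand), and random background inserts; concatenates
#' each insert with the 3' adapter, fills with random sequence and
#' truncates to a fixed 35 nt; and writes a per-read truth record.
#' Byte-deterministic given the config seed and tissue.
#'
#' @param config A [simulation_config()].
#' @param tissue A tissue name present in `config$tissues`.
#' @param reference Optional pre-built [make_reference()] result (rebuilt
#'   from the config if omitted).
#' @return A list: `reads` (tibble `read_id`, `sequence` (35 nt),
#'   `quality`, `tissue`) and `truth` (tibble `read_id`, `origin`,
#'   `parent_id`, `offset_5p`, `offset_3p`, `insert_length`, `truth_tier`,
#'   `low_quality`).
#' @export
simulate_library <- function(config, tissue, reference = NULL) {
  if (!tissue %in% names(config$tissues)) {
    abort(sprintf("Unknown tissue '%s'.", tissue),
          class = "tidysmallrna_contract_error")
  }
  if (is.null(reference)) reference <- make_reference(config)
  mature <- reference$mature
  repeats <- reference$repeats
  prof <- config$tissues[[tissue]]
  tissue_i <- match(tissue, names(config$tissues))

  withr::with_seed(sim_seed(config, 1000L + tissue_i), {
    n <- prof$library_size
    n_mi <- round(n * prof$mirna_fraction)
    n_rep <- round(n * prof$repeat_fraction)
    n_bg <- n - n_mi - n_rep

    ## --- miRNA-derived inserts ------------------------------------------
    w <- tissue_weights(config, mature, tissue)
    parent <- sample.int(nrow(mature), n_mi, replace = TRUE, prob = w)
    off <- matrix(0L, n_mi, 2L)
    base_tab <- config$isomir_offsets
    ri <- sample.int(nrow(base_tab), n_mi, replace = TRUE,
                     prob = base_tab$prob)
    off[, 1] <- base_tab$offset_5p[ri]
    off[, 2] <- base_tab$offset_3p[ri]
    ps <- config$planted_seed_shift
    if (!is.null(ps) && identical(ps$tissue, tissue) &&
        ps$id %in% mature$id) {
      shift_idx <- which(parent == match(ps$id, mature$id))
      if (length(shift_idx)) {
        st <- offset_table_for(config, ps$id, tissue)
        si <- sample.int(nrow(st), length(shift_idx), replace = TRUE,
                         prob = st$prob)
        off[shift_idx, 1] <- st$offset_5p[si]
        off[shift_idx, 2] <- st$offset_3p[si]
      }
    }
    refseq <- mature$sequence[parent]
    R <- nchar(refseq)
    o5 <- off[, 1]; o3 <- off[, 2]
    a <- pmax(1L, 1L + o5)
    b <- pmin(R, R + o3)
    core <- substr(refseq, a, b)
    ext5 <- rand_dna_vec(pmax(0L, -o5))
    ext3 <- rand_dna_vec(pmax(0L, o3))
    insert <- paste0(ext5, core, ext3)
    L <- nchar(insert)

    ## substitutions + generative truth tier
    n_subs <- stats::rbinom(n_mi, L, config$substitution_rate)
    truth_tier <- rep("miRNA_tier1", n_mi)
    ov_start <- 1L + pmax(0L, -o5)
    ov_end <- L - pmax(0L, o3)
    for (i in which(n_subs > 0L)) {
      pos <- sample.int(L[i], n_subs[i])
      s <- strsplit(insert[i], "")[[1]]
      for (p in pos) {
        s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1L)
      }
      insert[i] <- paste(s, collapse = "")
      M <- pos[pos >= ov_start[i] & pos <= ov_end[i]]
      truth_tier[i] <- truth_tier_one(M, o5[i], o3[i], L[i], R[i])
    }

    mi <- tibble(origin = "mirna", parent_id = mature$id[parent],
                 offset_5p = o5, offset_3p = o3, insert = insert,
                 truth_tier = truth_tier)

    ## --- repeat-derived 26-31-nt windows --------------------------------
    rp <- NULL
    if (n_rep > 0L) {
      el <- sample.int(nrow(repeats), n_rep, replace = TRUE)
      wlen <- sample(26:31, n_rep, replace = TRUE,
                     prob = c(0.20, 0.30, 0.25, 0.12, 0.08, 0.05))
      elseq <- repeats$sequence[el]
      start <- floor(runif(n_rep) * (nchar(elseq) - wlen + 1L)) + 1L
      win <- substr(elseq, start, start + wlen - 1L)
      rc <- runif(n_rep) < 0.5
      win[rc] <- revcomp(win[rc])
      rp <- tibble(origin = "repeat", parent_id = repeats$id[el],
                   offset_5p = NA_integer_, offset_3p = NA_integer_,
                   insert = win, truth_tier = NA_character_)
    }

    ## --- random background ----------------------------------------------
    bg <- NULL
    if (n_bg > 0L) {
      bg_len <- sample(18:35, n_bg, replace = TRUE)
      bg <- tibble(origin = "random", parent_id = NA_character_,
                   offset_5p = NA_integer_, offset_3p = NA_integer_,
                   insert = rand_dna_vec(bg_len),
                   truth_tier = NA_character_)
    }

    all <- bind_rows(mi, rp, bg)
    all <- all[sample.int(nrow(all)), , drop = FALSE]

    ## --- raw 35-nt reads: insert + adapter + random fill ----------------
    ilen <- nchar(all$insert)
    fill <- rand_dna_vec(pmax(0L, 35L - ilen - nchar(config$adapter)))
    raw <- substr(paste0(all$insert, config$adapter, fill), 1L, 35L)
    lowq <- runif(nrow(all)) < config$low_quality_fraction
    qual <- ifelse(lowq, strrep("#", 35L), strrep("I", 35L))
    read_id <- sprintf("%s_read%07d", tissue, seq_len(nrow(all)))

    list(
      reads = tibble(read_id = read_id, sequence = raw, quality = qual,
                     tissue = tissue),
      truth = tibble(read_id = read_id, origin = all$origin,
                     parent_id = all$parent_id,
                     offset_5p = all$offset_5p, offset_3p = all$offset_3p,
                     insert_length = ilen, truth_tier = all$truth_tier,
                     low_quality = lowq)
    )
  })
}

#' Simulate a full multi-tissue experiment to disk
#'
#' Writes `reference.fa`, `repeats.fa`, one FASTQ and one truth TSV per
#' tissue, and a `manifest.tsv` usable with [run_pipeline()]. All files
#' are byte-deterministic given the config seed.
#'
#' @param config A [simulation_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list of the written paths plus the in-memory
#'   reference.
#' @export
simulate_experiment <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  reference <- make_reference(config)
  write_fasta(reference$mature$id, reference$mature$sequence,
              file.path(dir, "reference.fa"))
  write_fasta(reference$repeats$id, reference$repeats$sequence,
              file.path(dir, "repeats.fa"))
  manifest <- tibble(sample_path = character(), tissue = character())
  truth_paths <- character()
  for (tissue in names(config$tissues)) {
    lib <- simulate_library(config, tissue, reference)
    fq <- file.path(dir, paste0(tissue, ".fastq"))
    write_fastq(lib$reads$read_id, lib$reads$sequence, lib$reads$quality, fq)
    tp <- file.path(dir, paste0(tissue, "_truth.tsv"))
    write_result_table(lib$truth, tp)
    manifest <- bind_rows(manifest,
                          tibble(sample_path = fq, tissue = tissue))
    truth_paths <- c(truth_paths, tp)
  }
  write_result_table(manifest, file.path(dir, "manifest.tsv"))
  invisible(list(reference_fasta = file.path(dir, "reference.fa"),
                 repeats_fasta = file.path(dir, "repeats.fa"),
                 manifest = file.path(dir, "manifest.tsv"),
                 truth = truth_paths, reference = reference))
}
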