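ref22 <- "TGAGGTAGTAGGTTGTATAGTT" # non-periodic 22-mer

test_that("offset-tolerant exact matching honours the 5'/3' tolerances", {
  expect_equal(tier1_match(ref22, ref22),
               tibble::tibble(match = TRUE, offset_5p = 0L, offset_3p = 0L))
  minus3p <- substr(ref22, 1, nchar(ref22) - 4) # 3' shortened by 4
  expect_equal(tier1_match(minus3p, ref22)$offset_3p, -4L)
  minus5p <- substr(ref22, 4, nchar(ref22)) # 5' shortened by 3: beyond tolerance
  expect_false(tier1_match(minus5p, ref22)$match)
  sub <- ref22
  substr(sub, 11, 11) <- "C" # internal substitution
  expect_false(tier1_match(sub, ref22)$match)
  expect_equal(tier1_oracle(sub, ref22)$match, FALSE)
})

test_that("tier1_match equals exhaustive placement enumeration", {
  set.seed(402)
  for (i in 1:400) {
    ref <- rand_seq(sample(18:25, 1))
    read <- if (runif(1) < 0.5) {
      # perturbed copy: random end offsets, occasional substitution
      o5 <- sample(-3:3, 1); o3 <- sample(-5:5, 1)
      core <- substr(ref, max(1, 1 + o5), min(nchar(ref), nchar(ref) + o3))
      r <- paste0(rand_seq(max(0, -o5)), core, rand_seq(max(0, o3)))
      if (runif(1) < 0.3 && nchar(r) > 0) {
        p <- sample(nchar(r), 1)
        substr(r, p, p) <- sample(c("A", "C", "G", "T"), 1)
      }
      r
    } else rand_seq(sample(18:25, 1))
    got <- tier1_match(read, ref)
    want <- tier1_oracle(read, ref)
    expect_equal(got$match, want$match)
    if (want$match) {
      expect_equal(got$offset_5p, want$offset_5p)
      expect_equal(got$offset_3p, want$offset_3p)
    }
  }
})

test_that("prefix candidates require identity of the first 10 nt exactly", {
  reference <- tibble::tibble(
    id = c("a-miR-1", "b-miR-2", "c-miR-3"),
    family = c("miR-1", "miR-2", "miR-3"),
    sequence = c(ref22,
                 paste0(substr(ref22, 1, 9), "C", substr(ref22, 11, 22)),
                 paste0(substr(ref22, 1, 10), "CCCCCCCCCCCC")))
  cand <- prefix10_candidates(ref22, reference)
  expect_setequal(cand$id, c("a-miR-1", "c-miR-3")) # pos-11 difference kept
  expect_false("b-miR-2" %in% cand$id)              # pos-10 difference out
  expect_equal(nrow(prefix10_candidates("ACGTACG", reference)), 0L)
})

test_that("longest run matches a position-wise scan", {
  expect_equal(longest_run(ref22, ref22), 22L)
  d17 <- ref22; substr(d17, 17, 17) <- setdiff(c("A", "C", "G", "T"),
                                               substr(ref22, 17, 17))[1]
  expect_equal(longest_run(d17, ref22), 16L)
  d1112 <- ref22
  substr(d1112, 11, 11) <- setdiff(c("A", "C", "G", "T"),
                                   substr(ref22, 11, 11))[1]
  substr(d1112, 12, 12) <- setdiff(c("A", "C", "G", "T"),
                                   substr(ref22, 12, 12))[1]
  expect_equal(longest_run(d1112, ref22), 10L)
  set.seed(403)
  for (i in 1:100) {
    a <- rand_seq(sample(8:25, 1)); b <- rand_seq(sample(8:25, 1))
    expect_equal(longest_run(a, b), longest_run_oracle(a, b))
  }
})

test_that("Smith-Waterman score hits its defining values", {
  expect_equal(sw_score(strrep("ACGT", 4), strrep("ACGT", 4)), 80L)
  expect_equal(sw_score("AAAA", "CCCC"), 0L)
  block <- strrep("AT", 7) # 14 nt
  s1 <- paste0("CCCCC", block, "CCCCC")
  s2 <- paste0("GGGGG", block, "GGGGG")
  expect_equal(sw_score(s1, s2), 70L) # 14 x 5, exactly at threshold
})

test_that("Smith-Waterman equals the recursive oracle and Biostrings", {
  set.seed(404)
  for (i in 1:250) {
    a <- rand_seq(sample(1:12, 1)); b <- rand_seq(sample(1:12, 1))
    s <- sw_score(a, b)
    expect_equal(s, local_align_oracle(a, b))
    expect_equal(s, biostrings_sw(a, b))
    expect_equal(s, sw_score(b, a)) # symmetry
  }
})

test_that("appending a matching nucleotide never decreases score or run", {
  set.seed(405)
  for (i in 1:100) {
    a <- rand_seq(sample(5:20, 1)); b <- rand_seq(sample(5:20, 1))
    nt <- sample(c("A", "C", "G", "T"), 1)
    expect_gte(sw_score(paste0(a, nt), paste0(b, nt)), sw_score(a, b))
    expect_gte(longest_run(paste0(a, nt), paste0(b, nt)), longest_run(a, b))
  }
})

test_that("gap-free scoring rarely changes the tier-3 threshold decision", {
  set.seed(406)
  agree <- 0L; n <- 300L
  for (i in 1:n) {
    ref <- rand_seq(22)
    read <- ref
    for (p in sample(11:22, sample(2:5, 1))) {
      substr(read, p, p) <- sample(c("A", "C", "G", "T"), 1)
    }
    gapped <- sw_score(read, ref) >= 70
    ungapped <- sw_score(read, ref, use_gaps = FALSE) >= 70
    agree <- agree + (gapped == ungapped)
  }
  expect_gte(agree / n, 0.99)
})

test_that("a >= 16-nt run guarantees a tier-3-passing score", {
  set.seed(407)
  for (i in 1:200) {
    ref <- rand_seq(22)
    read <- ref
    p <- sample(17:22, 1) # keep a 16-nt 5' block intact
    substr(read, p, p) <- sample(c("A", "C", "G", "T"), 1)
    if (longest_run(read, ref) >= 16) {
      expect_gte(sw_score(read, ref), 80L)
    }
  }
})

test_that("the cascade classifies the worked single-read examples", {
  reference <- tibble::tibble(id = "fru-miR-9-5p", family = "miR-9-5p",
                              sequence = ref22)
  expect_equal(as.character(classify_read(ref22, reference)$tier),
               "miRNA_tier1")
  # 10-nt prefix + a 16-nt run from position 1, then divergence -> tier 2
  t2 <- paste0(substr(ref22, 1, 16), "GGGGGG")
  expect_equal(as.character(classify_read(t2, reference)$tier),
               "miRNA_tier2")
  # prefix holds, best run 12, Smith-Waterman below threshold -> putative
  t4 <- paste0(substr(ref22, 1, 12), "GCCGGCCGGC")
  expect_equal(longest_run(t4, ref22), 12L)
  expect_lt(sw_score(t4, ref22), 70L)
  expect_equal(as.character(classify_read(t4, reference)$tier),
               "putative_miRNA")
  expect_error(classify_read("ACGT", reference),
               class = "tidysmallrna_contract_error")
})

test_that("library annotation equals the brute-force cascade oracle", {
  cfg <- small_config(seed = 21L, lib = 1200L)
  ref <- make_reference(cfg)
  pt <- process_tissue(cfg, "fast_muscle", ref)
  reads <- select_length(pt$collapsed, 18, 25)
  ann <- annotate_reads(reads, ref$mature)
  expect_equal(sum(ann$count), sum(reads$count)) # cascade is exhaustive
  set.seed(408)
  idx <- sample(nrow(ann), 120)
  for (i in idx) {
    want <- cascade_oracle(ann$sequence[i], ref$mature)
    expect_equal(as.character(ann$tier[i]), want$tier)
    if (want$tier != "unannotated") {
      expect_equal(ann$matched_id[i], want$matched_id)
    }
  }
})

test_that("annotation is deterministic and names families with fru-", {
  reference <- tibble::tibble(id = c("dre-miR-1-3p"), family = "miR-1-3p",
                              sequence = ref22)
  reads <- tibble::tibble(sequence = ref22, count = 7L, tissue = "heart")
  a1 <- annotate_reads(reads, reference)
  a2 <- annotate_reads(reads, reference)
  expect_identical(as.data.frame(a1), as.data.frame(a2))
  expect_equal(a1$matched_family, "fru-miR-1-3p")
})

test_that("an all-reference-copy library is 100% tier 1; empty cases", {
  set.seed(615)
  reference <- tibble::tibble(id = c("x-miR-1", "x-miR-2"),
                              family = c("miR-1", "miR-2"),
                              sequence = c(ref22, rand_seq(20)))
  reads <- tibble::tibble(sequence = rep(reference$sequence, c(3, 2)),
                          count = 1L, tissue = "t") |> collapse_reads()
  ann <- annotate_reads(reads, reference)
  expect_true(all(ann$tier == "miRNA_tier1"))
  empty <- annotate_reads(reads[0, ], reference)
  expect_equal(nrow(empty), 0L)
  expect_warning(none <- annotate_reads(reads, reference[0, ]),
                 "Empty reference")
  expect_true(all(none$tier == "unannotated"))
})

test_that("tidy() and glance() summarise an annotation", {
  set.seed(616)
  reference <- tibble::tibble(id = "x-miR-1", family = "miR-1",
                              sequence = ref22)
  reads <- tibble::tibble(sequence = c(ref22, rand_seq(20)),
                          count = c(9L, 1L), tissue = "t")
  ann <- annotate_reads(reads, reference)
  td <- tidy(ann)
  expect_equal(sum(td$fraction), 1)
  expect_equal(glance(ann)$pct_mirna, 90)
})
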