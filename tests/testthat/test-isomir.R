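test_that("seed extraction returns positions 2-8 and demands 8 nt", {
  expect_equal(seed_of("GTAACGGAACCCATAATGCAGCT"), "TAACGGA")
  expect_equal(seed_of("TAACGGAACCCATAATGCAGCT"), "AACGGAA")
  expect_equal(seed_of("TACAGTACTATGATAACTGA"), "ACAGTAC")
  expect_equal(seed_of("TTTGGTCCCCTTCAACCAGCC"), "TTGGTCC")
  expect_error(seed_of("ACGTACG"), class = "tidysmallrna_contract_error")
})

test_that("terminal variant classes come from offsets alone", {
  expect_equal(as.character(classify_variant(0L, 0L, 0L, 0L)), "identical")
  expect_equal(as.character(classify_variant(0L, -2L, 0L, 0L)), "3p_only")
  expect_equal(as.character(classify_variant(-1L, 1L, 0L, 0L)), "both")
  expect_equal(as.character(classify_variant(1L, 0L, 0L, 0L)), "5p_only")
})

test_that("major isomiR election is count-first, deterministic on ties", {
  g <- tibble::tibble(sequence = c("AAAA", "CCCC"), count = c(10L, 3L))
  expect_equal(major_isomir(g), "AAAA")
  expect_equal(major_isomir(g[2, ]), "CCCC")
  tie_len <- tibble::tibble(sequence = c("AAA", "CCCC"), count = c(5L, 5L))
  expect_equal(major_isomir(tie_len), "CCCC") # longer wins
  tie_lex <- tibble::tibble(sequence = c("CCCC", "AAAA"), count = c(5L, 5L))
  expect_equal(major_isomir(tie_lex), "AAAA") # then lexicographic
  expect_error(major_isomir(g[0, ]), class = "tidysmallrna_contract_error")
})

ref23 <- "GTAACGGAACCCATAATGCAGCT"

iso_fixture <- function() {
  reference <- tibble::tibble(id = "fru-miR-462-5p", family = "miR-462-5p",
                              sequence = ref23)
  # tissue a: canonical major + 3' trimmed variant
  # tissue b: 5'-shifted (+1) major + canonical minor
  reads <- tibble::tibble(
    sequence = c(ref23, substr(ref23, 1, 21),
                 substr(ref23, 2, 23), ref23),
    count = c(20L, 8L, 30L, 4L),
    tissue = c("a", "a", "b", "b"))
  suppressMessages(isomir_groups(annotate_reads(reads, reference)))
}

test_that("grouping elects per-tissue majors and classifies variants", {
  iso <- iso_fixture()
  expect_equal(nrow(iso), 4L)
  a <- iso[iso$tissue == "a", ]
  expect_equal(a$major_sequence[1], ref23)
  expect_equal(as.character(a$variant_class[a$sequence == ref23]),
               "identical")
  expect_equal(as.character(a$variant_class[a$count == 8L]), "3p_only")
  b <- iso[iso$tissue == "b", ]
  expect_equal(b$major_sequence[1], substr(ref23, 2, 23))
  expect_equal(as.character(b$variant_class[b$sequence == ref23]),
               "5p_only")
  # per-group class fractions are a partition
  expect_equal(sum(table(a$variant_class)), nrow(a))
})

test_that("every major is classified identical against itself", {
  iso <- iso_fixture()
  expect_true(all(iso$variant_class[iso$is_major] == "identical"))
})

test_that("seed shifts are reported only for families with two seeds", {
  iso <- iso_fixture()
  rep <- seed_shift_report(iso)
  expect_equal(unique(rep$family), "fru-miR-462-5p")
  expect_setequal(rep$seed, c("TAACGGA", "AACGGAA"))
  expect_equal(rep$tissue, sort(rep$tissue))
  # identical majors everywhere -> excluded
  reference <- tibble::tibble(id = "fru-miR-462-5p", family = "miR-462-5p",
                              sequence = ref23)
  same <- tibble::tibble(sequence = ref23, count = 5L,
                         tissue = c("a", "b")) |>
    annotate_reads(reference) |>
    isomir_groups()
  expect_equal(nrow(seed_shift_report(same)), 0L)
  # a single tissue can never show a shift
  one <- tibble::tibble(sequence = ref23, count = 5L, tissue = "a") |>
    annotate_reads(reference) |>
    isomir_groups()
  expect_equal(nrow(seed_shift_report(one)), 0L)
})

test_that("reported RPM uses the per-tissue 18-25-nt denominator", {
  iso <- iso_fixture()
  rep <- seed_shift_report(iso)
  # tissue a: major 20 of 28 reads; tissue b: major 30 of 34 reads
  expect_equal(rep$rpm[rep$tissue == "a"], 20 / 28 * 1e6)
  expect_equal(rep$rpm[rep$tissue == "b"], 30 / 34 * 1e6)
})

test_that("internal variants are flagged but stay terminal-identical", {
  reference <- tibble::tibble(id = "fru-miR-462-5p", family = "miR-462-5p",
                              sequence = ref23)
  internal <- ref23
  substr(internal, 15, 15) <- "G" # same termini, internal substitution
  reads <- tibble::tibble(sequence = c(ref23, internal),
                          count = c(10L, 2L), tissue = "a")
  expect_message(iso <- isomir_groups(annotate_reads(reads, reference)),
                 "internal")
  expect_equal(as.character(iso$variant_class[iso$sequence == internal]),
               "identical")
  expect_true(iso$internal_variant[iso$sequence == internal])
})
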