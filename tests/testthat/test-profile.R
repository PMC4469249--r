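ref22 <- "TGAGGTAGTAGGTTGTATAGTT"

make_ann <- function(reads, reference) {
  annotate_reads(reads, reference)
}

test_that("RPM is the exact formula, linear, and guards its denominator", {
  expect_equal(compute_rpm(50, 1e6), 50)
  expect_equal(compute_rpm(0, 123), 0)
  expect_equal(compute_rpm(777, 777), 1e6)
  expect_equal(compute_rpm(2 * 13, 1e5), 2 * compute_rpm(13, 1e5))
  expect_error(compute_rpm(1, 0), class = "tidysmallrna_contract_error")
})

test_that("expression matrix: counts, zero fill, and separated putative", {
  set.seed(611)
  reference <- tibble::tibble(id = "x-miR-1-5p", family = "miR-1-5p",
                              sequence = ref22)
  # 10 miRNA reads among 100 18-25-nt reads -> 100,000 RPM
  reads <- tibble::tibble(
    sequence = c(ref22, rand_seq(20)), count = c(10L, 90L), tissue = "a")
  expr <- expression_matrix(make_ann(reads, reference))
  expect_equal(expr$rpm, 1e5)
  expect_equal(attr(expr, "denominators")$total_18_25, 100L)
  # second tissue without the miRNA -> explicit zero cell
  reads2 <- dplyr::bind_rows(
    reads, tibble::tibble(sequence = rand_seq(21), count = 50L,
                          tissue = "b"))
  expr2 <- expression_matrix(make_ann(reads2, reference))
  expect_equal(nrow(expr2), 2L)
  expect_equal(expr2$rpm[expr2$tissue == "b"], 0)
  # putative reads are tabulated separately, never in the miRNA matrix
  put_read <- paste0(substr(ref22, 1, 12), "GCCGGCCGGC")
  reads3 <- tibble::tibble(sequence = put_read, count = 5L, tissue = "a")
  ann3 <- make_ann(reads3, reference)
  expect_equal(as.character(ann3$tier), "putative_miRNA")
  expect_equal(nrow(expression_matrix(ann3)), 0L)
  expect_equal(putative_expression(ann3)$raw_count, 5L)
})

test_that("empty annotations give an empty matrix", {
  reference <- tibble::tibble(id = "x-miR-1-5p", family = "miR-1-5p",
                              sequence = ref22)
  ann <- make_ann(tibble::tibble(sequence = character(), count = integer(),
                                 tissue = character()), reference)
  expect_equal(nrow(expression_matrix(ann)), 0L)
})

test_that("size distribution normalizes to one million 1-35-nt reads", {
  set.seed(612)
  spike <- tibble::tibble(sequence = strrep("A", 22), count = 10L,
                          tissue = "t")
  sd1 <- size_distribution(spike)
  expect_equal(sd1$rpm[sd1$length == 22], 1e6)
  expect_equal(sum(sd1$rpm), 1e6)
  unif <- tibble::tibble(sequence = vapply(18:25, rand_seq, character(1)),
                         count = 3L, tissue = "t")
  sd2 <- size_distribution(unif)
  expect_equal(sd2$rpm[sd2$length %in% 18:25], rep(125000, 8))
  expect_error(size_distribution(spike[0, ]),
               class = "tidysmallrna_contract_error")
})

test_that("category proportions sum to one and average over lengths", {
  set.seed(613)
  reference <- tibble::tibble(id = "x-miR-1-5p", family = "miR-1-5p",
                              sequence = ref22)
  reads <- tibble::tibble(
    sequence = c(ref22, substr(ref22, 1, 21), rand_seq(19), rand_seq(20)),
    count = c(5L, 3L, 2L, 2L), tissue = "t")
  ann <- make_ann(reads, reference)
  cp <- category_proportions(ann)
  expect_equal(sum(cp$fraction), 1)
  expect_equal(nrow(cp), 5L) # all five categories always present
  strat <- category_proportions(ann, stratify_by_length = TRUE)
  # length-weighted average of stratified fractions = unstratified
  back <- strat |>
    dplyr::group_by(tissue, tier) |>
    dplyr::summarise(reads = sum(reads), .groups = "drop_last") |>
    dplyr::mutate(fraction = reads / sum(reads)) |>
    dplyr::ungroup()
  expect_equal(back$fraction[order(back$tier)],
               cp$fraction[order(cp$tier)])
})

test_that("all-tier1 and all-unannotated libraries hit the extremes", {
  set.seed(614)
  reference <- tibble::tibble(id = "x-miR-1-5p", family = "miR-1-5p",
                              sequence = ref22)
  all1 <- category_proportions(
    make_ann(tibble::tibble(sequence = ref22, count = 4L, tissue = "t"),
             reference))
  expect_equal(all1$fraction[all1$tier == "miRNA_tier1"], 1)
  none <- category_proportions(
    make_ann(tibble::tibble(sequence = rand_seq(20), count = 4L,
                            tissue = "t"), reference))
  expect_equal(none$fraction[none$tier == "unannotated"], 1)
})
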