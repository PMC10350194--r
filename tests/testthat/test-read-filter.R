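test_that("fixture places reads in exact UTR/CDS proportion", {
  ann <- simulate_annotation(n_genes = 5)
  fx <- simulate_alignment_fixture(ann, reads_per_gene = 100,
                                   utr_fraction = 0.3, seed = 1)
  expect_equal(nrow(fx$reads), 500)
  expect_equal(fx$n_utr_reads, 150L)
  expect_true(all(fx$expected_counts$expected_count == 70L))

  fx0 <- simulate_alignment_fixture(ann, reads_per_gene = 10,
                                    utr_fraction = 0, seed = 1)
  expect_equal(fx0$n_utr_reads, 0L)
  expect_true(all(fx0$expected_counts$expected_count == 10L))

  fx1 <- simulate_alignment_fixture(ann, reads_per_gene = 10,
                                    utr_fraction = 1, seed = 1)
  expect_true(all(fx1$expected_counts$expected_count == 0L))

  no_cds <- dplyr::filter(ann, region != "CDS")
  expect_error(simulate_alignment_fixture(no_cds, 10, utr_fraction = 0.5),
               "no CDS")
})

test_that("SAM round trip preserves read coordinates", {
  ann <- simulate_annotation(n_genes = 3)
  fx <- simulate_alignment_fixture(ann, reads_per_gene = 20,
                                   utr_fraction = 0.5, seed = 2)
  sam <- withr::local_tempfile(fileext = ".sam")
  write_sam(fx$reads, sam, ann)
  back <- read_alignments(sam)
  orig <- dplyr::arrange(fx$reads, read_id)
  got <- dplyr::arrange(back, read_id)
  expect_equal(got$start, orig$start)
  expect_equal(got$end, orig$end)
  expect_equal(got$chrom, orig$chrom)
  expect_equal(got$strand, orig$strand)
})

test_that("read classification distinguishes UTR, CDS and unannotated", {
  ann <- simulate_annotation(n_genes = 1)  # UTR5 1-200, CDS 201-800, UTR3 801-1200
  reads <- tibble::tibble(
    read_id = c("in_utr3", "in_cds", "off_chrom", "spans_cds_utr3", "in_utr5"),
    chrom = c("chr1", "chr1", "chrX", "chr1", "chr1"),
    start = c(900, 300, 100, 780, 50),
    end = c(949, 349, 149, 829, 99),
    strand = "+")
  v <- classify_reads(reads, ann)
  verdicts <- setNames(as.character(v$verdict), v$read_id)
  expect_equal(verdicts[["in_utr3"]], "utr")
  expect_equal(verdicts[["in_cds"]], "non_utr")
  expect_equal(verdicts[["off_chrom"]], "unassigned")
  expect_equal(verdicts[["spans_cds_utr3"]], "utr")  # >= 1 bp UTR overlap
  expect_equal(verdicts[["in_utr5"]], "utr")

  v3 <- classify_reads(reads, ann, utr3_only = TRUE)
  expect_equal(as.character(v3$verdict[v3$read_id == "in_utr5"]), "non_utr")

  unmapped <- reads; unmapped$start[1] <- NA
  expect_error(classify_reads(unmapped, ann), "unmapped")
})

test_that("strand-aware mode only counts same-strand overlaps", {
  ann <- simulate_annotation(n_genes = 1)  # gene001 on +
  reads <- tibble::tibble(read_id = "r1", chrom = "chr1",
                          start = 900, end = 949, strand = "-")
  expect_equal(as.character(classify_reads(reads, ann)$verdict), "utr")
  expect_equal(as.character(classify_reads(reads, ann,
                                           stranded = TRUE)$verdict),
               "unassigned")
})

test_that("UTR filtering removes exactly the fixture's UTR reads", {
  ann <- simulate_annotation(n_genes = 5)
  fx <- simulate_alignment_fixture(ann, reads_per_gene = 100,
                                   utr_fraction = 0.3, seed = 3)
  kept <- filter_utr_reads(fx$reads, ann)
  s <- filter_summary(kept)
  expect_equal(s$removed, 150L)
  expect_equal(s$kept, 350L)
  expect_equal(s$unassigned, 0L)

  # idempotence: a second pass removes nothing
  again <- filter_utr_reads(kept, ann)
  expect_equal(filter_summary(again)$removed, 0L)
  expect_equal(nrow(again), nrow(kept))

  # empty input
  empty <- filter_utr_reads(fx$reads[0, ], ann)
  expect_equal(unlist(filter_summary(empty)),
               c(kept = 0L, removed = 0L, unassigned = 0L))

  # annotation without UTR intervals: filter is the identity
  cds_only <- dplyr::filter(ann, region == "CDS")
  all_kept <- filter_utr_reads(fx$reads, cds_only)
  expect_equal(nrow(all_kept), nrow(fx$reads))
})

test_that("counting assigns unambiguous reads and matches the fixture oracle", {
  ann <- simulate_annotation(n_genes = 5)
  fx <- simulate_alignment_fixture(ann, reads_per_gene = 100,
                                   utr_fraction = 0.3, seed = 4)
  counts <- fx$reads |>
    filter_utr_reads(ann) |>
    count_reads(ann)
  expect_equal(counts$count, fx$expected_counts$expected_count)

  # a read overlapping two genes is counted for neither
  overlapping <- tibble::tibble(
    gene_id = c("gA", "gB"), chrom = "chr9", strand = "+",
    start = c(1, 50), end = c(100, 150), region = "CDS")
  reads <- tibble::tibble(read_id = c("amb", "uniq"), chrom = "chr9",
                          start = c(60, 1), end = c(90, 30), strand = "+")
  cnt <- count_reads(reads, overlapping)
  expect_equal(cnt$count[cnt$gene_id == "gA"], 1L)  # only "uniq"
  expect_equal(cnt$count[cnt$gene_id == "gB"], 0L)
})

test_that("filter-then-count commutes with counting non-UTR reads", {
  ann <- simulate_annotation(n_genes = 4)
  fx <- simulate_alignment_fixture(ann, reads_per_gene = 40,
                                   utr_fraction = 0.45, seed = 5)
  route1 <- count_reads(filter_utr_reads(fx$reads, ann), ann)
  verdicts <- classify_reads(fx$reads, ann)
  non_utr_ids <- verdicts$read_id[verdicts$verdict != "utr"]
  route2 <- count_reads(
    dplyr::filter(fx$reads, read_id %in% non_utr_ids), ann)
  expect_equal(route1, route2)
  # conservation: counted reads never exceed assigned reads
  expect_lte(sum(route1$count), length(non_utr_ids))
})
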