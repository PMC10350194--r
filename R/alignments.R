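#' Simulate an alignment fixture with known post-filter counts
#'
#' Places single-end ungapped reads wholly inside the CDS or wholly
#' inside the 3' UTR of each annotated gene, in an exact proportion:
#' `round(reads_per_gene * utr_fraction)` UTR reads per gene, the rest
#' CDS. Because placement is whole-read, the expected gene count after
#' UTR filtering is known by construction and returned alongside the
#' reads.
#'
#' @param annotation Annotation tibble; every gene needs a CDS interval
#'   (unless `utr_fraction == 1`) and a UTR3 interval (unless
#'   `utr_fraction == 0`), each at least `read_length` bp long.
#' @param reads_per_gene Reads simulated per gene.
#' @param utr_fraction Fraction of each gene's reads placed in its
#'   3' UTR, in `[0, 1]`.
#' @param read_length Read length in bp.
#' @param seed Integer seed for read start positions.
#' @return A list with `reads` (tibble: `read_id`, `chrom`, `start`,
#'   `end`, `strand`; 1-based inclusive), `expected_counts` (tibble:
#'   `gene_id`, `expected_count` after UTR filtering) and `n_utr_reads`
#'   (total UTR reads emitted).
#' @export
#' @examples
#' ann <- simulate_annotation(n_genes = 2)
#' fx <- simulate_alignment_fixture(ann, reads_per_gene = 10,
#'                                  utr_fraction = 0.3, seed = 1)
#' fx$expected_counts
simulate_alignment_fixture <- function(annotation, reads_per_gene = 100,
                                       utr_fraction = 0.3, read_length = 50,
                                       seed = 1) {
  validate_annotation(annotation)
  if (utr_fraction < 0 || utr_fraction > 1)
    abort("`utr_fraction` must be in [0, 1].")
  genes <- unique(annotation$gene_id)
  n_utr <- round(reads_per_gene * utr_fraction)
  n_cds <- reads_per_gene - n_utr

  interval_for <- function(g, region) {
    iv <- annotation |>
      filter(.data$gene_id == g, .data$region == !!region) |>
      filter(.data$end - .data$start + 1 >= read_length)
    if (nrow(iv) == 0) return(NULL)
    iv[1, , drop = FALSE]
  }

  withr::local_seed(seed)
  reads <- purrr::map_dfr(genes, function(g) {
    cds <- interval_for(g, "CDS")
    utr <- interval_for(g, "UTR3")
    if (n_cds > 0 && is.null(cds))
      abort(paste0("gene ", g, " has no CDS interval of length >= ",
                   read_length, " but utr_fraction < 1."))
    if (n_utr > 0 && is.null(utr))
      abort(paste0("gene ", g, " has no 3' UTR interval of length >= ",
                   read_length, "."))
    place <- function(iv, n, tag) {
      if (n == 0) return(NULL)
      start <- sample.int(iv$end - iv$start + 2 - read_length, n,
                          replace = TRUE) + iv$start - 1
      tibble(read_id = paste0(g, "_", tag, "_", seq_len(n)),
             chrom = iv$chrom, start = start,
             end = start + read_length - 1, strand = iv$strand)
    }
    bind_rows(place(cds, n_cds, "cds"), place(utr, n_utr, "utr"))
  })
  list(
    reads = reads,
    expected_counts = tibble(gene_id = genes,
                             expected_count = as.integer(n_cds)),
    n_utr_reads = as.integer(n_utr * length(genes))
  )
}

#' Write reads as a SAM file
#'
#' Emits an unsorted single-end SAM with ungapped records (`<len>M`
#' CIGAR), suitable for round-tripping through `samtools` or
#' [read_alignments()]. Reference lengths in the header are taken from
#' `annotation` when given, else from the reads themselves.
#'
#' @param reads Read tibble (`read_id`, `chrom`, `start`, `end`,
#'   `strand`; 1-based inclusive).
#' @param path Output path (conventionally `.sam`).
#' @param annotation Optional annotation tibble used to size the
#'   `@SQ` header lines.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, path, annotation = NULL) {
  chroms <- sort(unique(reads$chrom))
  max_end <- vapply(chroms, function(ch) {
    m <- max(reads$end[reads$chrom == ch])
    if (!is.null(annotation)) {
      a <- annotation$end[annotation$chrom == ch]
      if (length(a) > 0) m <- max(m, a)
    }
    m
  }, numeric(1))
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", chroms,
                      as.integer(max_end + 1000)))
  len <- reads$end - reads$start + 1
  records <- sprintf("%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t*",
                     reads$read_id,
                     ifelse(reads$strand == "-", 16L, 0L),
                     reads$chrom, reads$start, len,
                     strrep("A", len))
  writeLines(c(header, records), path)
  invisible(path)
}

#' Read aligned reads from SAM or BAM
#'
#' Loads mapped primary alignments into a tidy block table: one row per
#' aligned block (M/=/X stretches split across N gaps), 1-based
#' inclusive coordinates. SAM input is converted on the fly via
#' `Rsamtools::asBam()`.
#'
#' @param path Path to a `.sam` or `.bam` file.
#' @return A tibble: `read_id`, `chrom`, `start`, `end`, `strand`, one
#'   row per block.
#' @export
read_alignments <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, destination = dest,
                             overwrite = TRUE, indexDestination = FALSE)
  }
  ga <- GenomicAlignments::readGAlignments(
    path, param = Rsamtools::ScanBamParam(what = "qname"))
  blocks <- GenomicAlignments::grglist(ga)
  names(blocks) <- S4Vectors::mcols(ga)$qname
  flat <- unlist(blocks, use.names = TRUE)
  tibble(
    read_id = names(flat),
    chrom = as.character(GenomicRanges::seqnames(flat)),
    start = GenomicRanges::start(flat),
    end = GenomicRanges::end(flat),
    strand = as.character(GenomicRanges::strand(flat))
  )
}

reads_granges <- function(reads) {
  needed <- c("read_id", "chrom", "start", "end", "strand")
  missing <- setdiff(needed, names(reads))
  if (length(missing) > 0)
    abort(paste0("reads lack column(s): ", paste(missing, collapse = ", ")))
  if (any(is.na(reads$start)) || any(is.na(reads$end)))
    abort("reads contain unmapped records (missing coordinates); filter them first.")
  if (any(reads$start > reads$end))
    abort("read blocks must satisfy start <= end.")
  GenomicRanges::GRanges(
    seqnames = reads$chrom,
    ranges = IRanges::IRanges(reads$start, reads$end),
    strand = reads$strand,
    read_id = reads$read_id
  )
}
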