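#' Simulate a toy gene annotation
#'
#' Lays out non-overlapping genes in tandem on one chromosome, each with
#' a 5' UTR, a CDS and a 3' UTR (1-based inclusive coordinates, GTF
#' convention). Strands alternate so strand-aware code paths are
#' exercised.
#'
#' @param n_genes Number of genes.
#' @param chrom Chromosome name.
#' @param utr5_length,cds_length,utr3_length Interval lengths in bp.
#' @param gap Gap between consecutive genes in bp.
#' @return An annotation tibble: `gene_id`, `chrom`, `strand`, `start`,
#'   `end`, `region` (one of `UTR5`, `CDS`, `UTR3`, `other_exon`).
#' @export
#' @examples
#' simulate_annotation(n_genes = 2)
simulate_annotation <- function(n_genes = 5, chrom = "chr1",
                                utr5_length = 200, cds_length = 600,
                                utr3_length = 400, gap = 500) {
  stopifnot(n_genes >= 1, utr5_length > 0, cds_length > 0, utr3_length > 0)
  span <- utr5_length + cds_length + utr3_length
  starts <- (seq_len(n_genes) - 1) * (span + gap) + 1
  purrr::map_dfr(seq_len(n_genes), function(i) {
    s <- starts[i]
    tibble(
      gene_id = sprintf("gene%03d", i),
      chrom = chrom,
      strand = if (i %% 2 == 1) "+" else "-",
      start = c(s, s + utr5_length, s + utr5_length + cds_length),
      end = c(s + utr5_length - 1, s + utr5_length + cds_length - 1,
              s + span - 1),
      region = c("UTR5", "CDS", "UTR3")
    )
  })
}

validate_annotation <- function(annotation) {
  needed <- c("gene_id", "chrom", "strand", "start", "end", "region")
  missing <- setdiff(needed, names(annotation))
  if (length(missing) > 0)
    abort(paste0("annotation lacks column(s): ",
                 paste(missing, collapse = ", ")))
  if (any(annotation$start > annotation$end))
    abort("annotation intervals must satisfy start <= end.")
  bad <- setdiff(unique(annotation$region),
                 c("UTR5", "UTR3", "CDS", "other_exon"))
  if (length(bad) > 0)
    abort(paste0("unknown region class(es): ", paste(bad, collapse = ", ")))
  per_gene <- annotation |>
    group_by(.data$gene_id) |>
    summarise(n_chrom = dplyr::n_distinct(.data$chrom),
              n_strand = dplyr::n_distinct(.data$strand))
  if (any(per_gene$n_chrom > 1) || any(per_gene$n_strand > 1))
    abort("all intervals of a gene must share chromosome and strand.")
  invisible(annotation)
}

annotation_granges <- function(annotation) {
  validate_annotation(annotation)
  GenomicRanges::GRanges(
    seqnames = annotation$chrom,
    ranges = IRanges::IRanges(annotation$start, annotation$end),
    strand = annotation$strand,
    gene_id = annotation$gene_id,
    region = annotation$region
  )
}

#' Read a gene annotation from GTF
#'
#' Imports a GTF via `rtracklayer` and keeps CDS, UTR and exon features,
#' mapped onto the package's region classes. UTR features carrying an
#' explicit side (`five_prime_utr` / `three_prime_utr`, or `5UTR` /
#' `3UTR`) keep it; bare `UTR` features are classed `UTR5` when upstream
#' of the gene's CDS midpoint on its strand, else `UTR3`. Exons are kept
#' as `other_exon` only where they extend beyond all CDS/UTR intervals
#' of the gene.
#'
#' @param path Path to a GTF file with `gene_id` attributes.
#' @return An annotation tibble (see [simulate_annotation()]).
#' @export
read_gtf_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  if (is.null(gr$gene_id)) abort("GTF lacks gene_id attributes.")
  type <- as.character(gr$type)
  keep <- type %in% c("CDS", "five_prime_utr", "three_prime_utr",
                      "5UTR", "3UTR", "UTR", "exon")
  gr <- gr[keep]
  type <- type[keep]
  region <- dplyr::case_match(type,
    "CDS" ~ "CDS",
    c("five_prime_utr", "5UTR") ~ "UTR5",
    c("three_prime_utr", "3UTR") ~ "UTR3",
    "UTR" ~ "UTR",
    "exon" ~ "other_exon"
  )
  ann <- tibble(
    gene_id = gr$gene_id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    region = region
  )
  # resolve bare UTRs by position relative to the gene's CDS on its strand
  if (any(ann$region == "UTR")) {
    cds_mid <- ann |>
      filter(.data$region == "CDS") |>
      group_by(.data$gene_id) |>
      summarise(mid = (min(.data$start) + max(.data$end)) / 2)
    ann <- ann |>
      left_join(cds_mid, by = "gene_id") |>
      mutate(region = ifelse(
        .data$region == "UTR",
        ifelse(is.na(.data$mid), "UTR3",
               ifelse(xor((.data$start + .data$end) / 2 < .data$mid,
                          .data$strand == "-"), "UTR5", "UTR3")),
        .data$region)) |>
      select(-"mid")
  }
  # drop exon records fully covered by CDS/UTR intervals of the same gene
  if (any(ann$region == "other_exon")) {
    core <- ann |> filter(.data$region != "other_exon")
    ex <- ann |> filter(.data$region == "other_exon")
    if (nrow(core) > 0 && nrow(ex) > 0) {
      covered <- vapply(seq_len(nrow(ex)), function(i) {
        g <- core |> filter(.data$gene_id == ex$gene_id[i])
        if (nrow(g) == 0) return(FALSE)
        cov <- IRanges::reduce(IRanges::IRanges(g$start, g$end))
        q <- IRanges::IRanges(ex$start[i], ex$end[i])
        sum(IRanges::width(IRanges::intersect(cov, q))) == IRanges::width(q)
      }, logical(1))
      ann <- bind_rows(core, ex[!covered, , drop = FALSE])
    }
  }
  validate_annotation(ann)
  arrange(ann, .data$chrom, .data$start, .data$gene_id)
}

#' Write a gene annotation as GTF
#'
#' @param annotation An annotation tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(annotation, path) {
  validate_annotation(annotation)
  type <- dplyr::case_match(annotation$region,
    "CDS" ~ "CDS", "UTR5" ~ "five_prime_utr",
    "UTR3" ~ "three_prime_utr", "other_exon" ~ "exon")
  lines <- sprintf(
    "%s\ttraprescue\t%s\t%d\t%d\t.\t%s\t.\tgene_id \"%s\";",
    annotation$chrom, type, annotation$start, annotation$end,
    annotation$strand, annotation$gene_id)
  writeLines(lines, path)
  invisible(path)
}
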