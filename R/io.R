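#' Read and write package tables as TSV
#'
#' Thin wrappers around `readr` with the column contracts used across
#' the pipeline: counts are `gene_id` + one integer column per sample,
#' designs carry `sample`, `genotype`, `treatment`, `replicate`.
#' List-columns (gene lists) are serialized comma-separated.
#'
#' @param path File path.
#' @name trap_io
NULL

#' @rdname trap_io
#' @export
read_counts <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  if (!"gene_id" %in% names(x)) abort("count TSV must have a gene_id column.")
  x
}

#' @rdname trap_io
#' @param counts Count tibble.
#' @export
write_counts <- function(counts, path) {
  readr::write_tsv(counts, path)
  invisible(path)
}

#' @rdname trap_io
#' @export
read_design <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  validate_design(x)
  x
}

#' @rdname trap_io
#' @param design Design tibble.
#' @export
write_design <- function(design, path) {
  readr::write_tsv(design, path)
  invisible(path)
}

# serialize list-columns as comma-joined strings before writing
write_table_tsv <- function(x, path) {
  is_list <- vapply(x, is.list, logical(1))
  x[is_list] <- lapply(x[is_list],
                       function(col) vapply(col, paste, character(1),
                                            collapse = ","))
  readr::write_tsv(x, path)
  invisible(path)
}
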