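#' Supervenn-style membership partition of gene sets
#'
#' Tabulates every membership pattern over k named gene sets: each gene
#' in the union falls in exactly one pattern (the subset of sets that
#' contain it). All `2^k - 1` non-empty patterns are reported, empty
#' ones with count 0. Rows are ordered by descending count, then by the
#' pattern's lexicographic key.
#'
#' @param sets Named list of character vectors; names must be unique
#'   and non-empty, `k >= 1`.
#' @return A `trap_partition` tibble: one logical column per set,
#'   `pattern` (e.g. `"A&C"`), `count`, `genes` (list-column).
#' @export
#' @examples
#' membership_partition(list(A = c("g1", "g2"), B = c("g2", "g3"),
#'                           C = "g2"))
membership_partition <- function(sets) {
  if (length(sets) < 1) abort("need at least one set.")
  nms <- names(sets)
  if (is.null(nms) || any(!nzchar(nms)))
    abort("every set must be named.")
  if (anyDuplicated(nms)) abort("duplicate set names.")
  if (length(sets) > 15) abort("more than 15 sets is not supported.")
  sets <- purrr::map(sets, unique)
  union_genes <- sort(unique(unlist(sets, use.names = FALSE)))

  member <- matrix(FALSE, length(union_genes), length(sets),
                   dimnames = list(union_genes, nms))
  for (nm in nms) member[, nm] <- union_genes %in% sets[[nm]]
  key <- apply(member, 1, function(r) paste(as.integer(r), collapse = ""))

  k <- length(sets)
  grid <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), k),
                                KEEP.OUT.ATTRS = FALSE))
  grid <- grid[rowSums(grid) > 0, , drop = FALSE]
  colnames(grid) <- nms
  grid_key <- apply(grid, 1, function(r) paste(as.integer(r), collapse = ""))

  genes_by_key <- split(union_genes, key)
  rows <- as_tibble(grid)
  rows$pattern <- apply(grid, 1, function(r) paste(nms[r], collapse = "&"))
  rows$genes <- purrr::map(grid_key, ~ genes_by_key[[.x]] %||% character(0))
  rows$count <- lengths(rows$genes)
  out <- rows |>
    arrange(dplyr::desc(.data$count), .data$pattern) |>
    select(dplyr::all_of(nms), "pattern", "count", "genes")
  class(out) <- c("trap_partition", class(out))
  out
}

#' Cross-genotype direction concordance
#'
#' Partitions the genes basal-significant in all three mutant genotypes
#' by the sign pattern of their fold changes: `all_up`, `all_down`, or
#' an opposing bucket keyed by the genotype whose direction disagrees
#' with the other two.
#'
#' @param basal_calls Named list of three [call_basal()] outputs (one
#'   per genotype).
#' @return A tibble: `gene_id`, per-genotype `direction_<name>`,
#'   `bucket` (e.g. `all_up`, `opposing_cKO`).
#' @export
direction_concordance <- function(basal_calls) {
  stopifnot(length(basal_calls) == 3, !is.null(names(basal_calls)))
  nms <- names(basal_calls)
  tbls <- purrr::imap(basal_calls, function(cb, nm) {
    tibble(gene_id = cb$gene_id,
           !!paste0("direction_", nm) := as.character(cb$direction))
  })
  joined <- purrr::reduce(tbls, ~ inner_join(.x, .y, by = "gene_id"))
  dir_cols <- paste0("direction_", nms)
  dirs <- as.matrix(joined[dir_cols])
  sig_all <- rowSums(dirs != "ns") == 3
  joined <- joined[sig_all, , drop = FALSE]
  dirs <- dirs[sig_all, , drop = FALSE]
  n_up <- rowSums(dirs == "up")
  odd <- character(nrow(dirs))
  odd[n_up == 1] <- apply(dirs[n_up == 1, , drop = FALSE], 1,
                          function(r) nms[r == "up"])
  odd[n_up == 2] <- apply(dirs[n_up == 2, , drop = FALSE], 1,
                          function(r) nms[r == "down"])
  joined |>
    mutate(bucket = dplyr::case_when(
      n_up == 3 ~ "all_up",
      n_up == 0 ~ "all_down",
      TRUE ~ paste0("opposing_", odd)
    ))
}

#' Complete-linkage hierarchical clustering of a log2FC matrix
#'
#' Agglomerative clustering with Euclidean distance and complete
#' linkage (the heatmap row-ordering used throughout the analysis),
#' delegating to `stats::hclust`. Missing values are imputed as 0 with
#' a warning. A single-row input returns a one-leaf dendrogram.
#'
#' @param mat Numeric matrix (typically genes x contrasts of log2 fold
#'   changes) with rownames, or a tibble with a `gene_id` column.
#' @return An `hclust` object (or, for one row, a one-leaf
#'   `dendrogram`).
#' @export
#' @examples
#' hcluster_complete(matrix(c(0, 1, 10), dimnames = list(c("a", "b", "c"))))
hcluster_complete <- function(mat) {
  if (is.data.frame(mat)) {
    m <- as.matrix(mat[setdiff(names(mat), "gene_id")])
    rownames(m) <- mat$gene_id
    mat <- m
  }
  if (is.null(rownames(mat)))
    rownames(mat) <- paste0("row", seq_len(nrow(mat)))
  if (anyNA(mat)) {
    warn("missing values imputed as 0 before clustering.")
    mat[is.na(mat)] <- 0
  }
  if (nrow(mat) < 1) abort("need at least one row.")
  if (nrow(mat) == 1) {
    leaf <- 1L
    attributes(leaf) <- list(members = 1L, height = 0,
                             label = rownames(mat)[1], leaf = TRUE,
                             class = "dendrogram")
    return(leaf)
  }
  hclust(dist(mat, method = "euclidean"), method = "complete")
}

#' Write a dendrogram as Newick
#'
#' @param h An `hclust` object (or one-leaf `dendrogram` from
#'   [hcluster_complete()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(h, path) {
  if (inherits(h, "dendrogram")) {
    writeLines(paste0(attr(h, "label"), ";"), path)
    return(invisible(path))
  }
  phy <- ape::as.phylo(h)
  ape::write.tree(phy, file = path)
  invisible(path)
}
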