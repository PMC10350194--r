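#' Read a GMT gene-set collection
#'
#' Parses the tab-separated GMT format: one set per line as
#' `name<TAB>description<TAB>member1<TAB>member2...`. Empty lines are
#' skipped; gene identifiers are case-preserving; duplicate members
#' within a set are dropped.
#'
#' @param path Path to a `.gmt` file.
#' @return A tibble: `set`, `description`, `genes` (list-column),
#'   `size`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0)
    return(tibble(set = character(0), description = character(0),
                  genes = list(), size = integer(0)))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  short <- lengths(fields) < 3
  if (any(short))
    abort(paste0("malformed GMT line ", keep[which(short)[1]],
                 ": fewer than 3 tab-separated fields."))
  out <- tibble(
    set = vapply(fields, `[[`, character(1), 1),
    description = vapply(fields, `[[`, character(1), 2),
    genes = purrr::map(fields, ~ unique(.x[-(1:2)]))
  )
  if (anyDuplicated(out$set)) abort("duplicate set names in GMT.")
  out$size <- lengths(out$genes)
  out
}

#' Hypergeometric overrepresentation of a gene list
#'
#' One-sided overrepresentation test of a query gene list against each
#' set of a collection: with universe size N, set size K (after
#' intersecting the set with the universe) and query size n, the
#' p-value is the upper hypergeometric tail `P(X >= overlap)`. BH
#' adjustment is applied across sets. Query genes outside the universe
#' are dropped with a warning.
#'
#' @param query Character vector of gene ids.
#' @param collection A tibble from [read_gmt()] or a named list of
#'   character vectors.
#' @param universe Character vector of all eligible gene ids; in a DE
#'   workflow, the testable genes (not all annotated genes), to avoid
#'   detection-bias inflation.
#' @return A `trap_enrichment` tibble, one row per set: `set`,
#'   `set_size` (K), `overlap`, `p`, `q`, `overlap_genes`
#'   (list-column), sorted by `p`.
#' @export
#' @examples
#' hypergeom_enrich(letters[1:5],
#'                  list(S = letters[1:5]),
#'                  universe = letters[1:20])
hypergeom_enrich <- function(query, collection, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) abort("universe is empty.")
  if (is.data.frame(collection)) {
    sets <- setNames(collection$genes, collection$set)
  } else {
    sets <- collection
  }
  if (length(sets) == 0)
    return(structure(tibble(set = character(0), set_size = integer(0),
                            overlap = integer(0), p = numeric(0),
                            q = numeric(0), overlap_genes = list()),
                     class = c("trap_enrichment", class(tibble()))))
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside) > 0) {
    warn(paste0(length(outside),
                " query gene(s) outside the universe were dropped."))
    query <- intersect(query, universe)
  }
  N <- length(universe)
  n <- length(query)
  res <- purrr::imap_dfr(sets, function(members, nm) {
    members <- intersect(unique(members), universe)
    K <- length(members)
    ov_genes <- intersect(query, members)
    ov <- length(ov_genes)
    p <- if (K == 0 || n == 0) 1 else
      phyper(ov - 1, K, N - K, n, lower.tail = FALSE)
    tibble(set = nm, set_size = K, overlap = ov, p = min(p, 1),
           overlap_genes = list(ov_genes))
  })
  res$q <- bh_adjust(res$p)
  out <- res |>
    arrange(.data$p, .data$set) |>
    select("set", "set_size", "overlap", "p", "q", "overlap_genes")
  class(out) <- c("trap_enrichment", class(out))
  out
}
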