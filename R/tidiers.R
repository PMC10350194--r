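#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a differential-expression table
#'
#' @param x A `trap_de` object.
#' @param ... Unused.
#' @return A plain tibble of the per-gene results.
#' @export
tidy.trap_de <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "trap_de")
  attr(out, "contrast") <- NULL
  as_tibble(out)
}

#' One-row summary of a differential-expression table
#'
#' @param x A `trap_de` object.
#' @param lfc_threshold,p_threshold Thresholds used to count
#'   significant genes (defaults match the basal criterion).
#' @param ... Unused.
#' @return A one-row tibble: `contrast`, `n_genes`, `n_testable`,
#'   `n_up`, `n_down`.
#' @export
glance.trap_de <- function(x, lfc_threshold = 0.56, p_threshold = 0.05,
                           ...) {
  cs <- attr(x, "contrast")
  label <- if (is.null(cs)) NA_character_ else
    paste(paste(cs$numerator, collapse = ":"), "vs",
          paste(cs$denominator, collapse = ":"))
  sig <- x$testable & x$wald_p < p_threshold & !is.na(x$log2fc)
  tibble(
    contrast = label,
    n_genes = nrow(x),
    n_testable = sum(x$testable),
    n_up = sum(sig & x$log2fc > lfc_threshold, na.rm = TRUE),
    n_down = sum(sig & x$log2fc < -lfc_threshold, na.rm = TRUE)
  )
}

#' Tidy a rescue classification
#'
#' @param x A `trap_rescue` object ([classify_rescue()]).
#' @param ... Unused.
#' @return The per-gene table as a plain tibble.
#' @export
tidy.trap_rescue <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "trap_rescue")
  as_tibble(out)
}

#' One-row summary of a rescue classification
#'
#' @param x A `trap_rescue` object.
#' @param ... Unused.
#' @return A one-row tibble with the number of basal-different genes
#'   and the size of each rescue category.
#' @export
glance.trap_rescue <- function(x, ...) {
  basal <- x$basal_direction != "ns"
  cat_tab <- table(x$category[basal])
  tibble(
    n_genes = nrow(x),
    n_basal = sum(basal),
    n_rescued_both = unname(cat_tab["rescued_both"]),
    n_rescued_plus19_only = unname(cat_tab["rescued_plus19_only"]),
    n_rescued_delta19_only = unname(cat_tab["rescued_delta19_only"]),
    n_not_rescued = unname(cat_tab["not_rescued"])
  )
}
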