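#' Volcano plot of a differential-expression table
#'
#' @param object A `trap_de` object.
#' @param lfc_threshold,p_threshold Dashed guide lines (the basal
#'   criterion by default).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.trap_de <- function(object, lfc_threshold = 0.56,
                             p_threshold = 0.05, ...) {
  df <- tidy(object) |> filter(.data$testable)
  df$state <- dplyr::case_when(
    abs(df$log2fc) > lfc_threshold & df$wald_p < p_threshold &
      df$log2fc > 0 ~ "up",
    abs(df$log2fc) > lfc_threshold & df$wald_p < p_threshold ~ "down",
    TRUE ~ "ns")
  ggplot2::ggplot(df, ggplot2::aes(.data$log2fc, -log10(.data$wald_p),
                                   colour = .data$state)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * lfc_threshold,
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = -log10(p_threshold),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::scale_colour_manual(values = c(up = "#b2182b",
                                            down = "#2166ac",
                                            ns = "grey70")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Rescue scatter: residual versus baseline fold change
#'
#' Plots, per ICD variant, the absolute log2 fold change remaining
#' versus wild type under the ICD against the baseline absolute fold
#' change; rescued transcripts fall below the diagonal.
#'
#' @param object A `trap_rescue` object ([classify_rescue()]).
#' @param ... Unused.
#' @return A ggplot, faceted by ICD variant.
#' @export
autoplot.trap_rescue <- function(object, ...) {
  df <- tidy(object) |>
    filter(.data$basal_direction != "ns") |>
    select("gene_id", "log2fc_A", dplyr::starts_with("log2fc_C_"),
           dplyr::starts_with("rescue_status_")) |>
    tidyr::pivot_longer(-c("gene_id", "log2fc_A"),
                        names_to = c(".value", "icd"),
                        names_pattern = "(log2fc_C|rescue_status)_(.*)")
  ggplot2::ggplot(df, ggplot2::aes(abs(.data$log2fc_A),
                                   abs(.data$log2fc_C),
                                   colour = .data$rescue_status)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         linewidth = 0.3) +
    ggplot2::geom_point(size = 0.7, alpha = 0.7) +
    ggplot2::facet_wrap(~icd) +
    ggplot2::scale_colour_manual(values = c(rescued = "#1b7837",
                                            not_rescued = "#762a83")) +
    ggplot2::labs(x = "|log2FC| baseline vs WT",
                  y = "|log2FC| with ICD vs WT", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Bar chart of a membership partition
#'
#' @param object A `trap_partition` object ([membership_partition()]).
#' @param ... Unused.
#' @return A ggplot of non-empty membership patterns by count.
#' @export
autoplot.trap_partition <- function(object, ...) {
  df <- as_tibble(object) |> filter(.data$count > 0)
  ggplot2::ggplot(df, ggplot2::aes(stats::reorder(.data$pattern,
                                                  .data$count),
                                   .data$count)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "genes") +
    ggplot2::theme_minimal()
}

#' Dot plot of overrepresentation results
#'
#' @param object A `trap_enrichment` object ([hypergeom_enrich()]).
#' @param max_sets Show at most this many top sets (by p-value).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.trap_enrichment <- function(object, max_sets = 20, ...) {
  df <- as_tibble(object) |>
    arrange(.data$p) |> head(max_sets)
  ggplot2::ggplot(df, ggplot2::aes(-log10(.data$p),
                                   stats::reorder(.data$set, -.data$p),
                                   size = .data$overlap)) +
    ggplot2::geom_point(colour = "#2166ac") +
    ggplot2::labs(x = "-log10 p", y = NULL, size = "overlap") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
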