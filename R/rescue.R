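#' Combined genotype-rescue p-value
#'
#' The combined evidence statistic used to call rescue: the square of
#' the summed p-values divided by their number, clamped to `[0, 1]`:
#' `min(1, (sum p_i)^2 / n)`. In the rescue procedure it combines, per
#' gene, the p-value of the baseline genotype-vs-wild-type contrast
#' with that of the within-genotype ICD contrast (n = 2), so that a
#' strong baseline difference and a strong ICD response jointly yield a
#' small combined value. The raw formula can exceed 1 (whenever
#' `sum p > sqrt(n)`), hence the clamp.
#'
#' @param p Numeric vector of p-values (length >= 1, each in `[0, 1]`).
#' @return A single combined p-value in `[0, 1]`.
#' @export
#' @examples
#' combined_p(c(0.04, 0.01))  # (0.05)^2 / 2 = 0.00125
combined_p <- function(p) {
  if (length(p) < 1) abort("need at least one p-value.")
  if (anyNA(p) || any(p < 0) || any(p > 1))
    abort("p-values must lie in [0, 1] with no NA.")
  min(1, sum(p)^2 / length(p))
}

# vectorized two-argument version used on whole tables
combine_p2 <- function(pa, pb) pmin(1, (pa + pb)^2 / 2)

#' Call basal genotype differences
#'
#' Applies the basal significance criterion to a
#' (genotype, Cre) vs (WT, Cre) contrast: `up` when
#' `log2fc > lfc_threshold` and p < `p_threshold`, `down` for the
#' mirrored condition, else `ns`. Both inequalities are strict; a gene
#' sitting exactly on the fold-change threshold is not called.
#' Not-testable genes are `ns` and keep `testable = FALSE` as the flag.
#'
#' @param de A `trap_de` table for the baseline contrast.
#' @param lfc_threshold Absolute log2 fold-change threshold (default
#'   0.56, i.e. ~1.47-fold).
#' @param p_threshold P-value threshold (default 0.05).
#' @param use_bh Threshold `bh_q` instead of the raw Wald p.
#' @return A tibble `gene_id`, `log2fc`, `wald_p`, `bh_q`, `testable`,
#'   `direction` (factor `up`/`down`/`ns`).
#' @export
#' @examples
#' de <- tibble::tibble(gene_id = "g", base_mean = 50, log2fc = 0.6,
#'                      se = 0.1, wald_p = 0.01, bh_q = 0.02,
#'                      testable = TRUE)
#' call_basal(de)
call_basal <- function(de, lfc_threshold = 0.56, p_threshold = 0.05,
                       use_bh = FALSE) {
  stopifnot(lfc_threshold > 0, p_threshold > 0)
  p <- if (use_bh) de$bh_q else de$wald_p
  de |>
    mutate(.p = p,
           direction = factor(dplyr::case_when(
             !.data$testable ~ "ns",
             .data$log2fc > lfc_threshold & .data$.p < p_threshold ~ "up",
             .data$log2fc < -lfc_threshold & .data$.p < p_threshold ~ "down",
             TRUE ~ "ns"
           ), levels = c("up", "down", "ns"))) |>
    select("gene_id", "log2fc", "wald_p", "bh_q", "testable", "direction")
}

#' Call rescue for one genotype and one ICD variant
#'
#' A basal-different transcript is `rescued` by an ICD variant when (i)
#' its absolute log2 fold change versus wild type shrinks under the ICD
#' (`|log2fc_C| < |log2fc_A|`, strictly: movement toward the wild-type
#' translatome) and (ii) the combined genotype-rescue p-value of the
#' baseline contrast A and the within-genotype ICD contrast B is below
#' `p_threshold`. Genes without a basal call are `not_applicable`;
#' genes not testable in B or C are `not_rescued` with
#' `missing_data = TRUE`. Ties in (i) are `not_rescued` ("smaller"
#' read strictly).
#'
#' Contrast roles, for a genotype `geno` and ICD `icd`:
#' \describe{
#'   \item{A (`basal`)}{(geno, Cre) vs (WT, Cre) — the baseline
#'     difference.}
#'   \item{B (`icd_within`)}{(geno, icd) vs (geno, Cre) — the ICD
#'     response within the genotype.}
#'   \item{C (`icd_vs_wt`)}{(geno, icd) vs (WT, Cre) — the residual
#'     difference from wild type under the ICD.}
#' }
#'
#' @param basal `trap_de` table for contrast A, or the output of
#'   [call_basal()] on it (it is recomputed when directions are
#'   absent).
#' @param icd_vs_wt `trap_de` table for contrast C.
#' @param icd_within `trap_de` table for contrast B.
#' @param lfc_threshold,p_threshold Basal thresholds passed to
#'   [call_basal()]; `p_threshold` also bounds the combined p-value.
#' @param use_bh Feed BH-adjusted p-values (instead of raw Wald p) into
#'   both the basal criterion and the combined statistic.
#' @param strict Additionally require contrast C itself to be
#'   non-significant (`p >= p_threshold` or
#'   `|log2fc_C| <= lfc_threshold`) for a `rescued` call.
#' @return A tibble per gene: `gene_id`, `basal_direction`, `log2fc_A`,
#'   `p_A`, `log2fc_C`, `p_B`, `combined_p`, `rescue_status` (factor
#'   `rescued`/`not_rescued`/`not_applicable`), `missing_data`.
#' @export
call_rescue <- function(basal, icd_vs_wt, icd_within,
                        lfc_threshold = 0.56, p_threshold = 0.05,
                        use_bh = FALSE, strict = FALSE) {
  dirs <- if ("direction" %in% names(basal)) basal else
    call_basal(basal, lfc_threshold, p_threshold, use_bh = use_bh)
  pcol <- function(x) if (use_bh) x$bh_q else x$wald_p
  a <- tibble(gene_id = dirs$gene_id, basal_direction = dirs$direction,
              log2fc_A = dirs$log2fc,
              p_A = if (use_bh) dirs$bh_q else dirs$wald_p,
              testable_A = dirs$testable)
  c_tbl <- tibble(gene_id = icd_vs_wt$gene_id, log2fc_C = icd_vs_wt$log2fc,
                  p_C = pcol(icd_vs_wt), testable_C = icd_vs_wt$testable)
  b_tbl <- tibble(gene_id = icd_within$gene_id, p_B = pcol(icd_within),
                  testable_B = icd_within$testable)
  out <- a |>
    left_join(c_tbl, by = "gene_id") |>
    left_join(b_tbl, by = "gene_id") |>
    mutate(
      missing_data = !(tidyr::replace_na(.data$testable_C, FALSE) &
                         tidyr::replace_na(.data$testable_B, FALSE)),
      combined_p = combine_p2(.data$p_A, .data$p_B),
      smaller = abs(.data$log2fc_C) < abs(.data$log2fc_A),
      c_quiet = !strict |
        !(abs(.data$log2fc_C) > lfc_threshold & .data$p_C < p_threshold),
      rescue_status = factor(dplyr::case_when(
        .data$basal_direction == "ns" ~ "not_applicable",
        .data$missing_data ~ "not_rescued",
        .data$smaller & .data$combined_p < p_threshold &
          .data$c_quiet ~ "rescued",
        TRUE ~ "not_rescued"
      ), levels = c("rescued", "not_rescued", "not_applicable"))
    ) |>
    select("gene_id", "basal_direction", "log2fc_A", "p_A", "log2fc_C",
           "p_B", "combined_p", "rescue_status", "missing_data")
  out
}

#' Combine per-ICD rescue statuses into a category
#'
#' @param plus19,delta19 Factors/characters of per-gene rescue status
#'   for the two ICD variants (`rescued`, `not_rescued`,
#'   `not_applicable`).
#' @return Factor with levels `rescued_both`, `rescued_plus19_only`,
#'   `rescued_delta19_only`, `not_rescued`, `not_applicable`.
#' @export
#' @examples
#' categorize_rescue("rescued", "not_rescued")
categorize_rescue <- function(plus19, delta19) {
  p <- as.character(plus19); d <- as.character(delta19)
  factor(dplyr::case_when(
    p == "not_applicable" | d == "not_applicable" ~ "not_applicable",
    p == "rescued" & d == "rescued" ~ "rescued_both",
    p == "rescued" ~ "rescued_plus19_only",
    d == "rescued" ~ "rescued_delta19_only",
    TRUE ~ "not_rescued"
  ), levels = c("rescued_both", "rescued_plus19_only",
                "rescued_delta19_only", "not_rescued", "not_applicable"))
}

#' Classify rescue across both ICD variants for one genotype
#'
#' Runs [call_rescue()] for each ICD variant and assembles the master
#' per-gene table with the combined category.
#'
#' @param basal `trap_de` table for (geno, Cre) vs (WT, Cre).
#' @param icd_tables Named list with elements `plus19` and `delta19`,
#'   each `list(vs_wt = <trap_de C>, within = <trap_de B>)`.
#' @inheritParams call_rescue
#' @return A tibble: `gene_id`, `basal_direction`, `log2fc_A`, then per
#'   ICD `log2fc_C_*`, `combined_p_*`, `rescue_status_*`, and
#'   `category`.
#' @export
classify_rescue <- function(basal, icd_tables, lfc_threshold = 0.56,
                            p_threshold = 0.05, use_bh = FALSE,
                            strict = FALSE) {
  stopifnot(all(c("plus19", "delta19") %in% names(icd_tables)))
  dirs <- call_basal(basal, lfc_threshold, p_threshold, use_bh = use_bh)
  per_icd <- purrr::map(icd_tables, function(tabs) {
    call_rescue(dirs, tabs$vs_wt, tabs$within,
                lfc_threshold = lfc_threshold, p_threshold = p_threshold,
                use_bh = use_bh, strict = strict)
  })
  out <- tibble(
    gene_id = dirs$gene_id,
    basal_direction = dirs$direction,
    log2fc_A = dirs$log2fc,
    p_A = if (use_bh) dirs$bh_q else dirs$wald_p,
    log2fc_C_plus19 = per_icd$plus19$log2fc_C,
    combined_p_plus19 = per_icd$plus19$combined_p,
    rescue_status_plus19 = per_icd$plus19$rescue_status,
    log2fc_C_delta19 = per_icd$delta19$log2fc_C,
    combined_p_delta19 = per_icd$delta19$combined_p,
    rescue_status_delta19 = per_icd$delta19$rescue_status,
    category = categorize_rescue(per_icd$plus19$rescue_status,
                                 per_icd$delta19$rescue_status)
  )
  class(out) <- c("trap_rescue", class(out))
  out
}

#' Genotype-independent ICD effects
#'
#' Among genes with no basal call (`ns`), applies the basal thresholds
#' to each within-genotype ICD contrast to find transcripts moved by
#' ICD expression itself, and flags genes the two ICD variants move in
#' opposite directions.
#'
#' @param icd_within_plus19,icd_within_delta19 `trap_de` tables for
#'   (geno, ICD) vs (geno, Cre), one per variant.
#' @param basal_directions Output of [call_basal()] for the genotype's
#'   baseline contrast, or `NULL` when the genotype has no baseline
#'   contrast (wild type: every gene is eligible).
#' @inheritParams call_basal
#' @return A tibble: `gene_id`, `direction_plus19`, `direction_delta19`
#'   (factors `up`/`down`/`ns`), `opposite_flag`.
#' @export
call_icd_effect <- function(icd_within_plus19, icd_within_delta19,
                            basal_directions = NULL, lfc_threshold = 0.56,
                            p_threshold = 0.05, use_bh = FALSE) {
  d19 <- call_basal(icd_within_delta19, lfc_threshold, p_threshold,
                    use_bh = use_bh)
  p19 <- call_basal(icd_within_plus19, lfc_threshold, p_threshold,
                    use_bh = use_bh)
  out <- tibble(gene_id = p19$gene_id,
                direction_plus19 = p19$direction) |>
    left_join(tibble(gene_id = d19$gene_id,
                     direction_delta19 = d19$direction), by = "gene_id")
  if (!is.null(basal_directions)) {
    eligible <- basal_directions$gene_id[basal_directions$direction == "ns"]
    out <- out |> filter(.data$gene_id %in% eligible)
  }
  out |>
    mutate(opposite_flag =
             (.data$direction_plus19 == "up" &
                .data$direction_delta19 == "down") |
             (.data$direction_plus19 == "down" &
                .data$direction_delta19 == "up"))
}

#' Relaxed common-module membership across all three mutant genotypes
#'
#' Within the genes basal-significant (full criterion:
#' `|log2fc| > lfc_threshold`, p < `p_threshold`) in at least one
#' genotype, finds transcripts moving the same way in all three under a
#' relaxed fold-change-only criterion: common-up when
#' `log2fc > relaxed_threshold` in every genotype, common-down when
#' below its negative in every genotype; no p-value requirement on the
#' relaxed members.
#'
#' @param basal_list Named list of three `trap_de` tables (one per
#'   mutant genotype, each vs WT + Cre).
#' @param relaxed_threshold Relaxed absolute log2 fold-change bound
#'   (default 0.5).
#' @inheritParams call_basal
#' @return A tibble: `gene_id`, per-genotype `log2fc_<name>`,
#'   `n_significant`, `common` (factor `up`/`down`), restricted to
#'   common genes.
#' @export
expanded_common <- function(basal_list, relaxed_threshold = 0.5,
                            lfc_threshold = 0.56, p_threshold = 0.05,
                            use_bh = FALSE) {
  stopifnot(length(basal_list) == 3, !is.null(names(basal_list)))
  calls <- purrr::imap(basal_list, function(de, nm) {
    cb <- call_basal(de, lfc_threshold, p_threshold, use_bh = use_bh)
    tibble(gene_id = cb$gene_id,
           !!paste0("log2fc_", nm) := cb$log2fc,
           !!paste0("sig_", nm) := cb$direction != "ns")
  })
  joined <- purrr::reduce(calls, ~ inner_join(.x, .y, by = "gene_id"))
  lfc_cols <- paste0("log2fc_", names(basal_list))
  sig_cols <- paste0("sig_", names(basal_list))
  lfc <- as.matrix(joined[lfc_cols])
  n_sig <- rowSums(as.matrix(joined[sig_cols]))
  up <- rowSums(lfc > relaxed_threshold, na.rm = FALSE) == 3
  down <- rowSums(lfc < -relaxed_threshold, na.rm = FALSE) == 3
  joined |>
    mutate(n_significant = n_sig,
           common = factor(dplyr::case_when(
             n_sig >= 1 & up ~ "up",
             n_sig >= 1 & down ~ "down",
             TRUE ~ NA_character_
           ), levels = c("up", "down"))) |>
    filter(!is.na(.data$common)) |>
    select("gene_id", dplyr::all_of(lfc_cols), "n_significant", "common")
}
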