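#' Simulate per-gene ground truth for a rescue experiment
#'
#' Draws a gene-level truth table emulating the effect classes of a
#' genotype-rescue translatome study: genes may carry a baseline
#' genotype effect (log2 scale, versus wild type + Cre), a per-ICD
#' rescue fraction (how much of the baseline effect the ICD variant
#' reverses), and a genotype-independent ICD effect. Label allocation is
#' exact: `round(n_genes * proportion)` genes receive each label, the
#' remainder are null.
#'
#' Labels and their parameter structure:
#' \describe{
#'   \item{null}{no effects at all.}
#'   \item{basal_only}{baseline effect, untouched by either ICD.}
#'   \item{rescued_both}{baseline effect fully reversed
#'     (`rescue = rescue_full`) by both ICD variants.}
#'   \item{rescued_plus19_only / rescued_delta19_only}{baseline effect
#'     reversed by exactly one variant.}
#'   \item{not_rescued}{baseline effect, rescue fraction `rescue_none`
#'     for both variants; the explicit negative class for recovery
#'     benchmarks. Under the defaults (`rescue_none = 0`) its parameters
#'     coincide with `basal_only`; the two labels are kept distinct so
#'     benchmarks can target a designated negative set.}
#'   \item{icd_effect_only}{no baseline effect, but a shared
#'     (genotype-independent) log2 effect of ICD expression; both ICDs
#'     move the gene in the same direction, mirroring the near-total
#'     directional concordance seen between the two variants.}
#' }
#'
#' Baseline effects are drawn with magnitude `lfc_basal` and a random
#' sign, shared across the three mutant genotypes (the labels are not
#' genotype-specific). Base means are log-uniform on `base_mean_range`;
#' dispersion is the NB overdispersion alpha in
#' `variance = mu + alpha * mu^2`.
#'
#' @param n_genes Number of genes.
#' @param proportions Named numeric vector of label proportions over
#'   `basal_only`, `rescued_both`, `rescued_plus19_only`,
#'   `rescued_delta19_only`, `not_rescued`, `icd_effect_only`; must sum
#'   to <= 1, the remainder is `null`.
#' @param lfc_basal Magnitude of baseline genotype log2 fold changes.
#' @param lfc_icd Magnitude of genotype-independent ICD log2 effects.
#' @param rescue_full,rescue_none Rescue fraction assigned to rescuing /
#'   non-rescuing ICD variants (defaults 1 and 0: full reversal or none).
#' @param base_mean_range Log-uniform range of expected counts in
#'   WT + Cre at unit depth.
#' @param dispersion NB dispersion alpha; scalar or length `n_genes`.
#' @param seed Integer seed; identical seeds give byte-identical tables.
#' @return A tibble of class `trap_truth`: `gene_id`, `label`,
#'   `base_mean`, `dispersion`, `lfc_basal` (baseline log2 effect, 0
#'   when absent), `rescue_plus19`, `rescue_delta19` (rescue fractions),
#'   `icd_lfc_plus19`, `icd_lfc_delta19` (genotype-independent ICD log2
#'   effects).
#' @export
#' @examples
#' simulate_truth(n_genes = 20, seed = 1)
simulate_truth <- function(n_genes = 2000,
                           proportions = c(basal_only = 0.10,
                                           rescued_both = 0.08,
                                           rescued_plus19_only = 0.04,
                                           rescued_delta19_only = 0.04,
                                           not_rescued = 0.08,
                                           icd_effect_only = 0.06),
                           lfc_basal = 1.5,
                           lfc_icd = 1.5,
                           rescue_full = 1,
                           rescue_none = 0,
                           base_mean_range = c(20, 500),
                           dispersion = 0.05,
                           seed = 1) {
  known <- c("basal_only", "rescued_both", "rescued_plus19_only",
             "rescued_delta19_only", "not_rescued", "icd_effect_only")
  if (length(proportions) > 0) {
    bad <- setdiff(names(proportions), known)
    if (length(bad) > 0)
      abort(paste0("unknown label(s) in `proportions`: ",
                   paste(bad, collapse = ", ")))
  }
  props <- setNames(numeric(length(known)), known)
  props[names(proportions)] <- proportions
  if (any(props < 0)) abort("proportions must be nonnegative.")
  if (sum(props) > 1 + 1e-12)
    abort("label proportions must sum to at most 1.")
  if (any(dispersion < 0)) abort("dispersion must be nonnegative.")
  stopifnot(all(base_mean_range > 0))

  n_per <- round(n_genes * props)
  if (sum(n_per) > n_genes)
    abort("rounded label allocation exceeds `n_genes`; lower the proportions.")
  labels <- c(rep(names(n_per), n_per),
              rep("null", n_genes - sum(n_per)))

  withr::local_seed(seed)
  labels <- sample(labels)
  gene_id <- sprintf("gene%05d", seq_len(n_genes))
  base_mean <- exp(stats::runif(n_genes, log(base_mean_range[1]),
                                log(base_mean_range[2])))
  alpha <- rep_len(dispersion, n_genes)

  has_basal <- labels %in% c("basal_only", "rescued_both",
                             "rescued_plus19_only", "rescued_delta19_only",
                             "not_rescued")
  sign_basal <- sample(c(-1, 1), n_genes, replace = TRUE)
  lfc <- ifelse(has_basal, sign_basal * lfc_basal, 0)

  rescue_p19 <- ifelse(labels %in% c("rescued_both", "rescued_plus19_only"),
                       rescue_full,
                       ifelse(has_basal, rescue_none, 0))
  rescue_d19 <- ifelse(labels %in% c("rescued_both", "rescued_delta19_only"),
                       rescue_full,
                       ifelse(has_basal, rescue_none, 0))

  has_icd <- labels == "icd_effect_only"
  sign_icd <- sample(c(-1, 1), n_genes, replace = TRUE)
  gamma <- ifelse(has_icd, sign_icd * lfc_icd, 0)

  out <- tibble(
    gene_id = gene_id,
    label = factor(labels, levels = c("null", known)),
    base_mean = base_mean,
    dispersion = alpha,
    lfc_basal = lfc,
    rescue_plus19 = rescue_p19,
    rescue_delta19 = rescue_d19,
    icd_lfc_plus19 = gamma,
    icd_lfc_delta19 = gamma
  )
  class(out) <- c("trap_truth", class(out))
  out
}

#' True condition-level log2 effect for each gene
#'
#' Expands a truth table into the log2 effect (relative to WT + Cre)
#' that each (genotype, treatment) condition applies to each gene:
#' baseline effect for mutant + Cre, shrunk baseline
#' `lfc_basal * (1 - rescue)` plus the genotype-independent ICD effect
#' for mutant + ICD, and the ICD effect alone for WT + ICD.
#'
#' @param truth A `trap_truth` tibble.
#' @param genotype,treatment Vectors of equal length naming conditions.
#' @return A genes-by-conditions matrix of log2 effects (rownames
#'   `gene_id`).
#' @export
truth_log2_effects <- function(truth, genotype, treatment) {
  stopifnot(length(genotype) == length(treatment))
  icd_col <- function(trt) {
    switch(trt, ICD_plus19 = "plus19", ICD_delta19 = "delta19",
           abort(paste0("unknown treatment: ", trt)))
  }
  eff <- vapply(seq_along(genotype), function(i) {
    g <- genotype[i]; t <- treatment[i]
    if (!g %in% trap_genotypes) abort(paste0("unknown genotype: ", g))
    if (!t %in% trap_treatments) abort(paste0("unknown treatment: ", t))
    if (g == "WT" && t == "Cre") return(rep(0, nrow(truth)))
    if (t == "Cre") return(truth$lfc_basal)
    icd <- icd_col(t)
    gamma <- truth[[paste0("icd_lfc_", icd)]]
    if (g == "WT") return(gamma)
    rho <- truth[[paste0("rescue_", icd)]]
    truth$lfc_basal * (1 - rho) + gamma
  }, numeric(nrow(truth)))
  eff <- matrix(eff, nrow = nrow(truth))
  rownames(eff) <- truth$gene_id
  eff
}
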