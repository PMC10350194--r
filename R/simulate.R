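#' Simulate a TRAP-Seq count matrix from ground truth
#'
#' Draws negative-binomial gene counts for every sample in `design`
#' under the truth table's effect structure. The expected count of gene
#' g in sample s is
#' `size_multiplier_s * base_mean_g * 2^(log2 effect of s's condition)`,
#' with NB variance `mu + dispersion * mu^2`; a dispersion of exactly 0
#' yields Poisson counts.
#'
#' @param truth A `trap_truth` tibble ([simulate_truth()]).
#' @param design A design tibble ([trap_design()]); a missing
#'   `size_multiplier` column defaults to 1 for every sample.
#' @param seed Integer seed; identical (truth, design, seed) triples
#'   give identical matrices.
#' @return A tibble with `gene_id` and one integer count column per
#'   sample, in design order.
#' @export
#' @examples
#' truth <- simulate_truth(n_genes = 10, seed = 1)
#' design <- trap_design(replicates = 2, seed = 1)
#' simulate_counts(truth, design, seed = 2)
simulate_counts <- function(truth, design, seed = 1) {
  validate_design(design)
  if (any(truth$base_mean < 0)) abort("base_mean must be nonnegative.")
  if (any(truth$dispersion < 0)) abort("dispersion must be nonnegative.")
  if (!"size_multiplier" %in% names(design)) design$size_multiplier <- 1
  if (any(design$size_multiplier <= 0))
    abort("size multipliers must be positive.")

  eff <- truth_log2_effects(truth, design$genotype, design$treatment)
  mu <- (truth$base_mean * 2^eff) %*% diag(design$size_multiplier,
                                           nrow = nrow(design))
  withr::local_seed(seed)
  alpha <- rep_len(truth$dispersion, nrow(truth))
  counts <- matrix(0L, nrow(truth), nrow(design))
  poisson <- alpha < 1e-12
  if (any(poisson))
    counts[poisson, ] <- rpois(sum(poisson) * nrow(design),
                               lambda = mu[poisson, , drop = FALSE])
  if (any(!poisson))
    counts[!poisson, ] <- rnbinom(sum(!poisson) * nrow(design),
                                  mu = mu[!poisson, , drop = FALSE],
                                  size = 1 / alpha[!poisson])
  storage.mode(counts) <- "integer"
  colnames(counts) <- design$sample
  bind_cols(tibble(gene_id = truth$gene_id), as_tibble(counts))
}
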