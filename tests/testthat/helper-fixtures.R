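# Shared fixture builders for the test suite. Everything is generated in
# code; nothing is read from disk except files the tests write themselves.

# A minimal hand-specified count table: 3 genes x 2 samples whose
# median-of-ratios factors are known in closed form.
toy_counts <- function() {
  tibble::tibble(gene_id = c("g1", "g2", "g3"),
                 s1 = c(10, 30, 50), s2 = c(20, 60, 100))
}

# Design covering two conditions with n replicates each, unit depth.
two_group_design <- function(n = 4, genotype = "cKO") {
  tibble::tibble(
    sample = c(paste0("wt", seq_len(n)), paste0("mut", seq_len(n))),
    genotype = rep(c("WT", genotype), each = n),
    treatment = "Cre",
    replicate = rep(seq_len(n), 2),
    size_multiplier = 1
  )
}

# Hand-built trap_de-shaped table for classifier unit tests.
fake_de <- function(gene_id, log2fc, wald_p, testable = TRUE) {
  tibble::tibble(gene_id = gene_id, base_mean = 100, log2fc = log2fc,
                 se = 0.1, wald_p = wald_p,
                 bh_q = pmin(1, wald_p * 2), testable = testable)
}

# Truth table with a single fully specified gene (bypasses the sampler).
single_gene_truth <- function(base_mean = 50, dispersion = 0,
                              lfc_basal = 0, rescue_plus19 = 0,
                              rescue_delta19 = 0, icd_lfc = 0) {
  tibble::tibble(gene_id = "g1", label = factor("null"),
                 base_mean = base_mean, dispersion = dispersion,
                 lfc_basal = lfc_basal,
                 rescue_plus19 = rescue_plus19,
                 rescue_delta19 = rescue_delta19,
                 icd_lfc_plus19 = icd_lfc, icd_lfc_delta19 = icd_lfc)
}
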