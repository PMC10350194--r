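test_that("size factors match the hand median-of-ratios computation", {
  f <- size_factors(toy_counts())
  # geometric means (sqrt(200), sqrt(1800), sqrt(5000)); every ratio in a
  # column is identical, so the medians are sqrt(1/2) and sqrt(2)
  expect_equal(round(f$size_factor, 4), c(0.7071, 1.4142))

  same <- tibble::tibble(gene_id = c("a", "b"), s1 = c(5, 9), s2 = c(5, 9))
  expect_equal(size_factors(same)$size_factor, c(1, 1))
})

test_that("size factors are scale-equivariant and gene-permutation invariant", {
  withr::local_seed(1)
  m <- matrix(rnbinom(600, mu = 80, size = 10), ncol = 3,
              dimnames = list(sprintf("g%03d", 1:200), c("a", "b", "c")))
  f <- size_factors(m)$size_factor
  scaled <- m; scaled[, 2] <- scaled[, 2] * 3
  f_scaled <- size_factors(scaled)$size_factor
  expect_equal(f_scaled[2] / f_scaled[1], 3 * f[2] / f[1], tolerance = 1e-10)
  perm <- m[sample(nrow(m)), ]
  expect_equal(size_factors(perm)$size_factor, f)
})

test_that("all-zero-containing matrices need the pseudo-reference fallback", {
  m <- matrix(c(0, 5, 8, 0, 3, 9), ncol = 2,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  m[1, 1] <- 0; m[2, 2] <- 0; m[3, 1] <- 0
  expect_error(size_factors(m), "pseudo_reference")
  f <- size_factors(m, pseudo_reference = TRUE)
  expect_true(all(f$size_factor > 0))
})

test_that("dispersion estimation recovers Poisson, NB and degenerate cases", {
  # Poisson data: alpha-hat collapses to the floor for most genes
  d <- trap_design(replicates = 4, seed = 1)
  tr <- simulate_truth(n_genes = 500, proportions = c(basal_only = 0),
                       base_mean_range = c(100, 100), dispersion = 0,
                       seed = 11)
  cnt <- simulate_counts(tr, d, seed = 12)
  a_pois <- estimate_dispersion(cnt, d)$dispersion
  expect_lte(median(a_pois), 0.01)

  # NB alpha = 0.1 at mu = 200, 50 replicates in one condition
  d50 <- tibble::tibble(sample = paste0("s", 1:50), genotype = "WT",
                        treatment = "Cre", replicate = 1:50,
                        size_multiplier = 1)
  tr2 <- simulate_truth(n_genes = 500, proportions = c(basal_only = 0),
                        base_mean_range = c(200, 200), dispersion = 0.1,
                        seed = 13)
  cnt2 <- simulate_counts(tr2, d50, seed = 14)
  a_nb <- estimate_dispersion(cnt2, d50)$dispersion
  expect_gte(mean(a_nb >= 0.05 & a_nb <= 0.2), 0.90)

  # constant counts: zero variance pins alpha at the floor
  const <- matrix(7, 3, 4, dimnames = list(paste0("g", 1:3),
                                           paste0("s", 1:4)))
  dc <- tibble::tibble(sample = paste0("s", 1:4), genotype = "WT",
                       treatment = "Cre", replicate = 1:4)
  expect_equal(estimate_dispersion(const, dc)$dispersion, rep(1e-8, 3))

  # no replicated condition at all
  d1 <- tibble::tibble(sample = c("s1", "s2"),
                       genotype = c("WT", "cKO"), treatment = "Cre",
                       replicate = 1)
  expect_error(estimate_dispersion(const[, 1:2], d1), ">= 2 replicates")
})

test_that("exactly doubled counts give log2fc of 1", {
  m <- matrix(rep(c(10, 25, 40, 75), each = 8) *
                rep(c(1, 1, 1, 1, 2, 2, 2, 2), 4),
              nrow = 4, byrow = TRUE,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:8)))
  d <- two_group_design(4)
  d$sample <- paste0("s", 1:8)
  sf <- tibble::tibble(sample = d$sample, size_factor = 1)
  dsp <- tibble::tibble(gene_id = rownames(m), dispersion = 0)
  de <- trap_de(m, d, "cKO:Cre vs WT:Cre", factors = sf, dispersions = dsp)
  expect_true(all(abs(de$log2fc - 1) < 1e-6))
})

test_that("swapping the contrast negates log2fc and preserves p", {
  d <- trap_design(replicates = 3, seed = 2)
  tr <- simulate_truth(n_genes = 200, seed = 21)
  cnt <- simulate_counts(tr, d, seed = 22)
  fwd <- trap_de(cnt, d, "cKO:Cre vs WT:Cre")
  rev <- trap_de(cnt, d, "WT:Cre vs cKO:Cre")
  ok <- fwd$testable & rev$testable
  expect_gt(mean(ok), 0.95)
  expect_equal(fwd$log2fc[ok], -rev$log2fc[ok], tolerance = 1e-6)
  expect_equal(fwd$wald_p[ok], rev$wald_p[ok], tolerance = 1e-6)
})

test_that("untestable genes are flagged, not dropped", {
  m <- matrix(c(0, 0, 0, 0, 0, 0, 0, 0,
                5, 6, 7, 8, 9, 10, 11, 12), nrow = 2, byrow = TRUE,
              dimnames = list(c("dead", "alive"), paste0("s", 1:8)))
  d <- two_group_design(4); d$sample <- paste0("s", 1:8)
  sf <- tibble::tibble(sample = d$sample, size_factor = 1)
  dsp <- tibble::tibble(gene_id = rownames(m), dispersion = 0.05)
  de <- trap_de(m, d, "cKO:Cre vs WT:Cre", factors = sf, dispersions = dsp)
  expect_equal(nrow(de), 2)
  expect_false(de$testable[de$gene_id == "dead"])
  expect_true(is.na(de$wald_p[de$gene_id == "dead"]))
  expect_true(de$testable[de$gene_id == "alive"])
})

test_that("a group with no counts at all is flagged rather than infinite", {
  m <- matrix(c(0, 0, 0, 0, 20, 22, 19, 21), nrow = 1,
              dimnames = list("g1", paste0("s", 1:8)))
  d <- two_group_design(4); d$sample <- paste0("s", 1:8)
  sf <- tibble::tibble(sample = d$sample, size_factor = 1)
  dsp <- tibble::tibble(gene_id = "g1", dispersion = 0.05)
  de <- trap_de(m, d, "WT:Cre vs cKO:Cre", factors = sf, dispersions = dsp)
  expect_false(de$testable[1])
})

test_that("the NB Wald fit agrees with an independent GLM engine", {
  skip_if_not_installed("DESeq2")
  d <- trap_design(replicates = 4, seed = 3)
  tr <- simulate_truth(n_genes = 150, proportions = c(basal_only = 0.3),
                       seed = 31)
  cnt <- simulate_counts(tr, d, seed = 32)
  sf <- size_factors(cnt)
  dsp <- estimate_dispersion(cnt, d, factors = sf)
  de <- trap_de(cnt, d, "cKO:Cre vs WT:Cre", factors = sf,
                dispersions = dsp)

  sel <- d$genotype %in% c("WT", "cKO") & d$treatment == "Cre"
  m <- as.matrix(cnt[-1])[, sel]
  rownames(m) <- cnt$gene_id
  cd <- S4Vectors::DataFrame(condition = factor(
    ifelse(d$genotype[sel] == "cKO", "num", "den"),
    levels = c("den", "num")))
  dds <- DESeq2::DESeqDataSetFromMatrix(m, cd, ~condition)
  DESeq2::sizeFactors(dds) <- sf$size_factor[match(colnames(m), sf$sample)]
  DESeq2::dispersions(dds) <- dsp$dispersion[match(rownames(m),
                                                   dsp$gene_id)]
  dds <- DESeq2::nbinomWaldTest(dds)
  res <- DESeq2::results(dds, contrast = c("condition", "num", "den"))
  ok <- de$testable & !is.na(res$log2FoldChange)
  expect_gt(mean(ok), 0.95)
  expect_equal(de$log2fc[ok], res$log2FoldChange[ok], tolerance = 1e-4)
  expect_equal(de$se[ok], res$lfcSE[ok], tolerance = 1e-4)
  expect_equal(de$wald_p[ok], res$pvalue[ok], tolerance = 1e-4)
})

test_that("log2fc estimation is unbiased and well powered at beta = 1.5", {
  d <- trap_design(replicates = 4, seed = 4)
  tr <- simulate_truth(n_genes = 2000, proportions = c(basal_only = 0.5),
                       lfc_basal = 1.5, dispersion = 0.05, seed = 41)
  cnt <- simulate_counts(tr, d, seed = 42)
  de <- trap_de(cnt, d, "cKO:Cre vs WT:Cre")
  sig <- tr$label == "basal_only" & de$testable
  oriented <- de$log2fc[sig] * sign(tr$lfc_basal[sig])
  expect_lt(abs(mean(oriented) - 1.5), 0.1)
  expect_gte(mean(de$wald_p[sig] < 0.05), 0.9)
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  withr::local_seed(5)
  p <- runif(100)
  q <- bh_adjust(p)
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-12))
  expect_true(all(q >= p - 1e-12))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("contrast parsing accepts strings and lists, rejects nonsense", {
  cs <- parse_contrast("cKO:Cre vs WT:Cre")
  expect_equal(cs$numerator, c("cKO", "Cre"))
  cs2 <- parse_contrast(list(numerator = c("KI_plus19", "ICD_plus19"),
                             denominator = c("WT", "Cre")))
  expect_equal(cs2$denominator, c("WT", "Cre"))
  expect_error(parse_contrast("cKO:Cre"), "vs")
  expect_error(parse_contrast("cKO:Cre vs cKO:Cre"), "equals")
  expect_error(parse_contrast("banana:Cre vs WT:Cre"), "unknown genotype")
})
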