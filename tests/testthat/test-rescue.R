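test_that("combined p-value follows the squared-sum formula with clamp", {
  expect_equal(combined_p(c(0.04, 0.01)), 0.05^2 / 2)
  expect_equal(combined_p(c(0, 0)), 0)
  expect_equal(combined_p(c(0.9, 0.9)), 1)  # raw formula 1.62, clamped
  expect_equal(combined_p(0.2), 0.04)       # n = 1
  expect_error(combined_p(numeric(0)), "at least one")
  expect_error(combined_p(c(0.5, 1.1)), "\\[0, 1\\]")

  # non-decreasing in each argument, clamp engaged iff sum > sqrt(n)
  grid <- seq(0, 1, length.out = 25)
  for (p2 in c(0.05, 0.4, 0.9)) {
    vals <- vapply(grid, function(p1) combined_p(c(p1, p2)), numeric(1))
    expect_true(all(diff(vals) >= -1e-12))
  }
  expect_equal(combined_p(c(0.7, 0.7)), 0.98)      # sum < sqrt(2): exact
  expect_equal(combined_p(c(0.72, 0.70)), 1)       # sum > sqrt(2): clamped
})

test_that("basal calls apply strict thresholds", {
  de <- fake_de(paste0("g", 1:5),
                log2fc = c(0.60, 0.56, -1.0, -0.57, 0.8),
                wald_p = c(0.01, 0.001, 0.2, 0.04, 0.05))
  cb <- call_basal(de)
  expect_equal(as.character(cb$direction),
               c("up",   # above both thresholds
                 "ns",   # exactly on the FC threshold: strict
                 "ns",   # p too large
                 "down",
                 "ns"))  # p exactly on the threshold: strict
  nt <- fake_de("g9", 1.5, 0.001, testable = FALSE)
  expect_equal(as.character(call_basal(nt)$direction), "ns")
})

test_that("the rescue rule reproduces the worked example and the tie case", {
  basal <- fake_de("g1", log2fc = 1.2, wald_p = 0.001)
  icd_c <- fake_de("g1", log2fc = 0.2, wald_p = 0.5)
  icd_b <- fake_de("g1", log2fc = -1.0, wald_p = 0.004)
  r <- call_rescue(basal, icd_c, icd_b)
  expect_equal(r$combined_p, (0.001 + 0.004)^2 / 2)  # 1.25e-5
  expect_equal(as.character(r$rescue_status), "rescued")

  # |log2fc_C| not smaller than baseline: not rescued despite tiny p
  icd_c2 <- fake_de("g1", log2fc = 1.3, wald_p = 1e-6)
  r2 <- call_rescue(basal, icd_c2, fake_de("g1", -0.1, 1e-6))
  expect_equal(as.character(r2$rescue_status), "not_rescued")

  # exact tie reads "smaller" strictly
  icd_c3 <- fake_de("g1", log2fc = 1.2, wald_p = 0.001)
  r3 <- call_rescue(basal, icd_c3, icd_b)
  expect_equal(as.character(r3$rescue_status), "not_rescued")

  # no basal call: not applicable
  ns_basal <- fake_de("g1", log2fc = 0.1, wald_p = 0.9)
  r4 <- call_rescue(ns_basal, icd_c, icd_b)
  expect_equal(as.character(r4$rescue_status), "not_applicable")

  # untestable ICD contrast: not rescued, flagged
  r5 <- call_rescue(basal, fake_de("g1", NA, NA, testable = FALSE), icd_b)
  expect_equal(as.character(r5$rescue_status), "not_rescued")
  expect_true(r5$missing_data)
})

test_that("strict mode additionally requires the ICD-vs-WT contrast quiet", {
  basal <- fake_de("g1", log2fc = 2.4, wald_p = 0.0001)
  icd_b <- fake_de("g1", log2fc = -1.2, wald_p = 0.001)
  # fold change halved but still significantly different from WT
  icd_c <- fake_de("g1", log2fc = 1.2, wald_p = 0.0005)
  expect_equal(as.character(call_rescue(basal, icd_c, icd_b)$rescue_status),
               "rescued")
  expect_equal(as.character(call_rescue(basal, icd_c, icd_b,
                                        strict = TRUE)$rescue_status),
               "not_rescued")
})

test_that("per-ICD statuses combine into the four categories", {
  expect_equal(as.character(categorize_rescue("rescued", "rescued")),
               "rescued_both")
  expect_equal(as.character(categorize_rescue("rescued", "not_rescued")),
               "rescued_plus19_only")
  expect_equal(as.character(categorize_rescue("not_rescued", "rescued")),
               "rescued_delta19_only")
  expect_equal(as.character(categorize_rescue("not_rescued", "not_rescued")),
               "not_rescued")
  expect_equal(as.character(categorize_rescue("not_applicable", "rescued")),
               "not_applicable")
})

test_that("every basal-significant gene lands in exactly one category", {
  d <- trap_design(replicates = 4, seed = 5)
  tr <- simulate_truth(n_genes = 600, seed = 51)
  cnt <- simulate_counts(tr, d, seed = 52)
  de_for <- function(contrast) trap_de(cnt, d, contrast)
  res <- classify_rescue(
    de_for("cKO:Cre vs WT:Cre"),
    list(plus19 = list(vs_wt = de_for("cKO:ICD_plus19 vs WT:Cre"),
                       within = de_for("cKO:ICD_plus19 vs cKO:Cre")),
         delta19 = list(vs_wt = de_for("cKO:ICD_delta19 vs WT:Cre"),
                        within = de_for("cKO:ICD_delta19 vs cKO:Cre"))))
  basal <- res$basal_direction != "ns"
  expect_true(all(res$category[basal] != "not_applicable"))
  expect_true(all(res$category[!basal] == "not_applicable"))
  four <- table(res$category[basal])
  expect_equal(sum(four[c("rescued_both", "rescued_plus19_only",
                          "rescued_delta19_only", "not_rescued")]),
               sum(basal))
})

test_that("under the global null, basal calls are rare", {
  d <- trap_design(replicates = 4, seed = 6)
  tr <- simulate_truth(n_genes = 2000, proportions = c(basal_only = 0),
                       seed = 61)
  cnt <- simulate_counts(tr, d, seed = 62)
  cb <- call_basal(trap_de(cnt, d, "cKO:Cre vs WT:Cre"))
  expect_lt(mean(cb$direction != "ns"), 0.05)
})

test_that("genotype-independent ICD effects cover only basal-ns genes", {
  basal <- call_basal(fake_de(c("g1", "g2", "g3"),
                              log2fc = c(2, 0.1, -0.2),
                              wald_p = c(0.001, 0.8, 0.7)))
  p19 <- fake_de(c("g1", "g2", "g3"), log2fc = c(1, 0.8, 0.9),
                 wald_p = c(0.01, 0.01, 0.02))
  d19 <- fake_de(c("g1", "g2", "g3"), log2fc = c(1, 0.7, -0.8),
                 wald_p = c(0.01, 0.02, 0.01))
  eff <- call_icd_effect(p19, d19, basal_directions = basal)
  expect_false("g1" %in% eff$gene_id)  # basal-up gene handled by rescue path
  g2 <- eff[eff$gene_id == "g2", ]
  expect_equal(as.character(g2$direction_plus19), "up")
  expect_false(g2$opposite_flag)
  g3 <- eff[eff$gene_id == "g3", ]
  expect_true(g3$opposite_flag)  # up by one ICD, down by the other
})

test_that("the relaxed common module gates on one full-criterion call", {
  mk <- function(l1, l2, l3, p1 = 0.01, p2 = 0.5, p3 = 0.5) {
    list(cKO = fake_de("g", l1, p1),
         KI_plus19 = fake_de("g", l2, p2),
         KI_delta19 = fake_de("g", l3, p3))
  }
  # significant in one genotype, above 0.5 in all three
  cm <- expanded_common(mk(0.60, 0.52, 0.55))
  expect_equal(as.character(cm$common), "up")
  # one genotype below the relaxed bound
  expect_equal(nrow(expanded_common(mk(0.60, 0.52, 0.49))), 0)
  # strong fold changes but no full-criterion call anywhere
  none <- mk(0.55, 0.52, 0.55)  # 0.55 < 0.56: no gate
  expect_equal(nrow(expanded_common(none)), 0)
  # downward module
  dn <- expanded_common(mk(-0.60, -0.52, -0.55))
  expect_equal(as.character(dn$common), "down")
})
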