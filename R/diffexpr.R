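#' Median-of-ratios size factors
#'
#' Per-sample normalization constants computed against a geometric-mean
#' pseudo-reference: for each sample s,
#' `factor_s = median_g count(g, s) / geomean_g` over the reference set
#' of genes with no zero count in any sample. This is the standard
#' normalization for NB count models of bulk expression data.
#'
#' @param counts Count tibble (`gene_id` + one column per sample) or a
#'   numeric matrix with gene rownames.
#' @param pseudo_reference When the strict reference set is empty
#'   (every gene has a zero somewhere), setting this to `TRUE` falls
#'   back to a pseudo-reference built from the geometric mean over
#'   positive counts only, with per-sample medians taken over that
#'   sample's positive counts.
#' @return A tibble `sample`, `size_factor`.
#' @export
#' @examples
#' counts <- tibble::tibble(gene_id = c("a", "b", "c"),
#'                          s1 = c(10, 30, 50), s2 = c(20, 60, 100))
#' size_factors(counts)
size_factors <- function(counts, pseudo_reference = FALSE) {
  m <- counts_matrix(counts)
  if (any(m < 0)) abort("counts must be nonnegative.")
  ref <- rowSums(m == 0) == 0
  if (!any(ref)) {
    if (!pseudo_reference)
      abort(paste0(
        "no gene has nonzero counts in every sample; rerun with ",
        "`pseudo_reference = TRUE` to normalize against a positive-count ",
        "pseudo-reference."))
    lg <- log(m)
    lg[!is.finite(lg)] <- NA
    geo <- exp(rowMeans(lg, na.rm = TRUE))
    use <- is.finite(geo) & geo > 0
    ratios <- m[use, , drop = FALSE] / geo[use]
    ratios[m[use, , drop = FALSE] == 0] <- NA
    f <- apply(ratios, 2, median, na.rm = TRUE)
  } else {
    geo <- exp(rowMeans(log(m[ref, , drop = FALSE])))
    f <- apply(m[ref, , drop = FALSE] / geo, 2, median)
  }
  if (any(!is.finite(f)) || any(f <= 0))
    abort("size factor estimation failed (non-positive factor).")
  tibble(sample = colnames(m), size_factor = unname(f))
}

#' Method-of-moments NB dispersion, pooled across conditions
#'
#' Estimates a per-gene dispersion alpha (NB variance
#' `mu + alpha * mu^2`) from size-factor-normalized counts: within each
#' (genotype, treatment) condition having at least two replicates the
#' sample variance is computed, variances are pooled across conditions
#' weighted by their degrees of freedom, and
#' `alpha = max(floor, (pooled_var - mean) / mean^2)` with the mean
#' taken over all samples of the contributing conditions. Estimated
#' once on the full matrix and shared across contrasts, which
#' stabilizes small-n comparisons.
#'
#' @param counts Count tibble or matrix.
#' @param design Design tibble covering the count columns.
#' @param factors Optional size-factor tibble ([size_factors()]);
#'   computed from `counts` when omitted.
#' @param floor Lower bound for alpha (default `1e-8`).
#' @return A tibble `gene_id`, `dispersion`.
#' @export
estimate_dispersion <- function(counts, design, factors = NULL,
                                floor = 1e-8) {
  m <- counts_matrix(counts)
  validate_design(design)
  design <- design[match(colnames(m), design$sample), , drop = FALSE]
  if (anyNA(design$sample))
    abort("every count column must appear in the design.")
  if (is.null(factors)) factors <- size_factors(counts)
  sf <- factors$size_factor[match(colnames(m), factors$sample)]
  norm <- sweep(m, 2, sf, "/")

  cond <- paste(design$genotype, design$treatment, sep = ":")
  reps <- table(cond)
  usable <- names(reps)[reps >= 2]
  if (length(usable) == 0)
    abort("no condition has >= 2 replicates; cannot estimate dispersion.")
  in_use <- cond %in% usable

  ss <- 0; df <- 0
  for (cc in usable) {
    sel <- cond == cc
    mu_c <- rowMeans(norm[, sel, drop = FALSE])
    ss <- ss + rowSums((norm[, sel, drop = FALSE] - mu_c)^2)
    df <- df + sum(sel) - 1
  }
  pooled_var <- ss / df
  mean_all <- rowMeans(norm[, in_use, drop = FALSE])
  alpha <- ifelse(mean_all > 0,
                  pmax(floor, (pooled_var - mean_all) / mean_all^2),
                  floor)
  tibble(gene_id = rownames(m), dispersion = unname(alpha))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with monotonicity enforcement (delegates to
#' `stats::p.adjust`). Genes excluded from testing must be excluded
#' from the input: `m` is the number of p-values supplied.
#'
#' @param p Numeric vector of p-values in `[0, 1]`, no `NA`.
#' @return Adjusted q-values, same length and order.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p) || any(p < 0) || any(p > 1))
    abort("p-values must lie in [0, 1] with no NA.")
  p.adjust(p, method = "BH")
}

#' Two-group negative-binomial Wald test for one contrast
#'
#' Fits, per gene, the two-group NB model with log link and size-factor
#' offsets, dispersion held fixed at the pooled estimate, by
#' iteratively reweighted least squares; no fold-change shrinkage is
#' applied. The reported `log2fc` is the numerator-vs-denominator group
#' difference on the log2 scale, `wald_p` the two-sided normal tail of
#' `log2fc / se`, and `bh_q` the BH adjustment across testable genes.
#'
#' Genes with all-zero counts in both groups, fits that fail to
#' converge, and fits driven to extreme effects by an all-zero group
#' are flagged `testable = FALSE` with `NA` statistics rather than
#' dropped.
#'
#' @param counts Count tibble or matrix.
#' @param design Design tibble; both contrast conditions need >= 2
#'   replicates.
#' @param contrast Contrast as `"cKO:Cre vs WT:Cre"` or a list
#'   `list(numerator = c("cKO", "Cre"), denominator = c("WT", "Cre"))`.
#' @param factors,dispersions Optional precomputed [size_factors()] /
#'   [estimate_dispersion()] tibbles; computed from the full `counts`
#'   when omitted.
#' @param max_iter,tol IRLS iteration cap and convergence tolerance on
#'   the coefficients (natural-log scale).
#' @return A `trap_de` tibble: `gene_id`, `base_mean` (mean normalized
#'   count over the contrast's samples), `log2fc`, `se`, `wald_p`,
#'   `bh_q`, `testable`; the contrast is carried in
#'   `attr(x, "contrast")`.
#' @export
#' @examples
#' design <- trap_design(replicates = 3, seed = 1)
#' truth <- simulate_truth(n_genes = 50, seed = 1)
#' counts <- simulate_counts(truth, design, seed = 2)
#' trap_de(counts, design, "cKO:Cre vs WT:Cre")
trap_de <- function(counts, design, contrast, factors = NULL,
                    dispersions = NULL, max_iter = 50, tol = 1e-8) {
  m <- counts_matrix(counts)
  validate_design(design)
  cs <- parse_contrast(contrast)
  design <- design[match(colnames(m), design$sample), , drop = FALSE]
  if (anyNA(design$sample))
    abort("every count column must appear in the design.")

  cond <- paste(design$genotype, design$treatment, sep = ":")
  num_key <- paste(cs$numerator, collapse = ":")
  den_key <- paste(cs$denominator, collapse = ":")
  in_num <- cond == num_key
  in_den <- cond == den_key
  if (sum(in_num) < 2 || sum(in_den) < 2)
    abort(paste0("contrast ", num_key, " vs ", den_key,
                 " needs >= 2 replicates on each side."))

  if (is.null(factors)) factors <- size_factors(counts)
  sf_all <- factors$size_factor[match(colnames(m), factors$sample)]
  if (is.null(dispersions))
    dispersions <- estimate_dispersion(counts, design, factors = factors)
  alpha <- dispersions$dispersion[match(rownames(m), dispersions$gene_id)]
  if (anyNA(alpha)) abort("dispersion missing for some genes.")

  sel <- in_num | in_den
  y <- m[, sel, drop = FALSE]
  sf <- sf_all[sel]
  x <- as.numeric(in_num[sel])

  fit <- nb_two_group_irls(y, sf, x, alpha, max_iter = max_iter, tol = tol)

  base_mean <- rowMeans(sweep(y, 2, sf, "/"))
  log2fc <- fit$b1 / log(2)
  se <- fit$se_b1 / log(2)
  wald_p <- 2 * pnorm(-abs(fit$b1 / fit$se_b1))
  testable <- fit$ok
  log2fc[!testable] <- NA_real_
  se[!testable] <- NA_real_
  wald_p[!testable] <- NA_real_
  bh_q <- rep(NA_real_, length(wald_p))
  bh_q[testable] <- bh_adjust(wald_p[testable])

  out <- tibble(
    gene_id = rownames(m),
    base_mean = unname(base_mean),
    log2fc = unname(log2fc),
    se = unname(se),
    wald_p = unname(wald_p),
    bh_q = unname(bh_q),
    testable = unname(testable)
  )
  attr(out, "contrast") <- cs
  class(out) <- c("trap_de", class(out))
  out
}

# Vectorized IRLS for the per-gene model
#   count ~ NB(mu, alpha),  log mu = b0 + b1 * x + log(sf)
# across all genes at once. Working weights w = mu / (1 + alpha * mu)
# (inverse variance on the link scale); the 2x2 weighted normal
# equations are solved in closed form per gene. Genes whose effect
# diverges (a group with no counts) or that fail to converge are
# flagged not-ok.
nb_two_group_irls <- function(y, sf, x, alpha, max_iter = 50, tol = 1e-8) {
  G <- nrow(y)
  norm <- sweep(y, 2, sf, "/")
  m0 <- rowMeans(norm[, x == 0, drop = FALSE])
  m1 <- rowMeans(norm[, x == 1, drop = FALSE])
  eps <- 1e-8
  b0 <- log(pmax(m0, eps))
  b1 <- log(pmax(m1, eps)) - b0
  off <- matrix(log(sf), G, length(sf), byrow = TRUE)

  all_zero <- rowSums(y) == 0
  active <- !all_zero
  converged <- rep(FALSE, G)
  se_b1 <- rep(NA_real_, G)
  bound <- 20  # |b1| beyond this (~2^29-fold) marks a divergent fit

  for (iter in seq_len(max_iter)) {
    if (!any(active)) break
    idx <- which(active)
    eta <- b0[idx] + outer(b1[idx], x) + off[idx, , drop = FALSE]
    mu <- pmin(pmax(exp(eta), 1e-10), 1e12)
    w <- mu / (1 + alpha[idx] * mu)
    z <- (eta - off[idx, , drop = FALSE]) +
      (y[idx, , drop = FALSE] - mu) / mu
    sw <- rowSums(w)
    swx <- as.vector(w %*% x)          # x in {0,1}: also sum w x^2
    swz <- rowSums(w * z)
    swxz <- as.vector((w * z) %*% x)
    det <- sw * swx - swx^2
    det[det <= 0] <- NA
    b0_new <- (swx * swz - swx * swxz) / det
    b1_new <- (sw * swxz - swx * swz) / det
    bad <- !is.finite(b0_new) | !is.finite(b1_new) | abs(b1_new) > bound
    delta <- pmax(abs(b0_new - b0[idx]), abs(b1_new - b1[idx]))
    b0[idx] <- ifelse(bad, b0[idx], b0_new)
    b1[idx] <- ifelse(bad, b1[idx], b1_new)
    done <- !bad & delta < tol
    converged[idx[done]] <- TRUE
    active[idx[done | bad]] <- FALSE
    if (any(bad)) converged[idx[bad]] <- FALSE
  }

  ok <- converged & !all_zero
  if (any(ok)) {
    idx <- which(ok)
    eta <- b0[idx] + outer(b1[idx], x) + off[idx, , drop = FALSE]
    mu <- pmin(pmax(exp(eta), 1e-10), 1e12)
    w <- mu / (1 + alpha[idx] * mu)
    sw <- rowSums(w)
    swx <- as.vector(w %*% x)
    det <- sw * swx - swx^2
    se_b1[idx] <- sqrt(sw / det)
  }
  ok <- ok & is.finite(se_b1) & se_b1 > 0
  list(b0 = b0, b1 = b1, se_b1 = se_b1, ok = ok)
}

#' @rdname trap_de
#' @param x A contrast specification (string or list).
#' @export
parse_contrast <- function(x) {
  if (is.list(x) && !is.null(x$numerator) && !is.null(x$denominator)) {
    num <- x$numerator; den <- x$denominator
  } else if (is.character(x) && length(x) == 1) {
    parts <- strsplit(x, "\\s+vs\\s+")[[1]]
    if (length(parts) != 2)
      abort("contrast string must look like \"cKO:Cre vs WT:Cre\".")
    num <- strsplit(parts[1], ":")[[1]]
    den <- strsplit(parts[2], ":")[[1]]
  } else {
    abort("contrast must be a string or list(numerator=, denominator=).")
  }
  if (length(num) != 2 || length(den) != 2)
    abort("each contrast side must be (genotype, treatment).")
  if (identical(num, den)) abort("contrast numerator equals denominator.")
  for (side in list(num, den)) {
    if (!side[1] %in% trap_genotypes)
      abort(paste0("unknown genotype in contrast: ", side[1]))
    if (!side[2] %in% trap_treatments)
      abort(paste0("unknown treatment in contrast: ", side[2]))
  }
  list(numerator = num, denominator = den)
}

# Accept a counts tibble (gene_id + sample columns) or numeric matrix.
counts_matrix <- function(counts) {
  if (is.matrix(counts)) {
    if (is.null(rownames(counts)))
      rownames(counts) <- sprintf("gene%05d", seq_len(nrow(counts)))
    return(counts)
  }
  if (!"gene_id" %in% names(counts))
    abort("count table must have a gene_id column.")
  if (anyDuplicated(counts$gene_id)) abort("gene_ids must be unique.")
  m <- as.matrix(counts[setdiff(names(counts), "gene_id")])
  if (!is.numeric(m)) abort("count columns must be numeric.")
  rownames(m) <- counts$gene_id
  m
}
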