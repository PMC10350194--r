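#' The rescue-design contrast lattice
#'
#' Enumerates every contrast the analysis needs for a full
#' genotype-by-treatment design: for each mutant genotype, the baseline
#' contrast A = (geno, Cre) vs (WT, Cre) and, for each ICD variant, the
#' within-genotype response B = (geno, ICD) vs (geno, Cre) and the
#' residual-vs-wild-type contrast C = (geno, ICD) vs (WT, Cre); plus
#' the two wild-type ICD contrasts (WT, ICD) vs (WT, Cre). For the
#' standard 4 x 3 vocabulary this is 3 x 5 + 2 = 17 contrasts.
#'
#' @param genotypes,treatments Condition vocabulary.
#' @return A tibble: `name`, `genotype`, `icd` (`NA` for baseline
#'   contrasts), `role` (`basal`, `icd_within`, `icd_vs_wt`,
#'   `wt_icd`), `numerator`, `denominator` (each `"geno:treatment"`).
#' @export
#' @examples
#' trap_contrasts()
trap_contrasts <- function(genotypes = trap_genotypes,
                           treatments = trap_treatments) {
  icds <- setdiff(treatments, "Cre")
  mutants <- setdiff(genotypes, "WT")
  rows <- list()
  for (g in mutants) {
    rows[[length(rows) + 1]] <- tibble(
      name = paste0(g, "_basal"), genotype = g, icd = NA_character_,
      role = "basal", numerator = paste0(g, ":Cre"),
      denominator = "WT:Cre")
    for (trt in icds) {
      short <- sub("^ICD_", "", trt)
      num <- paste0(g, ":", trt)
      rows[[length(rows) + 1]] <- tibble(
        name = paste0(g, "_", short, "_within"), genotype = g, icd = short,
        role = "icd_within", numerator = num,
        denominator = paste0(g, ":Cre"))
      rows[[length(rows) + 1]] <- tibble(
        name = paste0(g, "_", short, "_vs_wt"), genotype = g, icd = short,
        role = "icd_vs_wt", numerator = num,
        denominator = "WT:Cre")
    }
  }
  for (trt in icds) {
    short <- sub("^ICD_", "", trt)
    rows[[length(rows) + 1]] <- tibble(
      name = paste0("WT_", short, "_within"), genotype = "WT", icd = short,
      role = "wt_icd", numerator = paste0("WT:", trt),
      denominator = "WT:Cre")
  }
  bind_rows(rows)
}

#' Run the full translatome rescue analysis
#'
#' End-to-end orchestration: obtain a count matrix (either supplied, or
#' simulated from ground truth), normalize, estimate dispersions, fit
#' every contrast of the lattice, classify rescue and
#' genotype-independent ICD effects per genotype, extract the relaxed
#' common module, partition the three basal gene sets supervenn-style,
#' cluster the basal log2FC matrix, optionally run overrepresentation
#' against a GMT collection, and write every stage plus a reproducible
#' manifest under `out_dir`. Re-running with an identical configuration
#' reproduces byte-identical outputs.
#'
#' @param out_dir Output directory (created if needed).
#' @param counts,design Optional count and design tibbles (or paths to
#'   their TSVs); when `counts` is `NULL` a synthetic study is
#'   generated from `n_genes`, `replicates` and `seed`.
#' @param truth Optional `trap_truth` tibble matching `counts`; when
#'   the study is simulated internally it is generated and written.
#'   When present, a truth-vs-called rescue confusion table goes into
#'   the manifest.
#' @param n_genes,replicates Synthetic study size.
#' @param seed Integer seed for every stochastic stage.
#' @param lfc_threshold,p_threshold Basal significance thresholds.
#' @param relaxed_threshold Relaxed common-module fold-change bound.
#' @param use_bh,strict Rescue-rule flags (see [call_rescue()]).
#' @param gmt Optional path to a GMT collection for enrichment of the
#'   per-genotype basal-significant sets.
#' @return Invisibly, a list with every stage result (`counts`,
#'   `design`, `size_factors`, `dispersions`, `de` (named list),
#'   `rescue` (named list per genotype), `icd_effects`, `common`,
#'   `partition`, `manifest`).
#' @export
run_pipeline <- function(out_dir,
                         counts = NULL, design = NULL, truth = NULL,
                         n_genes = 2000, replicates = 4, seed = 1,
                         lfc_threshold = 0.56, p_threshold = 0.05,
                         relaxed_threshold = 0.5,
                         use_bh = FALSE, strict = FALSE,
                         gmt = NULL) {
  stopifnot(lfc_threshold > 0, p_threshold > 0, relaxed_threshold > 0)
  seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  if (is.character(counts)) counts <- read_counts(counts)
  if (is.character(design)) design <- read_design(design)
  simulated <- is.null(counts)
  if (simulated) {
    design <- trap_design(replicates = replicates, seed = seed)
    truth <- simulate_truth(n_genes = n_genes, seed = seed + 1L)
    counts <- simulate_counts(truth, design, seed = seed + 2L)
  }
  if (is.null(design)) abort("a design is required when counts are supplied.")
  validate_design(design, require_replication = TRUE)

  write_counts(counts, file.path(out_dir, "counts.tsv"))
  write_design(design, file.path(out_dir, "design.tsv"))
  if (!is.null(truth))
    readr::write_tsv(truth, file.path(out_dir, "truth.tsv"))

  # contrast lattice, validated against the conditions actually present
  lattice <- trap_contrasts()
  present <- unique(paste(design$genotype, design$treatment, sep = ":"))
  buildable <- lattice$numerator %in% present &
    lattice$denominator %in% present
  if (!all(buildable)) {
    bad <- lattice$name[!buildable]
    abort(paste0("design lacks conditions for contrast(s): ",
                 paste(bad, collapse = ", ")))
  }

  factors <- size_factors(counts)
  dispersions <- estimate_dispersion(counts, design, factors = factors)
  readr::write_tsv(factors, file.path(out_dir, "size_factors.tsv"))
  readr::write_tsv(dispersions, file.path(out_dir, "dispersions.tsv"))

  de_dir <- file.path(out_dir, "de")
  dir.create(de_dir, showWarnings = FALSE)
  de <- purrr::map(seq_len(nrow(lattice)), function(i) {
    tab <- trap_de(counts, design,
                   paste(lattice$numerator[i], "vs", lattice$denominator[i]),
                   factors = factors, dispersions = dispersions)
    readr::write_tsv(tab, file.path(de_dir, paste0(lattice$name[i], ".tsv")))
    tab
  })
  names(de) <- lattice$name

  mutants <- setdiff(unique(lattice$genotype), "WT")
  rescue <- purrr::map(setNames(mutants, mutants), function(g) {
    classify_rescue(
      de[[paste0(g, "_basal")]],
      list(plus19 = list(vs_wt = de[[paste0(g, "_plus19_vs_wt")]],
                         within = de[[paste0(g, "_plus19_within")]]),
           delta19 = list(vs_wt = de[[paste0(g, "_delta19_vs_wt")]],
                          within = de[[paste0(g, "_delta19_within")]])),
      lfc_threshold = lfc_threshold, p_threshold = p_threshold,
      use_bh = use_bh, strict = strict)
  })
  master <- bind_rows(purrr::imap(rescue, ~ mutate(.x, genotype = .y,
                                                   .before = 1)))
  readr::write_tsv(master, file.path(out_dir, "rescue_calls.tsv"))

  basal_calls <- purrr::map(setNames(mutants, mutants), function(g) {
    call_basal(de[[paste0(g, "_basal")]], lfc_threshold, p_threshold,
               use_bh = use_bh)
  })
  icd_effects <- bind_rows(purrr::map(
    setNames(c("WT", mutants), c("WT", mutants)), function(g) {
      within <- if (g == "WT")
        list(p19 = de[["WT_plus19_within"]], d19 = de[["WT_delta19_within"]])
      else
        list(p19 = de[[paste0(g, "_plus19_within")]],
             d19 = de[[paste0(g, "_delta19_within")]])
      call_icd_effect(within$p19, within$d19,
                      basal_directions = basal_calls[[g]],
                      lfc_threshold = lfc_threshold,
                      p_threshold = p_threshold, use_bh = use_bh) |>
        mutate(genotype = g, .before = 1)
    }))
  readr::write_tsv(icd_effects, file.path(out_dir, "icd_effects.tsv"))

  common <- expanded_common(
    purrr::map(setNames(mutants, mutants),
               ~ de[[paste0(.x, "_basal")]]),
    relaxed_threshold = relaxed_threshold,
    lfc_threshold = lfc_threshold, p_threshold = p_threshold,
    use_bh = use_bh)
  readr::write_tsv(common, file.path(out_dir, "expanded_common.tsv"))

  basal_sets <- purrr::map(basal_calls,
                           ~ .x$gene_id[.x$direction != "ns"])
  partition <- membership_partition(basal_sets)
  write_table_tsv(select(partition, "pattern", "count", "genes"),
                  file.path(out_dir, "basal_partition.tsv"))

  union_sig <- sort(unique(unlist(basal_sets)))
  if (length(union_sig) >= 2) {
    lfc_mat <- vapply(mutants, function(g) {
      tab <- de[[paste0(g, "_basal")]]
      v <- tab$log2fc[match(union_sig, tab$gene_id)]
      ifelse(is.finite(v), v, 0)
    }, numeric(length(union_sig)))
    rownames(lfc_mat) <- union_sig
    hc <- hcluster_complete(lfc_mat)
    write_newick(hc, file.path(out_dir, "basal_dendrogram.nwk"))
  }

  enrich <- NULL
  if (!is.null(gmt)) {
    collection <- read_gmt(gmt)
    universe <- de[[paste0(mutants[1], "_basal")]] |>
      filter(.data$testable) |> pull("gene_id")
    enrich <- purrr::imap_dfr(basal_sets, function(genes, g) {
      hypergeom_enrich(intersect(genes, universe), collection, universe) |>
        select(-"overlap_genes") |>
        mutate(genotype = g, .before = 1)
    })
    readr::write_tsv(enrich, file.path(out_dir, "enrichment.tsv"))
  }

  confusion <- NULL
  if (!is.null(truth)) {
    confusion <- purrr::imap(rescue, function(r, g) {
      tab <- table(truth = truth$label[match(r$gene_id, truth$gene_id)],
                   called = r$category)
      as.data.frame(tab, stringsAsFactors = FALSE)
    })
  }

  files <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                        "manifest.json"))
  manifest <- list(
    package = "traprescue",
    version = as.character(utils::packageVersion("traprescue")),
    seed = seed,
    simulated = simulated,
    n_genes = nrow(counts),
    n_samples = nrow(design),
    thresholds = list(lfc = lfc_threshold, p = p_threshold,
                      relaxed = relaxed_threshold),
    flags = list(use_bh = use_bh, strict = strict),
    contrasts = lattice$name,
    row_counts = list(
      de = nrow(de[[1]]), rescue = nrow(master),
      icd_effects = nrow(icd_effects), common = nrow(common),
      partition = nrow(partition)),
    checksums = as.list(tools::md5sum(file.path(out_dir, files))) |>
      setNames(files),
    confusion = confusion
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(counts = counts, design = design, truth = truth,
                 size_factors = factors, dispersions = dispersions,
                 contrasts = lattice, de = de, rescue = rescue,
                 master = master, icd_effects = icd_effects,
                 common = common, partition = partition,
                 enrichment = enrich, manifest = manifest))
}
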