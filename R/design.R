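#' Build a sample design for a rescue-style TRAP-Seq experiment
#'
#' Constructs the sample sheet for a full genotype-by-treatment rescue
#' design: every genotype crossed with every treatment, `replicates`
#' animals per condition. Each sample also carries a true library-depth
#' multiplier (synthetic-data ground truth only; real designs read from
#' disk have none) drawn log-uniformly from `size_range`, so that
#' normalization has something to undo.
#'
#' The default of 4 replicates across the 4 x 3 condition grid yields 48
#' samples, matching the scale of the hippocampal study the package
#' models (48 amplified RNA samples from 6-9 mice per genotype split
#' across three lentiviral treatments).
#'
#' @param replicates Replicates per condition; a single integer or a
#'   vector with one entry per condition (recycled across the
#'   genotype-by-treatment grid). Conditions destined for differential
#'   testing need at least 2.
#' @param genotypes,treatments Condition vocabulary; defaults to the
#'   package vocabulary ([trap_vocabulary()]).
#' @param size_range Range of the log-uniform true size multipliers.
#' @param seed Integer seed for the size multipliers.
#' @return A tibble with columns `sample`, `genotype`, `treatment`,
#'   `replicate`, `size_multiplier`.
#' @export
#' @examples
#' trap_design(replicates = 2, seed = 1)
trap_design <- function(replicates = 4,
                        genotypes = trap_genotypes,
                        treatments = trap_treatments,
                        size_range = c(0.5, 2),
                        seed = 1) {
  stopifnot(length(size_range) == 2, all(size_range > 0),
            size_range[1] <= size_range[2])
  if (any(replicates < 1)) abort("`replicates` must be positive.")
  grid <- tidyr::expand_grid(genotype = genotypes, treatment = treatments)
  reps <- rep_len(as.integer(replicates), nrow(grid))
  design <- grid |>
    mutate(replicate_n = reps) |>
    tidyr::uncount(.data$replicate_n, .id = "replicate") |>
    mutate(sample = paste(.data$genotype, .data$treatment, .data$replicate,
                          sep = "_"))
  withr::local_seed(seed)
  u <- stats::runif(nrow(design), log(size_range[1]), log(size_range[2]))
  design |>
    mutate(size_multiplier = exp(u)) |>
    select("sample", "genotype", "treatment", "replicate", "size_multiplier")
}

#' Validate a sample design
#'
#' Checks the invariants a design must satisfy before simulation or
#' differential testing: unique sample ids, known genotype/treatment
#' labels, positive replicate indices and (optionally) at least two
#' replicates in every condition present.
#'
#' @param design A design tibble (see [trap_design()]).
#' @param require_replication If `TRUE`, every (genotype, treatment)
#'   condition present must have >= 2 replicates.
#' @return `design`, invisibly; errors describe any violation.
#' @export
validate_design <- function(design, require_replication = FALSE) {
  needed <- c("sample", "genotype", "treatment", "replicate")
  missing <- setdiff(needed, names(design))
  if (length(missing) > 0)
    abort(paste0("design lacks column(s): ", paste(missing, collapse = ", ")))
  if (anyDuplicated(design$sample))
    abort("design sample ids must be unique.")
  bad_g <- setdiff(unique(design$genotype), trap_genotypes)
  bad_t <- setdiff(unique(design$treatment), trap_treatments)
  if (length(bad_g) > 0)
    abort(paste0("unknown genotype(s): ", paste(bad_g, collapse = ", ")))
  if (length(bad_t) > 0)
    abort(paste0("unknown treatment(s): ", paste(bad_t, collapse = ", ")))
  if (any(design$replicate < 1)) abort("replicate indices must be positive.")
  if (require_replication) {
    cells <- design |>
      dplyr::count(.data$genotype, .data$treatment) |>
      filter(.data$n < 2)
    if (nrow(cells) > 0)
      abort(paste0("condition(s) with < 2 replicates: ",
                   paste(cells$genotype, cells$treatment, sep = ":",
                         collapse = ", ")))
  }
  invisible(design)
}
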