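#' Specification of a synthetic case/control expression cohort
#'
#' Describes a cohort with three kinds of genes: informative genes whose
#' class means differ by `effect_size` standard deviations, redundant genes
#' that are noisy copies of an informative parent, and null genes drawn
#' identically for both classes. The default cohort shape mirrors a typical
#' unbalanced blood-transcriptome study (106 cases vs 33 controls); all
#' counts are configurable so tests can run on smaller cohorts.
#'
#' @param n_case,n_control Samples per class (>= 1).
#' @param n_informative Number of class-informative genes.
#' @param n_redundant_per_informative Noisy copies generated per
#'   informative gene.
#' @param n_null Number of background genes with no class signal.
#' @param effect_size Standardized mean shift delta between classes, in SD
#'   units (case mean = `base_mean + effect_size * base_sd`).
#' @param redundancy_noise_sd SD of independent noise added to each
#'   redundant copy.
#' @param base_mean,base_sd Baseline expression mean and SD (log2-intensity
#'   scale).
#' @param seed Integer seed; identical spec + seed gives bit-identical
#'   cohorts.
#' @return List of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n_case = 106, n_control = 33,
                           n_informative = 5,
                           n_redundant_per_informative = 1,
                           n_null = 200,
                           effect_size = 3,
                           redundancy_noise_sd = 0.2,
                           base_mean = 8, base_sd = 1,
                           seed = 1) {
  counts <- c(n_case = n_case, n_control = n_control,
              n_informative = n_informative,
              n_redundant_per_informative = n_redundant_per_informative,
              n_null = n_null)
  if (any(counts != round(counts)) || any(counts < 0))
    stop("all counts must be non-negative integers")
  if (n_case < 1 || n_control < 1)
    stop("need at least one sample per class")
  if (base_sd <= 0) stop("`base_sd` must be > 0")
  if (redundancy_noise_sd < 0) stop("`redundancy_noise_sd` must be >= 0")
  total_genes <- n_informative * (1 + n_redundant_per_informative) + n_null
  if (total_genes < 1) stop("spec describes zero genes")
  structure(list(n_case = as.integer(n_case),
                 n_control = as.integer(n_control),
                 n_informative = as.integer(n_informative),
                 n_redundant_per_informative = as.integer(n_redundant_per_informative),
                 n_null = as.integer(n_null),
                 effect_size = effect_size,
                 redundancy_noise_sd = redundancy_noise_sd,
                 base_mean = base_mean, base_sd = base_sd,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a labeled synthetic cohort with known ground truth
#'
#' Draws every gene from normal distributions using one pseudo-random
#' stream ordered genes-then-samples (each gene's values, then its
#' redundant copies' noise, are drawn before the next gene), so enlarging
#' `n_null` leaves earlier genes' values unchanged. Cases come first in the
#' sample order. The RNG state of the caller is preserved.
#'
#' @param spec `synthetic_spec`.
#' @return List with elements `expr` (an [expression_matrix()]) and
#'   `truth` (list of class `"synthetic_truth"`: `informative_gene_ids`,
#'   `redundant_map` — named character vector redundant -> parent — and
#'   `null_gene_ids`).
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) stop("`spec` must be a synthetic_spec")
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(spec$seed)
  n <- spec$n_case + spec$n_control
  is_case <- c(rep(TRUE, spec$n_case), rep(FALSE, spec$n_control))
  sample_ids <- c(sprintf("case_%03d", seq_len(spec$n_case)),
                  sprintf("control_%03d", seq_len(spec$n_control)))
  delta <- spec$effect_size * spec$base_sd

  cols <- list()
  informative <- character(0)
  redundant_map <- character(0)
  for (i in seq_len(spec$n_informative)) {
    id <- sprintf("INF%02d", i)
    informative <- c(informative, id)
    vals <- stats::rnorm(n, mean = spec$base_mean + ifelse(is_case, delta, 0),
                         sd = spec$base_sd)
    cols[[id]] <- vals
    for (r in seq_len(spec$n_redundant_per_informative)) {
      rid <- sprintf("%s_R%d", id, r)
      cols[[rid]] <- vals + stats::rnorm(n, 0, spec$redundancy_noise_sd)
      redundant_map[rid] <- id
    }
  }
  null_ids <- if (spec$n_null > 0) sprintf("NUL%04d", seq_len(spec$n_null)) else character(0)
  for (id in null_ids)
    cols[[id]] <- stats::rnorm(n, spec$base_mean, spec$base_sd)

  values <- do.call(cbind, cols)
  rownames(values) <- sample_ids
  labels <- ifelse(is_case, "case", "control")
  expr <- expression_matrix(values, labels)
  truth <- structure(list(informative_gene_ids = informative,
                          redundant_map = redundant_map,
                          null_gene_ids = null_ids),
                     class = "synthetic_truth")
  list(expr = expr, truth = truth)
}

#' Write a synthetic cohort to disk
#'
#' Emits the matrix and label files in the layout [read_expression_table()]
#' and [read_labels()] read back, plus a two-column truth table
#' (`gene_id`, `role`) where redundant genes carry their parent as
#' `redundant:<parent>`.
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(matrix = file.path(dir, "expression.tsv"),
             labels = file.path(dir, "labels.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_expression_matrix(cohort$expr, paths["matrix"], paths["labels"])
  truth <- cohort$truth
  role <- c(stats::setNames(rep("informative", length(truth$informative_gene_ids)),
                            truth$informative_gene_ids),
            stats::setNames(paste0("redundant:", truth$redundant_map),
                            names(truth$redundant_map)),
            stats::setNames(rep("null", length(truth$null_gene_ids)),
                            truth$null_gene_ids))
  utils::write.table(data.frame(gene_id = names(role), role = unname(role)),
                     paths["truth"], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
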