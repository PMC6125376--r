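#' Hypergeometric gene-set overlap test
#'
#' Tests whether two gene sets drawn from a common universe share more
#' members than chance expects. The p-value is the one-sided upper tail
#' P(X >= k) of the hypergeometric distribution (the enrichment
#' convention); the effect size is the sample odds ratio of the implied
#' 2 x 2 table
#' (overlap, a-only, b-only, neither). Gene IDs are matched exactly after
#' upper-casing.
#'
#' @param set_a,set_b Character vectors of gene IDs (duplicates removed).
#' @param universe_size Total number of genes N the sets were drawn from;
#'   must be at least the size of the union.
#' @return List of class `"overlap_result"`: counts `k`, `a_only`,
#'   `b_only`, `neither`, `universe_size`, plus `p_value` and
#'   `odds_ratio`. A zero overlap gives odds ratio 0; a zero in the
#'   denominator (no a-only or no b-only genes) gives `Inf`.
#' @examples
#' # two 20-gene sets sharing 5 members in a 1,000-gene universe
#' overlap_test(paste0("G", 1:20), paste0("G", 16:35), 1000)
#' @export
overlap_test <- function(set_a, set_b, universe_size) {
  a <- unique(toupper(as.character(set_a)))
  b <- unique(toupper(as.character(set_b)))
  k <- length(intersect(a, b))
  union_size <- length(union(a, b))
  if (universe_size < union_size)
    stop("`universe_size` (", universe_size,
         ") is smaller than the union of the sets (", union_size, ")")
  a_only <- length(a) - k
  b_only <- length(b) - k
  neither <- universe_size - k - a_only - b_only
  p <- stats::phyper(k - 1, length(a), universe_size - length(a), length(b),
                     lower.tail = FALSE)
  odds <- if (k == 0) 0
          else if (a_only == 0 || b_only == 0) Inf
          else (k * neither) / (a_only * b_only)
  structure(list(k = k, a_only = a_only, b_only = b_only, neither = neither,
                 universe_size = universe_size, p_value = p,
                 odds_ratio = odds),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("overlap %d of %d x %d in universe %d: p = %.3g, odds ratio = %.2f\n",
              x$k, x$k + x$a_only, x$k + x$b_only, x$universe_size,
              x$p_value, x$odds_ratio))
  invisible(x)
}

#' Write an overlap test result as TSV
#'
#' @param x `overlap_result`.
#' @param path Output path.
#' @export
write_overlap <- function(x, path) {
  utils::write.table(
    data.frame(overlap = x$k, a_only = x$a_only, b_only = x$b_only,
               neither = x$neither, universe = x$universe_size,
               p_value = x$p_value, odds_ratio = x$odds_ratio),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-gene class-direction summary
#'
#' For each requested gene, reports the mean expression in cases and
#' controls and whether the gene is more highly expressed in cases
#' (`up-in-case`), in controls (`up-in-control`), or exactly tied
#' (`tied`).
#'
#' @param em `expr_matrix` with both classes present.
#' @param genes Character vector of gene IDs, all present in `em`.
#' @return Data frame of class `"direction_summary"` with columns
#'   `gene_id`, `mean_case`, `mean_control`, `direction`.
#' @export
class_direction <- function(em, genes) {
  if (!inherits(em, "expr_matrix")) stop("`em` must be an expr_matrix")
  genes <- as.character(genes)
  unknown <- setdiff(genes, colnames(em$values))
  if (length(unknown))
    stop("unknown gene ID(s): ", paste(unknown, collapse = ", "))
  case_rows <- em$labels == "case"
  mc <- colMeans(em$values[case_rows, genes, drop = FALSE])
  mk <- colMeans(em$values[!case_rows, genes, drop = FALSE])
  diff <- mc - mk
  structure(
    data.frame(gene_id = genes, mean_case = unname(mc),
               mean_control = unname(mk),
               direction = ifelse(diff > 0, "up-in-case",
                           ifelse(diff < 0, "up-in-control", "tied")),
               stringsAsFactors = FALSE),
    class = c("direction_summary", "data.frame"))
}
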