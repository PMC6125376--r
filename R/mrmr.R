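#' Relevance of a gene to the sample labels
#'
#' The mutual information between a discretized gene and the class labels,
#' the "maximal relevance" half of the mRMR objective.
#'
#' @inheritParams mutual_information
#' @param g Discretized gene vector (factor or codes).
#' @param l Label vector.
#' @return Relevance in bits.
#' @export
relevance <- function(g, l, base = 2) mutual_information(g, l, base = base)

#' Redundancy of a gene with an already-selected gene set
#'
#' The mean mutual information between a candidate gene and each selected
#' gene; zero for an empty selection (the convention that makes the first
#' ranked gene's score equal its relevance).
#'
#' @param g Discretized candidate gene (factor or codes).
#' @param selected List of discretized gene vectors already selected
#'   (possibly empty).
#' @param base Logarithm base.
#' @return Mean pairwise MI in bits; 0 when `selected` is empty.
#' @export
redundancy <- function(g, selected, base = 2) {
  if (length(selected) == 0L) return(0)
  mean(vapply(selected, function(s) mutual_information(g, s, base = base),
              numeric(1)))
}

#' Greedy minimal-redundancy maximal-relevance gene ranking
#'
#' Iteratively moves the candidate maximizing
#' relevance(g, labels) - mean MI(g, selected) from the candidate pool into
#' the ranked list, recording the objective value at selection time. The
#' first gene's score is its pure relevance. Ties are broken by input gene
#' order (first column wins). Pairwise MIs against each newly selected gene
#' are computed once per step and accumulated, which is algebraically
#' identical to naive recomputation of the mean redundancy.
#'
#' @param dm `disc_matrix` from [discretize_matrix()] (or any integer code
#'   matrix, samples x genes, with gene column names).
#' @param labels Per-sample class labels (factor or codes).
#' @param top_n Number of genes to rank; default 300 (capped at the number
#'   of genes).
#' @param base Logarithm base for MI; 2 gives bits. The ranking itself is
#'   base-invariant.
#' @return Data frame of class `"mrmr_ranking"` with columns `rank`,
#'   `gene_id`, `score`.
#' @export
mrmr_rank <- function(dm, labels, top_n = 300, base = 2) {
  D <- unclass(dm)
  if (!is.matrix(D)) stop("`dm` must be a matrix of category codes")
  if (is.null(colnames(D))) stop("`dm` must have gene column names")
  storage.mode(D) <- "integer"
  G <- ncol(D)
  if (G < 1L) stop("need at least one gene")
  if (top_n <= 0L) stop("`top_n` must be positive")
  top_n <- min(top_n, G)
  y <- as_codes(labels)

  rel <- mi_columns(D, y, base = base)
  red_sum <- numeric(G)              # cumulative MI with selected genes
  candidate <- rep(TRUE, G)
  ranked <- integer(top_n)
  scores <- numeric(top_n)
  for (m in seq_len(top_n)) {
    score <- if (m == 1L) rel else rel - red_sum / (m - 1L)
    score[!candidate] <- -Inf
    # first index wins on ties; the 1e-9 slack keeps exact-arithmetic ties
    # (common for small discrete tables) from being broken by float noise
    pick <- which(score >= max(score) - 1e-9)[1L]
    ranked[m] <- pick
    scores[m] <- score[pick]
    candidate[pick] <- FALSE
    if (m < top_n)
      red_sum <- red_sum + mi_columns(D, D[, pick], base = base)
  }
  structure(
    data.frame(rank = seq_len(top_n),
               gene_id = colnames(D)[ranked],
               score = scores,
               stringsAsFactors = FALSE),
    class = c("mrmr_ranking", "data.frame"))
}

#' Write an mRMR ranking as TSV
#'
#' Three columns: rank, gene name, mRMR score (the selection-time objective
#' value, in bits).
#'
#' @param ranking `mrmr_ranking` from [mrmr_rank()].
#' @param path Output path.
#' @export
write_ranking <- function(ranking, path) {
  utils::write.table(
    data.frame(Rank = ranking$rank, Name = ranking$gene_id,
               `mRMR score` = ranking$score, check.names = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
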