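# Independent reference implementations used as oracles. These stay naive
# (explicit loops, no shared code with the package internals) so that
# agreement is meaningful.

# Plug-in MI by direct cell-by-cell summation over the contingency table.
oracle_mi <- function(x, y, base = 2) {
  tab <- table(x, y)
  n <- sum(tab)
  total <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      nij <- tab[i, j]
      if (nij > 0) {
        pij <- nij / n
        total <- total + pij * log(pij / ((sum(tab[i, ]) / n) * (sum(tab[, j]) / n)),
                                   base = base)
      }
    }
  }
  total
}

oracle_entropy <- function(x, base = 2) {
  p <- table(x) / length(x)
  p <- p[p > 0]
  -sum(p * log(p, base = base))
}

# Naive greedy mRMR: recomputes every pairwise MI at every step from
# scratch via oracle_mi. Returns the ranked column indices and scores.
oracle_mrmr <- function(D, y, top_n = ncol(D)) {
  selected <- integer(0)
  scores <- numeric(0)
  candidates <- seq_len(ncol(D))
  while (length(selected) < top_n) {
    best <- -Inf
    best_j <- NA_integer_
    for (j in candidates) {
      rel <- oracle_mi(D[, j], y)
      red <- if (length(selected) == 0) 0 else
        mean(sapply(selected, function(s) oracle_mi(D[, j], D[, s])))
      sc <- rel - red
      if (sc > best + 1e-12) { best <- sc; best_j <- j }
    }
    selected <- c(selected, best_j)
    scores <- c(scores, best)
    candidates <- setdiff(candidates, best_j)
  }
  list(order = selected, scores = scores)
}

# Upper-tail hypergeometric P(X >= k) by exhaustive enumeration of all
# feasible overlap counts via binomial coefficients.
oracle_hyper_upper <- function(k, size_a, size_b, N) {
  lo <- max(0, size_a + size_b - N)
  hi <- min(size_a, size_b)
  total <- 0
  for (j in lo:hi) {
    if (j >= k)
      total <- total + choose(size_a, j) * choose(N - size_a, size_b - j) / choose(N, size_b)
  }
  total
}

# Small labeled expression matrix with named dims, for classifier tests.
make_expr <- function(values, labels) {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("s%02d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("g%02d", seq_len(ncol(values)))
  expression_matrix(values, labels)
}

# Map a gene ID to its planted signal cluster (a redundant copy counts as
# its informative parent).
signal_cluster <- function(ids, truth) {
  ifelse(ids %in% names(truth$redundant_map),
         truth$redundant_map[ids], ids)
}
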