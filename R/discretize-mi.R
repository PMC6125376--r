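#' Discretize a continuous vector at mean +/- SD
#'
#' Maps expression values onto three ordered categories so that categorical
#' mutual information can be computed: values strictly below mean - SD are
#' `"low"`, values strictly above mean + SD are `"high"`, everything else
#' (boundaries included) is `"mid"`. SD is the sample standard deviation
#' (n - 1 denominator) unless `sd_fun` is replaced. A constant vector has
#' SD 0 and is all `"mid"`.
#'
#' @param values Numeric vector of length >= 2.
#' @param sd_fun Function computing the spread; defaults to [stats::sd()].
#' @return Factor with levels `c("low", "mid", "high")`.
#' @examples
#' discretize(c(0, 0, 0, 10))  # thresholds -2.5 / 7.5: mid mid mid high
#' @export
discretize <- function(values, sd_fun = stats::sd) {
  if (!is.numeric(values) || length(values) < 2L)
    stop("`values` must be a numeric vector with at least 2 entries")
  m <- mean(values)
  s <- sd_fun(values)
  codes <- ifelse(values < m - s, "low", ifelse(values > m + s, "high", "mid"))
  factor(codes, levels = c("low", "mid", "high"))
}

#' Discretize every gene of an expression matrix
#'
#' Applies [discretize()] per gene (column), using that gene's mean and SD
#' over all samples. Statistics are computed on the full cohort before any
#' cross-validation; see the package vignette for the selection-bias caveat
#' this implies.
#'
#' @param x `expr_matrix` or numeric samples x genes matrix.
#' @return Integer matrix (samples x genes) with codes 1 = low, 2 = mid,
#'   3 = high and a `"levels"` attribute, class `"disc_matrix"`.
#' @export
discretize_matrix <- function(x) {
  values <- if (inherits(x, "expr_matrix")) x$values else x
  if (!is.matrix(values)) stop("`x` must be a matrix or expr_matrix")
  m <- colMeans(values)
  s <- apply(values, 2L, stats::sd)
  lo <- sweep(values, 2L, m - s, `<`)
  hi <- sweep(values, 2L, m + s, `>`)
  codes <- matrix(2L, nrow(values), ncol(values), dimnames = dimnames(values))
  codes[lo] <- 1L
  codes[hi] <- 3L
  structure(codes, levels = c("low", "mid", "high"), class = "disc_matrix")
}

#' Write a discretized matrix as TSV (codes -1/0/1)
#'
#' @param dm `disc_matrix` from [discretize_matrix()].
#' @param path Output path.
#' @export
write_discretized <- function(dm, path) {
  out <- unclass(dm) - 2L   # low/mid/high -> -1/0/1
  df <- data.frame(sample_id = rownames(out), out,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Coerce a categorical input (factor, character, integer, logical) to
# integer codes 1..K. Used by every MI entry point.
as_codes <- function(x) {
  if (is.factor(x)) return(as.integer(x))
  if (is.character(x) || is.logical(x)) return(as.integer(factor(x)))
  if (is.numeric(x)) {
    if (any(x != round(x))) stop("categorical input must not be continuous")
    return(match(x, sort(unique(x))))
  }
  stop("cannot interpret input as categorical")
}

#' Mutual information between two categorical vectors
#'
#' Plug-in (maximum-likelihood) estimate
#' \deqn{I(X;Y) = \sum_{a,b} \hat p(a,b)\, \log_2 \frac{\hat p(a,b)}
#'   {\hat p(a)\,\hat p(b)},}
#' with empty cells contributing zero. Reported in bits (log base 2) by
#' default; the mRMR ranking is invariant to the base because relevance and
#' redundancy scale together.
#'
#' @param x,y Categorical vectors (factor, character, integer codes) of
#'   equal length.
#' @param base Logarithm base; 2 gives bits.
#' @return Non-negative numeric scalar.
#' @examples
#' mutual_information(c(0, 0, 1, 1), c(0, 0, 1, 1))  # 1 bit
#' @export
mutual_information <- function(x, y, base = 2) {
  if (length(x) != length(y))
    stop("`x` and `y` must have equal length (", length(x), " vs ", length(y), ")")
  tab <- table(x, y)
  n <- sum(tab)
  pxy <- tab / n
  px <- rowSums(pxy)
  py <- colSums(pxy)
  pp <- outer(px, py)
  nz <- pxy > 0
  max(0, sum(pxy[nz] * log(pxy[nz] / pp[nz], base = base)))
}

# Vectorized MI of one categorical vector `y` (integer codes 1..L) against
# every column of an integer code matrix D (samples x genes). Same plug-in
# estimator as mutual_information(); used by the mRMR greedy loop where
# thousands of pairwise MIs are needed.
mi_columns <- function(D, y, base = 2) {
  n <- nrow(D)
  if (length(y) != n) stop("length of `y` must equal nrow(D)")
  ymax <- max(y)
  xmax <- max(D)
  py <- tabulate(y, nbins = ymax) / n
  mi <- numeric(ncol(D))
  px <- matrix(vapply(seq_len(xmax), function(b) colSums(D == b),
                      numeric(ncol(D))), ncol = xmax) / n
  for (a in seq_len(ymax)) {
    if (py[a] == 0) next
    Da <- D[y == a, , drop = FALSE]
    for (b in seq_len(xmax)) {
      pab <- colSums(Da == b) / n
      nz <- pab > 0
      mi[nz] <- mi[nz] + pab[nz] * log(pab[nz] / (px[nz, b] * py[a]), base = base)
    }
  }
  pmax(mi, 0)
}
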