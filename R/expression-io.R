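#' Labeled expression matrix
#'
#' Bundles a samples x genes numeric matrix with a binary phenotype label
#' per sample. The positive class (cases, e.g. OA patients) is always the
#' factor level `"case"`; controls are `"control"`.
#'
#' @param values Numeric matrix, samples in rows, genes in columns, with
#'   unique row (sample) and column (gene) names and finite values.
#' @param labels Character or factor vector of per-sample labels, one per
#'   row of `values`, either in `values` row order or named by sample ID.
#' @param case_aliases,control_aliases Label spellings mapped to
#'   `"case"` / `"control"` (case-insensitive). `"OA"` is accepted as a
#'   case alias by default.
#' @return An object of class `"expr_matrix"`: a list with elements
#'   `values` (the matrix) and `labels` (factor with levels
#'   `c("control", "case")`, named by sample ID).
#' @export
expression_matrix <- function(values, labels,
                              case_aliases = c("case", "oa"),
                              control_aliases = c("control", "normal", "healthy")) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (samples x genes)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have sample row names and gene column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample IDs in `values`")
  if (anyDuplicated(colnames(values)))
    stop("duplicate gene IDs in `values`")
  if (!all(is.finite(values)))
    stop("`values` contains non-finite entries")
  if (!is.null(names(labels))) {
    missing <- setdiff(rownames(values), names(labels))
    if (length(missing))
      stop("labels missing for samples: ", paste(missing, collapse = ", "))
    labels <- labels[rownames(values)]
  } else if (length(labels) != nrow(values)) {
    stop("`labels` must have one entry per sample")
  }
  lab <- tolower(as.character(labels))
  canon <- ifelse(lab %in% tolower(case_aliases), "case",
           ifelse(lab %in% tolower(control_aliases), "control", NA_character_))
  if (anyNA(canon))
    stop("unrecognized label(s): ",
         paste(unique(labels[is.na(canon)]), collapse = ", "))
  labels <- factor(canon, levels = c("control", "case"))
  names(labels) <- rownames(values)
  if (nlevels(droplevels(labels)) < 2)
    stop("both classes (case and control) must be present")
  structure(list(values = values, labels = labels), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d samples x %d genes (%d case, %d control)\n",
              nrow(x$values), ncol(x$values),
              sum(x$labels == "case"), sum(x$labels == "control")))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Read a tab-separated expression table
#'
#' Reads a TSV matrix with one header row of IDs and one leading ID column.
#' Lines beginning with `!` (GEO series-matrix metadata) are skipped, as are
#' blank lines. The result is always oriented samples x probes regardless of
#' the file orientation.
#'
#' @param path Path to the TSV file.
#' @param orientation Either `"samples"` (rows of the file are samples) or
#'   `"probes"` (rows are probes/genes; the matrix is transposed on read).
#' @return Numeric matrix, samples in rows, probes (or genes) in columns.
#' @export
read_expression_table <- function(path, orientation = c("samples", "probes")) {
  orientation <- match.arg(orientation)
  raw <- readLines(path)
  keep <- !startsWith(raw, "!") & nzchar(trimws(raw))
  lineno <- which(keep)          # original line numbers of retained lines
  raw <- raw[keep]
  if (length(raw) < 2L)
    stop("parse error in '", path, "': need a header row and at least one data row")
  fields <- strsplit(raw, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != nf[1L])) {
    bad <- which(nf != nf[1L])[1L]
    stop("parse error in '", path, "' at line ", lineno[bad],
         ": expected ", nf[1L], " fields, found ", nf[bad])
  }
  header <- fields[[1L]][-1L]
  row_ids <- vapply(fields[-1L], `[[`, character(1), 1L)
  if (anyDuplicated(header))
    stop("parse error in '", path, "': duplicate column ID(s): ",
         paste(unique(header[duplicated(header)]), collapse = ", "))
  if (anyDuplicated(row_ids))
    stop("parse error in '", path, "': duplicate row ID(s): ",
         paste(unique(row_ids[duplicated(row_ids)]), collapse = ", "))
  body <- vapply(fields[-1L], function(f) f[-1L], character(length(header)))
  # body is columns-of-file x rows-of-file when length(header) > 1
  body <- matrix(body, nrow = length(header))
  num <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop("parse error in '", path, "' at line ", lineno[bad[2L] + 1L],
         ": non-numeric value '", body[bad[1L], bad[2L]],
         "' in column '", header[bad[1L]], "'")
  }
  m <- t(num)
  dimnames(m) <- list(row_ids, header)
  if (orientation == "probes") m <- t(m)
  m
}

#' Read a two-column sample label file
#'
#' @param path TSV with columns `sample_id` and `label` (header optional;
#'   detected by a non-data first line).
#' @return Character vector of raw labels named by sample ID. Combine with
#'   an expression matrix via [expression_matrix()], which canonicalizes
#'   aliases such as `"OA"`.
#' @export
read_labels <- function(path) {
  df <- utils::read.delim(path, header = FALSE, colClasses = "character",
                          comment.char = "!")
  if (ncol(df) != 2L)
    stop("label file '", path, "' must have exactly two columns")
  if (tolower(df[1L, 1L]) %in% c("sample_id", "sample", "id"))
    df <- df[-1L, , drop = FALSE]
  if (anyDuplicated(df[[1L]]))
    stop("duplicate sample ID(s) in label file '", path, "'")
  stats::setNames(df[[2L]], df[[1L]])
}

#' Collapse probe-level values to gene level by averaging
#'
#' Probes mapping to the same gene are replaced by their per-sample
#' arithmetic mean, the standard summarization for beadchip arrays where
#' several probes interrogate one gene. Probes absent from the mapping are
#' dropped with a message stating how many were lost.
#'
#' @param pm Numeric matrix, samples x probes (see
#'   [read_expression_table()]).
#' @param mapping Data frame whose first two columns are probe ID and gene
#'   ID.
#' @return Numeric matrix, samples x genes. Gene order follows the first
#'   appearance of each gene along the probe order of `pm`.
#' @export
collapse_probes <- function(pm, mapping) {
  if (!is.matrix(pm) || is.null(colnames(pm)))
    stop("`pm` must be a samples x probes matrix with probe column names")
  if (!is.data.frame(mapping) || ncol(mapping) < 2L || nrow(mapping) == 0L)
    stop("`mapping` must be a non-empty data frame with probe and gene columns")
  map <- stats::setNames(as.character(mapping[[2L]]), as.character(mapping[[1L]]))
  probes <- colnames(pm)
  mapped <- probes %in% names(map)
  if (!any(mapped)) stop("no probe of `pm` appears in `mapping`")
  if (any(!mapped))
    message(sum(!mapped), " unmapped probe(s) dropped")
  pm <- pm[, mapped, drop = FALSE]
  gene <- map[colnames(pm)]
  # rowsum on the transposed matrix sums probes per gene, in first-appearance
  # order (reorder = FALSE); divide by probe counts to get means
  sums <- rowsum(t(pm), group = gene, reorder = FALSE)
  counts <- as.vector(table(factor(gene, levels = rownames(sums))))
  t(sums / counts)
}

#' Quantile-normalize an expression matrix across samples
#'
#' Forces every sample's value distribution onto the common reference
#' distribution (the across-sample mean of sorted values at each rank).
#' Tied values within a sample receive the mean of the reference values at
#' their tied ranks. Delegates to [limma::normalizeQuantiles()].
#'
#' @param x Numeric matrix (samples x genes) or an `expr_matrix`.
#' @return Object of the same type with normalized values.
#' @export
quantile_normalize <- function(x) {
  if (inherits(x, "expr_matrix")) {
    x$values <- quantile_normalize(x$values)
    return(x)
  }
  if (!is.matrix(x) || !is.numeric(x)) stop("`x` must be a numeric matrix")
  # limma normalizes columns, which it takes to be arrays/samples
  out <- t(limma::normalizeQuantiles(t(x), ties = TRUE))
  dimnames(out) <- dimnames(x)
  out
}

#' Write an expression matrix (and labels) as TSV
#'
#' Emits the samples x genes layout that [read_expression_table()] reads
#' back with `orientation = "samples"`, and optionally a two-column label
#' file.
#'
#' @param x `expr_matrix` or plain numeric matrix.
#' @param path Output TSV path for the matrix.
#' @param labels_path Optional path for the `sample_id<TAB>label` file
#'   (only written when `x` carries labels).
#' @export
write_expression_matrix <- function(x, path, labels_path = NULL) {
  values <- if (inherits(x, "expr_matrix")) x$values else x
  # %.17g survives a write/read round trip bit-exactly for doubles
  txt <- matrix(sprintf("%.17g", values), nrow(values),
                dimnames = dimnames(values))
  df <- data.frame(sample_id = rownames(values), txt,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(labels_path) && inherits(x, "expr_matrix")) {
    utils::write.table(
      data.frame(sample_id = names(x$labels), label = as.character(x$labels)),
      labels_path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
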