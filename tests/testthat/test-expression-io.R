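write_tsv_lines <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

test_that("expression tables are returned samples x probes for both file orientations", {
  # file rows are probes: 3 probes x 2 samples
  path <- write_tsv_lines(c("probe\tsA\tsB",
                            "p1\t1\t2",
                            "p2\t3\t4",
                            "p3\t5\t6"))
  m <- read_expression_table(path, orientation = "probes")
  expect_equal(dim(m), c(2L, 3L))
  expect_equal(rownames(m), c("sA", "sB"))
  expect_equal(m["sB", "p2"], 4)
  # same numbers laid out samples-in-rows give the identical matrix
  path2 <- write_tsv_lines(c("sample\tp1\tp2\tp3",
                             "sA\t1\t3\t5",
                             "sB\t2\t4\t6"))
  expect_identical(read_expression_table(path2, orientation = "samples"), m)
})

test_that("parse errors name the offending line or ID", {
  dup <- write_tsv_lines(c("probe\tsA\tsB", "p1\t1\t2", "p1\t3\t4"))
  expect_error(read_expression_table(dup, "probes"), "duplicate row ID.*p1")
  ragged <- write_tsv_lines(c("probe\tsA\tsB", "p1\t1\t2", "p2\t3"))
  expect_error(read_expression_table(ragged, "probes"), "line 3")
  alpha <- write_tsv_lines(c("probe\tsA\tsB", "p1\t1\t2", "p2\tx\t4"))
  expect_error(read_expression_table(alpha, "probes"), "line 3.*non-numeric|non-numeric.*line 3")
})

test_that("GEO series-matrix metadata lines are skipped", {
  path <- write_tsv_lines(c("!Series_title\tfoo",
                            "!Sample_geo_accession\tGSM1\tGSM2",
                            "ID_REF\tGSM1\tGSM2",
                            "p1\t1.5\t2.5"))
  m <- read_expression_table(path, "probes")
  expect_equal(dim(m), c(2L, 1L))
  expect_equal(unname(m[, "p1"]), c(1.5, 2.5))
})

test_that("write-then-read round trip is exact", {
  set.seed(11)
  values <- matrix(rnorm(12) * 1e3, 3, 4,
                   dimnames = list(paste0("s", 1:3), paste0("g", 1:4)))
  path <- tempfile(fileext = ".tsv")
  write_expression_matrix(values, path)
  expect_identical(read_expression_table(path, "samples"), values)
})

test_that("probe collapsing averages probes per gene in first-appearance order", {
  # hand example: p1=2, p2=4 both -> geneA, single sample
  pm <- matrix(c(2, 4), 1, 2, dimnames = list("s1", c("p1", "p2")))
  em <- collapse_probes(pm, data.frame(probe = c("p1", "p2"),
                                       gene = c("geneA", "geneA")))
  expect_equal(unname(em[1, "geneA"]), 3)

  # 4 probes over 2 genes, 3 samples, vs direct hand computation;
  # gene order follows first appearance along the probe order
  pm <- matrix(c(1, 2, 3,
                 5, 6, 7,
                 2, 4, 6,
                 10, 20, 30), nrow = 3,
               dimnames = list(paste0("s", 1:3), c("pB1", "pA1", "pB2", "pA2")))
  map <- data.frame(probe = c("pA1", "pA2", "pB1", "pB2"),
                    gene = c("gA", "gA", "gB", "gB"))
  em <- collapse_probes(pm, map)
  expect_equal(colnames(em), c("gB", "gA"))   # pB1 appears first
  expect_equal(unname(em[, "gA"]), c((5 + 10) / 2, (6 + 20) / 2, (7 + 30) / 2))
  expect_equal(unname(em[, "gB"]), c((1 + 2) / 2, (2 + 4) / 2, (3 + 6) / 2))
  expect_equal(nrow(em), nrow(pm))

  # single-probe gene passes through unchanged
  em1 <- collapse_probes(pm[, "pA1", drop = FALSE],
                         data.frame(probe = "pA1", gene = "gA"))
  expect_equal(unname(em1[, "gA"]), unname(pm[, "pA1"]))
})

test_that("unmapped probes are dropped with a count; empty mapping errors", {
  pm <- matrix(1:6, 2, 3, dimnames = list(c("s1", "s2"), c("p1", "p2", "p3")))
  expect_message(em <- collapse_probes(pm, data.frame(probe = c("p1", "p2"),
                                                      gene = c("gA", "gB"))),
                 "1 unmapped")
  expect_equal(colnames(em), c("gA", "gB"))
  expect_error(collapse_probes(pm, data.frame(probe = character(0),
                                              gene = character(0))),
               "non-empty")
})

test_that("quantile normalization maps samples onto the rank-mean reference", {
  # hand-computed: sorted means of (2,4,6) and (3,6,9) are (2.5, 5, 7.5)
  m <- rbind(sA = c(2, 4, 6), sB = c(9, 3, 6))
  colnames(m) <- paste0("g", 1:3)
  qn <- quantile_normalize(m)
  expect_equal(unname(qn["sA", ]), c(2.5, 5, 7.5))
  expect_equal(unname(qn["sB", ]), c(7.5, 2.5, 5))  # original rank order kept
})

test_that("quantile normalization postconditions and idempotence hold", {
  set.seed(5)
  m <- matrix(rexp(60, 1 / 50), nrow = 5,
              dimnames = list(paste0("s", 1:5), paste0("g", 1:12)))
  qn <- quantile_normalize(m)
  # all samples share one value multiset afterwards
  sorted <- apply(qn, 1, sort)
  expect_true(all(abs(sorted - sorted[, 1]) < 1e-12))
  # within-sample rank order preserved (tie-free input)
  for (i in seq_len(nrow(m)))
    expect_equal(order(qn[i, ]), order(m[i, ]))
  # idempotent to 1e-9
  expect_equal(quantile_normalize(qn), qn, tolerance = 1e-9)
  # identical samples are a fixed point
  flat <- matrix(rep(c(1, 5, 9), each = 3), nrow = 3, byrow = FALSE,
                 dimnames = list(paste0("s", 1:3), paste0("g", 1:3)))
  expect_equal(quantile_normalize(flat), flat)
})

test_that("label handling canonicalizes aliases and validates coverage", {
  values <- matrix(rnorm(6), 3, 2,
                   dimnames = list(c("s1", "s2", "s3"), c("g1", "g2")))
  em <- expression_matrix(values, c(s1 = "OA", s2 = "control", s3 = "oa"))
  expect_equal(as.character(em$labels), c("case", "control", "case"))
  expect_error(expression_matrix(values, c(s1 = "OA", s2 = "control")),
               "missing.*s3")
  expect_error(expression_matrix(values, c(s1 = "OA", s2 = "weird", s3 = "OA")),
               "unrecognized")
  expect_error(expression_matrix(values, c(s1 = "OA", s2 = "OA", s3 = "OA")),
               "both classes")
})
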